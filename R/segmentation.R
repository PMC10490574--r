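#' 5x5 median filter
#'
#' Each output pixel is the median of its 5x5 neighbourhood; edges are
#' handled by reflection. This is the standard salt-and-pepper denoising
#' step applied before segmentation.
#'
#' @param image A [pfb_image] or matrix, at least 5x5.
#' @return Same type as the input, filtered.
#' @export
median_filter5 <- function(image) {
  px <- as_pixels(image)
  if (nrow(px) < 5 || ncol(px) < 5) {
    stop_pfb("image smaller than the 5x5 median kernel", "pfbmri_size_error")
  }
  p <- reflect_pad(px, 2)
  nr <- nrow(px)
  nc <- ncol(px)
  stack <- matrix(0, nr * nc, 25)
  k <- 0
  for (dr in -2:2) {
    for (dc in -2:2) {
      k <- k + 1
      stack[, k] <- p[(3 + dr):(nr + 2 + dr), (3 + dc):(nc + 2 + dc)]
    }
  }
  out <- matrix(apply(stack, 1, median), nr, nc)
  if (inherits(image, "pfb_image")) {
    image$pixels <- out
    image
  } else {
    out
  }
}

#' Region growing bounded by Canny edges
#'
#' Computes a Canny edge map, flood-fills (4-connectivity) the complement
#' of the dilated edge map from the seed, re-dilates the grown region to
#' compensate the edge-band erosion, then applies morphological closing
#' (5-px disc) and hole filling. The result always contains the seed and
#' has exactly one foreground component.
#'
#' @param image A [pfb_image] or matrix (ideally median-filtered first).
#' @param seed `(row, col)` seed pixel inside the bone.
#' @param ... Passed to [canny_edges()].
#' @return A [pfb_mask] with `method = "region_growing"`.
#' @export
region_grow_canny <- function(image, seed, ...) {
  px <- as_pixels(image)
  nr <- nrow(px)
  nc <- ncol(px)
  seed <- round(seed)
  if (seed[1] < 1 || seed[1] > nr || seed[2] < 1 || seed[2] > nc) {
    stop_pfb("seed lies outside the image", "pfbmri_param_error")
  }
  edges <- canny_edges(px, ...)
  if (edges[seed[1], seed[2]]) {
    stop_pfb("seed lies on an edge pixel", "pfbmri_seed_error")
  }
  kern3 <- EBImage::makeBrush(3, "box")
  blocked <- EBImage::dilate(edges * 1, kern3) > 0
  if (blocked[seed[1], seed[2]]) {
    stop_pfb("seed lies on the dilated edge band", "pfbmri_seed_error")
  }
  lab <- EBImage::bwlabel((!blocked) * 1)
  region <- lab == lab[seed[1], seed[2]]
  border <- c(region[1, ], region[nr, ], region[, 1], region[, nc])
  if (mean(border) > 0.5) {
    stop_pfb("region flooded to the image border: segmentation failure",
             "pfbmri_seg_failure")
  }
  # re-dilate (box then diamond) to compensate the ~1.5 px erosion left by
  # flooding the complement of the dilated edge band
  grown <- EBImage::dilate(EBImage::dilate(region * 1, kern3),
                           EBImage::makeBrush(3, "diamond")) > 0
  closed <- EBImage::closing(grown * 1, EBImage::makeBrush(5, "disc")) > 0
  filled <- EBImage::fillHull(closed * 1) > 0
  lab2 <- EBImage::bwlabel(filled * 1)
  id <- lab2[seed[1], seed[2]]
  if (id == 0) id <- which.max(tabulate(lab2[lab2 > 0]))
  final <- lab2 == id
  final[seed[1], seed[2]] <- TRUE
  pfb_mask(final, method = "region_growing", seed = seed)
}

#' Active-contour segmentation (morphological Chan-Vese)
#'
#' Evolves a binary level set from an initial circle by the region-based
#' Chan-Vese energy: boundary pixels join whichever side (foreground /
#' background mean) they are closer to in intensity, with a 3x3 median
#' smoothing of the interface each iteration. The scheme is deterministic,
#' grows contiguously from the initialisation, and stops at the bone
#' boundary where the two region means separate.
#'
#' @param image A [pfb_image] or matrix.
#' @param init_center `(row, col)` centre of the initial circle.
#' @param init_radius Initial circle radius (must fit inside the image).
#' @param iterations Iteration cap.
#' @param smoothing Number of median-smoothing passes per iteration.
#' @return A [pfb_mask] with `method = "active_contour"`.
#' @export
active_contour_segment <- function(image, init_center, init_radius,
                                   iterations = 200, smoothing = 1) {
  px <- as_pixels(image)
  nr <- nrow(px)
  nc <- ncol(px)
  ctr <- as.numeric(init_center)
  r <- init_radius
  if (ctr[1] - r < 1 || ctr[1] + r > nr || ctr[2] - r < 1 || ctr[2] + r > nc) {
    stop_pfb("initial circle must lie fully inside the image",
             "pfbmri_param_error")
  }
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  u <- matrix((g$r - ctr[1])^2 + (g$c - ctr[2])^2 <= r^2, nr, nc)
  init <- u
  sm <- EBImage::gblur(px, sigma = 1)
  # 3x3 neighbourhood sum by shifted adds: cheap dilate/erode/majority
  nsum3 <- function(b) {
    s <- matrix(0, nrow(b), ncol(b))
    for (dr in -1:1) for (dc in -1:1) s <- s + shift_matrix(b, dr, dc, 0)
    s
  }
  for (it in seq_len(iterations)) {
    a <- sum(u)
    if (a < 10) {
      stop_pfb("contour collapsed below 10 pixels", "pfbmri_seg_failure")
    }
    if (a == length(u)) break
    c1 <- mean(sm[u])
    c0 <- mean(sm[!u])
    ns <- nsum3(u * 1)
    band <- ns > 0 & ns < 9 # boundary band: mixed 3x3 neighbourhood
    newu <- u
    newu[band] <- (sm[band] - c1)^2 < (sm[band] - c0)^2
    for (s in seq_len(smoothing)) {
      newu <- nsum3(newu * 1) >= 5 # 3x3 binary median = majority
    }
    if (identical(newu, u)) break
    u <- newu
  }
  if (sum(u) < 10) {
    stop_pfb("contour collapsed below 10 pixels", "pfbmri_seg_failure")
  }
  lab <- EBImage::bwlabel(u * 1)
  ids <- lab[init & u]
  ids <- ids[ids > 0]
  if (!length(ids)) {
    stop_pfb("contour drifted away from its initialisation",
             "pfbmri_seg_failure")
  }
  final <- lab == as.integer(names(which.max(table(ids))))
  final <- EBImage::fillHull(final * 1) > 0
  border <- c(final[1, ], final[nr, ], final[, 1], final[, nc])
  if (mean(border) > 0.5) {
    stop_pfb("contour flooded to the image border: segmentation failure",
             "pfbmri_seg_failure")
  }
  pfb_mask(final, method = "active_contour",
           seed = round(ctr))
}

check_mask_pair <- function(S, T_) {
  s <- as_mask_matrix(S)
  t <- as_mask_matrix(T_)
  if (!all(dim(s) == dim(t))) {
    stop_pfb("masks must lie on congruent grids", "pfbmri_param_error")
  }
  list(s = s, t = t)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |S intersect T| / (|S| + |T|)`.
#'
#' @param S,T_ Segmentation and reference masks ([pfb_mask] or logical
#'   matrices) on congruent grids.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(S, T_) {
  p <- check_mask_pair(S, T_)
  denom <- sum(p$s) + sum(p$t)
  if (denom == 0) {
    stop_pfb("DSC undefined: both masks are empty", "pfbmri_metric_error")
  }
  2 * sum(p$s & p$t) / denom
}

#' Intersection over union (Jaccard index)
#'
#' `IoU = |S intersect T| / |S union T|`.
#'
#' @inheritParams dsc
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(S, T_) {
  p <- check_mask_pair(S, T_)
  denom <- sum(p$s | p$t)
  if (denom == 0) {
    stop_pfb("IoU undefined: both masks are empty", "pfbmri_metric_error")
  }
  sum(p$s & p$t) / denom
}

# Convex-hull solidity of a mask: area / filled-hull area, hull filled by
# even-odd scanline rasterisation of the chull() polygon.
mask_solidity <- function(m) {
  pts <- which(m, arr.ind = TRUE)
  if (nrow(pts) < 3) return(1)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  poly <- pts[h, , drop = FALSE]
  hull <- fill_polygon(poly, nrow(m), ncol(m))
  sum(m) / max(sum(hull), sum(m))
}

# Even-odd scanline polygon fill; vertices as (row, col) matrix.
fill_polygon <- function(poly, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  yv <- poly[, 1]
  xv <- poly[, 2]
  n <- nrow(poly)
  for (row in seq_len(nr)) {
    y <- row
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((yv[i] > y) != (yv[j] > y)) {
        xs <- c(xs, xv[i] + (y - yv[i]) / (yv[j] - yv[i]) * (xv[j] - xv[i]))
      }
      j <- i
    }
    xs <- sort(xs)
    if (length(xs) >= 2) {
      for (k in seq(1, length(xs) - 1, by = 2)) {
        lo <- max(1, ceiling(xs[k]))
        hi <- min(nc, floor(xs[k + 1]))
        if (lo <= hi) out[row, lo:hi] <- TRUE
      }
    }
  }
  out | {
    # include the vertices themselves
    v <- matrix(FALSE, nr, nc)
    v[cbind(pmin(pmax(round(yv), 1), nr), pmin(pmax(round(xv), 1), nc))] <- TRUE
    v
  }
}

#' Segment with both methods and keep the better mask
#'
#' Runs the full segmentation stage: 5x5 median filtering, region growing
#' from a Hough-circle seed (falling back to the histogram-projection
#' seed), and the active contour initialised at 1.5x the Hough radius.
#' When a ground-truth mask is available the higher-DSC result wins (ties
#' prefer region growing). Without ground truth a plausibility screen is
#' applied (single component, area within `area_bounds` as a fraction of
#' the image, convex-hull solidity at least `solidity_min`). If both
#' methods fail, `manual_mask_path` (a 0/255 PNG) is loaded as a manual
#' delineation fallback.
#'
#' @param image A [pfb_image] or matrix.
#' @param truth Optional ground-truth [pfb_mask].
#' @param manual_mask_path Optional path to a manual-mask PNG fallback.
#' @param radius_range Hough radius range (defaults per [seed_by_hough()]).
#' @param area_bounds Plausible mask area as a fraction of the image.
#' @param solidity_min Minimum convex-hull solidity for the screen.
#' @return A [pfb_mask]; the chosen method is recorded in `$method` and
#'   per-method diagnostics in attribute `"candidates"`.
#' @export
segment_best <- function(image, truth = NULL, manual_mask_path = NULL,
                         radius_range = NULL, area_bounds = c(0.02, 0.40),
                         solidity_min = 0.70) {
  px <- as_pixels(image)
  f <- median_filter5(px)
  reasons <- list()

  hough <- tryCatch(seed_by_hough(f, radius_range = radius_range),
                    error = function(e) e)
  seed <- if (inherits(hough, "error")) {
    tryCatch(seed_by_histogram_max(f), error = function(e) e)
  } else {
    c(hough[1], hough[2])
  }

  rg <- if (inherits(seed, "error")) {
    reasons$region_growing <- conditionMessage(seed)
    NULL
  } else {
    tryCatch(region_grow_canny(f, seed), error = function(e) {
      reasons$region_growing <<- conditionMessage(e)
      NULL
    })
  }

  nr <- nrow(px)
  nc <- ncol(px)
  if (!inherits(hough, "error")) {
    ctr <- c(hough[1], hough[2])
    rad <- 1.5 * attr(hough, "radius")
  } else if (!inherits(seed, "error")) {
    ctr <- seed
    rad <- 0.25 * min(nr, nc)
  } else {
    ctr <- NULL
  }
  ac <- if (is.null(ctr)) {
    reasons$active_contour <- "no seed available for initialisation"
    NULL
  } else {
    rad <- min(rad, ctr[1] - 1, nr - ctr[1], ctr[2] - 1, nc - ctr[2])
    if (rad < 5) {
      reasons$active_contour <- "initial circle does not fit inside the image"
      NULL
    } else {
      tryCatch(active_contour_segment(f, ctr, rad), error = function(e) {
        reasons$active_contour <<- conditionMessage(e)
        NULL
      })
    }
  }

  candidates <- Filter(Negate(is.null), list(region_growing = rg,
                                             active_contour = ac))
  pick <- NULL
  if (length(candidates)) {
    if (!is.null(truth)) {
      scores <- vapply(candidates, function(m) dsc(m, truth), numeric(1))
      pick <- candidates[[which.max(scores)]]
      attr(pick, "dsc") <- max(scores)
    } else {
      plausible <- vapply(candidates, function(m) {
        afrac <- sum(m$mask) / length(m$mask)
        afrac >= area_bounds[1] && afrac <= area_bounds[2] &&
          mask_solidity(m$mask) >= solidity_min
      }, logical(1))
      if (any(plausible)) {
        pick <- candidates[plausible][[1]] # list order prefers region growing
      } else {
        for (nm in names(candidates)) {
          reasons[[nm]] <- "mask failed the plausibility screen"
        }
      }
    }
  }
  if (is.null(pick)) {
    if (!is.null(manual_mask_path)) {
      pick <- read_mask_png(manual_mask_path, method = "manual_file")
    } else {
      stop_pfb(paste0("segmentation failed by both methods: ",
                      paste(sprintf("[%s] %s", names(reasons),
                                    unlist(reasons)), collapse = "; ")),
               "pfbmri_seg_failure")
    }
  }
  attr(pick, "candidates") <- lapply(candidates, function(m) sum(m$mask))
  pick
}
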