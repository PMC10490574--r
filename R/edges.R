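# Canny edge detection and circular Hough transform. No installed R
# package provides these, so they are implemented here on top of base
# matrix arithmetic and EBImage morphology: Gaussian blur -> Sobel
# gradients -> non-maximum suppression -> hysteresis by connected-component
# labeling; the Hough accumulator is vectorised over perimeter offsets.

sobel_gradients <- function(px) {
  p <- reflect_pad(px, 1)
  s <- function(dr, dc) p[(2 + dr):(nrow(px) + 1 + dr),
                          (2 + dc):(ncol(px) + 1 + dc)]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
        (s(-1, -1) + 2 * s(0, -1) + s(1, -1))   # d/dcol
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
        (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))   # d/drow
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' gradient direction, and two-threshold hysteresis (weak-edge components
#' are kept only when they contain a strong pixel). Hysteresis thresholds
#' are the `lo_quantile`/`hi_quantile` quantiles of the supported
#' (above-floor) gradient magnitudes.
#'
#' @param image A [pfb_image] or matrix.
#' @param sigma Gaussian blur SD in pixels.
#' @param lo_quantile,hi_quantile Hysteresis quantiles of the gradient
#'   magnitude (defaults 0.70 / 0.90).
#' @return Logical edge matrix.
#' @export
canny_edges <- function(image, sigma = 1.4, lo_quantile = 0.70,
                        hi_quantile = 0.90) {
  px <- as_pixels(image)
  sm <- EBImage::gblur(px, sigma = sigma)
  g <- sobel_gradients(sm)
  mag <- g$mag
  if (max(mag) <= 0) {
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  # fold gradient angle into [0, 180) and bin to 0/45/90/135 degrees
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  bin <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4 # 0,45,90,135
  nbr <- function(dr, dc) shift_matrix(mag, dr, dc, 0)
  keep <-
    (bin == 0 & mag >= nbr(0, 1) & mag >= nbr(0, -1)) |
    (bin == 1 & mag >= nbr(1, 1) & mag >= nbr(-1, -1)) |
    (bin == 2 & mag >= nbr(1, 0) & mag >= nbr(-1, 0)) |
    (bin == 3 & mag >= nbr(1, -1) & mag >= nbr(-1, 1))
  nms <- ifelse(keep, mag, 0)
  # quantiles over the full magnitude distribution (background included),
  # floored at a small fraction of the peak so flat images with exact-zero
  # quantiles do not admit numerical dust
  hi <- max(quantile(mag, hi_quantile, names = FALSE), 0.05 * max(nms))
  lo <- max(quantile(mag, lo_quantile, names = FALSE), 0.025 * max(nms))
  strong <- nms >= hi
  weak <- nms >= lo
  if (!any(strong)) {
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  lab <- EBImage::bwlabel(weak * 1)
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  matrix(lab %in% keep_ids, nrow(px), ncol(px))
}

#' Hough-circle seed point
#'
#' Finds the centre of the highest-scoring circle over Canny edge pixels
#' with radius inside `radius_range`. The accumulator is normalised by the
#' perimeter length so different radii are comparable, and lightly
#' box-smoothed to absorb radius quantisation. The femoral head is the
#' dominant circular structure in a hip slice, so its centre makes a
#' robust region-growing seed.
#'
#' @param image A [pfb_image] or matrix.
#' @param radius_range Numeric `(min, max)` radius in pixels; defaults to
#'   15-45% of the smaller image dimension.
#' @param score_min Minimum supported perimeter fraction below which a
#'   seed-not-found error is raised.
#' @param edges Optional precomputed logical edge map.
#' @return `(row, col)` centre, with the fitted radius and score attached
#'   as attributes `"radius"` and `"score"`.
#' @export
seed_by_hough <- function(image, radius_range = NULL, score_min = 0.30,
                          edges = NULL) {
  px <- as_pixels(image)
  nr <- nrow(px)
  nc <- ncol(px)
  if (is.null(radius_range)) {
    radius_range <- c(0.15, 0.45) * min(nr, nc)
  }
  if (radius_range[1] <= 0 || radius_range[1] >= radius_range[2]) {
    stop_pfb("radius_range must be positive with min < max",
             "pfbmri_param_error")
  }
  if (is.null(edges)) edges <- canny_edges(px)
  ep <- which(edges, arr.ind = TRUE)
  if (nrow(ep) == 0) {
    stop_pfb("no edge pixels: Hough seed not found", "pfbmri_seed_error")
  }
  radii <- unique(round(seq(radius_range[1], radius_range[2],
                            by = max(1, (radius_range[2] - radius_range[1]) / 12))))
  best <- list(score = -Inf)
  for (r in radii) {
    ang <- seq(0, 2 * pi, length.out = max(24, ceiling(2 * pi * r)) + 1)
    ang <- ang[-length(ang)]
    off <- unique(cbind(round(r * sin(ang)), round(r * cos(ang))))
    cr <- rep(ep[, 1], nrow(off)) + rep(off[, 1], each = nrow(ep))
    cc <- rep(ep[, 2], nrow(off)) + rep(off[, 2], each = nrow(ep))
    ok <- cr >= 1 & cr <= nr & cc >= 1 & cc <= nc
    if (!any(ok)) next
    acc <- matrix(tabulate((cc[ok] - 1) * nr + cr[ok], nbins = nr * nc),
                  nr, nc)
    # 3x3 box smoothing absorbs centre quantisation
    accs <- acc
    for (dr in -1:1) for (dc in -1:1) {
      if (dr || dc) accs <- accs + shift_matrix(acc, dr, dc, 0)
    }
    sc <- max(accs) / nrow(off)
    if (sc > best$score) {
      i <- which.max(accs)
      best <- list(score = sc, center = c((i - 1) %% nr + 1,
                                          (i - 1) %/% nr + 1),
                   radius = r)
    }
  }
  if (!is.finite(best$score) || best$score < score_min) {
    stop_pfb(sprintf("no circle with accumulator support >= %.2f found",
                     score_min), "pfbmri_seed_error")
  }
  structure(best$center, radius = best$radius, score = best$score)
}

#' Histogram-projection seed point
#'
#' Returns `(r*, c*)` where `r*` maximises the row-wise intensity sum and
#' `c*` the column-wise intensity sum (ties broken by the smaller index) --
#' a bright in-bone pixel when the bone is the dominant bright structure.
#'
#' @param image A [pfb_image] or matrix.
#' @return `(row, col)` seed.
#' @export
seed_by_histogram_max <- function(image) {
  px <- as_pixels(image)
  if (max(px) == min(px)) {
    stop_pfb("seed not found: constant image has no histogram peak",
             "pfbmri_seed_error")
  }
  c(which.max(rowSums(px)), which.max(colSums(px)))
}
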