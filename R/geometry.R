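#' Canonicalise a mask (and image) by flipping, cropping and framing
#'
#' Right-side femurs are mirrored horizontally so every bone is analysed
#' in the same (left-femur) orientation, then the mask is cropped to its
#' bounding box plus a fixed frame. All downstream features are computed
#' in this canonical crop, which makes them side-invariant by
#' construction.
#'
#' @param mask A [pfb_mask] (or logical matrix).
#' @param side `"left"` or `"right"`.
#' @param image Optional [pfb_image] or matrix, transformed identically.
#' @param frame Frame width in pixels around the bounding box (default 5).
#' @return The canonical [pfb_mask] (with attribute `"crop_window"`), or a
#'   list `(mask, image)` when `image` is supplied.
#' @export
crop_and_orient <- function(mask, side = "left", image = NULL, frame = 5) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop_pfb("cannot canonicalise an empty mask",
                        "pfbmri_mask_error")
  px <- if (!is.null(image)) as_pixels(image)
  if (side == "right") {
    m <- m[, rev(seq_len(ncol(m)))]
    if (!is.null(px)) px <- px[, rev(seq_len(ncol(px)))]
  }
  rr <- range(which(rowSums(m) > 0))
  cr <- range(which(colSums(m) > 0))
  r0 <- max(1, rr[1] - frame)
  r1 <- min(nrow(m), rr[2] + frame)
  c0 <- max(1, cr[1] - frame)
  c1 <- min(ncol(m), cr[2] + frame)
  cm <- pfb_mask(m[r0:r1, c0:c1],
                 method = if (inherits(mask, "pfb_mask")) mask$method
                          else "ground_truth")
  attr(cm, "crop_window") <- c(r0, r1, c0, c1)
  if (is.null(px)) {
    cm
  } else {
    list(mask = cm, image = px[r0:r1, c0:c1])
  }
}

# In-mask chord through point p along unit direction d (marched in
# quarter-pixel steps both ways; width 0 when p itself is outside).
# Returns c(width, mid_row, mid_col): the chord midpoint lies on the
# centreline of a symmetric band regardless of the chord's obliquity.
chord_info <- function(m, p, d, step = 0.25) {
  inside <- function(q) {
    r <- round(q[1]); c <- round(q[2])
    r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && m[r, c]
  }
  if (!inside(p)) return(c(0, NA, NA))
  len <- function(sign) {
    t <- 0
    repeat {
      t2 <- t + step
      if (!inside(p + sign * t2 * d)) return(t)
      t <- t2
    }
  }
  tp <- len(1)
  tn <- len(-1)
  mid <- p + (tp - tn) / 2 * d
  c(tp + tn + step, mid[1], mid[2])
}

chord_width <- function(m, p, d, step = 0.25) chord_info(m, p, d, step)[1]

principal_axis <- function(pts) {
  ctr <- colMeans(pts)
  cc <- cbind(pts[, 1] - ctr[1], pts[, 2] - ctr[2])
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  v <- ev$vectors[, 1]
  list(center = ctr, dir = v / sqrt(sum(v^2)),
       elongation = ev$values[1] / max(ev$values[2], 1e-9))
}

#' Extract the 12 geometric features of a canonical PFB mask
#'
#' Operational definitions (the published feature diagram is pictorial, so
#' these are this package's reconstruction, chosen to be scale-equivariant
#' and parameter-recoverable on phantoms):
#' * head circle: largest inscribed circle in the superior part of the
#'   mask (distance-transform maximum); centre `(x1, y1)`, diameter `W0`;
#' * `(x, y)`: mask centroid;
#' * shaft axis: principal axis of the inferior third of the mask;
#' * neck-shaft junction: found by marching up the shaft axis inside the
#'   mask, then correcting the overshoot caused by the neck/shaft overlap
#'   (the march exits through the neck band, half a neck-width early) by a
#'   short fixed-point iteration;
#' * neck axis: head centre to junction; `theta` is the angle between the
#'   neck axis and the distal shaft direction (anatomical neck-shaft
#'   convention, degrees);
#' * `W1`: minimal mask width perpendicular to the neck axis along the
#'   head-centre-to-junction path; `L1` its distance from the head
#'   centre (the neck base); `W2` the width at the path midpoint;
#' * `W3`, `W4`: widths perpendicular to the shaft axis at the proximal /
#'   distal thirds of the inferior segment; `L2`: mask extent along the
#'   shaft axis.
#'
#' Near-circular masks with no identifiable neck (whole-mask principal
#' elongation below 1.3) are flagged degenerate: `theta` takes the
#' 90-degree sentinel and `W1 = W2 = W0`.
#'
#' All coordinates are `(row, col)`-derived with `x` = column and `y` =
#' row, in pixels of the canonical crop.
#'
#' @param mask Canonical [pfb_mask] from [crop_and_orient()].
#' @return A `pfb_geometry` list with fields `x1, y1, L1, L2, theta,
#'   W0, W1, W2, W3, W4, x, y` and a logical `degenerate` flag.
#' @export
extract_geometry <- function(mask) {
  m <- as_mask_matrix(mask)
  if (sum(m) < 100) {
    stop_pfb("mask too small for geometric features (< 100 px)",
             "pfbmri_mask_error")
  }
  pts <- which(m, arr.ind = TRUE)
  cy <- mean(pts[, 1])
  cx <- mean(pts[, 2])

  dm <- EBImage::distmap(m * 1)
  sup <- dm
  sup[seq_len(nrow(m)) > cy, ] <- 0
  i <- which.max(sup)
  hy <- (i - 1) %% nrow(m) + 1
  hx <- (i - 1) %/% nrow(m) + 1
  r0 <- sup[i]
  W0 <- 2 * r0

  rr <- range(pts[, 1])
  inf_start <- rr[1] + 2 / 3 * (rr[2] - rr[1])
  inf_pts <- pts[pts[, 1] >= inf_start, , drop = FALSE]

  # no identifiable neck on near-circular masks
  degenerate <- nrow(inf_pts) < 20 ||
    principal_axis(pts)$elongation < 1.3

  if (!degenerate) {
    sh <- principal_axis(inf_pts)
    v <- sh$dir
    if (v[1] < 0) v <- -v                       # distal = downwards
    proj_all <- pts[, 1] * v[1] + pts[, 2] * v[2]
    L2 <- diff(range(proj_all))
    tproj <- (inf_pts[, 1] - sh$center[1]) * v[1] +
             (inf_pts[, 2] - sh$center[2]) * v[2]
    tlo <- min(tproj); thi <- max(tproj)
    vperp <- c(-v[2], v[1])
    p3 <- sh$center + (tlo + (thi - tlo) / 3) * v
    p4 <- sh$center + (tlo + 2 * (thi - tlo) / 3) * v
    W3 <- chord_width(m, p3, vperp)
    W4 <- chord_width(m, p4, vperp)

    # rough neck-shaft junction: march up the shaft axis inside the mask,
    # floored below the head (the junction is inferior-lateral to it)
    head_ctr <- c(hy, hx)
    inside <- function(q) {
      r <- round(q[1]); c <- round(q[2])
      r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && m[r, c]
    }
    t <- 0
    repeat {
      nxt <- sh$center - (t + 0.5) * v
      if (!inside(nxt) || nxt[1] < hy + 0.75 * r0) break
      t <- t + 0.5
    }
    junction <- sh$center - t * v

    # chords perpendicular to the neck-axis estimate along the
    # head-to-endpoint path; near-minimal chords sit in the neck proper
    # and their midpoints lie on its centreline
    measure <- function(endpoint, u_axis) {
      w <- endpoint - head_ctr
      len <- sqrt(sum(w^2))
      if (len < 1e-6) return(NULL)
      w <- w / len
      uperp <- c(-u_axis[2], u_axis[1])
      svals <- seq(0, len, by = 0.5)
      prof <- t(vapply(svals, function(s) {
        chord_info(m, head_ctr + s * w, uperp)
      }, numeric(3)))
      ok <- prof[, 1] > 0 & svals > 0.5 * r0
      if (!any(ok)) return(NULL)
      imin <- which(ok)[which.min(prof[ok, 1])]
      list(len = len, svals = svals, widths = prof[, 1], ok = ok,
           mids = prof[, 2:3, drop = FALSE],
           imin = imin, w_min = prof[imin, 1])
    }
    cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]
    endpoint_for <- function(u_axis) {
      # neck-line / shaft-line intersection, falling back to the march
      den <- cross2(u_axis, v)
      if (abs(den) < 0.05) return(junction)
      t_int <- cross2(sh$center - head_ctr, v) / den
      if (t_int < r0 || t_int > 3 * nrow(m)) junction
      else head_ctr + t_int * u_axis
    }

    # neck axis: line through the head centre (a centreline point) and
    # the mean midpoint of the near-minimal ("plateau") chords. Full band
    # crossings have on-centreline midpoints regardless of chord
    # obliquity; corner-clipped chords are rejected by their residual to
    # the current axis line before averaging.
    fit_direction <- function(mm, u_cur) {
      sel <- which(mm$ok & mm$widths <= 1.25 * mm$w_min &
                   !is.na(mm$mids[, 1]))
      if (!length(sel)) return(NULL)
      mids <- mm$mids[sel, , drop = FALSE]
      resid <- abs((mids[, 1] - head_ctr[1]) * (-u_cur[2]) +
                   (mids[, 2] - head_ctr[2]) * u_cur[1])
      keep <- resid <= max(2, quantile(resid, 0.6, names = FALSE))
      mids <- mids[keep, , drop = FALSE]
      target <- colMeans(mids)
      d <- target - head_ctr
      nrm <- sqrt(sum(d^2))
      if (nrm < 1e-6) return(NULL)
      d <- d / nrm
      if (sum(d * u_cur) < 0) d <- -d
      d
    }

    u <- (junction - head_ctr) / sqrt(sum((junction - head_ctr)^2))
    mm <- NULL
    for (iter in 1:5) {
      mm2 <- measure(endpoint_for(u), u)
      if (is.null(mm2)) break
      mm <- mm2
      u_new <- fit_direction(mm, u)
      if (is.null(u_new)) break
      converged <- sum(u_new * u) > cos(0.5 * pi / 180)
      u <- u_new
      if (converged) break
    }
    if (is.null(mm)) {
      degenerate <- TRUE
    } else {
      theta <- acos(pmin(pmax(sum(-u * v), -1), 1)) * 180 / pi
      # drop corner-clipped chords: midpoint must sit on the fitted
      # centreline (line through the median midpoint along u)
      sel <- which(mm$ok & !is.na(mm$mids[, 1]))
      line_pt <- c(median(mm$mids[sel, 1]), median(mm$mids[sel, 2]))
      resid <- abs((mm$mids[sel, 1] - line_pt[1]) * (-u[2]) +
                   (mm$mids[sel, 2] - line_pt[2]) * u[1])
      on_line <- sel[resid <= 1.5]
      if (!length(on_line)) on_line <- sel
      iw <- on_line[which.min(mm$widths[on_line])]
      W1 <- mm$widths[iw]
      L1 <- mm$svals[iw]
      # width at the path midpoint, averaged over the three nearest
      # sampled chords to damp sub-pixel path quantisation
      near_mid <- sel[order(abs(mm$svals[sel] - mm$len / 2))]
      W2 <- mean(mm$widths[head(near_mid, 3)])
    }
  }

  if (degenerate) {
    theta <- 90
    W1 <- W0
    W2 <- W0
    L1 <- 0
    if (!exists("L2", inherits = FALSE)) L2 <- diff(range(pts[, 1]))
    if (!exists("W3", inherits = FALSE)) W3 <- W0
    if (!exists("W4", inherits = FALSE)) W4 <- W0
  }

  structure(
    list(x1 = hx, y1 = hy, L1 = L1, L2 = L2, theta = theta,
         W0 = W0, W1 = W1, W2 = W2, W3 = W3, W4 = W4,
         x = cx, y = cy, degenerate = degenerate),
    class = "pfb_geometry")
}

#' @export
print.pfb_geometry <- function(x, ...) {
  v <- geometry_vector(x)
  cat("<pfb_geometry>", if (x$degenerate) "(degenerate)" else "", "\n")
  print(round(v, 2))
  invisible(x)
}

# The 12 geometric features as a named vector in canonical (feature-table)
# order.
geometry_vector <- function(g) {
  nm <- c("x1", "y1", "L1", "L2", "theta", "W0", "W1", "W2", "W3", "W4",
          "x", "y")
  setNames(vapply(nm, function(n) as.numeric(g[[n]]), numeric(1)), nm)
}
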