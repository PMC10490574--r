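#' Intensity statistics inside the bone mask
#'
#' Mean, variance and skewness of the in-mask intensities (population
#' convention). The gray-level mean is a proxy for marrow fat content and
#' hence bone mineral density on T1-weighted images.
#'
#' @param image A [pfb_image] or matrix.
#' @param mask A [pfb_mask] or logical matrix on the same grid.
#' @return Named vector `(gray_mean, gray_variance, gray_skew)` with a
#'   `"degenerate"` attribute for constant regions.
#' @export
gray_stats <- function(image, mask) {
  px <- as_pixels(image)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop_pfb("mask is empty", "pfbmri_mask_error")
  v <- px[m]
  degenerate <- pop_variance(v) <= .Machine$double.eps
  structure(c(gray_mean = mean(v), gray_variance = pop_variance(v),
              gray_skew = pop_skew(v)),
            degenerate = degenerate)
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes of the pixel set at dyadic box sizes (2, 4, 8,
#' ... up to a quarter of the set's extent) and returns minus the OLS
#' slope of `log N(s)` versus `log s`. By default the set is the mask's
#' boundary (the fractal dimension is used here as a boundary-complexity
#' descriptor); pass `of = "mask"` to measure the filled set.
#'
#' @param mask A [pfb_mask] or logical matrix.
#' @param of `"boundary"` (default) or `"mask"`.
#' @param sizes Optional explicit box sizes.
#' @return The estimated dimension (in `[0, 2]` for planar sets).
#' @export
fractal_dimension <- function(mask, of = c("boundary", "mask"),
                              sizes = NULL) {
  of <- match.arg(of)
  m <- as_mask_matrix(mask)
  set <- if (of == "boundary") mask_border_pixels(m) else m
  pts <- which(set, arr.ind = TRUE)
  if (nrow(pts) == 0) stop_pfb("point set is empty", "pfbmri_mask_error")
  pr <- pts[, 1] - min(pts[, 1])
  pc <- pts[, 2] - min(pts[, 2])
  extent <- max(max(pr), max(pc)) + 1
  if (is.null(sizes)) {
    sizes <- 2^(1:5)
    sizes <- sizes[sizes <= max(2, extent / 4)]
  }
  if (length(sizes) < 3) {
    stop_pfb("fewer than 3 usable box scales for this set",
             "pfbmri_scale_error")
  }
  counts <- vapply(sizes, function(s) {
    length(unique((pr %/% s) * (max(pc) %/% s + 2) + (pc %/% s)))
  }, numeric(1))
  -ols_fit_slope(log(sizes), log(counts))
}

ols_fit_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Gray-level co-occurrence (GLCM) features inside the mask
#'
#' Intensities are quantised to `levels` gray levels over the in-mask
#' range; the symmetric, normalised co-occurrence matrix at distance 1 is
#' averaged over the requested angles (pairs are counted only when both
#' pixels lie inside the mask) and summarised by the canonical Haralick
#' quartet: contrast, correlation, energy and homogeneity.
#'
#' @param image A [pfb_image] or matrix.
#' @param mask A [pfb_mask] or logical matrix.
#' @param levels Number of quantisation levels (default 32).
#' @param angles Subset of `c(0, 45, 90, 135)` degrees (default all four).
#' @return Named vector `(glcm_contrast, glcm_correlation, glcm_energy,
#'   glcm_homogeneity)` with a `"degenerate"` attribute; a constant region
#'   returns `(0, 1, 1, 1)` flagged degenerate.
#' @export
glcm_features <- function(image, mask, levels = 32,
                          angles = c(0, 45, 90, 135)) {
  px <- as_pixels(image)
  m <- as_mask_matrix(mask)
  if (!any(m)) stop_pfb("mask is empty", "pfbmri_mask_error")
  v <- px[m]
  rng <- max(v) - min(v)
  if (rng <= 0) {
    return(structure(c(glcm_contrast = 0, glcm_correlation = 1,
                       glcm_energy = 1, glcm_homogeneity = 1),
                     degenerate = TRUE))
  }
  q <- matrix(NA_real_, nrow(px), ncol(px))
  q[m] <- pmin(floor((px[m] - min(v)) / rng * levels) + 1, levels)

  offsets <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                  `135` = c(-1, -1))
  counts <- matrix(0, levels, levels)
  for (a in as.character(angles)) {
    off <- offsets[[a]]
    qb <- shift_matrix(q, -off[1], -off[2], NA)
    ok <- !is.na(q) & !is.na(qb)
    if (!any(ok)) next
    idx <- (q[ok] - 1) * levels + qb[ok]
    cm <- matrix(tabulate(idx, nbins = levels * levels), levels, levels,
                 byrow = TRUE)
    counts <- counts + cm + t(cm) # symmetric pairs
  }
  tot <- sum(counts)
  if (tot == 0) {
    return(structure(c(glcm_contrast = 0, glcm_correlation = 1,
                       glcm_energy = 1, glcm_homogeneity = 1),
                     degenerate = TRUE))
  }
  P <- counts / tot
  i <- row(P)
  j <- col(P)
  pi_marg <- rowSums(P)
  mu <- sum(seq_len(levels) * pi_marg)
  sig2 <- sum((seq_len(levels) - mu)^2 * pi_marg)
  contrast <- sum(P * (i - j)^2)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  correlation <- if (sig2 <= .Machine$double.eps) {
    1
  } else {
    sum((i - mu) * (j - mu) * P) / sig2
  }
  structure(c(glcm_contrast = contrast, glcm_correlation = correlation,
              glcm_energy = energy, glcm_homogeneity = homogeneity),
            degenerate = FALSE)
}
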