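#' Boundary-distance curves of a canonical PFB mask
#'
#' The five bespoke 1D shape descriptors of the bone boundary. The
#' canonical crop's row range is split into three equal horizontal bands:
#' `C1-0`, `C1-1`, `C1-2` record, for each row of the top / middle /
#' bottom band, the distance from the left crop edge to the first bone
#' pixel. `C2-0` records, for each column of the left half, the distance
#' from the top edge down to the first bone pixel, and `C4-0`, for each
#' column of the right half, the distance from the bottom edge up to the
#' last bone pixel. Rows/columns that never meet the mask are dropped and
#' every curve is linearly resampled to a fixed length of 64 so curves
#' from different crop sizes are comparable.
#'
#' @param mask Canonical [pfb_mask] from [crop_and_orient()].
#' @param resample_to Fixed output length (default 64).
#' @return Named list of five `pfb_curve` objects
#'   (`C1-0`, `C1-1`, `C1-2`, `C2-0`, `C4-0`).
#' @export
extract_curves <- function(mask, resample_to = 64) {
  m <- as_mask_matrix(mask)
  nr <- nrow(m)
  nc <- ncol(m)
  first_from_left <- apply(m, 1, function(row) {
    i <- which(row)[1]
    if (is.na(i)) NA_real_ else i - 1
  })
  first_from_top <- apply(m, 2, function(col) {
    i <- which(col)[1]
    if (is.na(i)) NA_real_ else i - 1
  })
  first_from_bottom <- apply(m, 2, function(col) {
    w <- which(col)
    if (!length(w)) NA_real_ else nr - w[length(w)]
  })

  b1 <- floor(nr / 3)
  b2 <- floor(2 * nr / 3)
  bands <- list(
    `C1-0` = list(values = first_from_left[seq_len(b1)],
                  region = c(1, b1), direction = "from_left"),
    `C1-1` = list(values = first_from_left[(b1 + 1):b2],
                  region = c(b1 + 1, b2), direction = "from_left"),
    `C1-2` = list(values = first_from_left[(b2 + 1):nr],
                  region = c(b2 + 1, nr), direction = "from_left"),
    `C2-0` = list(values = first_from_top[seq_len(floor(nc / 2))],
                  region = c(1, floor(nc / 2)), direction = "from_top"),
    `C4-0` = list(values = first_from_bottom[(floor(nc / 2) + 1):nc],
                  region = c(floor(nc / 2) + 1, nc),
                  direction = "from_bottom")
  )
  lapply(setNames(names(bands), names(bands)), function(nm) {
    b <- bands[[nm]]
    v <- b$values[!is.na(b$values)]
    if (length(v) < 8) {
      stop_pfb(sprintf("curve %s has only %d raw samples (< 8): degenerate",
                       nm, length(v)), "pfbmri_curve_error")
    }
    res <- approx(seq_along(v), v, xout = seq(1, length(v),
                                              length.out = resample_to))$y
    structure(list(name = nm, values = res, raw = v, region = b$region,
                   direction = b$direction),
              class = "pfb_curve")
  })
}

#' @export
print.pfb_curve <- function(x, ...) {
  cat(sprintf("<pfb_curve> %s (%s, region %d-%d), %d samples\n",
              x$name, x$direction, x$region[1], x$region[2],
              length(x$values)))
  invisible(x)
}

curve_values <- function(curve) {
  if (inherits(curve, "pfb_curve")) curve$values
  else as.numeric(curve)
}

#' Linear-trend slope of a boundary curve ("average ramp")
#'
#' Ordinary least-squares slope of the curve values over their index.
#'
#' @param curve A `pfb_curve` or numeric vector (length >= 2).
#' @return The OLS slope.
#' @export
average_ramp <- function(curve) {
  v <- curve_values(curve)
  if (length(v) < 2) stop_pfb("curve must have at least 2 points",
                              "pfbmri_param_error")
  ols_slope(v)
}

#' Endpoint slope of a boundary curve ("first to last point ramp")
#'
#' `(last - first) / (index span)`.
#'
#' @inheritParams average_ramp
#' @return The endpoint slope.
#' @export
first_to_last_ramp <- function(curve) {
  v <- curve_values(curve)
  if (length(v) < 2) stop_pfb("curve must have at least 2 points",
                              "pfbmri_param_error")
  (v[length(v)] - v[1]) / (length(v) - 1)
}

#' Detrended boundary curve ("ramp removed signal")
#'
#' Subtracts the fitted linear trend's slope component index-wise:
#' `values[i] - average_ramp * (i - 1)`. Detrending makes the
#' skewness/kurtosis of sloped curves meaningful; the residual of an exact
#' line `a + b*i` is the constant `a`.
#'
#' @inheritParams average_ramp
#' @return Numeric vector of detrended values.
#' @export
ramp_removed <- function(curve) {
  v <- curve_values(curve)
  if (length(v) < 2) stop_pfb("curve must have at least 2 points",
                              "pfbmri_param_error")
  v - average_ramp(v) * (seq_along(v) - 1)
}

# Statistic menus per curve family (the bottom left-distance band C1-2
# uses plain-signal statistics; the other four use the ramp features and
# detrended moments).
curve_stat_names <- function(name) {
  if (name == "C1-2") {
    c("min", "max", "mean", "variance", "kurtosis", "skew",
      "moment1", "moment2")
  } else {
    c("min", "max", "average_ramp", "kurtosis_rr", "skew_rr",
      "first_to_last_ramp", "moment1_rr", "moment2_rr", "variance",
      "max_second_derivative")
  }
}

#' Statistics of a boundary curve
#'
#' Computes the statistic set defined for the curve's family: 8 plain
#' statistics for `C1-2` (min, max, mean, variance, kurtosis, skew, first
#' and second central moments) and 10 for the other curves (min, max,
#' average ramp, kurtosis/skew/first/second central moments of the
#' detrended signal, first-to-last ramp, variance, max discrete second
#' derivative). Conventions: population (biased) moments, excess
#' kurtosis; zero-variance curves get skew/kurtosis 0 and a `degenerate`
#' attribute.
#'
#' @param curve A `pfb_curve`.
#' @return Named numeric vector of the curve's statistics (names prefixed
#'   with the curve name), with attribute `"degenerate"`.
#' @export
curve_stats <- function(curve) {
  stopifnot(inherits(curve, "pfb_curve"))
  v <- curve$values
  degenerate <- pop_variance(v) <= .Machine$double.eps
  vals <- if (curve$name == "C1-2") {
    c(min = min(v), max = max(v), mean = mean(v),
      variance = pop_variance(v),
      kurtosis = pop_excess_kurtosis(v), skew = pop_skew(v),
      moment1 = central_moment(v, 1), moment2 = central_moment(v, 2))
  } else {
    rr <- ramp_removed(v)
    c(min = min(v), max = max(v), average_ramp = average_ramp(v),
      kurtosis_rr = pop_excess_kurtosis(rr), skew_rr = pop_skew(rr),
      first_to_last_ramp = first_to_last_ramp(v),
      moment1_rr = central_moment(rr, 1),
      moment2_rr = central_moment(rr, 2),
      variance = pop_variance(v),
      max_second_derivative = max(diff(v, differences = 2)))
  }
  names(vals) <- paste0(curve$name, "_", names(vals))
  structure(vals, degenerate = degenerate)
}
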