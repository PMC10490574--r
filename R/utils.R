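# Shared internal helpers: seeded evaluation, raster resampling, small
# geometry utilities. Image matrices are indexed [row, col], row 1 at the
# top; coordinates are (row, col) throughout unless a function says
# otherwise.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All exported stochastic operations funnel
# through this so a seed argument never disturbs global reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

stop_pfb <- function(msg, class, ...) {
  abort(msg, class = c(class, "pfbmri_error"), ...)
}

# Shift a matrix by (dr, dc), padding with `fill`. Positive dr moves
# content down, positive dc moves it right.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Reflection-padded copy of m with `pad` extra pixels on every side.
reflect_pad <- function(m, pad) {
  nr <- nrow(m)
  nc <- ncol(m)
  ridx <- c(rev(seq_len(pad) + 1L), seq_len(nr), nr - seq_len(pad))
  cidx <- c(rev(seq_len(pad) + 1L), seq_len(nc), nc - seq_len(pad))
  ridx <- pmin(pmax(ridx, 1L), nr)
  cidx <- pmin(pmax(cidx, 1L), nc)
  m[ridx, cidx]
}

# Bilinear sample of matrix m at fractional (row, col) positions; points
# outside the grid return `fill`.
bilinear_sample <- function(m, r, c, fill = 0) {
  nr <- nrow(m)
  nc <- ncol(m)
  r0 <- floor(r)
  c0 <- floor(c)
  fr <- r - r0
  fc <- c - c0
  out <- rep(fill, length(r))
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok])
    i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- m[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      m[i01] * (1 - fr[ok]) * fc[ok] +
      m[i10] * fr[ok] * (1 - fc[ok]) +
      m[i11] * fr[ok] * fc[ok]
  }
  # exact grid points on the last row/column
  edge <- !ok & r >= 1 & r <= nr & c >= 1 & c <= nc
  if (any(edge)) {
    out[edge] <- m[cbind(pmin(pmax(round(r[edge]), 1), nr),
                         pmin(pmax(round(c[edge]), 1), nc))]
  }
  out
}

# Inverse-mapped affine resample: rotation by `angle_deg` about the image
# centre followed by a translation of (dr, dc) pixels. `interp` is
# "bilinear" (images) or "nearest" (masks).
affine_resample <- function(m, angle_deg, dr = 0, dc = 0,
                            interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  nr <- nrow(m)
  nc <- ncol(m)
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  # inverse transform: undo translation, then rotate by -theta about centre
  yr <- g$r - dr - cr
  xc <- g$c - dc - cc
  src_r <- cos(th) * yr + sin(th) * xc + cr
  src_c <- -sin(th) * yr + cos(th) * xc + cc
  if (interp == "nearest") {
    src_r <- round(src_r)
    src_c <- round(src_c)
    vals <- rep(fill, length(src_r))
    ok <- src_r >= 1 & src_r <= nr & src_c >= 1 & src_c <= nc
    vals[ok] <- m[cbind(src_r[ok], src_c[ok])]
  } else {
    vals <- bilinear_sample(m, src_r, src_c, fill = fill)
  }
  matrix(vals, nr, nc)
}

# Resize a matrix to nr x nc by bilinear sampling (used to bring canonical
# crops of different sizes onto a common frame).
resize_matrix <- function(m, nr, nc) {
  rr <- seq(1, nrow(m), length.out = nr)
  cc <- seq(1, ncol(m), length.out = nc)
  g <- expand.grid(r = rr, c = cc)
  matrix(bilinear_sample(m, g$r, g$c), nr, nc)
}

# Population (biased) central moments; the package-wide convention for
# curve and texture statistics.
central_moment <- function(x, k) mean((x - mean(x))^k)

pop_variance <- function(x) central_moment(x, 2)

pop_skew <- function(x) {
  m2 <- central_moment(x, 2)
  if (m2 <= .Machine$double.eps) return(0)
  central_moment(x, 3) / m2^1.5
}

pop_excess_kurtosis <- function(x) {
  m2 <- central_moment(x, 2)
  if (m2 <= .Machine$double.eps) return(0)
  central_moment(x, 4) / m2^2 - 3
}

# OLS slope of y over a 0-based index (cov/var form, no lm() overhead).
ols_slope <- function(y) {
  x <- seq_along(y) - 1
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
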