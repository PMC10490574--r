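make_curve <- function(values, name = "C1-1") {
  structure(list(name = name, values = values, raw = values,
                 region = c(1, length(values)), direction = "from_left"),
            class = "pfb_curve")
}

test_that("an axis-aligned square yields five constant curves", {
  sq <- matrix(FALSE, 64, 64); sq[17:48, 17:48] <- TRUE
  curves <- extract_curves(crop_and_orient(pfb_mask(sq)))
  expect_named(curves, c("C1-0", "C1-1", "C1-2", "C2-0", "C4-0"))
  for (cv in curves) {
    expect_length(cv$values, 64)
    expect_equal(var(cv$values), 0)
  }
})

test_that("a left-facing right triangle gives monotone linear C1 curves", {
  n <- 60
  tri <- matrix(FALSE, n, n)
  for (r in 10:50) tri[r, (n - 9 - (r - 10)):(n - 9)] <- TRUE
  curves <- extract_curves(crop_and_orient(pfb_mask(tri)))
  for (nm in c("C1-0", "C1-1", "C1-2")) {
    v <- curves[[nm]]$values
    expect_true(all(diff(v) <= 1e-9)) # hypotenuse recedes monotonically
    # linear: residual from the OLS line is tiny
    expect_lt(max(abs(ramp_removed(v) - mean(ramp_removed(v)))), 1)
  }
})

test_that("curves of a phantom and its canonical mirror are identical", {
  l <- generate_phantom(phantom_spec(rng_seed = 4))
  r <- generate_phantom(phantom_spec(rng_seed = 4, side = "right"))
  cl <- extract_curves(crop_and_orient(l$mask, "left"))
  cr <- extract_curves(crop_and_orient(r$mask, "right"))
  for (nm in names(cl)) expect_identical(cl[[nm]]$values, cr[[nm]]$values)
})

test_that("degenerate bands raise a curve error naming the curve", {
  thin <- matrix(FALSE, 40, 40)
  thin[10:12, 5:35] <- TRUE # only 3 rows: every C1 band is starved
  err <- expect_error(extract_curves(crop_and_orient(pfb_mask(thin))),
                      class = "pfbmri_curve_error")
  expect_match(conditionMessage(err), "C1-")
})

test_that("average ramp is the OLS slope", {
  expect_equal(average_ramp(c(0, 2, 4, 6)), 2)
  expect_equal(average_ramp(c(5, 5, 5)), 0)
  expect_equal(average_ramp(c(0, 1, 4)), 2)
  expect_error(average_ramp(3), class = "pfbmri_param_error")
})

test_that("first-to-last ramp uses literal endpoints", {
  expect_equal(first_to_last_ramp(c(0, 1, 4)), 2)
  expect_equal(first_to_last_ramp(c(7, 7, 7, 7)), 0)
  lin <- 3 + 1.5 * (0:20)
  expect_equal(first_to_last_ramp(lin), average_ramp(lin))
})

test_that("ramp removal subtracts the slope component index-wise", {
  expect_equal(ramp_removed(c(0, 1, 4)), c(0, -1, 0))
  lin <- 4 + 2.5 * (0:15)
  expect_equal(ramp_removed(lin), rep(4, 16))
  withr::with_seed(2, v <- cumsum(rnorm(64)))
  expect_lt(abs(average_ramp(ramp_removed(v))), 1e-9)
})

test_that("curve statistics follow the per-curve menus and conventions", {
  v <- c(0, 1, 4)
  st <- curve_stats(make_curve(v, "C1-2"))
  expect_length(st, 8)
  expect_equal(unname(st["C1-2_variance"]), 26 / 9) # population convention
  expect_equal(unname(st["C1-2_moment1"]), 0)
  expect_equal(unname(st["C1-2_moment2"]), unname(st["C1-2_variance"]))
  expect_equal(unname(st["C1-2_min"]), 0)
  expect_equal(unname(st["C1-2_max"]), 4)

  st10 <- curve_stats(make_curve(v, "C1-1"))
  expect_length(st10, 10)
  expect_equal(unname(st10["C1-1_average_ramp"]), 2)
  expect_equal(unname(st10["C1-1_first_to_last_ramp"]), 2)
  expect_equal(unname(st10["C1-1_max_second_derivative"]), 2) # 4 - 2*1 + 0
  expect_equal(unname(st10["C1-1_moment1_rr"]), 0)
})

test_that("constant curves are flagged degenerate with zeroed shape stats", {
  st <- curve_stats(make_curve(rep(3, 16), "C1-1"))
  expect_true(attr(st, "degenerate"))
  expect_equal(unname(st[c("C1-1_min", "C1-1_max")]), c(3, 3))
  expect_equal(unname(st["C1-1_variance"]), 0)
  expect_equal(unname(st["C1-1_kurtosis_rr"]), 0)
  expect_equal(unname(st["C1-1_skew_rr"]), 0)
})

test_that("normal samples give near-zero skew and excess kurtosis", {
  withr::with_seed(11, v <- rnorm(64))
  st <- curve_stats(make_curve(v, "C1-2"))
  se_skew <- sqrt(6 / 64)
  se_kurt <- sqrt(24 / 64)
  expect_lt(abs(st["C1-2_skew"]), 3 * se_skew)
  expect_lt(abs(st["C1-2_kurtosis"]), 3 * se_kurt)
})

test_that("statistics are stable under 2x density resampling", {
  ph <- default_phantom()
  cm <- crop_and_orient(ph$mask, "left")
  c64 <- extract_curves(cm, resample_to = 64)
  c128 <- extract_curves(cm, resample_to = 128)
  for (nm in c("C1-1", "C2-0")) {
    a <- curve_stats(c64[[nm]])
    v128 <- c128[[nm]]$values
    b <- curve_stats(make_curve(approx(seq_along(v128), v128,
                                       xout = seq(1, 128, length.out = 64))$y,
                                nm))
    for (k in c(1, 2, 9)) { # min, max, variance
      denom <- max(abs(a[k]), 1)
      expect_lt(abs(a[k] - b[k]) / denom, 0.05)
    }
  }
})
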