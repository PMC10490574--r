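test_that("median filter matches a brute-force sorted-median oracle", {
  withr::with_seed(3, {
    img <- matrix(runif(81), 9, 9)
  })
  out <- median_filter5(img)
  # centre pixel: explicit sort of its 25-neighbourhood
  expect_equal(out[5, 5], sort(as.numeric(img[3:7, 3:7]))[13])
  # constant image is a fixed point
  const <- matrix(4, 16, 16)
  expect_identical(median_filter5(const), const)
  # single salt pixel is removed
  salt <- matrix(0, 16, 16)
  salt[8, 8] <- 100
  expect_true(all(median_filter5(salt) == 0))
  expect_error(median_filter5(matrix(1, 4, 4)), class = "pfbmri_size_error")
})

test_that("median filter commutes with intensity flipping", {
  withr::with_seed(8, img <- matrix(runif(32 * 32, 0, 10), 32, 32))
  flipped <- median_filter5(max(img) - img)
  expect_equal(flipped, max(img) - median_filter5(img), tolerance = 1e-12)
})

test_that("Hough seed lands near the phantom head centre", {
  ph <- default_phantom()
  truth <- attr(ph$mask, "head_center")
  f <- median_filter5(ph$image)
  s <- seed_by_hough(f, radius_range = c(15, 25))
  expect_lt(sqrt(sum((c(s[1], s[2]) - truth)^2)), 2)
})

test_that("Hough seed fails on blank images and obeys the radius range", {
  expect_error(seed_by_hough(matrix(5, 64, 64)), class = "pfbmri_seed_error")
  # two disks, radii 10 and 20; range (15, 25) must pick the larger
  g <- expand.grid(r = 1:96, c = 1:96)
  img <- matrix(0, 96, 96)
  img[(g$r - 25)^2 + (g$c - 25)^2 <= 100] <- 200
  img[(g$r - 60)^2 + (g$c - 60)^2 <= 400] <- 200
  s <- seed_by_hough(img, radius_range = c(15, 25))
  expect_lt(sqrt(sum((c(s[1], s[2]) - c(60, 60))^2)), 3)
  expect_error(seed_by_hough(img, radius_range = c(10, 5)),
               class = "pfbmri_param_error")
})

test_that("histogram seed maximises the row and column projections", {
  img <- matrix(0, 32, 32)
  img[3, ] <- 10
  img[, 7] <- 10
  expect_equal(unname(seed_by_histogram_max(img)), c(3, 7))
  # tie-break: smaller index
  img2 <- matrix(0, 32, 32)
  img2[c(4, 9), ] <- 5
  img2[, c(6, 11)] <- 5
  expect_equal(unname(seed_by_histogram_max(img2)), c(4, 6))
  expect_error(seed_by_histogram_max(matrix(1, 32, 32)),
               class = "pfbmri_seed_error")
})

test_that("region growing segments a noiseless phantom accurately", {
  ph <- generate_phantom(phantom_spec(salt_pepper_fraction = 0,
                                      bone_intensity_sd = 2, rng_seed = 4))
  f <- median_filter5(ph$image)
  seed <- attr(ph$mask, "head_center")
  m <- region_grow_canny(f, seed)
  expect_gte(dsc(m, ph$mask), 0.95)
  expect_true(m$mask[round(seed[1]), round(seed[2])]) # contains its seed
  expect_equal(max(EBImage::bwlabel(m$mask * 1)), 1)
})

test_that("region growing fails safely without edges and on edge seeds", {
  expect_error(region_grow_canny(matrix(0, 64, 64), c(32, 32)),
               class = "pfbmri_seg_failure")
  ph <- default_phantom()
  f <- median_filter5(ph$image)
  edges <- canny_edges(f)
  on_edge <- which(edges, arr.ind = TRUE)[1, ]
  expect_error(region_grow_canny(f, on_edge), class = "pfbmri_seed_error")
  expect_error(region_grow_canny(f, c(-3, 1000)), class = "pfbmri_param_error")
})

test_that("active contour reaches the bone from a 1.5x head-radius circle", {
  ph <- generate_phantom(phantom_spec(salt_pepper_fraction = 0, rng_seed = 4))
  f <- median_filter5(ph$image)
  ctr <- attr(ph$mask, "head_center")
  m <- active_contour_segment(f, ctr, 1.5 * 20)
  expect_gte(dsc(m, ph$mask), 0.90)
  # determinism
  m2 <- active_contour_segment(f, ctr, 1.5 * 20)
  expect_identical(m$mask, m2$mask)
})

test_that("active contour far from the bone fails or is flagged by DSC", {
  ph <- generate_phantom(phantom_spec(size = 160, rng_seed = 4))
  f <- median_filter5(ph$image)
  res <- tryCatch(active_contour_segment(f, c(140, 20), 12),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_s3_class(res, "pfbmri_seg_failure")
  } else {
    expect_lt(dsc(res, ph$mask), 0.5)
  }
  expect_error(active_contour_segment(f, c(5, 5), 30),
               class = "pfbmri_param_error")
})

test_that("DSC and IoU match direct set counting", {
  S <- matrix(FALSE, 8, 8); S[1:2, 1:2] <- TRUE            # |S| = 4
  T_ <- matrix(FALSE, 8, 8); T_[1:2, 2:3] <- TRUE          # |T| = 4, overlap 2
  expect_equal(dsc(S, T_), 0.5)
  expect_equal(iou(S, T_), 1 / 3)
  expect_equal(dsc(S, S), 1)
  D <- matrix(FALSE, 8, 8); D[6:8, 6:8] <- TRUE
  expect_equal(dsc(S, D), 0)
  expect_error(dsc(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)),
               class = "pfbmri_metric_error")
  expect_error(dsc(S, matrix(TRUE, 4, 4)), class = "pfbmri_param_error")
})

test_that("dsc = 2 iou / (1 + iou) and both are symmetric", {
  withr::with_seed(5, {
    for (i in 1:50) {
      p <- random_mask_pair()
      d <- dsc(p$S, p$T_)
      j <- iou(p$S, p$T_)
      expect_lte(j, d + 1e-12)
      expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
      expect_equal(d, dsc(p$T_, p$S))
      expect_equal(j, iou(p$T_, p$S))
    }
  })
})

test_that("segment_best keeps the higher-DSC candidate when truth exists", {
  ph <- default_phantom()
  best <- segment_best(ph$image, truth = ph$mask)
  expect_gte(attr(best, "dsc"), 0.9)
  cands <- attr(best, "candidates")
  expect_true(best$method %in% c("region_growing", "active_contour"))
  expect_gte(length(cands), 1)
})

test_that("segment_best falls back to a manual mask and errors without one", {
  blank <- pfb_image(matrix(2, 64, 64), subject_id = "blank")
  tmp <- withr::local_tempfile(fileext = ".png")
  manual <- matrix(FALSE, 64, 64); manual[20:40, 20:40] <- TRUE
  write_mask_png(pfb_mask(manual), tmp)
  got <- segment_best(blank, manual_mask_path = tmp)
  expect_equal(got$method, "manual_file")
  expect_identical(got$mask, manual)
  err <- expect_error(segment_best(blank), class = "pfbmri_seg_failure")
  expect_match(conditionMessage(err), "region_growing")
})

test_that("segment_best averages DSC >= 0.93 on random noiseless phantoms", {
  # 25 random phantoms per run keeps the suite quick; the acceptance
  # suite covers the larger end-to-end benchmark
  withr::with_seed(10, {
    scores <- vapply(1:25, function(i) {
      sp <- phantom_spec(head_radius_px = runif(1, 17, 23),
                         neck_width_px = runif(1, 12, 17),
                         neck_shaft_angle_deg = runif(1, 120, 145),
                         salt_pepper_fraction = 0,
                         rng_seed = sample.int(1e6, 1))
      ph <- generate_phantom(sp)
      attr(segment_best(ph$image, truth = ph$mask), "dsc")
    }, numeric(1))
    expect_gte(mean(scores), 0.93)
  })
})
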