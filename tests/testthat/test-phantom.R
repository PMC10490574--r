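test_that("noiseless phantom takes exactly the two specified intensities", {
  ph <- generate_phantom(phantom_spec(salt_pepper_fraction = 0,
                                      bone_intensity_sd = 0,
                                      bone_mean_intensity = 180,
                                      background_mean = 30,
                                      protocol_gain = 1.5))
  vals <- sort(unique(as.numeric(ph$image$pixels)))
  expect_equal(vals, c(45, 270))
  expect_setequal(unique(ph$image$pixels[ph$mask$mask]), 270)
})

test_that("phantom generation is bit-identical under a fixed seed", {
  a <- generate_phantom(phantom_spec(rng_seed = 11))
  b <- generate_phantom(phantom_spec(rng_seed = 11))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask$mask, b$mask$mask)
  c <- generate_phantom(phantom_spec(rng_seed = 12))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("right-side phantoms mirror the left phantom exactly", {
  l <- generate_phantom(phantom_spec(rng_seed = 11))
  r <- generate_phantom(phantom_spec(rng_seed = 11, side = "right"))
  expect_identical(r$image$pixels, l$image$pixels[, rev(seq_len(128))])
  expect_identical(r$mask$mask, l$mask$mask[, rev(seq_len(128))])
})

test_that("the mask's head component has the requested radius", {
  # brute-force circle fit: centre from the superior distance-map maximum,
  # radius as the fitted inscribed radius
  ph <- generate_phantom(phantom_spec(head_radius_px = 20, rng_seed = 3))
  m <- ph$mask$mask
  dm <- EBImage::distmap(m * 1)
  top <- dm
  top[seq_len(nrow(m)) > mean(which(m, arr.ind = TRUE)[, 1]), ] <- 0
  expect_lt(abs(max(top) - 20), 1)
})

test_that("phantom ground-truth mask is simply connected", {
  for (seed in 1:5) {
    ph <- generate_phantom(phantom_spec(rng_seed = seed))
    expect_equal(max(EBImage::bwlabel(ph$mask$mask * 1)), 1)
    filled <- EBImage::fillHull(ph$mask$mask * 1) > 0
    expect_identical(filled, ph$mask$mask) # no holes
  }
})

test_that("invariant-violating phantom specs are rejected", {
  expect_error(phantom_spec(head_radius_px = 5, neck_width_px = 14),
               class = "pfbmri_param_error")
  expect_error(phantom_spec(salt_pepper_fraction = 1.5),
               class = "pfbmri_param_error")
  expect_error(phantom_spec(protocol_gain = 0), class = "pfbmri_param_error")
})

test_that("gaussian noise hits the requested SNR within 0.5 dB", {
  ph <- generate_phantom(phantom_spec(size = 256, rng_seed = 3))
  p_sig <- mean(ph$image$pixels^2)
  for (snr in c(-4, 0, 10, 20)) {
    noisy <- add_gaussian_noise(ph$image, snr, rng_seed = 7, clip = FALSE)
    nv <- var(as.numeric(noisy$pixels - ph$image$pixels))
    realized <- 10 * log10(p_sig / nv)
    expect_lt(abs(realized - snr), 0.5)
  }
  # clipped output never goes negative
  clipped <- add_gaussian_noise(ph$image, -4, rng_seed = 7)
  expect_gte(min(clipped$pixels), 0)
})

test_that("vanishing noise leaves the image essentially unchanged", {
  ph <- default_phantom()
  noisy <- add_gaussian_noise(ph$image, 60, rng_seed = 1, clip = FALSE)
  rms_dev <- sqrt(mean((noisy$pixels - ph$image$pixels)^2))
  rms_sig <- sqrt(mean(ph$image$pixels^2))
  expect_lt(rms_dev / rms_sig, 0.002)
})

test_that("different noise seeds give different fields, same variance target", {
  ph <- default_phantom()
  a <- add_gaussian_noise(ph$image, 10, rng_seed = 1, clip = FALSE)
  b <- add_gaussian_noise(ph$image, 10, rng_seed = 2, clip = FALSE)
  expect_false(identical(a$pixels, b$pixels))
  expect_equal(attr(a, "noise_sd"), attr(b, "noise_sd"))
  expect_error(add_gaussian_noise(matrix(5, 64, 64), 10),
               class = "pfbmri_param_error")
})

test_that("minority augmentation exactly balances class counts", {
  ds <- phantom_dataset(n_per_class = 5, separation = 1, size = 96,
                        rng_seed = 2)
  ds$images <- ds$images[1:8] # 5 healthy vs 3 unhealthy
  ds$masks <- ds$masks[1:8]
  aug <- augment_minority(ds, rng_seed = 3)
  labs <- vapply(aug$images, function(im) im$label, numeric(1))
  expect_equal(sum(labs == 0), 5)
  expect_equal(sum(labs == 1), 5)
  expect_length(aug$images, 10)
  # originals untouched, majority count unchanged
  for (i in 1:8) {
    expect_identical(aug$images[[i]]$pixels, ds$images[[i]]$pixels)
  }
})

test_that("augmentation reproduces the cohort's 185/99 -> 185/185 balance", {
  imgs <- lapply(seq_len(284), function(i) {
    pfb_image(matrix(runif(32 * 32, 10, 50), 32, 32),
              subject_id = sprintf("s%03d", i),
              label = if (i <= 185) 0 else 1)
  })
  aug <- augment_minority(pfb_dataset(imgs), rng_seed = 5)
  labs <- vapply(aug$images, function(im) im$label, numeric(1))
  expect_equal(unname(c(sum(labs == 0), sum(labs == 1))), c(185, 185))
})

test_that("already-balanced datasets pass through augmentation unchanged", {
  ds <- phantom_dataset(n_per_class = 3, separation = 0, size = 96,
                        rng_seed = 2)
  expect_identical(augment_minority(ds, rng_seed = 1), ds)
  one_class <- pfb_dataset(ds$images[1:3], ds$masks[1:3])
  expect_error(augment_minority(one_class, rng_seed = 1),
               class = "pfbmri_balance_error")
})

test_that("separation-0 datasets draw both classes from the same distributions", {
  ds <- phantom_dataset(n_per_class = 12, separation = 0, size = 96,
                        rng_seed = 6)
  specs <- lapply(ds$masks, attr, "spec")
  nw <- vapply(specs, function(s) s$neck_width_px, numeric(1))
  labs <- dataset_labels(ds)
  # same generating law: a t-test should find nothing (checked loosely)
  expect_gt(t.test(nw[labs == 0], nw[labs == 1])$p.value, 0.01)
})

test_that("labels follow the T-score threshold rule", {
  expect_equal(healthy_label(c(-0.89, -0.9, -0.91, 1.2)), c(0, 1, 1, 0))
  expect_error(pfb_image(matrix(1, 32, 32), t_score = -2, label = 0),
               class = "pfbmri_param_error")
  ds <- phantom_dataset(n_per_class = 5, separation = 1, size = 96,
                        rng_seed = 4)
  for (im in ds$images) {
    expect_equal(im$label, healthy_label(im$t_score))
  }
})
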