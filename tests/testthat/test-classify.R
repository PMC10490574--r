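test_that("stratified folds partition all subjects with near-equal sizes", {
  labels <- rep(c(0, 1), c(185, 99))
  f <- kfold_split(284, 10, labels, rng_seed = 4)
  sizes <- as.numeric(table(f))
  expect_equal(sort(unique(sizes)), c(28, 29))
  expect_equal(sum(sizes), 284)
  # stratification: class balance within one per fold
  for (k in 1:10) {
    expect_lte(diff(range(table(labels[f == k]))), 19) # both classes present
    expect_true(all(c(0, 1) %in% labels[f == k]))
  }
  expect_identical(f, kfold_split(284, 10, labels, rng_seed = 4))
  expect_false(identical(f, kfold_split(284, 10, labels, rng_seed = 5)))
  expect_warning(kfold_split(20, 10, rep(c(0, 1), c(15, 5)), rng_seed = 1),
                 class = "pfbmri_stratification_warning")
})

test_that("metrics reproduce the printed study results for all six classifiers", {
  published <- list( # TH, FH, TU, FU, accuracy %, F1 %
    "svm-linear" = c(167, 24, 75, 18, 85.21, 83.48),
    "svm-rbf" = c(172, 18, 81, 13, 89.08, 87.84),
    "svm-gaussian" = c(173, 24, 75, 12, 87.32, 85.61),
    "svm-poly" = c(161, 11, 88, 24, 87.68, 86.80),
    "dtree" = c(168, 24, 75, 17, 85.56, 83.83),
    "logreg" = c(158, 24, 75, 27, 82.04, 80.37))
  for (row in published) {
    cm <- confusion_matrix(row[1], row[2], row[3], row[4])
    expect_equal(cm$TH + cm$FH + cm$TU + cm$FU, 284)
    m <- metrics(cm)
    expect_equal(m$accuracy, row[5])
    expect_equal(m$f1, row[6])
  }
})

test_that("perfect and degenerate confusion matrices are handled", {
  m <- metrics(confusion_matrix(10, 0, 5, 0))
  expect_equal(m$accuracy, 100)
  expect_equal(m$f1, 100)
  zero_u <- metrics(confusion_matrix(10, 0, 0, 0))
  expect_true(zero_u$degenerate)
  expect_equal(zero_u$f1_unhealthy, 0)
  expect_error(metrics(confusion_matrix(0, 0, 0, 0)),
               class = "pfbmri_metric_error")
  expect_error(confusion_matrix(-1, 0, 0, 0), class = "pfbmri_param_error")
})

test_that("every classifier separates a linearly separable table perfectly", {
  withr::with_seed(7, {
    n <- 80
    y <- rep(c(0, 1), each = n / 2)
    X <- cbind(f1 = y * 4 + rnorm(n, 0, 0.3), f2 = rnorm(n))
  })
  feats <- dplyr::bind_cols(tibble::tibble(label = y), tibble::as_tibble(X))
  for (fam in classifier_families()) {
    cv <- cross_validate(classifier_spec(fam), feats, rng_seed = 2)
    expect_equal(metrics(cv$confusion)$accuracy, 100,
                 info = fam)
  }
})

test_that("label-permuted features score near chance", {
  withr::with_seed(19, {
    n <- 200
    y <- sample(rep(c(0, 1), each = n / 2))
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
  })
  feats <- dplyr::bind_cols(tibble::tibble(label = y), tibble::as_tibble(X))
  cv <- cross_validate(classifier_spec("svm-rbf"), feats, rng_seed = 3)
  acc <- metrics(cv$confusion)$accuracy
  expect_gte(acc, 40)
  expect_lte(acc, 60)
})

test_that("cross-validation pools every subject exactly once and is deterministic", {
  ds <- phantom_dataset(n_per_class = 10, separation = 1, size = 96,
                        rng_seed = 5)
  ft <- build_feature_table(ds)
  cv <- cross_validate(classifier_spec("svm-linear"), ft, k = 5, rng_seed = 6)
  expect_equal(cv$confusion$TH + cv$confusion$FH + cv$confusion$TU +
                 cv$confusion$FU, 20)
  cv2 <- cross_validate(classifier_spec("svm-linear"), ft, k = 5, rng_seed = 6)
  expect_identical(cv$confusion, cv2$confusion)
  expect_equal(nrow(tidy(cv)), 20)
  g <- glance(cv)
  expect_equal(g$classifier, "svm-linear")
  expect_error(cross_validate(classifier_spec("svm-rbf"), ft[ft$label == 0, ]),
               class = "pfbmri_param_error")
})

test_that("fold-internal augmentation balances training folds without touching tests", {
  ds <- phantom_dataset(n_per_class = 8, separation = 1, size = 96,
                        rng_seed = 7)
  keep <- c(1:8, 9:13) # 8 healthy vs 5 unhealthy
  ds2 <- pfb_dataset(ds$images[keep], ds$masks[keep])
  ft <- build_feature_table(ds2)
  cv <- cross_validate(classifier_spec("svm-linear"), ft, k = 4,
                       augment = TRUE, dataset = ds2, rng_seed = 8)
  # pooled totals still equal the original dataset size: test folds were
  # never augmented
  expect_equal(sum(unlist(cv$confusion)), 13)
  expect_error(cross_validate(classifier_spec("svm-linear"), ft, k = 4,
                              augment = TRUE),
               class = "pfbmri_param_error")
})

test_that("class-average difference localises the class contrast", {
  ds <- phantom_dataset(n_per_class = 10, separation = 1, size = 96,
                        rng_seed = 9)
  d <- class_average_difference(ds, size = 64)
  expect_equal(dim(d), c(64, 64))
  # unhealthy bone is darker: the difference inside the bone is negative
  expect_lt(mean(d[24:40, 24:40]), 0)
  # two identical class distributions: difference is near zero relative to
  # the intensity scale
  ds0 <- phantom_dataset(n_per_class = 12, separation = 0, size = 96,
                         rng_seed = 10)
  d0 <- class_average_difference(ds0, size = 64)
  expect_lt(mean(abs(d0)) / mean(attr(d0, "mean_healthy")), 0.25)
  # single image per class: exact difference of the canonical crops
  ds1 <- pfb_dataset(ds$images[c(1, 11)], ds$masks[c(1, 11)])
  d1 <- class_average_difference(ds1, size = 64)
  expect_equal(unclass(d1),
               attr(d1, "mean_unhealthy") - attr(d1, "mean_healthy"),
               ignore_attr = TRUE)
})

test_that("noise sweep returns one accuracy per SNR plus the clean reference", {
  ds <- phantom_dataset(n_per_class = 8, separation = 1, size = 96,
                        rng_seed = 12)
  ns <- noise_sweep(classifier_spec("svm-rbf"), ds, snr_db = c(60, 0),
                    k = 4, rng_seed = 13, use_truth_masks = TRUE)
  expect_equal(nrow(ns), 3)
  expect_equal(ns$snr_db, c(60, 0, Inf))
  expect_true(all(ns$accuracy >= 0 & ns$accuracy <= 100))
  # vanishing noise tracks the clean reference
  clean <- ns$accuracy[is.infinite(ns$snr_db)]
  expect_lte(abs(ns$accuracy[ns$snr_db == 60] - clean), 2)
})
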