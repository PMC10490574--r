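test_that("the selection cost trades accuracy against feature count", {
  expect_equal(ga_cost(0.5, 2), 1)
  expect_equal(ga_cost(0.8908, 56), 1 / (0.8908 + 1 / 56), tolerance = 1e-12)
  expect_equal(round(ga_cost(0.8908, 56), 4), 1.1005)
  expect_lt(ga_cost(0.9, 10), ga_cost(0.9, 20)) # fewer features is better
  expect_lt(ga_cost(0.9, 10), ga_cost(0.8, 10)) # higher accuracy is better
  expect_error(ga_cost(0.5, 0), class = "pfbmri_ga_error")
  expect_error(ga_cost(1.2, 5), class = "pfbmri_param_error")
})

test_that("a perfectly predictive single feature evaluates to cost 0.5", {
  feats <- planted_feature_table(n = 100, noise_features = 5, seed = 2,
                                 signal_sd = 0)
  bits <- c(TRUE, rep(FALSE, 5))
  ev <- evaluate_chromosome(bits, feats, classifier_spec("logreg"),
                            rng_seed = 1)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$cost, 0.5)
  expect_equal(ev$nof, 1)
  expect_error(evaluate_chromosome(rep(FALSE, 6), feats,
                                   classifier_spec("logreg")),
               class = "pfbmri_ga_error")
})

test_that("all-noise chromosomes evaluate near chance", {
  feats <- planted_feature_table(n = 200, noise_features = 10, seed = 3)
  bits <- c(FALSE, rep(TRUE, 10)) # noise columns only
  ev <- evaluate_chromosome(bits, feats, classifier_spec("logreg"),
                            rng_seed = 4)
  expect_gte(ev$accuracy, 0.4)
  expect_lte(ev$accuracy, 0.6)
})

test_that("chromosome evaluation is cached and deterministic", {
  feats <- planted_feature_table(n = 100, noise_features = 5, seed = 5)
  cache <- new.env(parent = emptyenv())
  folds <- kfold_split(100, 10, feats$label, rng_seed = 6)
  bits <- c(TRUE, TRUE, rep(FALSE, 4))
  a <- evaluate_chromosome(bits, feats, classifier_spec("svm-linear"),
                           folds = folds, cache = cache)
  b <- evaluate_chromosome(bits, feats, classifier_spec("svm-linear"),
                           folds = folds, cache = cache)
  expect_identical(a, b)
  expect_length(ls(cache), 1)
})

test_that("the GA finds the planted singleton that exhaustive search certifies", {
  feats <- planted_feature_table(n = 200, noise_features = 20, seed = 9)
  spec <- classifier_spec("logreg")
  # oracle: exhaustive search over singleton subsets
  folds <- kfold_split(200, 10, feats$label, rng_seed = 1)
  singleton_costs <- vapply(1:21, function(j) {
    b <- rep(FALSE, 21); b[j] <- TRUE
    evaluate_chromosome(b, feats, spec, folds = folds)$cost
  }, numeric(1))
  expect_equal(which.min(singleton_costs), 1)
  expect_equal(min(singleton_costs), 0.5)

  run <- ga_select(feats, spec, population = 40, iterations = 40,
                   rng_seed = 1)
  expect_equal(which(run$best_bits), 1)
  expect_equal(run$best_cost, 0.5)
  # elitism: the best-cost series never increases
  expect_true(all(diff(run$history$cost) <= 1e-12))
})

test_that("GA history and accessors expose the run structure", {
  feats <- planted_feature_table(n = 100, noise_features = 8, seed = 10)
  run <- ga_select(feats, classifier_spec("logreg"), population = 15,
                   iterations = 10, rng_seed = 2)
  expect_equal(nrow(run$history), 10)
  expect_equal(tidy(run), run$history)
  g <- glance(run)
  expect_equal(g$nof, sum(run$best_bits))
  expect_equal(g$iterations, 10)
  expect_error(ga_select(feats[feats$label == 1, ],
                         classifier_spec("logreg")),
               class = "pfbmri_param_error")
})

test_that("selection maps mirror the per-iteration best chromosomes", {
  feats <- planted_feature_table(n = 100, noise_features = 8, seed = 11)
  run <- ga_select(feats, classifier_spec("logreg"), population = 15,
                   iterations = 10, rng_seed = 3)
  m <- selection_map(run)
  expect_equal(dim(m), c(9, 10))
  expect_identical(rownames(m), run$feature_names)
  # column popcount equals the best chromosome's NOF at that iteration
  expect_equal(unname(colSums(m)), run$history$nof)
  # a feature selected in every recorded generation is an all-ones row
  final <- which(run$best_bits)
  if (all(m[final[1], ] == 1)) expect_equal(sum(m[final[1], ]), 10)
  tmp <- withr::local_tempfile(fileext = ".png")
  write_selection_map_png(run, tmp)
  expect_true(file.exists(tmp))
})

test_that("different seeds may select different feature sets", {
  feats <- planted_feature_table(n = 100, noise_features = 8, seed = 12,
                                 signal_sd = 1.5) # weak signal
  r1 <- ga_select(feats, classifier_spec("logreg"), population = 12,
                  iterations = 6, rng_seed = 4)
  r2 <- ga_select(feats, classifier_spec("logreg"), population = 12,
                  iterations = 6, rng_seed = 5)
  # stability is measured, not required: both runs complete with valid costs
  expect_gte(r1$best_cost, 0)
  expect_gte(r2$best_cost, 0)
})
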