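#' Feature-selection cost of a chromosome
#'
#' `cost = 1 / (accuracy + 1/NOF)`: lower is better, so the genetic
#' algorithm is pushed both towards high cross-validated accuracy
#' (a fraction in `[0, 1]`) and towards few selected features (NOF).
#'
#' @param accuracy Cross-validated accuracy as a fraction in `[0, 1]`.
#' @param nof Number of selected features (>= 1).
#' @return The cost (positive real; lower is better).
#' @export
ga_cost <- function(accuracy, nof) {
  if (any(nof < 1)) {
    stop_pfb("chromosome selects no features (NOF = 0); repair it first",
             "pfbmri_ga_error")
  }
  if (any(accuracy < 0 | accuracy > 1)) {
    stop_pfb("accuracy must be a fraction in [0, 1]", "pfbmri_param_error")
  }
  1 / (accuracy + 1 / nof)
}

# Pooled k-fold CV accuracy (fraction) of `spec` on the selected columns.
cv_accuracy <- function(spec, X, labels, folds) {
  correct <- 0
  for (f in sort(unique(folds))) {
    te <- which(folds == f)
    tr <- which(folds != f)
    st <- standardize_fit_apply(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    fit <- fit_classifier(spec, st$train, labels[tr])
    correct <- correct + sum(predict_classifier(fit, st$test) ==
                               as.character(labels[te]))
  }
  correct / length(labels)
}

#' Evaluate one chromosome
#'
#' Cross-validated accuracy of the classifier restricted to the selected
#' feature columns, and the corresponding cost. Fold assignment is fixed
#' per GA run (all chromosomes see the same folds, so costs are
#' comparable) and evaluations are cached by bitstring.
#'
#' @param bits Logical selection mask over the feature columns.
#' @param features Feature tibble.
#' @param spec A [classifier_spec()].
#' @param folds Optional fold vector (computed from `rng_seed` if
#'   missing).
#' @param k Folds when `folds` is missing.
#' @param rng_seed Integer seed.
#' @param cache Optional environment used as an evaluation cache.
#' @return List with `accuracy` (fraction), `cost` and `nof`.
#' @export
evaluate_chromosome <- function(bits, features, spec, folds = NULL, k = 10,
                                rng_seed = 1, cache = NULL) {
  bits <- as.logical(bits)
  if (!any(bits)) {
    stop_pfb("chromosome selects no features", "pfbmri_ga_error")
  }
  key <- paste0(as.integer(bits), collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  cols <- feature_columns(features)
  stopifnot(length(bits) == length(cols))
  labels <- features[["label"]]
  if (is.null(folds)) {
    folds <- kfold_split(nrow(features), k, labels, rng_seed = rng_seed)
  }
  X <- as.matrix(features[, cols[bits], drop = FALSE])
  acc <- cv_accuracy(spec, X, labels, folds)
  out <- list(accuracy = acc, cost = ga_cost(acc, sum(bits)),
              nof = sum(bits))
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Genetic-algorithm wrapper feature selection
#'
#' Minimises [ga_cost()] over bitmask chromosomes (one bit per feature
#' column) with tournament selection, uniform crossover, bit-flip
#' mutation and elitism. Empty chromosomes are repaired by switching one
#' random bit on. The best-cost series is monotone non-increasing
#' (elitism), and the per-iteration best chromosomes are kept so
#' selection maps can be rendered.
#'
#' @param features Feature tibble with both classes.
#' @param spec A [classifier_spec()] used inside the fitness evaluation.
#' @param population Population size (study setting: 100).
#' @param iterations Maximum generations (study setting: 500).
#' @param p_crossover Uniform-crossover probability (default 0.8).
#' @param mutation_rate Per-bit flip probability (default `1/n_bits`).
#' @param tournament_size Tournament size (default 3).
#' @param elitism Number of elites copied unchanged (default 1).
#' @param k CV folds in the fitness (default 10).
#' @param patience Optional early stop after this many stagnant
#'   generations (default `NULL`: run all iterations).
#' @param rng_seed Integer seed.
#' @return A `pfb_ga` object with `history` (per-iteration tibble),
#'   `bits_history` (features x iterations logical matrix), `best_bits`,
#'   `best_cost`, `best_accuracy` and bookkeeping fields.
#' @export
ga_select <- function(features, spec, population = 100, iterations = 500,
                      p_crossover = 0.8, mutation_rate = NULL,
                      tournament_size = 3, elitism = 1, k = 10,
                      patience = NULL, rng_seed = 1) {
  labels <- features[["label"]]
  if (is.null(labels) || length(unique(labels)) < 2) {
    stop_pfb("feature table must contain both classes", "pfbmri_param_error")
  }
  cols <- feature_columns(features)
  nbits <- length(cols)
  mutation_rate <- mutation_rate %||% (1 / nbits)
  folds <- kfold_split(nrow(features), k, labels, rng_seed = rng_seed)
  cache <- new.env(parent = emptyenv())

  repair <- function(bits) {
    if (!any(bits)) bits[sample.int(nbits, 1)] <- TRUE
    bits
  }
  evaluate <- function(bits) {
    evaluate_chromosome(bits, features, spec, folds = folds, cache = cache)
  }

  with_seed(rng_seed, {
    pop <- matrix(runif(population * nbits) < 0.5, population, nbits)
    pop <- t(apply(pop, 1, repair))
    scores <- apply(pop, 1, function(b) evaluate(b)$cost)

    hist_rows <- vector("list", iterations)
    bits_history <- matrix(FALSE, nbits, iterations)
    best_cost <- Inf
    best_bits <- pop[1, ]
    stagnant <- 0
    it_done <- 0

    for (it in seq_len(iterations)) {
      gen_best <- which.min(scores)
      if (scores[gen_best] < best_cost - 1e-12) {
        best_cost <- scores[gen_best]
        best_bits <- pop[gen_best, ]
        stagnant <- 0
      } else {
        stagnant <- stagnant + 1
      }
      ev <- evaluate(best_bits)
      hist_rows[[it]] <- tibble::tibble(
        iteration = it, cost = ev$cost, accuracy = ev$accuracy,
        nof = ev$nof)
      bits_history[, it] <- best_bits
      it_done <- it
      if (!is.null(patience) && stagnant >= patience) break
      if (it == iterations) break

      elite_idx <- order(scores)[seq_len(elitism)]
      new_pop <- matrix(FALSE, population, nbits)
      new_pop[seq_len(elitism), ] <- pop[elite_idx, , drop = FALSE]
      # elitism must preserve the all-time best
      new_pop[1, ] <- best_bits
      for (i in (elitism + 1):population) {
        tournament <- function() {
          cand <- sample.int(population, tournament_size)
          cand[which.min(scores[cand])]
        }
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        child <- if (runif(1) < p_crossover) {
          mask <- runif(nbits) < 0.5
          ifelse(mask, p1, p2)
        } else {
          p1
        }
        flip <- runif(nbits) < mutation_rate
        child <- xor(child, flip)
        new_pop[i, ] <- repair(child)
      }
      pop <- new_pop
      scores <- apply(pop, 1, function(b) evaluate(b)$cost)
    }

    history <- dplyr::bind_rows(hist_rows[seq_len(it_done)])
    structure(
      list(history = history,
           bits_history = bits_history[, seq_len(it_done), drop = FALSE],
           best_bits = best_bits, best_cost = best_cost,
           best_accuracy = evaluate(best_bits)$accuracy,
           feature_names = cols, classifier = spec,
           population = population, iterations = it_done,
           evaluations = length(ls(cache)), rng_seed = rng_seed),
      class = "pfb_ga")
  })
}

#' @export
print.pfb_ga <- function(x, ...) {
  cat(sprintf("<pfb_ga> %s, pop %d, %d iterations: best cost %.4f (accuracy %.3f, %d features)\n",
              x$classifier$family, x$population, x$iterations,
              x$best_cost, x$best_accuracy, sum(x$best_bits)))
  invisible(x)
}

#' Broom-style accessors for GA runs
#'
#' `tidy()` returns the per-iteration best cost/accuracy/NOF history;
#' `glance()` a one-row summary.
#'
#' @param x A `pfb_ga` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pfb_ga <- function(x, ...) x$history

#' @rdname tidy.pfb_ga
#' @export
glance.pfb_ga <- function(x, ...) {
  tibble::tibble(classifier = x$classifier$family,
                 best_cost = x$best_cost,
                 best_accuracy = x$best_accuracy,
                 nof = sum(x$best_bits),
                 iterations = x$iterations,
                 evaluations = x$evaluations)
}

#' Feature-selection map of a GA run
#'
#' Binary matrix with one row per feature and one column per iteration;
#' entry `(i, t)` is 1 when feature `i` was selected in the best
#' chromosome at iteration `t`. A horizontal all-ones row is a feature
#' that was steadily chosen. Use [write_selection_map_png()] to export
#' (white = selected).
#'
#' @param run A `pfb_ga` object.
#' @return Integer 0/1 matrix, `n_features x n_iterations`, with feature
#'   names as row names.
#' @export
selection_map <- function(run) {
  stopifnot(inherits(run, "pfb_ga"))
  m <- run$bits_history * 1L
  rownames(m) <- run$feature_names
  m
}

#' @rdname selection_map
#' @param path Output PNG path.
#' @export
write_selection_map_png <- function(run, path) {
  m <- selection_map(run)
  png::writePNG(m * 1.0, path)
  invisible(path)
}
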