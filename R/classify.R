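#' Classifier specification
#'
#' The six classifier families evaluated by the pipeline. `"svm-rbf"` and
#' `"svm-gaussian"` share the radial kernel form but use two different
#' kernel-scale policies: the scale heuristic `gamma = 1 / (d * mean
#' feature variance)` for RBF and the median-pairwise-distance bandwidth
#' for Gaussian. Hyperparameters not set here fall back to fixed defaults
#' (SVM cost 1, polynomial degree 3, tree complexity `cp = 0.01`,
#' unpenalised logistic regression).
#'
#' @param family One of `"svm-linear"`, `"svm-poly"`, `"svm-rbf"`,
#'   `"svm-gaussian"`, `"dtree"`, `"logreg"`.
#' @param ... Named hyperparameters (`cost`, `degree`, `cp`, ...).
#' @param rng_seed Optional seed recorded on the spec.
#' @return A `pfb_classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm-linear", "svm-poly", "svm-rbf",
                                       "svm-gaussian", "dtree", "logreg"),
                            ..., rng_seed = NULL) {
  family <- match.arg(family)
  structure(list(family = family, params = list(...), rng_seed = rng_seed),
            class = "pfb_classifier_spec")
}

#' The six classifier families
#' @return Character vector of family names.
#' @export
classifier_families <- function() {
  c("svm-linear", "svm-poly", "svm-rbf", "svm-gaussian", "dtree", "logreg")
}

fit_classifier <- function(spec, X, y) {
  stopifnot(is.matrix(X))
  y <- factor(y, levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2) {
    stop_pfb("training fold contains a single class", "pfbmri_fold_error")
  }
  p <- spec$params
  cost <- p$cost %||% 1
  model <- switch(
    spec$family,
    "svm-linear" = e1071::svm(X, y, kernel = "linear", cost = cost,
                              scale = FALSE),
    "svm-poly" = e1071::svm(X, y, kernel = "polynomial",
                            degree = p$degree %||% 3, coef0 = 1,
                            cost = cost, scale = FALSE),
    "svm-rbf" = {
      mv <- mean(apply(X, 2, var))
      gamma <- if (is.finite(mv) && mv > 0) 1 / (ncol(X) * mv) else 1 / ncol(X)
      e1071::svm(X, y, kernel = "radial", gamma = gamma, cost = cost,
                 scale = FALSE)
    },
    "svm-gaussian" = {
      idx <- if (nrow(X) > 200) seq(1, nrow(X), length.out = 200) else seq_len(nrow(X))
      d <- as.numeric(dist(X[round(idx), , drop = FALSE]))
      sigma <- median(d[d > 0])
      gamma <- if (is.finite(sigma) && sigma > 0) 1 / (2 * sigma^2) else 1 / ncol(X)
      e1071::svm(X, y, kernel = "radial", gamma = gamma, cost = cost,
                 scale = FALSE)
    },
    "dtree" = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = p$cp %||% 0.01,
                                                  xval = 0))
    },
    "logreg" = {
      # glm.fit directly: identical model, none of the formula overhead
      fit <- suppressWarnings(
        glm.fit(cbind(`(Intercept)` = 1, X), as.numeric(y) - 1,
                family = binomial(),
                control = list(maxit = p$maxit %||% 25)))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      list(beta = beta)
    })
  structure(list(model = model, spec = spec, cols = colnames(X)),
            class = "pfb_fit")
}

predict_classifier <- function(fit, X) {
  stopifnot(is.matrix(X))
  fam <- fit$spec$family
  if (fam == "dtree") {
    df <- data.frame(X, check.names = FALSE)
    as.character(predict(fit$model, df, type = "class"))
  } else if (fam == "logreg") {
    eta <- drop(cbind(1, X) %*% fit$model$beta)
    ifelse(eta > 0, "1", "0")
  } else {
    as.character(predict(fit$model, X))
  }
}

#' Stratified k-fold assignment
#'
#' Shuffles indices within each class and deals them cyclically into `k`
#' folds with a running counter across classes, so per-class counts are
#' balanced within one and total fold sizes differ by at most one. A
#' class with fewer than `k` members triggers a warning and a plain
#' (unstratified) partition.
#'
#' @param n Number of subjects.
#' @param k Number of folds (default 10).
#' @param labels Class labels (length `n`).
#' @param rng_seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
kfold_split <- function(n, k = 10, labels, rng_seed = 1) {
  stopifnot(length(labels) == n)
  if (n < k) stop_pfb("need at least k subjects", "pfbmri_param_error")
  counts <- table(labels)
  if (length(counts) < 2) {
    stop_pfb("both classes must be present", "pfbmri_param_error")
  }
  with_seed(rng_seed, {
    folds <- integer(n)
    if (any(counts < k)) {
      warn("a class has fewer than k members; falling back to a plain partition",
           class = "pfbmri_stratification_warning")
      ord <- sample.int(n)
      folds[ord] <- rep_len(seq_len(k), n)
    } else {
      ord <- unlist(lapply(sort(unique(labels)), function(lv) {
        idx <- which(labels == lv)
        idx[sample.int(length(idx))]
      }))
      folds[ord] <- rep_len(seq_len(k), n)
    }
    folds
  })
}

#' Pooled confusion matrix in the healthy/unhealthy naming
#'
#' `TH`/`TU` are correctly predicted healthy/unhealthy subjects; `FH` are
#' unhealthy subjects predicted healthy (the clinically costly miss); `FU`
#' are healthy subjects predicted unhealthy.
#'
#' @param TH,FH,TU,FU Non-negative integer counts.
#' @return A `pfb_confusion` tibble row.
#' @export
confusion_matrix <- function(TH, FH, TU, FU) {
  counts <- c(TH = TH, FH = FH, TU = TU, FU = FU)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_pfb("confusion counts must be non-negative integers",
             "pfbmri_param_error")
  }
  structure(tibble::tibble(TH = TH, FH = FH, TU = TU, FU = FU),
            class = c("pfb_confusion", class(tibble::tibble())))
}

#' Accuracy and macro-F1 of a confusion matrix (percent)
#'
#' `accuracy = 100 (TH + TU) / (TH + TU + FH + FU)`; macro-F1 averages
#' the F1 of the healthy-as-positive view (TP = TH, FP = FH, FN = FU) and
#' the unhealthy-as-positive view (TP = TU, FP = FU, FN = FH). Both are
#' rounded to 2 decimals for report parity; a per-class F1 with a zero
#' denominator is scored 0 and flagged.
#'
#' @param cm A [confusion_matrix()] (or list with TH, FH, TU, FU).
#' @return Tibble with `accuracy`, `f1` (macro), `f1_healthy`,
#'   `f1_unhealthy` in percent, and a `degenerate` flag.
#' @export
metrics <- function(cm) {
  TH <- cm$TH; FH <- cm$FH; TU <- cm$TU; FU <- cm$FU
  total <- TH + FH + TU + FU
  if (total <= 0) stop_pfb("empty confusion matrix", "pfbmri_metric_error")
  f1_part <- function(tp, fp, fn) {
    den <- 2 * tp + fp + fn
    if (den == 0) c(0, TRUE) else c(2 * tp / den, FALSE)
  }
  fh <- f1_part(TH, FH, FU)
  fu <- f1_part(TU, FU, FH)
  tibble::tibble(
    accuracy = round(100 * (TH + TU) / total, 2),
    f1 = round(100 * mean(c(fh[1], fu[1])), 2),
    f1_healthy = round(100 * fh[1], 2),
    f1_unhealthy = round(100 * fu[1], 2),
    degenerate = as.logical(fh[2] + fu[2] > 0))
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation with fold-internal preprocessing:
#' optional minority-class augmentation on the training images only, then
#' z-scoring fit on the training rows, classifier fit, and test-fold
#' prediction. Test-fold predictions are pooled over all folds into a
#' single confusion matrix, so the totals equal the dataset size.
#'
#' @param spec A [classifier_spec()].
#' @param features Feature tibble ([build_feature_table()]).
#' @param k Number of folds (default 10).
#' @param augment Balance classes inside each training fold by image
#'   augmentation; requires `dataset`.
#' @param dataset The [pfb_dataset] (with masks) aligned row-for-row with
#'   `features`; only needed when `augment = TRUE`.
#' @param rng_seed Integer seed (folds and augmentation).
#' @return A `pfb_cv` object: `confusion`, per-subject `predictions`
#'   tibble, the fold vector and the spec.
#' @export
cross_validate <- function(spec, features, k = 10, augment = FALSE,
                           dataset = NULL, rng_seed = 1) {
  labels <- features[["label"]]
  if (is.null(labels) || length(unique(labels)) < 2) {
    stop_pfb("feature table must contain both classes", "pfbmri_param_error")
  }
  if (augment && is.null(dataset)) {
    stop_pfb("augment = TRUE requires the aligned image dataset",
             "pfbmri_param_error")
  }
  n <- nrow(features)
  folds <- kfold_split(n, k, labels, rng_seed = rng_seed)
  cols <- feature_columns(features)
  X <- as.matrix(features[, cols])
  pred <- character(n)
  for (f in sort(unique(folds))) {
    te <- which(folds == f)
    tr <- which(folds != f)
    Xtr <- X[tr, , drop = FALSE]
    ytr <- labels[tr]
    if (augment) {
      sub <- pfb_dataset(dataset$images[tr],
                        if (!is.null(dataset$masks)) dataset$masks[tr])
      aug <- augment_minority(sub, rng_seed = rng_seed + f)
      extra <- setdiff(seq_along(aug$images), seq_along(sub$images))
      if (length(extra)) {
        newX <- do.call(rbind, lapply(extra, function(i) {
          extract_features(aug$images[[i]], aug$masks[[i]])
        }))
        Xtr <- rbind(Xtr, newX[, cols, drop = FALSE])
        ytr <- c(ytr, vapply(aug$images[extra],
                             function(im) im$label, numeric(1)))
      }
    }
    st <- standardize_fit_apply(Xtr, X[te, , drop = FALSE])
    fit <- tryCatch(fit_classifier(spec, st$train, ytr), error = function(e) {
      stop_pfb(sprintf("classifier fit failed in fold %d: %s", f,
                       conditionMessage(e)), "pfbmri_fold_error")
    })
    pred[te] <- predict_classifier(fit, st$test)
  }
  truth <- as.character(labels)
  cm <- confusion_matrix(
    TH = sum(pred == "0" & truth == "0"),
    FH = sum(pred == "0" & truth == "1"),
    TU = sum(pred == "1" & truth == "1"),
    FU = sum(pred == "1" & truth == "0"))
  structure(
    list(confusion = cm,
         predictions = tibble::tibble(
           subject_id = features[["subject_id"]] %||%
             as.character(seq_len(n)),
           truth = truth, predicted = pred, fold = folds),
         folds = folds, spec = spec, rng_seed = rng_seed),
    class = "pfb_cv")
}

#' @export
print.pfb_cv <- function(x, ...) {
  m <- metrics(x$confusion)
  cat(sprintf("<pfb_cv> %s: TH=%d FH=%d TU=%d FU=%d | acc %.2f%% F1 %.2f%%\n",
              x$spec$family, x$confusion$TH, x$confusion$FH,
              x$confusion$TU, x$confusion$FU, m$accuracy, m$f1))
  invisible(x)
}

#' Broom-style accessors for cross-validation results
#'
#' `tidy()` returns the per-subject predictions; `glance()` a one-row
#' summary with the pooled confusion counts and metrics.
#'
#' @param x A `pfb_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pfb_cv <- function(x, ...) x$predictions

#' @rdname tidy.pfb_cv
#' @export
glance.pfb_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(classifier = x$spec$family),
    tibble::as_tibble(x$confusion),
    metrics(x$confusion)[, c("accuracy", "f1")])
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Noise-robustness sweep
#'
#' For each requested SNR, Gaussian white noise is injected into the test
#' images before feature extraction (training always uses clean images),
#' the test images are re-segmented and their features recomputed, and
#' the pooled cross-validated accuracy is reported next to the clean
#' reference (`snr_db = Inf`). If segmentation of a noisy image fails,
#' its clean-image mask is reused (counted in attribute `"fallbacks"`).
#'
#' @param spec A [classifier_spec()].
#' @param dataset A labeled [pfb_dataset] with ground-truth masks.
#' @param snr_db Numeric vector of SNRs to test (dB).
#' @param k Folds.
#' @param rng_seed Integer seed.
#' @param use_truth_masks Skip segmentation and use the dataset's masks
#'   (faster; isolates the feature/classifier stages from segmentation).
#' @return A `pfb_noise_sweep` tibble: `snr_db`, `accuracy` (percent).
#' @export
noise_sweep <- function(spec, dataset, snr_db, k = 10, rng_seed = 1,
                        use_truth_masks = FALSE) {
  n <- length(dataset$images)
  get_mask <- function(img, i) {
    if (use_truth_masks) {
      dataset$masks[[i]]
    } else {
      segment_best(img, truth = dataset$masks[[i]])
    }
  }
  clean_masks <- lapply(seq_len(n), function(i) {
    get_mask(dataset$images[[i]], i)
  })
  features <- build_feature_table(dataset, masks = clean_masks)
  labels <- features[["label"]]
  folds <- kfold_split(n, k, labels, rng_seed = rng_seed)
  cols <- feature_columns(features)
  X <- as.matrix(features[, cols])

  correct <- setNames(numeric(length(snr_db) + 1),
                      c(as.character(snr_db), "clean"))
  fallbacks <- 0
  for (f in sort(unique(folds))) {
    te <- which(folds == f)
    tr <- which(folds != f)
    st <- standardize_fit_apply(X[tr, , drop = FALSE], X[te, , drop = FALSE])
    fit <- fit_classifier(spec, st$train, labels[tr])
    truth <- as.character(labels[te])
    correct["clean"] <- correct["clean"] +
      sum(predict_classifier(fit, st$test) == truth)
    for (s in snr_db) {
      noisy_feats <- do.call(rbind, lapply(te, function(i) {
        img <- add_gaussian_noise(dataset$images[[i]], s,
                                  rng_seed = rng_seed + 7919 * i + round(100 * s))
        mk <- tryCatch(get_mask(img, i), error = function(e) {
          fallbacks <<- fallbacks + 1
          clean_masks[[i]]
        })
        extract_features(img, mk)
      }))
      z <- standardize_fit_apply(X[tr, , drop = FALSE],
                                 noisy_feats[, cols, drop = FALSE])$test
      correct[as.character(s)] <- correct[as.character(s)] +
        sum(predict_classifier(fit, z) == truth)
    }
  }
  acc <- round(100 * c(correct[as.character(snr_db)],
                       correct["clean"]) / n, 2)
  out <- tibble::tibble(snr_db = c(snr_db, Inf),
                        accuracy = unname(acc))
  attr(out, "fallbacks") <- fallbacks
  class(out) <- c("pfb_noise_sweep", class(out))
  out
}

#' Class-average difference image
#'
#' Canonical crops of all images are resampled to a common frame and
#' averaged per class; the signed difference (unhealthy minus healthy)
#' highlights the image regions where the two classes differ most --
#' predominantly the bone boundary when acquisition protocols match.
#'
#' @param dataset A labeled [pfb_dataset] with masks.
#' @param size Common frame side length (default 64).
#' @return A `size x size` matrix (unhealthy mean minus healthy mean),
#'   with the per-class means in attributes `"mean_healthy"` /
#'   `"mean_unhealthy"`.
#' @export
class_average_difference <- function(dataset, size = 64) {
  labs <- dataset_labels(dataset)
  if (!any(labs == 0) || !any(labs == 1)) {
    stop_pfb("need at least one image per class", "pfbmri_param_error")
  }
  canon <- lapply(seq_along(dataset$images), function(i) {
    cc <- crop_and_orient(dataset$masks[[i]], side = dataset$images[[i]]$side,
                          image = dataset$images[[i]])
    resize_matrix(cc$image, size, size)
  })
  mean_of <- function(lab) {
    Reduce(`+`, canon[labs == lab]) / sum(labs == lab)
  }
  m0 <- mean_of(0)
  m1 <- mean_of(1)
  structure(m1 - m0, mean_healthy = m0, mean_unhealthy = m1)
}
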