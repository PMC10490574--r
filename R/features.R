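#' Canonical feature names
#'
#' The 68 primary features in canonical (feature-table) order -- 12
#' geometric, 10 each for curves C1-1, C1-0, C2-0, C4-0, 8 for C1-2, 3
#' intensity statistics, 1 fractal dimension and 4 GLCM statistics -- or
#' the full 204-length set where entry `i + 68` is `(name_i)^2` and entry
#' `i + 136` is `(name_i)^3`.
#'
#' @param primary_only If `TRUE`, return only the 68 primary names.
#' @return Character vector of length 68 or 204.
#' @export
feature_names <- function(primary_only = FALSE) {
  geom <- c("x1", "y1", "L1", "L2", "theta", "W0", "W1", "W2", "W3", "W4",
            "x", "y")
  curves <- unlist(lapply(c("C1-1", "C1-2", "C1-0", "C2-0", "C4-0"),
                          function(nm) paste0(nm, "_", curve_stat_names(nm))))
  primary <- c(geom, curves,
               "gray_mean", "gray_variance", "gray_skew",
               "fractal_dim",
               "glcm_contrast", "glcm_correlation", "glcm_energy",
               "glcm_homogeneity")
  if (primary_only) return(primary)
  c(primary, sprintf("(%s)^2", primary), sprintf("(%s)^3", primary))
}

#' Assemble the 204-length feature vector
#'
#' Takes the 68 primary features (canonical order) and appends their
#' element-wise second and third powers -- never any other transform.
#'
#' @param primary Named numeric vector of the 68 primary features, in
#'   [feature_names()] order (names are checked).
#' @return Named numeric vector of length 204.
#' @export
assemble_features <- function(primary) {
  expected <- feature_names(primary_only = TRUE)
  if (length(primary) != length(expected)) {
    stop_pfb(sprintf("expected %d primary features, got %d",
                     length(expected), length(primary)),
             "pfbmri_assembly_error")
  }
  if (!is.null(names(primary)) && !identical(names(primary), expected)) {
    stop_pfb("primary feature names are not in canonical order",
             "pfbmri_assembly_error")
  }
  bad <- which(!is.finite(primary))
  if (length(bad)) {
    stop_pfb(sprintf("non-finite primary feature: %s",
                     paste(expected[bad], collapse = ", ")),
             "pfbmri_assembly_error")
  }
  primary <- setNames(as.numeric(primary), expected)
  out <- c(primary, primary^2, primary^3)
  names(out) <- feature_names()
  out
}

#' Extract the full feature vector of one image/mask pair
#'
#' Canonicalises the mask and image ([crop_and_orient()]), then computes
#' the geometric features, the five boundary-curve statistic sets, the
#' in-mask intensity statistics, the boundary fractal dimension and the
#' GLCM statistics, and assembles them with their 2nd/3rd powers into the
#' 204-length feature vector.
#'
#' @param image A [pfb_image].
#' @param mask The image's [pfb_mask] (any provenance).
#' @param frame Canonical crop frame width.
#' @return Named numeric vector of length 204.
#' @export
extract_features <- function(image, mask, frame = 5) {
  side <- if (inherits(image, "pfb_image")) image$side else "left"
  can <- crop_and_orient(mask, side = side, image = image, frame = frame)
  g <- extract_geometry(can$mask)
  curves <- extract_curves(can$mask)
  stats <- unlist(lapply(c("C1-1", "C1-2", "C1-0", "C2-0", "C4-0"),
                         function(nm) curve_stats(curves[[nm]])))
  gs <- gray_stats(can$image, can$mask)
  fd <- fractal_dimension(can$mask, of = "boundary")
  gl <- glcm_features(can$image, can$mask)
  primary <- c(geometry_vector(g), stats, gs, fractal_dim = fd, gl)
  names(primary) <- feature_names(primary_only = TRUE)
  assemble_features(primary)
}

#' Build the feature table of a dataset
#'
#' One row per image: `subject_id`, `label`, then the 204 named feature
#' columns.
#'
#' @param dataset A [pfb_dataset].
#' @param masks Per-image masks; defaults to the dataset's ground-truth
#'   masks. Pass masks produced by [segment_best()] to run the full
#'   pipeline.
#' @param frame Canonical crop frame width.
#' @return A tibble with `2 + 204` columns.
#' @export
build_feature_table <- function(dataset, masks = dataset$masks, frame = 5) {
  if (is.null(masks)) {
    stop_pfb("no masks available: segment the dataset first",
             "pfbmri_param_error")
  }
  rows <- purrr::map(seq_along(dataset$images), function(i) {
    extract_features(dataset$images[[i]], masks[[i]], frame = frame)
  })
  vals <- do.call(rbind, rows)
  labs <- dataset_labels(dataset)
  out <- tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = vapply(dataset$images, function(im) im$subject_id,
                          character(1)),
      label = labs),
    out)
}

feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "label"))
}

#' Z-score features on the training set and apply to both sets
#'
#' Mean and SD are estimated on the training rows only (no test-fold
#' leakage) and applied to both; zero-SD features map to 0. Kernel
#' classifiers (SVMs) require comparable feature scales, which the raw
#' pixel-unit features do not have.
#'
#' @param train,test Numeric matrices or feature tibbles (non-feature
#'   columns `subject_id`/`label` are passed through untouched).
#' @return List with standardized `train`, `test` (or `NULL`), and the
#'   `center`/`scale` vectors used.
#' @export
standardize_fit_apply <- function(train, test = NULL) {
  is_tbl <- is.data.frame(train)
  get_mat <- function(x) {
    if (is.data.frame(x)) {
      as.matrix(x[, feature_columns(x), drop = FALSE])
    } else {
      as.matrix(x)
    }
  }
  mtr <- get_mat(train)
  ctr <- colMeans(mtr)
  scl <- apply(mtr, 2, sd)
  transform <- function(x) {
    m <- get_mat(x)
    z <- sweep(m, 2, ctr, "-")
    z <- sweep(z, 2, ifelse(scl > 0, scl, 1), "/")
    z[, scl == 0] <- 0
    if (is.data.frame(x)) {
      out <- x
      out[, colnames(m)] <- as.data.frame(z, check.names = FALSE)
      out
    } else {
      z
    }
  }
  list(train = transform(train),
       test = if (!is.null(test)) transform(test),
       center = ctr, scale = scl)
}
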