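#' PFB image objects
#'
#' A `pfb_image` is a light container for one 2D grayscale MRI slice (or
#' phantom) of the hip region: a non-negative intensity matrix plus the
#' acquisition and subject metadata the pipeline consumes. Labels follow the
#' DEXA convention used throughout the package: label 0 = healthy
#' (T-score > -0.9), label 1 = unhealthy (osteopenia or osteoporosis,
#' T-score <= -0.9).
#'
#' @param pixels Numeric matrix of intensities, `[row, col]`, row 1 at the
#'   top. Must be at least 32 x 32, finite and non-negative.
#' @param side `"left"` or `"right"` femur.
#' @param protocol Optional list with elements `TR` (ms), `TE` (ms) and
#'   `flip_angle` (degrees).
#' @param subject_id Opaque subject identifier.
#' @param t_score Optional DEXA T-score.
#' @param label Optional class label, 0 (healthy) or 1 (unhealthy). When
#'   both `t_score` and `label` are given they must agree with the
#'   T-score > -0.9 rule.
#'
#' @return A `pfb_image` object.
#' @export
pfb_image <- function(pixels, side = c("left", "right"), protocol = NULL,
                      subject_id = "subject", t_score = NULL, label = NULL) {
  side <- match.arg(side)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_pfb("`pixels` must be a numeric matrix", "pfbmri_param_error")
  }
  if (nrow(pixels) < 32 || ncol(pixels) < 32) {
    stop_pfb("image must be at least 32 x 32 pixels", "pfbmri_param_error")
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop_pfb("intensities must be finite and non-negative",
             "pfbmri_param_error")
  }
  if (!is.null(label)) {
    if (!label %in% c(0, 1)) {
      stop_pfb("label must be 0 (healthy) or 1 (unhealthy)",
               "pfbmri_param_error")
    }
    if (!is.null(t_score)) {
      implied <- healthy_label(t_score)
      if (label != implied) {
        stop_pfb(
          sprintf("label %d contradicts t_score %.2f (threshold: healthy iff T > -0.9)",
                  label, t_score),
          "pfbmri_param_error")
      }
    }
  }
  structure(
    list(pixels = pixels, side = side, protocol = protocol,
         subject_id = subject_id, t_score = t_score, label = label),
    class = "pfb_image")
}

#' Label implied by a DEXA T-score
#'
#' Healthy (0) iff T-score > -0.9, unhealthy (1) otherwise; exactly -0.9
#' is unhealthy.
#'
#' @param t_score Numeric T-score(s).
#' @return Integer label(s), 0 or 1.
#' @export
healthy_label <- function(t_score) {
  as.integer(!(t_score > -0.9))
}

#' @export
print.pfb_image <- function(x, ...) {
  cat(sprintf("<pfb_image> %s: %d x %d, side=%s, label=%s\n",
              x$subject_id, nrow(x$pixels), ncol(x$pixels), x$side,
              if (is.null(x$label)) "NA" else x$label))
  invisible(x)
}

#' @export
dim.pfb_image <- function(x) dim(x$pixels)

as_pixels <- function(image) {
  if (inherits(image, "pfb_image")) image$pixels
  else if (is.matrix(image)) image
  else stop_pfb("expected a pfb_image or matrix", "pfbmri_param_error")
}

#' Segmentation mask objects
#'
#' A `pfb_mask` couples a binary segmentation with its ordered closed
#' boundary and provenance. The mask must have exactly one foreground
#' connected component; the boundary is an ordered (row, col) polygon whose
#' first and last vertices coincide.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param method One of `"region_growing"`, `"active_contour"`,
#'   `"manual_file"`, `"ground_truth"`.
#' @param seed Optional (row, col) seed pixel the mask was grown from.
#' @param check If `TRUE` (default), enforce the single-component
#'   invariant.
#'
#' @return A `pfb_mask` object with fields `mask`, `boundary`, `method`,
#'   `seed`.
#' @export
pfb_mask <- function(mask, method = c("ground_truth", "region_growing",
                                      "active_contour", "manual_file"),
                     seed = NULL, check = TRUE) {
  method <- match.arg(method)
  m <- mask
  if (inherits(m, "pfb_mask")) return(m)
  if (!is.matrix(m)) stop_pfb("mask must be a matrix", "pfbmri_param_error")
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  if (check) {
    ncomp <- max(EBImage::bwlabel(m * 1))
    if (ncomp != 1) {
      stop_pfb(sprintf("mask must have exactly one foreground component (found %d)",
                       ncomp), "pfbmri_mask_error")
    }
  }
  structure(
    list(mask = m, boundary = mask_boundary(m), method = method, seed = seed),
    class = "pfb_mask")
}

# Ordered closed boundary polygon of a single-component binary matrix,
# as an n x 2 (row, col) matrix with first row == last row.
mask_boundary <- function(m) {
  if (!any(m)) return(matrix(numeric(0), 0, 2))
  oc <- EBImage::ocontour(EBImage::bwlabel(m * 1))[[1]]
  # EBImage returns 0-based (x, y) = (row-index-1, col-index-1) for a
  # matrix passed as-is (its x axis is the matrix row dimension)
  b <- cbind(oc[, 1] + 1, oc[, 2] + 1)
  rbind(b, b[1, , drop = FALSE])
}

# Binary border pixels of a mask (inside the mask, 4-neighbour erosion).
mask_border_pixels <- function(m) {
  er <- m &
    shift_matrix(m, 1, 0, FALSE) & shift_matrix(m, -1, 0, FALSE) &
    shift_matrix(m, 0, 1, FALSE) & shift_matrix(m, 0, -1, FALSE)
  m & !er
}

#' @export
print.pfb_mask <- function(x, ...) {
  cat(sprintf("<pfb_mask> %d x %d, area=%d px, method=%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$method))
  invisible(x)
}

as_mask_matrix <- function(m) {
  if (inherits(m, "pfb_mask")) m$mask
  else if (is.matrix(m)) matrix(as.logical(m), nrow(m), ncol(m))
  else stop_pfb("expected a pfb_mask or matrix", "pfbmri_param_error")
}

#' PFB datasets
#'
#' An ordered collection of [pfb_image] objects with optional per-image
#' ground-truth masks. Subject ids must be unique.
#'
#' @param images List of [pfb_image].
#' @param masks Optional list of [pfb_mask] (same length as `images`).
#' @return A `pfb_dataset` object.
#' @export
pfb_dataset <- function(images, masks = NULL) {
  ids <- vapply(images, function(im) im$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop_pfb("subject_ids must be unique", "pfbmri_param_error")
  }
  labs <- unlist(lapply(images, function(im) im$label))
  if (length(labs) && !all(labs %in% c(0, 1))) {
    stop_pfb("labels must be 0 or 1", "pfbmri_param_error")
  }
  if (!is.null(masks) && length(masks) != length(images)) {
    stop_pfb("masks must match images in length", "pfbmri_param_error")
  }
  structure(list(images = images, masks = masks), class = "pfb_dataset")
}

#' @export
length.pfb_dataset <- function(x) length(x$images)

#' @export
print.pfb_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<pfb_dataset> %d images (%d healthy / %d unhealthy), masks: %s\n",
              length(x$images), sum(labs == 0, na.rm = TRUE),
              sum(labs == 1, na.rm = TRUE),
              if (is.null(x$masks)) "none" else "yes"))
  invisible(x)
}

dataset_labels <- function(dataset) {
  vapply(dataset$images,
         function(im) if (is.null(im$label)) NA_integer_ else as.integer(im$label),
         integer(1))
}
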