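# ggplot2 views of the package's result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   labs scale_fill_gradient theme_minimal
NULL

#' Plot a GA run's convergence
#'
#' Best cost per iteration (monotone non-increasing under elitism).
#'
#' @param object A `pfb_ga` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfb_ga <- function(object, ...) {
  ggplot(object$history, aes(x = .data$iteration, y = .data$cost)) +
    geom_line(color = "steelblue") +
    labs(x = "GA iteration", y = "best cost 1/(accuracy + 1/NOF)",
         title = sprintf("GA feature selection (%s)",
                         object$classifier$family)) +
    theme_minimal()
}

#' Plot a boundary-distance curve
#'
#' @param object A `pfb_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfb_curve <- function(object, ...) {
  df <- tibble::tibble(index = seq_along(object$values),
                       distance_px = object$values)
  ggplot(df, aes(x = .data$index, y = .data$distance_px)) +
    geom_line() +
    labs(title = sprintf("%s (%s)", object$name, object$direction),
         x = "resampled position", y = "distance to boundary (px)") +
    theme_minimal()
}

#' Plot a noise sweep
#'
#' Accuracy versus SNR; the clean reference (`snr_db = Inf`) is drawn as
#' a point at the right margin.
#'
#' @param object A `pfb_noise_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfb_noise_sweep <- function(object, ...) {
  finite <- object[is.finite(object$snr_db), ]
  clean <- object[!is.finite(object$snr_db), ]
  p <- ggplot(finite, aes(x = .data$snr_db, y = .data$accuracy)) +
    geom_line() + geom_point() +
    labs(x = "SNR (dB)", y = "pooled CV accuracy (%)") +
    theme_minimal()
  if (nrow(clean)) {
    p <- p + geom_point(data = tibble::tibble(
      snr_db = max(finite$snr_db) + 5, accuracy = clean$accuracy),
      shape = 17, size = 3)
  }
  p
}

#' Plot a GA selection map
#'
#' Feature-by-iteration raster: bright cells are features selected in the
#' best chromosome at that iteration; a steady horizontal line is a
#' feature the GA keeps throughout.
#'
#' @param run A `pfb_ga` object.
#' @return A ggplot.
#' @export
plot_selection_map <- function(run) {
  m <- selection_map(run)
  df <- tidyr::expand_grid(iteration = seq_len(ncol(m)),
                           feature = seq_len(nrow(m)))
  df$selected <- as.vector(m) # column-major: feature varies fastest
  ggplot(df, aes(x = .data$iteration, y = .data$feature,
                 fill = .data$selected)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", guide = "none") +
    labs(x = "GA iteration", y = "feature index",
         title = sprintf("Selection map (%s)", run$classifier$family)) +
    theme_minimal()
}

#' Display an image or mask matrix
#'
#' Base-graphics convenience view (row 1 at the top).
#'
#' @param x A [pfb_image], [pfb_mask] or matrix.
#' @param ... Passed to [graphics::image()].
#' @export
plot_pfb <- function(x, ...) {
  m <- if (inherits(x, "pfb_mask")) x$mask * 1 else as_pixels(x)
  graphics::image(t(m)[, rev(seq_len(nrow(m)))], col = gray.colors(256),
                  asp = nrow(m) / ncol(m), axes = FALSE, ...)
}
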