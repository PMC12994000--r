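# ggplot2 visualizations of the main result types.

#' Plot the hemodynamic response kernel
#' @param hrf A `venc_hrf`.
#' @param rate_hz Sampling rate.
#' @return A ggplot.
#' @export
plot_hrf <- function(hrf = hrf_spec(), rate_hz = 45) {
  k <- hrf_kernel(hrf, rate_hz)
  df <- tibble::tibble(t = seq(0, hrf$duration, by = 1 / rate_hz), response = k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time since impulse (s)", y = "response (a.u.)",
                  title = "Hemodynamic response kernel")
}

#' @describeIn autoplot_voxelenc Histogram of voxel-wise prediction accuracy.
#' @export
autoplot.venc_encoding <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mean_r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "mean prediction accuracy (Pearson r)", y = "voxels",
                  title = paste0("Encoding accuracy (",
                                 attr(object, "layer_selection") %||% "all", ")"))
}

#' @describeIn autoplot_voxelenc Stacked per-ROI layer composition bars.
#' @export
autoplot.venc_composition <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$roi, y = .data$proportion,
                               fill = .data$layer)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = NULL, y = "proportion of voxels",
                  title = "Winner-layer composition by ROI")
}

#' @describeIn autoplot_voxelenc Lambda curve with the selected plateau.
#' @export
autoplot.venc_lambda_curve <- function(object, ...) {
  sel <- select_lambda(object$lambda, object$mean_r)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda, y = .data$mean_r)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sel, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "L1 penalty", y = "mean cross-validated r",
                  title = sprintf("Penalty selection (fixed at %.3g)", sel))
}

#' Autoplot methods for voxelenc results
#'
#' @param object A voxelenc result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot_voxelenc
NULL

#' Bar plot of condition means with normalized within-subject CIs
#'
#' @param data Subject-by-condition matrix or tidy tibble (see
#'   [normalized_ci()]).
#' @param level Confidence level.
#' @return A ggplot.
#' @export
plot_condition_means <- function(data, level = 0.95) {
  ci <- normalized_ci(data, level = level)
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean",
                  title = sprintf("Condition means (normalized %d%% CI)",
                                  round(level * 100)))
}
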