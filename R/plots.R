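#' Plot generalization predictions and data
#'
#' Normalized adaptation against hand-orientation offset, one panel per joint
#' configuration, one line per coordinate-frame model — the standard display
#' of a generalization pattern. Observed per-subject data (if supplied) are
#' overlaid as group means.
#'
#' @param predictions Tibble from [predict_generalization()] (columns
#'   `config`, `orientation`, `model`, `adaptation`).
#' @param data Optional dataset (`subject_id`, `movement_id`, `adaptation`);
#'   movement metadata is joined from `design`.
#' @param design Design tibble used to place the data points.
#' @return A ggplot object.
#' @export
plot_generalization <- function(predictions, data = NULL,
                                design = default_design()) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$orientation,
                                    y = .data$adaptation,
                                    colour = .data$model)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~config,
                        labeller = ggplot2::labeller(
                          config = function(x) paste("configuration", x))) +
    ggplot2::labs(x = "hand orientation offset (deg)",
                  y = "normalized adaptation", colour = "model") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    obs <- data |>
      dplyr::group_by(.data$movement_id) |>
      dplyr::summarise(adaptation = mean(.data$adaptation), .groups = "drop") |>
      dplyr::left_join(design[, c("movement_id", "config", "orientation")],
                       by = "movement_id")
    p <- p + ggplot2::geom_point(data = obs, colour = "black", shape = 4,
                                 size = 2,
                                 ggplot2::aes(x = .data$orientation,
                                              y = .data$adaptation),
                                 inherit.aes = FALSE)
  }
  p
}

#' Observed versus fitted adaptation for a mixture model
#'
#' @param object A `reachfit` object.
#' @param data The dataset the model was fit to.
#' @param design Design tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reachfit
#' @export
autoplot.reachfit <- function(object, data, design = default_design(), ...) {
  spec <- object$spec
  pred <- predict_mixture(design, spec, k = object$k[spec$components],
                          d = if (spec$decay) object$d[spec$components])
  df <- data |>
    dplyr::left_join(tibble::tibble(movement_id = design$movement_id,
                                    fitted = pred),
                     by = "movement_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$adaptation)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "fitted adaptation", y = "observed adaptation",
                  title = spec_label(spec),
                  subtitle = sprintf("MSE %.4f, BIC %.1f", object$mse,
                                     object$bic)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated learning curve
#'
#' Binned maximum perpendicular error over exposure trials, with catch-style
#' null-field probes shown separately (their signed error mirrors the field
#' trials once compensation is learned).
#'
#' @param exposure The `exposure` tibble from [simulate_cohort()].
#' @param bin Trials per bin.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(exposure, bin = 4) {
  df <- exposure |>
    dplyr::mutate(bin = (dplyr::row_number() - 1) %/% bin) |>
    dplyr::group_by(.data$bin, .data$catch) |>
    dplyr::summarise(mpe = mean(.data$signed_mpe), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = 100 * .data$mpe,
                                   colour = .data$catch)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "trial bin", y = "signed MPE (cm)",
                  colour = "null-field probe") +
    ggplot2::theme_minimal()
}
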