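#' Plot an averaged oddball waveform
#'
#' One panel per channel, amplitude against time from stimulus onset, with
#' the P300 search window (200-500 ms) shaded.
#'
#' @param object An `nf_erp` tibble from [build_erp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nf_erp <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uv)) +
    ggplot2::annotate("rect", xmin = 200, xmax = 500, ymin = -Inf, ymax = Inf,
                      alpha = 0.08, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line(colour = "black") +
    ggplot2::facet_wrap(~channel, ncol = 4) +
    ggplot2::labs(x = "time from stimulus onset (ms)",
                  y = expression("amplitude (" * mu * "V)"),
                  title = sprintf("Stimulus-locked average (%d epochs)",
                                  attr(object, "n_epochs") %||% NA)) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated evaluation grid
#'
#' Accuracy (or RMSE) against the number of features, one line per AO
#' duration, faceted by split scheme and variant.
#'
#' @param object An `nf_eval_grid` from [evaluate_grid()].
#' @param metric `"accuracy"` or `"rmse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nf_eval_grid <- function(object, metric = c("accuracy", "rmse"), ...) {
  metric <- match.arg(metric)
  se_col <- paste0(metric, "_se")
  df <- object[object$n_reps > 0, , drop = FALSE]
  df$duration <- factor(df$duration_s, levels = sort(unique(df$duration_s),
                                                     decreasing = TRUE),
                        labels = paste0(sort(unique(df$duration_s),
                                             decreasing = TRUE), " s"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data[[metric]],
                                   colour = .data$duration)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[metric]] - .data[[se_col]],
                                      ymax = .data[[metric]] + .data[[se_col]],
                                      fill = .data$duration),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(variant ~ split) +
    ggplot2::labs(x = "number of features (p-value rank prefix)",
                  y = if (metric == "accuracy") "classification accuracy (%)"
                      else "RMSE (FAS units)",
                  colour = "AO data", fill = "AO data") +
    ggplot2::theme_minimal()
}

#' Plot a feature-selection result
#'
#' Correlation strength of the selected features, ordered by p-value.
#'
#' @param object An `nf_selection` from [select_features()].
#' @param top_n How many features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nf_selection <- function(object, top_n = 20, ...) {
  df <- utils::head(object, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Pearson r with FAS total", y = NULL,
                  title = sprintf("Top %d of %d selected features (p < %g)",
                                  nrow(df), nrow(object),
                                  attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}
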