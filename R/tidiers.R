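#' Tidy a cross-validation report
#'
#' One row per repetition with the metrics computed from that repetition's
#' pooled held-out predictions.
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with `repetition` and the metric columns.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  x$per_rep
}

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One-row tibble: mean of each metric over repetitions, `ACC_sd`,
#'   `repetitions`, `n_subjects`.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  means <- setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(
    tibble::as_tibble(means),
    tibble::tibble(ACC_sd = x$summary$sd[x$summary$metric == "ACC"],
                   repetitions = x$config$repetitions,
                   n_subjects = x$n_subjects)
  )
}

#' Box plot of per-repetition metrics
#'
#' @param object A `cv_report`.
#' @param metrics Which metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, metrics = c("ACC", "SEN", "SPE"), ...) {
  df <- tidyr::pivot_longer(object$per_rep, dplyr::all_of(metrics),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Proportion",
                  title = "Nested cross-validation performance") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a kernel-weight sweep
#'
#' Accuracy (with a +/- 1 SD ribbon) against the ROI-kernel weight beta.
#' Small beta = network features dominate, large beta = ROI features
#' dominate.
#'
#' @param object A `weight_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weight_sweep
#' @export
autoplot.weight_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta, y = .data$ACC)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$ACC - .data$ACC_sd, 0),
                                      ymax = pmin(.data$ACC + .data$ACC_sd, 1)),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ROI-kernel weight (beta)", y = "Accuracy",
                  title = "Multi-kernel weight sweep") +
    ggplot2::theme_minimal()
}

#' Bar chart of a selection-frequency table
#'
#' @param x A tibble from [frequency_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_frequencies <- function(x, ...) {
  lab <- ifelse(is.na(x$roi_j_name),
                paste0(x$roi_i_name, " (", x$roi_i_hemi, ") ", x$measure),
                paste0("L", x$layer, ": ", x$roi_i_name, " (", x$roi_i_hemi,
                       ") - ", x$roi_j_name, " (", x$roi_j_hemi, ")"))
  df <- tibble::tibble(label = factor(lab, levels = rev(lab)),
                       frequency = x$frequency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Selection frequency (fold-fits)", y = NULL) +
    ggplot2::theme_minimal()
}
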