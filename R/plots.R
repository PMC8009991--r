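#' Plot measure curves across the density sweep
#'
#' Mean +/- SD ribbons of a measure as a function of density, pre vs post,
#' facetted by group — the standard way to inspect stimulation-induced
#' topological change.
#'
#' @param measure_tbl Tidy measure table from [compute_measures()].
#' @param groups Tibble from [assign_groups()].
#' @param measure One of [measure_names()].
#' @return A ggplot object.
#' @export
plot_measure_sweep <- function(measure_tbl, groups, measure = "C_net") {
  df <- measure_tbl |>
    dplyr::filter(.data$measure == !!measure, is.finite(.data$value)) |>
    dplyr::inner_join(groups, by = "subject_id") |>
    dplyr::group_by(.data$group, .data$condition, .data$density) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$mean,
                                   colour = .data$condition,
                                   fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "density threshold", y = measure,
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Significance curves of a sweep comparison
#'
#' Shows FDR-corrected q-values across the density grid per measure and
#' group, with the 0.05 and 0.01 levels marked.
#'
#' @param object A `ctdcs_sweep` from [sweep_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctdcs_sweep <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(unclass(object)),
                      !is.na(.data$q_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$q_value,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0.05, 0.01), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "density threshold", y = "q-value (FDR)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve of a nested CV fit
#'
#' @param object A `ctdcs_prediction` from [nested_cv_svm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctdcs_prediction <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Pooled ROC (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}
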