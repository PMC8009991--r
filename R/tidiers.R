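#' Tidy per-fold metrics of a nested CV fit
#'
#' @param x A `ctdcs_prediction` from [nested_cv_svm()].
#' @param ... Unused.
#' @return Tibble with one row per outer fold: `fold`, `n_test`, `acc`,
#'   `sn`, `sp`, `auc`, `cost`, `gamma`, `features` (list).
#' @export
tidy.ctdcs_prediction <- function(x, ...) {
  x$folds
}

#' One-row performance summary of a nested CV fit
#'
#' @param x A `ctdcs_prediction` from [nested_cv_svm()].
#' @param ... Unused.
#' @return One-row tibble: fold means and SDs of accuracy, sensitivity and
#'   specificity, the mean per-fold AUC, and the pooled-decision-value AUC.
#' @export
glance.ctdcs_prediction <- function(x, ...) {
  f <- x$folds
  tibble::tibble(
    n_folds = nrow(f),
    acc_mean = mean(f$acc), acc_sd = sd(f$acc),
    sn_mean = mean(f$sn, na.rm = TRUE), sn_sd = sd(f$sn, na.rm = TRUE),
    sp_mean = mean(f$sp, na.rm = TRUE), sp_sd = sd(f$sp, na.rm = TRUE),
    auc_mean = mean(f$auc, na.rm = TRUE), auc_sd = sd(f$auc, na.rm = TRUE),
    auc_pooled = x$auc
  )
}

#' Tidy a density-sweep comparison
#'
#' `sweep_compare()` already returns a tidy tibble; this method simply
#' strips the class for downstream tools expecting a bare tibble.
#'
#' @param x A `ctdcs_sweep` from [sweep_compare()].
#' @param ... Unused.
#' @return Tibble of test results.
#' @export
tidy.ctdcs_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
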