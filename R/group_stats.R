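#' Normality-gated paired comparison
#'
#' Tests pre vs post values paired by sample. If the Shapiro-Wilk test does
#' not reject normality of the paired differences (at `alpha_normality`),
#' a paired t-test is used; otherwise a Wilcoxon signed-rank test.
#' All-zero differences return p = 1 by convention; constant non-zero
#' differences fall through to the Wilcoxon branch (Shapiro-Wilk is
#' undefined for constants).
#'
#' @param pre,post Equal-length numeric vectors (>= 3 pairs; >= 5 for a
#'   meaningful test), paired by position.
#' @param alpha_normality Normality-gate level (default 0.05).
#' @return List: `test_used` (`"paired_t"` or `"wilcoxon"`), `statistic`,
#'   `p_value`, `n` (pairs used).
#' @export
paired_compare <- function(pre, post, alpha_normality = 0.05) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  if (length(pre) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- post - pre
  if (all(d == 0)) {
    return(list(test_used = "paired_t", statistic = 0, p_value = 1,
                n = length(d)))
  }
  normal <- if (sd(d) == 0) FALSE else {
    shapiro.test(d)$p.value >= alpha_normality
  }
  if (normal) {
    tt <- t.test(post, pre, paired = TRUE)
    list(test_used = "paired_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, n = length(d))
  } else {
    wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE,
                                       exact = FALSE, correct = TRUE))
    list(test_used = "wilcoxon", statistic = unname(wt$statistic),
         p_value = wt$p.value, n = length(d))
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; order-preserving and capped at
#' 1. NA p-values yield NA q-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  p.adjust(p_values, method = "BH")
}

#' Pre/post comparison across the density sweep
#'
#' For every (group, measure, density) cell the paired pre/post values are
#' compared with [paired_compare()], pairing samples by subject and window
#' (`unit = "window"`, replicating the augmented-sample analysis) or by
#' subject after averaging windows (`unit = "subject"`, free of
#' window-overlap dependence). FDR correction is applied within each
#' (group, measure) family across the densities.
#'
#' Pairs with non-finite values (disconnected graphs make path lengths
#' infinite) are dropped per cell and counted in `n_dropped`; a cell with
#' fewer than `min_pairs` usable pairs gets an NA test. A (group, measure,
#' density) cell with no data at all is an error.
#'
#' @param measure_tbl Tidy measure table from [compute_measures()].
#' @param groups Tibble `subject_id`, `group` from [assign_groups()].
#' @param unit `"window"` (default) or `"subject"`.
#' @param alpha_normality Normality-gate level for [paired_compare()].
#' @param min_pairs Minimum usable pairs per cell (default 5).
#' @return Tibble of class `ctdcs_sweep`: `group`, `measure`, `scope`,
#'   `density`, `test_used`, `statistic`, `p_value`, `q_value`,
#'   `significant_05`, `significant_01`, `direction` (sign of the mean
#'   post-pre difference), `n_pairs`, `n_dropped`.
#' @export
sweep_compare <- function(measure_tbl, groups, unit = c("window", "subject"),
                          alpha_normality = 0.05, min_pairs = 5L) {
  unit <- match.arg(unit)
  tbl <- dplyr::inner_join(measure_tbl, groups, by = "subject_id")
  if (nrow(tbl) == 0) stop("no samples match the groups table", call. = FALSE)
  if (unit == "subject") {
    tbl <- tbl |>
      dplyr::group_by(.data$group, .data$subject_id, .data$condition,
                      .data$density, .data$measure, .data$scope) |>
      dplyr::summarise(value = mean(.data$value[is.finite(.data$value)]),
                       .groups = "drop") |>
      dplyr::mutate(window = 1L)
  }
  wide <- tbl |>
    dplyr::select("group", "subject_id", "window", "condition", "density",
                  "measure", "scope", "value") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  if (!all(c("pre", "post") %in% names(wide))) {
    stop("measure table must contain both pre and post conditions",
         call. = FALSE)
  }
  observed <- dplyr::distinct(wide, .data$group, .data$measure,
                              .data$density)
  expected <- tidyr::expand_grid(group = unique(wide$group),
                                 measure = unique(wide$measure),
                                 density = unique(wide$density))
  missing_cells <- dplyr::anti_join(expected, observed,
                                    by = c("group", "measure", "density"))
  if (nrow(missing_cells)) {
    stop("cells without paired data: ",
         paste(sprintf("%s/%s@%.2f", missing_cells$group,
                       missing_cells$measure, missing_cells$density),
               collapse = "; "), call. = FALSE)
  }
  cells <- wide |>
    dplyr::group_by(.data$group, .data$measure, .data$scope, .data$density)
  res <- cells |>
    dplyr::group_modify(function(df, key) {
      ok <- is.finite(df$pre) & is.finite(df$post)
      n_ok <- sum(ok)
      if (n_ok < max(min_pairs, 3L)) {
        return(tibble::tibble(test_used = NA_character_,
                              statistic = NA_real_, p_value = NA_real_,
                              direction = NA_real_, n_pairs = n_ok,
                              n_dropped = sum(!ok)))
      }
      cmp <- paired_compare(df$pre[ok], df$post[ok], alpha_normality)
      tibble::tibble(test_used = cmp$test_used, statistic = cmp$statistic,
                     p_value = cmp$p_value,
                     direction = sign(mean(df$post[ok] - df$pre[ok])),
                     n_pairs = n_ok, n_dropped = sum(!ok))
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$group, .data$measure) |>
    dplyr::mutate(q_value = fdr_correct(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant_05 = !is.na(.data$q_value) & .data$q_value < 0.05,
                  significant_01 = !is.na(.data$q_value) & .data$q_value < 0.01)
  class(res) <- c("ctdcs_sweep", class(res))
  res
}

#' Summarise significance curves per measure
#'
#' @param sweep A `ctdcs_sweep` table from [sweep_compare()].
#' @return Tibble per (group, measure): fraction of densities significant at
#'   q < 0.05 and q < 0.01, and the dominant direction among significant
#'   densities.
#' @export
significance_summary <- function(sweep) {
  sweep |>
    dplyr::group_by(.data$group, .data$measure) |>
    dplyr::summarise(
      n_densities = dplyr::n(),
      frac_sig_05 = mean(.data$significant_05),
      frac_sig_01 = mean(.data$significant_01),
      direction = ifelse(any(.data$significant_05),
                         sign(sum(.data$direction[.data$significant_05])),
                         NA_real_),
      .groups = "drop"
    )
}
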