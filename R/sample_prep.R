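#' Label treatment response from seizure counts
#'
#' A subject responds when the 4-week follow-up seizure count is at least
#' 20% below the 4-week baseline count. The comparison is done in exact
#' integer arithmetic (`(baseline - followup) * 5 >= baseline` at the default
#' threshold), so boundary cases such as 5 -> 4 count as response without
#' floating-point surprises. Vectorised.
#'
#' @param baseline,followup Non-negative integer seizure counts; baseline
#'   must be positive (study inclusion requires a baseline seizure).
#' @param threshold Required reduction fraction (default 0.2).
#' @return Logical vector.
#' @export
label_response <- function(baseline, followup, threshold = 0.2) {
  if (any(baseline <= 0)) {
    stop("baseline seizure count must be positive (inclusion criterion)",
         call. = FALSE)
  }
  stopifnot(all(followup >= 0), threshold >= 0, threshold <= 1)
  # exact rational comparison: (b - f)/b >= t  <=>  (b - f) >= t * b
  frac <- as.numeric(threshold)
  (baseline - followup) >= frac * baseline - 1e-12 * baseline
}

#' Crop a time series into overlapping windows
#'
#' Augments one regions-by-time matrix into windows of `T` columns taken
#' every `stride` columns (window w covers columns `start + 1 .. start + T`
#' with `start = (w - 1) * stride`). With the acquisition defaults
#' (230 points, T = 90, stride 35) this yields five windows overlapping by
#' 55 points, a five-fold augmentation.
#'
#' @param ts Regions-by-time numeric matrix.
#' @param T_len Window length in time points (default 90).
#' @param stride Offset between consecutive window starts (default 35).
#' @return List of regions-by-`T_len` matrices; each carries a `start`
#'   attribute (0-based column offset).
#' @export
window_timeseries <- function(ts, T_len = 90L, stride = 35L) {
  n <- ncol(ts)
  if (n < T_len) {
    stop("time series has ", n, " points, fewer than window length ", T_len,
         call. = FALSE)
  }
  stopifnot(stride >= 1L)
  starts <- seq(0L, n - T_len, by = stride)
  lapply(starts, function(s) {
    w <- ts[, (s + 1L):(s + T_len), drop = FALSE]
    attr(w, "start") <- s
    w
  })
}

#' Assign analysis groups from arm and seizure counts
#'
#' Active-arm subjects split into responders and non-responders by
#' [label_response()]; sham subjects carry no response label and form their
#' own group.
#'
#' @param subjects Tibble with `subject_id`, `arm`, `baseline_seizures`,
#'   `followup_seizures`.
#' @param threshold Response threshold passed to [label_response()].
#' @return Tibble `subject_id`, `group` with levels `active_responder`,
#'   `active_nonresponder`, `sham`.
#' @export
assign_groups <- function(subjects, threshold = 0.2) {
  need <- c("subject_id", "arm", "baseline_seizures", "followup_seizures")
  missing_cols <- setdiff(need, names(subjects))
  if (length(missing_cols)) {
    stop("subjects table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  active <- subjects$arm == "active"
  if (any(active & (is.na(subjects$baseline_seizures) |
                    is.na(subjects$followup_seizures)))) {
    stop("active subjects with missing seizure counts: ",
         paste(subjects$subject_id[active & (is.na(subjects$baseline_seizures) |
             is.na(subjects$followup_seizures))], collapse = ", "),
         call. = FALSE)
  }
  group <- rep("sham", nrow(subjects))
  resp <- label_response(subjects$baseline_seizures[active],
                         subjects$followup_seizures[active], threshold)
  group[active] <- ifelse(resp, "active_responder", "active_nonresponder")
  tibble::tibble(subject_id = subjects$subject_id, group = group)
}

#' Build labelled analysis samples from a cohort
#'
#' Applies the overlapping-window augmentation to every subject's pre and
#' post scan. Pre and post windows are paired by window index downstream
#' (the only order-preserving pairing for paired statistics and change
#' rates). Subjects flagged in an optional `excluded` metadata column are
#' dropped.
#'
#' @param cohort A `ctdcs_cohort` (from [make_cohort()] or [read_cohort()]).
#' @param T_len,stride Windowing parameters, see [window_timeseries()].
#' @return Tibble: `sample_id`, `subject_id`, `condition` (`pre`/`post`),
#'   `window` (1-based), `data` (list column of regions-by-`T_len` matrices).
#' @export
prepare_samples <- function(cohort, T_len = 90L, stride = 35L) {
  subjects <- cohort$subjects
  if ("excluded" %in% names(subjects)) {
    subjects <- dplyr::filter(subjects, !.data$excluded)
  }
  rows <- purrr::map_dfr(subjects$subject_id, function(id) {
    purrr::map_dfr(c("pre", "post"), function(cond) {
      wins <- window_timeseries(cohort$timeseries[[id]][[cond]], T_len, stride)
      tibble::tibble(
        subject_id = id, condition = cond, window = seq_along(wins),
        data = wins
      )
    })
  })
  dplyr::mutate(rows,
                sample_id = paste(.data$subject_id, .data$condition,
                                  sprintf("w%d", .data$window), sep = "_"),
                .before = 1)
}
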