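#' Pipeline run configuration
#'
#' Collects everything an end-to-end run needs: either a cohort directory
#' with existing data or a [cohort_config()] to simulate one, the density
#' grid, the feature density, significance levels, null count for sigma,
#' mode flags and the master seed (which fans out deterministically to every
#' stochastic stage).
#'
#' @param cohort Either a `cohort_config` (simulate) or a directory path
#'   (load with [read_cohort()]).
#' @param out_dir Output directory for stage files.
#' @param d_min,d_max,step Density grid (defaults 0.17-0.46 by 0.01).
#' @param feature_density Density for prediction features (default 0.3;
#'   must lie on the grid).
#' @param T_len,stride Windowing parameters.
#' @param measures Measures to compute (default all eight).
#' @param n_nulls Rewired nulls per graph for sigma.
#' @param unit Pairing unit for the sweep comparison.
#' @param pooled_mode,group_aware Prediction mode flags.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), out_dir = tempfile("ctdcs_"),
                       d_min = 0.17, d_max = 0.46, step = 0.01,
                       feature_density = 0.3, T_len = 90L, stride = 35L,
                       measures = measure_names(), n_nulls = 100L,
                       unit = "window", pooled_mode = FALSE,
                       group_aware = TRUE, seed = 1L) {
  densities <- density_grid(d_min, d_max, step)
  if (!any(abs(densities - feature_density) < 1e-9)) {
    stop("feature_density must lie on the density grid", call. = FALSE)
  }
  structure(list(cohort = cohort, out_dir = out_dir, d_min = d_min,
                 d_max = d_max, step = step,
                 feature_density = feature_density, T_len = as.integer(T_len),
                 stride = as.integer(stride), measures = measures,
                 n_nulls = as.integer(n_nulls), unit = unit,
                 pooled_mode = pooled_mode, group_aware = group_aware,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [run_config()]; a nested
#' `cohort_config` mapping simulates a cohort, a `cohort_dir` string loads
#' one.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cohort <- if (!is.null(raw$cohort_dir)) {
    raw$cohort_dir
  } else {
    do.call(cohort_config, raw$cohort_config %||% list())
  }
  args <- raw[setdiff(names(raw), c("cohort_dir", "cohort_config"))]
  do.call(run_config, c(list(cohort = cohort), args))
}

#' Validate cohort input files
#'
#' Checks that the metadata table has the required columns, that every
#' subject has pre and post matrices of a consistent region count, and that
#' every electrode label resolves in the site map. Returns a report instead
#' of erroring.
#'
#' @param dir Cohort directory (layout of [write_cohort()]).
#' @return Tibble of failures (`item`, `problem`); zero rows when valid.
#' @export
validate_inputs <- function(dir) {
  fails <- list()
  note <- function(item, problem) {
    fails[[length(fails) + 1]] <<- tibble::tibble(item = item,
                                                  problem = problem)
  }
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    note(meta_path, "metadata file missing")
    return(dplyr::bind_rows(fails))
  }
  subjects <- readr::read_csv(meta_path, show_col_types = FALSE,
                              progress = FALSE)
  need <- c("subject_id", "arm", "baseline_seizures", "followup_seizures",
            "stimulation_sites")
  for (cl in setdiff(need, names(subjects))) {
    note("metadata.csv", paste("missing column", cl))
  }
  map_path <- file.path(dir, "site_map.json")
  site_map <- if (file.exists(map_path)) {
    lapply(jsonlite::read_json(map_path),
           function(x) as.integer(unlist(x)))
  } else NULL
  n_regions <- NA_integer_
  if ("subject_id" %in% names(subjects)) {
    for (id in subjects$subject_id) {
      for (cond in c("pre", "post")) {
        path <- file.path(dir, "timeseries", paste0(id, "_", cond, ".tsv"))
        if (!file.exists(path)) {
          note(id, paste("missing", cond, "time series"))
          next
        }
        m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
        if (is.na(n_regions)) n_regions <- ncol(m)
        if (ncol(m) != n_regions) {
          note(id, sprintf("%s matrix has %d regions, expected %d", cond,
                           ncol(m), n_regions))
        }
      }
    }
  }
  if (!is.null(site_map) && "stimulation_sites" %in% names(subjects)) {
    electrodes <- unique(unlist(strsplit(subjects$stimulation_sites, ";")))
    for (e in setdiff(electrodes, names(site_map))) {
      note(e, "electrode not resolvable in site map")
    }
    bad <- names(site_map)[vapply(site_map, function(ix) {
      !is.na(n_regions) && any(ix > n_regions)
    }, logical(1))]
    for (e in bad) note(e, "site map index exceeds region count")
  }
  out <- dplyr::bind_rows(fails)
  if (nrow(out) == 0) {
    tibble::tibble(item = character(), problem = character())
  } else {
    out
  }
}

#' Run the full analysis pipeline
#'
#' simulate/load -> window -> connectivity -> graph measures -> sweep
#' statistics -> outcome prediction, writing each stage's output under
#' `config$out_dir` with fixed filenames plus a reproducibility manifest.
#' Re-running the same configuration reproduces identical measure and
#' statistics tables.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `samples`, `measures`, `stats`, `prediction`
#'   and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (inherits(config$cohort, "cohort_config")) {
    make_cohort(config$cohort)
  } else {
    read_cohort(config$cohort)
  }
  cohort_dir <- file.path(config$out_dir, "cohort")
  write_cohort(cohort, cohort_dir)

  samples <- prepare_samples(cohort, config$T_len, config$stride)
  readr::write_csv(samples[, c("sample_id", "subject_id", "condition",
                               "window")],
                   file.path(config$out_dir, "samples.csv"), progress = FALSE)

  groups <- assign_groups(cohort$subjects)
  readr::write_csv(groups, file.path(config$out_dir, "groups.csv"),
                   progress = FALSE)

  densities <- density_grid(config$d_min, config$d_max, config$step)
  measures <- compute_measures(samples, cohort$subjects, densities,
                               site_map = cohort$site_map,
                               measures = config$measures,
                               n_nulls = config$n_nulls,
                               seed = fanout_seed(config$seed, 21L))
  readr::write_csv(measures[, setdiff(names(measures), "data")],
                   file.path(config$out_dir, "measures.csv"),
                   progress = FALSE)

  stats_tbl <- sweep_compare(measures, groups, unit = config$unit)
  readr::write_csv(tibble::as_tibble(unclass(stats_tbl)),
                   file.path(config$out_dir, "stats.csv"), progress = FALSE)

  prediction <- NULL
  if (sum(groups$group == "active_responder") >= 1 &&
      sum(groups$group == "active_nonresponder") >= 1) {
    feats <- change_features(measures, groups,
                             density = config$feature_density)
    if (min(table(feats$responder)) >= 2) {
      prediction <- nested_cv_svm(feats,
                                  seed = fanout_seed(config$seed, 22L),
                                  group_aware = config$group_aware,
                                  pooled_mode = config$pooled_mode)
      jsonlite::write_json(
        list(folds = tidy(prediction)[, c("fold", "n_test", "acc", "sn",
                                          "sp", "auc", "cost", "gamma")],
             summary = glance(prediction),
             selected = prediction$selected),
        file.path(config$out_dir, "prediction.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
      readr::write_csv(prediction$roc, file.path(config$out_dir, "roc.csv"),
                       progress = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctdcsnet")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_subjects = nrow(cohort$subjects),
    n_samples = nrow(samples),
    densities = densities,
    measures = config$measures,
    unit = config$unit
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, samples = samples, measures = measures,
                 stats = stats_tbl, prediction = prediction,
                 out_dir = config$out_dir))
}
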