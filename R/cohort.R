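#' Cohort configuration for the synthetic generator
#'
#' Bundles and validates every parameter of the synthetic cohort: a modular
#' inter-regional covariance, AR(1)-coloured BOLD-like signals (TR 2 s,
#' 230 retained volumes by default), a multiplicative pre-to-post weakening of
#' within-module correlation for true responders, and Poisson seizure diaries
#' around the 20% response rule.
#'
#' @param n_regions Number of parcellation regions (default 90).
#' @param n_timepoints Time points per scan after volume discard (default 230).
#' @param tr Repetition time in seconds (default 2).
#' @param n_active,n_sham Subjects per arm (defaults 12 and 8).
#' @param n_responders True responders among the active arm (default 4).
#' @param block_sizes Integer module sizes summing to `n_regions`
#'   (default: six near-equal modules).
#' @param rho_within,rho_between Within-/between-module correlations,
#'   `0 <= rho_between < rho_within < 1`.
#' @param n_shortcuts Strong "long-range" region pairs per module pair,
#'   correlated at `rho_within` (small-world shortcuts; keep > 0 so that
#'   density-thresholded graphs stay connected at the low end of the sweep).
#' @param responder_effect Fraction in `[0, 1)` by which within-module
#'   correlation is reduced after stimulation for true responders.
#' @param ar_coef Lag-1 autocorrelation of the signals in `[0, 1)`; 0.4
#'   approximates the temporal smoothness of 0.01-0.08 Hz band-limited BOLD
#'   at TR 2 s.
#' @param baseline_rate Mean seizures per 4 weeks at baseline (> 0).
#' @param responder_rate_ratio Follow-up/baseline rate ratio for true
#'   responders, in `[0, 1)`.
#' @param seed Master integer seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_regions = 90L, n_timepoints = 230L, tr = 2,
                          n_active = 12L, n_sham = 8L, n_responders = 4L,
                          block_sizes = NULL, rho_within = 0.5,
                          rho_between = 0.25, n_shortcuts = 2L,
                          responder_effect = 0.4, ar_coef = 0.4,
                          baseline_rate = 40, responder_rate_ratio = 0.2,
                          seed = 1L) {
  n_regions <- as.integer(n_regions)
  if (is.null(block_sizes)) {
    k <- max(2L, min(6L, n_regions %/% 4L))
    block_sizes <- rep(n_regions %/% k, k)
    block_sizes[seq_len(n_regions - sum(block_sizes))] <-
      block_sizes[seq_len(n_regions - sum(block_sizes))] + 1L
  }
  block_sizes <- as.integer(block_sizes)
  cfg <- list(
    n_regions = n_regions, n_timepoints = as.integer(n_timepoints), tr = tr,
    n_active = as.integer(n_active), n_sham = as.integer(n_sham),
    n_responders = as.integer(n_responders), block_sizes = block_sizes,
    rho_within = rho_within, rho_between = rho_between,
    n_shortcuts = as.integer(n_shortcuts),
    responder_effect = responder_effect, ar_coef = ar_coef,
    baseline_rate = baseline_rate,
    responder_rate_ratio = responder_rate_ratio, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    sum(cfg$block_sizes) == cfg$n_regions,
    all(cfg$block_sizes >= 1L),
    cfg$n_responders <= cfg$n_active,
    cfg$rho_between >= 0, cfg$rho_between < cfg$rho_within,
    cfg$rho_within < 1,
    cfg$responder_effect >= 0, cfg$responder_effect < 1,
    cfg$ar_coef >= 0, cfg$ar_coef < 1,
    cfg$baseline_rate > 0,
    cfg$responder_rate_ratio >= 0, cfg$responder_rate_ratio < 1,
    cfg$n_timepoints >= 2L
  )
  invisible(cfg)
}

#' Two-level modular correlation matrix
#'
#' Unit-diagonal matrix with `rho_within` inside diagonal blocks and
#' `rho_between` everywhere else. Positive definiteness is asserted.
#'
#' @param block_sizes Integer block sizes.
#' @param rho_within,rho_between Correlations, `0 <= rho_between <
#'   rho_within < 1`.
#' @return Symmetric positive-definite correlation matrix.
#' @export
make_covariance <- function(block_sizes, rho_within, rho_between) {
  stopifnot(rho_between >= 0, rho_between <= rho_within, rho_within < 1)
  if (rho_between >= rho_within && rho_between > 0) {
    stop("rho_between must be smaller than rho_within", call. = FALSE)
  }
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  same <- outer(block, block, "==")
  cov <- ifelse(same, rho_within, rho_between)
  diag(cov) <- 1
  assert_pd(cov, "make_covariance produced a non-positive-definite matrix")
  cov
}

assert_pd <- function(m, msg) {
  ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop(msg, " (smallest eigenvalue ", signif(ev, 3), ")",
                    call. = FALSE)
  invisible(ev)
}

# Strong long-range pairs between modules, deterministic (same "anatomy"
# for every subject). Endpoints rotate with the partner block so no single
# region accumulates too many strong cross-module correlations. If the
# result still loses positive definiteness, all off-diagonal entries are
# shrunk uniformly toward zero just enough to restore it (ordering of
# entries, hence thresholded topology, is unchanged).
add_shortcuts <- function(cov, block_sizes, n_shortcuts, rho) {
  if (n_shortcuts <= 0L) return(cov)
  ends <- cumsum(block_sizes)
  starts <- ends - block_sizes + 1L
  k <- length(block_sizes)
  for (a in seq_len(k - 1L)) {
    for (b in seq((a + 1L), k)) {
      for (s in seq_len(n_shortcuts)) {
        i <- starts[a] + (b + s - 2L) %% block_sizes[a]
        j <- starts[b] + (a + s - 2L) %% block_sizes[b]
        cov[i, j] <- cov[j, i] <- rho
      }
    }
  }
  ev <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8) {
    lambda <- (1e-6 - ev) / (1 - ev)
    cov <- (1 - lambda) * cov
    diag(cov) <- 1
  }
  assert_pd(cov, "shortcut correlations made the matrix non-positive-definite")
  cov
}

#' Weaken within-module correlation for responders
#'
#' Multiplies within-block off-diagonal correlations by `1 - effect`,
#' leaving the diagonal and between-block entries untouched. This is the
#' generator's model of the post-stimulation network change in responders:
#' it lowers clustering and efficiency of the strongest (retained) edges and
#' lengthens shortest paths.
#'
#' @param cov Correlation matrix.
#' @param effect Fraction in `[0, 1)`.
#' @param block_sizes Integer block sizes matching `cov`.
#' @return Modified symmetric positive-definite matrix.
#' @export
apply_responder_effect <- function(cov, effect, block_sizes) {
  stopifnot(effect >= 0, effect < 1, sum(block_sizes) == nrow(cov))
  if (effect == 0) return(cov)
  block <- rep(seq_along(block_sizes), block_sizes)
  same <- outer(block, block, "==")
  out <- ifelse(same, cov * (1 - effect), cov)
  diag(out) <- diag(cov)
  ev <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    stop("responder effect ", effect, " makes the covariance non-positive-",
         "definite; use a smaller effect", call. = FALSE)
  }
  out
}

#' Simulate AR(1)-coloured multivariate BOLD-like signals
#'
#' Draws a regions-by-time matrix whose innovations are Gaussian with the
#' target covariance and whose rows share lag-1 autocorrelation `ar_coef`.
#' Because every region carries the same AR coefficient, the stationary
#' zero-lag cross-correlation equals the target covariance exactly, while the
#' autocorrelation supplies the temporal smoothness of band-limited BOLD.
#' The process is initialised from its stationary distribution, so no
#' burn-in is needed.
#'
#' @param cov Positive-definite covariance (correlation) matrix.
#' @param n_timepoints Number of time points (>= 2).
#' @param ar_coef Lag-1 autocorrelation in `[0, 1)`.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return `nrow(cov)` x `n_timepoints` numeric matrix.
#' @export
simulate_bold <- function(cov, n_timepoints, ar_coef = 0.4, seed = 1L) {
  stopifnot(n_timepoints >= 2, ar_coef >= 0, ar_coef < 1)
  n <- nrow(cov)
  ch <- tryCatch(chol(cov), error = function(e) {
    stop("covariance is singular or not positive definite", call. = FALSE)
  })
  withr::with_seed(as.integer(seed), {
    z <- crossprod(ch, matrix(rnorm(n * n_timepoints), n, n_timepoints))
    x <- matrix(0, n, n_timepoints)
    x[, 1] <- z[, 1]
    if (n_timepoints > 1) {
      s <- sqrt(1 - ar_coef^2)
      for (t in 2:n_timepoints) {
        x[, t] <- ar_coef * x[, t - 1] + s * z[, t]
      }
    }
    x
  })
}

#' Simulate a 4-week baseline / follow-up seizure diary
#'
#' Baseline count is Poisson with mean `baseline_rate`; follow-up is Poisson
#' with mean `baseline_rate * rate_ratio` for a true responder and
#' `baseline_rate` otherwise. A zero baseline draw is redrawn (study
#' inclusion requires at least one baseline seizure).
#'
#' @param baseline_rate Mean seizures per 4 weeks (> 0).
#' @param rate_ratio Follow-up rate ratio for responders, in `[0, 1]`.
#' @param responder Logical: is this subject a true responder?
#' @param seed Integer seed.
#' @return Named integer vector `c(baseline = , followup = )`.
#' @export
simulate_seizure_diary <- function(baseline_rate, rate_ratio, responder,
                                   seed = 1L) {
  stopifnot(baseline_rate > 0)
  withr::with_seed(as.integer(seed), {
    baseline <- rpois(1L, baseline_rate)
    tries <- 0L
    while (baseline == 0L && tries < 1000L) {
      baseline <- rpois(1L, baseline_rate)
      tries <- tries + 1L
    }
    if (baseline == 0L) baseline <- 1L
    mu <- if (isTRUE(responder)) baseline_rate * rate_ratio else baseline_rate
    followup <- rpois(1L, mu)
    c(baseline = baseline, followup = followup)
  })
}

#' Generate a synthetic pre/post ctDCS cohort
#'
#' Produces per-subject metadata (arm, seizure diary, stimulation sites,
#' generator ground truth) and pre/post region-by-time series. True
#' responders receive post-stimulation series drawn from the effect-modified
#' covariance; all other post series are fresh draws from the unmodified
#' covariance. Deterministic for a fixed config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return List of class `ctdcs_cohort`:
#'   `subjects` (tibble: `subject_id`, `arm`, `baseline_seizures`,
#'   `followup_seizures`, `stimulation_sites`, `true_responder`),
#'   `timeseries` (named list per subject of `list(pre = , post = )`
#'   matrices), `site_map`, and the `config`.
#' @export
make_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  cov_pre <- make_covariance(cfg$block_sizes, cfg$rho_within, cfg$rho_between)
  cov_pre <- add_shortcuts(cov_pre, cfg$block_sizes, cfg$n_shortcuts,
                           cfg$rho_within)
  cov_post_resp <- apply_responder_effect(cov_pre, cfg$responder_effect,
                                          cfg$block_sizes)
  site_map <- default_site_map(cfg$n_regions)
  electrodes <- names(site_map)

  n_total <- cfg$n_active + cfg$n_sham
  ids <- sprintf("sub%02d", seq_len(n_total))
  arm <- rep(c("active", "sham"), c(cfg$n_active, cfg$n_sham))
  true_resp <- c(rep(c(TRUE, FALSE), c(cfg$n_responders,
                                       cfg$n_active - cfg$n_responders)),
                 rep(NA, cfg$n_sham))

  sites <- withr::with_seed(fanout_seed(cfg$seed, 1L), {
    vapply(seq_len(n_total), function(i) {
      k <- if (stats::runif(1) < 0.15) 2L else 1L
      paste(sample(electrodes, k), collapse = ";")
    }, character(1))
  })

  diaries <- lapply(seq_len(n_total), function(i) {
    simulate_seizure_diary(cfg$baseline_rate, cfg$responder_rate_ratio,
                           isTRUE(true_resp[i]),
                           seed = fanout_seed(cfg$seed, 2L, i))
  })

  timeseries <- lapply(seq_len(n_total), function(i) {
    cov_post <- if (isTRUE(true_resp[i])) cov_post_resp else cov_pre
    list(
      pre = simulate_bold(cov_pre, cfg$n_timepoints, cfg$ar_coef,
                          seed = fanout_seed(cfg$seed, 3L, i)),
      post = simulate_bold(cov_post, cfg$n_timepoints, cfg$ar_coef,
                           seed = fanout_seed(cfg$seed, 4L, i))
    )
  })
  names(timeseries) <- ids

  subjects <- tibble::tibble(
    subject_id = ids, arm = arm,
    baseline_seizures = vapply(diaries, `[[`, integer(1), "baseline"),
    followup_seizures = vapply(diaries, `[[`, integer(1), "followup"),
    stimulation_sites = sites, true_responder = true_resp
  )
  structure(list(subjects = subjects, timeseries = timeseries,
                 site_map = site_map, config = cfg),
            class = "ctdcs_cohort")
}

#' @export
print.ctdcs_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic ctDCS cohort:", cfg$n_active, "active /", cfg$n_sham,
      "sham subjects;", cfg$n_regions, "regions x", cfg$n_timepoints,
      "time points (pre/post)\n")
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' `write_cohort()` writes `metadata.csv`, `site_map.json` and one
#' tab-separated regions-by-time matrix per subject and condition under
#' `dir/timeseries/` (header row of region labels). `read_cohort()` reads
#' the same layout, which is also the expected format for user-supplied
#' real data.
#'
#' @param cohort A `ctdcs_cohort` (or a compatible list with `subjects`,
#'   `timeseries`, `site_map`).
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a
#'   `ctdcs_cohort`-shaped list (without generator config).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "metadata.csv"),
                   progress = FALSE)
  jsonlite::write_json(cohort$site_map, file.path(dir, "site_map.json"))
  n <- nrow(cohort$timeseries[[1]]$pre)
  labels <- if (n == 90L) aal90_labels() else sprintf("R%03d", seq_len(n))
  for (id in names(cohort$timeseries)) {
    for (cond in c("pre", "post")) {
      m <- cohort$timeseries[[id]][[cond]]
      df <- as.data.frame(t(m))
      names(df) <- labels
      readr::write_tsv(df, file.path(dir, "timeseries",
                                     paste0(id, "_", cond, ".tsv")),
                       progress = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("metadata file not found: ", meta_path, call. = FALSE)
  }
  subjects <- readr::read_csv(meta_path, show_col_types = FALSE,
                              progress = FALSE)
  site_map <- lapply(jsonlite::read_json(file.path(dir, "site_map.json")),
                     function(x) as.integer(unlist(x)))
  timeseries <- lapply(subjects$subject_id, function(id) {
    lapply(c(pre = "pre", post = "post"), function(cond) {
      path <- file.path(dir, "timeseries", paste0(id, "_", cond, ".tsv"))
      if (!file.exists(path)) {
        stop("time-series file not found: ", path, call. = FALSE)
      }
      t(as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                  progress = FALSE)))
    })
  })
  names(timeseries) <- subjects$subject_id
  structure(list(subjects = subjects, timeseries = timeseries,
                 site_map = site_map, config = NULL),
            class = "ctdcs_cohort")
}
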