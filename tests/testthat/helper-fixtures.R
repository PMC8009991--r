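# Small cohorts reused across tests. Sizes are scaled down (20 or 12
# regions, few subjects) so suites run quickly; the statistical structure is
# the generator's default.

tiny_cohort_config <- function(...) {
  cohort_config(n_regions = 20L, block_sizes = c(5L, 5L, 5L, 5L),
                n_active = 12L, n_sham = 8L, n_responders = 4L, seed = 3L,
                ...)
}

# minimal three-group cohort for sweep bookkeeping: 2 subjects per cell
mini_threegroup_measures <- function(measures = measure_names(),
                                     n_nulls = 2L) {
  cfg <- cohort_config(n_regions = 12L, block_sizes = c(4L, 4L, 4L),
                       n_active = 4L, n_sham = 2L, n_responders = 2L,
                       baseline_rate = 200, responder_rate_ratio = 0.05,
                       seed = 9L)
  ch <- make_cohort(cfg)
  groups <- assign_groups(ch$subjects)
  samples <- prepare_samples(ch)
  mt <- compute_measures(samples, ch$subjects, site_map = ch$site_map,
                         measures = measures, n_nulls = n_nulls, seed = 4L)
  list(cohort = ch, groups = groups, samples = samples, measures = mt)
}
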