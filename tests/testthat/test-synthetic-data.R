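test_that("modular covariance has the specified structure and is PD", {
  expect_equal(make_covariance(2L, 0.5, 0),
               matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(make_covariance(c(2L, 2L), 0, 0), diag(4))
  cv <- make_covariance(c(3L, 3L), 0.6, 0.1)
  expect_equal(cv[1, 2], 0.6)
  expect_equal(cv[1, 4], 0.1)
  expect_true(isSymmetric(cv))
  expect_equal(unname(diag(cv)), rep(1, 6))
  expect_gt(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(make_covariance(c(3L, 3L), 0.1, 0.6), "rho")
})

test_that("responder effect scales within-block correlations only", {
  cv <- make_covariance(c(3L, 3L), 0.6, 0.1)
  expect_identical(apply_responder_effect(cv, 0, c(3L, 3L)), cv)
  out <- apply_responder_effect(cv, 0.5, c(3L, 3L))
  expect_equal(out[1, 2], 0.3)
  expect_equal(out[1, 4], 0.1)
  expect_equal(unname(diag(out)), rep(1, 6))
  out2 <- apply_responder_effect(cv, 0.3, c(3L, 3L))
  expect_gt(min(eigen(out2, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("simulated signals recover the target cross-correlation", {
  # independent regions: sample correlations within Monte-Carlo tolerance
  x <- simulate_bold(diag(4), 10000, ar_coef = 0, seed = 2)
  r <- cor(t(x))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
  # strongly correlated pair, with AR colouring
  cv <- matrix(c(1, 0.8, 0.8, 1), 2)
  y <- simulate_bold(cv, 10000, ar_coef = 0.4, seed = 5)
  expect_gt(cor(y[1, ], y[2, ]), 0.75)
  expect_lt(cor(y[1, ], y[2, ]), 0.85)
  # lag-1 autocorrelation close to ar_coef
  ac <- cor(y[1, -1], y[1, -10000])
  expect_lt(abs(ac - 0.4), 0.05)
  # determinism
  expect_identical(simulate_bold(cv, 50, 0.4, seed = 7),
                   simulate_bold(cv, 50, 0.4, seed = 7))
  expect_error(simulate_bold(matrix(1, 2, 2), 10), "singular")
})

test_that("seizure diaries follow the responder rate model", {
  expect_identical(simulate_seizure_diary(8, 0.4, TRUE, seed = 1),
                   simulate_seizure_diary(8, 0.4, TRUE, seed = 1))
  # rate_ratio 0 for a responder: follow-up always 0
  f <- vapply(1:50, function(s) {
    simulate_seizure_diary(5, 0, TRUE, seed = s)[["followup"]]
  }, numeric(1))
  expect_true(all(f == 0))
  # rate_ratio 1: baseline and follow-up means agree within sampling error
  draws <- vapply(1:2000, function(s) {
    simulate_seizure_diary(8, 1, TRUE, seed = s)
  }, c(baseline = 0, followup = 0))
  expect_lt(abs(mean(draws["baseline", ]) - mean(draws["followup", ])), 0.3)
  # baseline never zero (inclusion criterion)
  expect_true(all(draws["baseline", ] >= 1))
})

test_that("cohorts have the right shape, determinism and pre/post effect", {
  cfg <- tiny_cohort_config()
  ch <- make_cohort(cfg)
  expect_equal(nrow(ch$subjects), 20L)
  expect_equal(sum(ch$subjects$arm == "active"), 12L)
  expect_length(ch$timeseries, 20L)
  expect_true(all(vapply(ch$timeseries, function(x) {
    all(dim(x$pre) == c(20, 230)) && all(dim(x$post) == c(20, 230))
  }, logical(1))))
  expect_identical(ch$subjects, make_cohort(cfg)$subjects)
  expect_identical(ch$timeseries$sub05$post, make_cohort(cfg)$timeseries$sub05$post)

  # responder effect lowers mean within-block correlation post vs pre
  block <- rep(1:4, each = 5)
  within <- outer(block, block, "==") & upper.tri(diag(20))
  resp <- ch$subjects$subject_id[which(ch$subjects$true_responder)[1]]
  pre_r <- cor(t(ch$timeseries[[resp]]$pre))[within]
  post_r <- cor(t(ch$timeseries[[resp]]$post))[within]
  expect_gt(mean(pre_r) - mean(post_r), 0.05)

  # no systematic change without the effect
  cfg0 <- tiny_cohort_config(responder_effect = 0)
  ch0 <- make_cohort(cfg0)
  id <- ch0$subjects$subject_id[1]
  pre0 <- cor(t(ch0$timeseries[[id]]$pre))[within]
  post0 <- cor(t(ch0$timeseries[[id]]$post))[within]
  expect_lt(abs(mean(pre0) - mean(post0)), 0.05)
})

test_that("cohort round-trips through plain-text files", {
  cfg <- cohort_config(n_regions = 6L, block_sizes = c(3L, 3L),
                       n_timepoints = 95L, n_active = 2L, n_sham = 1L,
                       n_responders = 1L, seed = 2L)
  ch <- make_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects$subject_id, ch$subjects$subject_id)
  expect_equal(back$subjects$baseline_seizures, ch$subjects$baseline_seizures)
  expect_equal(unname(back$timeseries$sub01$pre), ch$timeseries$sub01$pre,
               tolerance = 1e-12)
  expect_equal(back$site_map, lapply(ch$site_map, as.integer),
               ignore_attr = TRUE)
  expect_error(read_cohort(file.path(dir, "nope")), "metadata")
})
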