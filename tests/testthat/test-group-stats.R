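test_that("paired comparison gates on normality and handles degeneracy", {
  x <- c(1.2, 0.8, 1.5, 1.1, 0.9, 1.3, 1.0, 1.4)
  same <- paired_compare(x, x)
  expect_equal(same$p_value, 1)
  expect_equal(same$statistic, 0)

  # differences 1..5 are perfectly "normal" for Shapiro-Wilk: paired t,
  # closed form t = mean/(sd/sqrt(n)) = 3/(1.5811/2.2361) = 4.2426, df = 4
  pre <- c(10, 10, 10, 10, 10)
  post <- pre + 1:5
  out <- paired_compare(pre, post)
  expect_equal(out$test_used, "paired_t")
  expect_equal(out$statistic, 4.2426, tolerance = 1e-4)
  expect_equal(out$p_value, 0.0132, tolerance = 1e-2)

  # heavily non-normal differences select the signed-rank test
  d <- c(rep(0.01, 9), 50, rep(-0.01, 9), -49)
  skew <- paired_compare(rep(0, 20), d^3)
  expect_equal(skew$test_used, "wilcoxon")

  expect_error(paired_compare(1:4, 1:5), "equal length")
  expect_error(paired_compare(1:2, 2:3), "at least 3")
})

test_that("type-I error of the gated test is controlled", {
  withr::with_seed(77, {
    rej <- mean(vapply(1:400, function(i) {
      a <- rnorm(20)
      b <- rnorm(20)
      paired_compare(a, b)$p_value < 0.05
    }, logical(1)))
  })
  expect_lt(rej, 0.08)
  expect_gt(rej, 0.02)
})

test_that("BH correction equals the step-up definition", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(0.2, 7)), rep(0.2, 7))
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- runif(sample(2:50, 1))^sample(1:3, 1)
      q <- fdr_correct(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-12))
      expect_true(all(q <= 1))
      # order preserved
      expect_equal(order(q, p), order(p, p))
    }
  })
})

test_that("sweep comparison produces one gated, corrected test per cell", {
  fx <- mini_threegroup_measures(measures = c("C_net", "L_net", "E_net"))
  sw <- sweep_compare(fx$measures, fx$groups)
  expect_s3_class(sw, "ctdcs_sweep")
  expect_equal(nrow(sw), 3L * 3L * 30L)
  expect_true(all(sw$test_used[!is.na(sw$test_used)] %in%
                    c("paired_t", "wilcoxon")))
  ok <- !is.na(sw$q_value)
  expect_true(all(sw$q_value[ok] >= sw$p_value[ok] - 1e-12))
  expect_true(all(sw$significant_05 == (ok & sw$q_value < 0.05)))
  # q-values are BH within each (group, measure) family of 30 densities
  fam <- sw[sw$group == "active_responder" & sw$measure == "C_net", ]
  expect_equal(fam$q_value, oracle_bh(fam$p_value), tolerance = 1e-12)

  # structurally absent cells error with their names
  broken <- fx$measures[!(fx$measures$measure == "C_net" &
                            abs(fx$measures$density - 0.3) < 1e-9), ]
  expect_error(sweep_compare(broken, fx$groups), "C_net@0.30")

  # subject-level mode averages windows first: same cells, fewer pairs
  sw_subj <- sweep_compare(fx$measures, fx$groups, unit = "subject",
                           min_pairs = 2L)
  expect_equal(nrow(sw_subj), nrow(sw))
  expect_true(all(sw_subj$n_pairs <= 2L))
})

test_that("full eight-measure sweep on three groups yields 720 tests", {
  fx <- mini_threegroup_measures()  # all 8 measures, sigma from 2 nulls
  sw <- suppressWarnings(sweep_compare(fx$measures, fx$groups))
  expect_equal(nrow(sw), 3L * 8L * 30L)
  expect_equal(dplyr::n_distinct(sw$measure), 8L)
  expect_setequal(unique(sw$group),
                  c("active_responder", "active_nonresponder", "sham"))
})
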