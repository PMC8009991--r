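# synthetic feature tables for classifier tests: n_subj subjects x n_win
# windows, one informative feature with class separation `sep`, the rest
# noise
toy_features <- function(n_subj = 12, n_win = 5, sep = 4, n_noise = 2,
                         seed = 1) {
  withr::with_seed(seed, {
    subj_label <- rep(c(TRUE, FALSE), length.out = n_subj)
    row_label <- rep(subj_label, each = n_win)
    rows <- n_subj * n_win
    tb <- tibble::tibble(
      subject_id = rep(sprintf("s%02d", 1:n_subj), each = n_win),
      window = rep(1:n_win, n_subj),
      responder = row_label,
      cr_signal = rnorm(rows) + sep * row_label
    )
    for (k in seq_len(n_noise)) tb[[paste0("cr_noise", k)]] <- rnorm(rows)
    tb
  })
}

test_that("change rates are elementwise relative changes", {
  expect_equal(change_rate(2, 1), -0.5)
  expect_equal(change_rate(3, 3), 0)
  expect_equal(change_rate(1.25, 1.5), 0.2)
  expect_equal(change_rate(c(2, 4), c(1, 6)), c(-0.5, 0.5))
  expect_error(change_rate(0, 1), "pre = 0")
})

test_that("MIC matches the exhaustive oracle where the oracle is exact", {
  # noiseless monotone relationship: MIC = 1
  expect_equal(mic(1:20, (1:20)^3), 1)
  expect_equal(mic(1:20, 1:20), 1)
  # constant input: 0 by convention
  expect_equal(mic(rnorm(20), rep(2, 20)), 0)
  # symmetry
  withr::with_seed(3, {
    x <- rnorm(12); y <- x^2 + rnorm(12, sd = 0.3)
  })
  expect_equal(mic(x, y), mic(y, x))
  expect_equal(mic(x, x), 1)

  # binary labels (the package's use case): equipartition of a binary axis
  # is the class split, so the approximation is exact and must equal the
  # exhaustive-grid oracle at small n
  withr::with_seed(9, {
    for (i in 1:8) {
      n <- sample(8:10, 1)
      y <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      x <- rnorm(n) + y
      expect_equal(mic(x, y), mic_oracle(x, y), tolerance = 1e-12)
    }
  })

  # arbitrary continuous pairs: the one-axis-equipartition approximation
  # never exceeds the exhaustive maximum and stays in [0, 1]
  withr::with_seed(10, {
    for (i in 1:8) {
      x <- rnorm(10); y <- rnorm(10)
      m <- mic(x, y)
      expect_lte(m, mic_oracle(x, y) + 1e-12)
      expect_gte(m, 0)
      expect_lte(m, 1)
    }
  })
})

test_that("MIC ranking puts label-copies first and ignores row order", {
  withr::with_seed(4, {
    f <- toy_features(n_subj = 10, sep = 0)
    f$cr_copy <- as.numeric(f$responder)   # exact label copy
  })
  ranked <- rank_features_mic(f)
  expect_equal(ranked[1], "cr_copy")
  perm <- f[sample(nrow(f)), ]
  expect_equal(rank_features_mic(perm), ranked)
  one <- f[, c("subject_id", "window", "responder", "cr_signal")]
  expect_equal(rank_features_mic(one), "cr_signal")
})

test_that("SFS keeps the smallest best prefix", {
  f <- toy_features(sep = 6)
  ranked <- rank_features_mic(f)
  expect_equal(ranked[1], "cr_signal")
  sel <- sfs_select(f, ranked, seed = 2)
  expect_equal(sel, "cr_signal")
  # constant evaluator: first prefix wins ties
  sel2 <- sfs_select(f, ranked, evaluator = function(features, cols, ...) 0.5)
  expect_length(sel2, 1L)
  # identical features: adding more never helps
  fid <- f
  fid$cr_noise1 <- fid$cr_signal
  fid$cr_noise2 <- fid$cr_signal
  expect_length(sfs_select(fid, rank_features_mic(fid), seed = 2), 1L)
})

test_that("ROC/AUC equal the concordant-pair oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(T, T, T, F, F, F))$auc, 0.5)
  withr::with_seed(6, {
    for (i in 1:10) {
      n <- sample(6:15, 1)
      sc <- sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.1)
      lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(lb)) < 2) lb[1:2] <- c(TRUE, FALSE)
      out <- roc_auc(sc, lb)
      expect_equal(out$auc, oracle_auc(sc, lb), tolerance = 1e-12)
      expect_true(all(diff(out$roc$tpr) >= -1e-12))
      expect_true(all(diff(out$roc$fpr) >= -1e-12))
    }
  })
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("nested CV is deterministic and learns separable cohorts", {
  f <- toy_features(sep = 5, seed = 8)
  fit <- nested_cv_svm(f, seed = 21)
  expect_s3_class(fit, "ctdcs_prediction")
  fit2 <- nested_cv_svm(f, seed = 21)
  expect_equal(tidy(fit), tidy(fit2))
  expect_equal(fit$auc, fit2$auc)
  g <- glance(fit)
  expect_equal(g$n_folds, 5L)
  expect_true(all(unlist(g[, c("acc_mean", "sn_mean", "sp_mean",
                               "auc_pooled")]) >= 0))

  accs <- vapply(1:10, function(s) {
    glance(nested_cv_svm(toy_features(sep = 5, seed = s), seed = s))$acc_mean
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("label shuffling destroys nested CV performance", {
  aucs <- vapply(1:20, function(s) {
    f <- toy_features(sep = 5, seed = 30)
    # permute subject labels (keeping windows together)
    withr::with_seed(100 + s, {
      su <- unique(f$subject_id)
      newlab <- sample(f$responder[match(su, f$subject_id)])
      f$responder <- newlab[match(f$subject_id, su)]
    })
    if (length(unique(f$responder)) < 2) return(NA_real_)
    nested_cv_svm(f, seed = s)$auc
  }, numeric(1))
  expect_gt(mean(aucs, na.rm = TRUE), 0.35)
  expect_lt(mean(aucs, na.rm = TRUE), 0.65)
})

test_that("degenerate folds and classes raise informative errors", {
  f <- toy_features(n_subj = 4, n_win = 2)
  f$responder <- c(rep(TRUE, 7), FALSE)  # 1 nonresponder window
  expect_error(nested_cv_svm(f), "at least 2 samples per class")
})

test_that("pooled mode uses sample-level folds and full-data selection", {
  f <- toy_features(sep = 5, seed = 12)
  fit <- nested_cv_svm(f, seed = 3, pooled_mode = TRUE)
  expect_false(fit$settings$group_aware)
  expect_true(fit$settings$pooled_mode)
  # selection shared across folds in pooled mode
  expect_length(unique(lapply(tidy(fit)$features, identity)), 1L)
  expect_gt(fit$auc, 0.8)
})
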