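#' Relative change rate
#'
#' `(post - pre) / pre`, the per-window relative change of a measure.
#'
#' @param pre,post Numeric vectors; `pre` must be non-zero.
#' @return Numeric vector of change rates.
#' @export
change_rate <- function(pre, post) {
  if (any(pre == 0)) {
    stop("change rate undefined for pre = 0 (degenerate measure)",
         call. = FALSE)
  }
  (post - pre) / pre
}

#' Build the prediction feature matrix
#'
#' Change rates of the measures that discriminate responders (mean
#' clustering coefficient, characteristic path length, global efficiency,
#' and mean shortest path length at the stimulation sites), taken at a
#' single density, for active-arm samples only; sham subjects carry no
#' response label. One row per (subject, window) pair.
#'
#' @param measure_tbl Tidy measure table from [compute_measures()].
#' @param groups Tibble from [assign_groups()].
#' @param density Feature density (default 0.3).
#' @param measures Measures to turn into change-rate features.
#' @return Tibble: `subject_id`, `window`, `responder` (logical) and one
#'   `cr_<measure>` column per measure. Rows with non-finite feature values
#'   (disconnected graphs) are dropped with a warning.
#' @export
change_features <- function(measure_tbl, groups, density = 0.3,
                            measures = c("C_net", "L_net", "E_net",
                                         "L_site")) {
  tbl <- measure_tbl |>
    dplyr::inner_join(groups, by = "subject_id") |>
    dplyr::filter(.data$group %in% c("active_responder",
                                     "active_nonresponder"),
                  abs(.data$density - !!density) < 1e-9,
                  .data$measure %in% !!measures)
  if (nrow(tbl) == 0) {
    stop("no active-arm rows at density ", density, call. = FALSE)
  }
  wide <- tbl |>
    dplyr::select("subject_id", "window", "condition", "measure", "value",
                  "group") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  if (any(wide$pre == 0, na.rm = TRUE)) {
    stop("change rate undefined for pre = 0 (degenerate measure)",
         call. = FALSE)
  }
  feats <- wide |>
    dplyr::mutate(cr = change_rate(.data$pre, .data$post)) |>
    dplyr::select("subject_id", "window", "group", "measure", "cr") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "cr",
                       names_prefix = "cr_") |>
    dplyr::mutate(responder = .data$group == "active_responder",
                  .keep = "unused", .after = "window")
  cr_cols <- grep("^cr_", names(feats), value = TRUE)
  ok <- apply(is.finite(as.matrix(feats[cr_cols])), 1, all)
  if (!all(ok)) {
    warning(sum(!ok), " row(s) with non-finite features dropped",
            call. = FALSE)
    feats <- feats[ok, ]
  }
  feats[, c("subject_id", "window", "responder",
            paste0("cr_", measures[paste0("cr_", measures) %in% cr_cols]))]
}

# ---------------------------------------------------------------------------
# Maximal information coefficient (MINE ApproxMaxMI)

#' Maximal information coefficient
#'
#' MIC of two variables: the maximum over x-by-y grids, with total
#' resolution bounded by `B(n) = max(n^alpha, 4)`, of the mutual
#' information of the gridded variables normalised by `log2(min(nx, ny))`.
#' Computed with the published approximation: one axis is equipartitioned
#' (ties kept together), the other optimised exactly by dynamic programming
#' over clumps of tied values; both orientations are searched, so the result
#' is symmetric in `(x, y)`. Constant inputs return 0 by convention.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`.
#' @param alpha Grid-resolution exponent (default 0.6).
#' @return MIC in `[0, 1]`.
#' @export
mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  if (sd(x) == 0 || sd(y) == 0) return(0)
  B <- max(4, floor(n^alpha + 1e-9))
  max(mic_axis(x, y, B, n), mic_axis(y, x, B, n))
}

# best normalised MI with v equipartitioned and u optimised
mic_axis <- function(u, v, B, n) {
  best <- 0
  for (q in 2:max(2L, floor(B / 2))) {
    vb <- equipartition_bins(v, q)
    qq <- length(unique(vb))
    if (qq < 2) next
    pmax_ <- floor(B / qq)
    if (pmax_ < 2) next
    i_t <- optimize_axis_I(u, vb, qq, pmax_)   # max MI using exactly t bins
    tmax <- length(i_t)
    for (p in 2:pmax_) {
      val <- max(i_t[seq_len(min(p, tmax))][-1], 0) / log2(min(p, qq))
      if (val > best) best <- val
    }
  }
  min(best, 1)
}

# equipartition values into q bins, ties kept together; returns bin ids in
# the original order
equipartition_bins <- function(v, q) {
  n <- length(v)
  ord <- order(v)
  ends <- cumsum(rle(v[ord])$lengths)
  cand <- ends[-length(ends)]
  bnd <- integer(0)
  prev <- 0
  for (b in seq_len(q - 1)) {
    avail <- cand[cand > prev]
    if (!length(avail)) break
    pick <- avail[which.min(abs(avail - b * n / q))]
    bnd <- c(bnd, pick)
    prev <- pick
  }
  bins_sorted <- findInterval(seq_len(n), bnd + 1L) + 1L
  bins <- integer(n)
  bins[ord] <- bins_sorted
  bins
}

# DP over clumps of tied u-values: i_t[t] = max MI (bits) over partitions of
# u into exactly t consecutive bins, for t = 1..tmax, with v-bins fixed.
optimize_axis_I <- function(u, vb, q, pmax_) {
  n <- length(u)
  ord <- order(u)
  us <- u[ord]
  vbs <- vb[ord]
  clump <- cumsum(c(1L, as.integer(diff(us) != 0)))
  m <- clump[n]
  if (m < 2) return(0)
  cnt <- matrix(0L, m, q)
  cnt[cbind(clump, vbs)] <- 0L  # allocate then tabulate
  for (i in seq_len(n)) cnt[clump[i], vbs[i]] <- cnt[clump[i], vbs[i]] + 1L
  cum <- apply(cnt, 2, cumsum)
  if (m == 1) cum <- matrix(cum, 1)
  cumn <- rowSums(cum)
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  # additive bin score: -(tot/n)log(tot/n) + sum_q (c/n)log(c/n)
  gfun <- function(a, b) {
    cts <- if (a > 1) cum[b, ] - cum[a - 1, ] else cum[b, ]
    tot <- if (a > 1) cumn[b] - cumn[a - 1] else cumn[b]
    -plogp(tot / n) + sum(plogp(cts / n))
  }
  tmax <- min(pmax_, m)
  f <- matrix(-Inf, m, tmax)
  for (i in seq_len(m)) f[i, 1] <- gfun(1, i)
  if (tmax >= 2) {
    for (t in 2:tmax) {
      for (i in t:m) {
        best <- -Inf
        for (s in (t - 1):(i - 1)) {
          val <- f[s, t - 1] + gfun(s + 1, i)
          if (val > best) best <- val
        }
        f[i, t] <- best
      }
    }
  }
  hq <- -sum(plogp(tabulate(vbs, q) / n))
  pmax(hq + f[m, seq_len(tmax)], 0)
}

#' Rank features by MIC against the class label
#'
#' @param features Feature tibble from [change_features()] (or any tibble
#'   with `cr_*` columns and a logical `responder` column).
#' @return Character vector of feature column names, descending MIC; ties
#'   broken by the fixed column order.
#' @export
rank_features_mic <- function(features) {
  cols <- grep("^cr_", names(features), value = TRUE)
  stopifnot(length(cols) >= 1)
  y <- as.numeric(features$responder)
  mics <- vapply(cols, function(cl) mic(features[[cl]], y), numeric(1))
  cols[order(-mics, seq_along(cols))]
}

#' Sequential forward selection over a ranked feature list
#'
#' Grows prefixes of the ranked list and keeps the prefix with the highest
#' evaluator score; ties favour fewer features.
#'
#' @param features Feature tibble (see [rank_features_mic()]).
#' @param ranked Character vector of feature columns in rank order.
#' @param evaluator Function `(features, cols) -> accuracy`; the default is
#'   inner-CV accuracy of a default RBF SVM via [cv_accuracy()].
#' @param ... Passed to the default evaluator.
#' @return Character vector: the selected feature subset.
#' @export
sfs_select <- function(features, ranked, evaluator = NULL, ...) {
  stopifnot(length(ranked) >= 1)
  evaluator <- evaluator %||% function(features, cols, ...) {
    cv_accuracy(features, cols, ...)
  }
  accs <- vapply(seq_along(ranked), function(k) {
    evaluator(features, ranked[seq_len(k)], ...)
  }, numeric(1))
  ranked[seq_len(which.max(accs))]
}

# ---------------------------------------------------------------------------
# SVM machinery

# stratified fold assignment; group_aware keeps all windows of a subject in
# one fold (folds built over subjects, stratified by subject label)
make_folds <- function(y, subjects, k, group_aware, seed) {
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(y))
    if (group_aware) {
      su <- unique(subjects)
      sy <- y[match(su, subjects)]
      sfold <- integer(length(su))
      for (cl in unique(sy)) {
        idx <- sample(which(sy == cl))
        sfold[idx] <- rep_len(sample(k), length(idx))
      }
      fold <- sfold[match(subjects, su)]
    } else {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(sample(k), length(idx))
      }
    }
    fold
  })
}

# pooled hold-out accuracy of an RBF SVM over internal CV folds
#' Cross-validated accuracy of a default RBF SVM
#'
#' Supports the SFS evaluator: standardises within training folds, fits an
#' RBF SVM with fixed hyperparameters and returns pooled hold-out accuracy.
#'
#' @param features Feature tibble with `cr_*` columns, `responder`,
#'   `subject_id`.
#' @param cols Feature columns to use.
#' @param k Folds (default 5).
#' @param cost,gamma SVM hyperparameters (defaults 1 and `1/length(cols)`).
#' @param group_aware Keep each subject's windows in one fold.
#' @param class_weights Inverse-frequency class weights.
#' @param seed Fold seed.
#' @return Pooled accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(features, cols, k = 5L, cost = 1, gamma = NULL,
                        group_aware = TRUE, class_weights = TRUE,
                        seed = 1L) {
  y <- factor(ifelse(features$responder, "responder", "nonresponder"),
              levels = c("nonresponder", "responder"))
  X <- as.matrix(features[cols])
  gamma <- gamma %||% (1 / length(cols))
  fold <- make_folds(y, features$subject_id, k, group_aware, seed)
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    fit <- fit_svm(X[tr, , drop = FALSE], y[tr], cost, gamma, class_weights)
    pred <- predict_svm(fit, X[!tr, , drop = FALSE])$class
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

fit_svm <- function(X, y, cost, gamma, class_weights) {
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- scale(X, mu, sg)
  cw <- NULL
  if (isTRUE(class_weights)) {
    tab <- table(y)
    cw <- as.numeric(length(y) / (2 * tab))
    names(cw) <- names(tab)
  }
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = cw, scale = FALSE)
  list(fit = fit, mu = mu, sg = sg, levels = levels(y))
}

predict_svm <- function(model, X) {
  Xs <- scale(X, model$mu, model$sg)
  pred <- predict(model$fit, Xs, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # e1071 signs decision values toward the first class in the column name
  nm <- colnames(attr(pred, "decision.values"))[1]
  if (!startsWith(nm, "responder")) dv <- -dv
  list(class = pred, score = unname(dv))
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) statistic with ties credited 0.5; ROC
#' points from all score thresholds. Both classes must be present.
#'
#' @param scores Numeric scores, larger = more responder-like.
#' @param labels Logical (TRUE = responder) or two-level factor.
#' @return List: `roc` (tibble `fpr`, `tpr`, `threshold`, monotone in
#'   `fpr`), `auc` (scalar).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  list(
    roc = tibble::tibble(fpr = (1 - r$specificities)[ord],
                         tpr = r$sensitivities[ord],
                         threshold = r$thresholds[ord]),
    auc = as.numeric(pROC::auc(r))
  )
}

#' Nested cross-validated RBF-SVM outcome prediction
#'
#' Outer k-fold cross-validation estimates accuracy, sensitivity and
#' specificity (positive class = responder); within each outer training set,
#' features are ranked by MIC, a subset is chosen by sequential forward
#' selection, and `(C, gamma)` are tuned by an inner k-fold grid search.
#' Standardisation is fitted on training folds only. The pooled outer-fold
#' decision values give the ROC and AUC.
#'
#' Default mode is group-aware: all windows of a subject stay on one side of
#' every split, preventing leakage through overlapping windows. `pooled_mode
#' = TRUE` reproduces sample-level splitting with feature selection on the
#' full data and no class weights; it is leakage-prone and kept for
#' comparability.
#'
#' @param features Feature tibble from [change_features()].
#' @param outer_k,inner_k Fold counts (defaults 5).
#' @param seed Integer seed controlling all fold assignments.
#' @param group_aware Subject-level folds (default TRUE).
#' @param pooled_mode Sample-level folds, full-data selection, no class
#'   weights (default FALSE).
#' @param class_weights Inverse-frequency class weights (default: on unless
#'   `pooled_mode`).
#' @param cost_grid,gamma_grid Hyperparameter grids (powers of two).
#' @return Object of class `ctdcs_prediction`; see [tidy.ctdcs_prediction()]
#'   and [glance.ctdcs_prediction()].
#' @export
nested_cv_svm <- function(features, outer_k = 5L, inner_k = 5L, seed = 1L,
                          group_aware = TRUE, pooled_mode = FALSE,
                          class_weights = !pooled_mode,
                          cost_grid = 2^seq(-5, 15, 2),
                          gamma_grid = 2^seq(-15, 3, 2)) {
  if (pooled_mode) group_aware <- FALSE
  y <- factor(ifelse(features$responder, "responder", "nonresponder"),
              levels = c("nonresponder", "responder"))
  if (min(table(y)) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  fold <- make_folds(y, features$subject_id, outer_k, group_aware,
                     fanout_seed(seed, 11L))
  if (length(unique(fold)) < 2) stop("degenerate folds", call. = FALSE)
  selected_full <- NULL
  if (pooled_mode) {
    ranked <- rank_features_mic(features)
    selected_full <- sfs_select(
      features, ranked, k = inner_k, group_aware = group_aware,
      class_weights = class_weights, seed = fanout_seed(seed, 12L)
    )
  }
  folds_out <- list()
  pooled_scores <- numeric(0)
  pooled_labels <- logical(0)
  for (f in sort(unique(fold))) {
    tr <- features[fold != f, ]
    te <- features[fold == f, ]
    y_tr <- droplevels(y[fold != f])
    if (length(levels(y_tr)) < 2) {
      stop("an outer training fold contains a single class; use ",
           "stratified folds or more data", call. = FALSE)
    }
    sel <- selected_full %||% {
      ranked <- rank_features_mic(tr)
      sfs_select(tr, ranked, k = inner_k, group_aware = group_aware,
                 class_weights = class_weights,
                 seed = fanout_seed(seed, 13L, f))
    }
    # inner grid search on the selected subset
    best <- c(acc = -1, cost = NA, gamma = NA)
    for (cst in cost_grid) {
      for (gm in gamma_grid) {
        acc <- cv_accuracy(tr, sel, k = inner_k, cost = cst, gamma = gm,
                           group_aware = group_aware,
                           class_weights = class_weights,
                           seed = fanout_seed(seed, 14L, f))
        if (acc > best[["acc"]]) best <- c(acc = acc, cost = cst, gamma = gm)
      }
    }
    fit <- fit_svm(as.matrix(tr[sel]), y[fold != f], best[["cost"]],
                   best[["gamma"]], class_weights)
    pr <- predict_svm(fit, as.matrix(te[sel]))
    truth <- y[fold == f]
    tp <- sum(pr$class == "responder" & truth == "responder")
    tn <- sum(pr$class == "nonresponder" & truth == "nonresponder")
    fp <- sum(pr$class == "responder" & truth == "nonresponder")
    fn <- sum(pr$class == "nonresponder" & truth == "responder")
    fold_auc <- if (length(unique(truth)) == 2) {
      roc_auc(pr$score, truth == "responder")$auc
    } else NA_real_
    folds_out[[length(folds_out) + 1]] <- tibble::tibble(
      fold = f, n_test = nrow(te),
      acc = (tp + tn) / nrow(te),
      sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      auc = fold_auc, cost = best[["cost"]], gamma = best[["gamma"]],
      features = list(sel)
    )
    pooled_scores <- c(pooled_scores, pr$score)
    pooled_labels <- c(pooled_labels, truth == "responder")
  }
  folds_tbl <- dplyr::bind_rows(folds_out)
  pooled <- roc_auc(pooled_scores, pooled_labels)
  structure(list(
    folds = folds_tbl,
    roc = pooled$roc,
    auc = pooled$auc,
    selected = sort(unique(unlist(folds_tbl$features))),
    settings = list(outer_k = outer_k, inner_k = inner_k, seed = seed,
                    group_aware = group_aware, pooled_mode = pooled_mode,
                    class_weights = class_weights)
  ), class = "ctdcs_prediction")
}

#' @export
print.ctdcs_prediction <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Nested CV RBF-SVM (%s): ACC %.1f +/- %.1f%%, SN %.1f%%, SP %.1f%%, AUC %.2f\n",
    if (x$settings$pooled_mode) "pooled mode" else "group-aware",
    100 * g$acc_mean, 100 * g$acc_sd, 100 * g$sn_mean, 100 * g$sp_mean,
    g$auc_pooled))
  cat("Selected features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
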