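# Independent oracles: brute-force or third-party routes used only to check
# the package's implementations on small instances.

# random symmetric weight matrix with edge probability p and U(0.2, 1) weights
make_random_graph <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- runif(length(ut)) < p
    w[ut[on]] <- runif(sum(on), 0.2, 1)
    w + t(w)
  })
}

# Onnela clustering by explicit triangle enumeration
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(list(local = rep(0, n), net = 0))
  wh <- w / mx
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        j <- nb[a]; h <- nb[b]
        if (j != h && w[j, h] > 0) {
          e <- e + (wh[i, j] * wh[j, h] * wh[h, i])^(1 / 3)
        }
      }
    }
    local[i] <- (e / 2) / (k * (k - 1) / 2)
  }
  list(local = local, net = mean(local))
}

# all-pairs shortest paths through igraph (1/weight lengths)
oracle_distances <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

oracle_global_efficiency <- function(w) {
  d <- oracle_distances(w)
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  mean(rowSums(inv) / (n - 1))
}

# BH step-up from its definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# AUC by concordant-pair counting with 0.5 tie credit
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exhaustive MIC over all grids with axis cuts at distinct-value boundaries
# and nx * ny <= B(n)
mic_oracle <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(4, floor(n^alpha + 1e-9))
  cuts_of <- function(v) {
    ord <- order(v)
    ends <- cumsum(rle(v[ord])$lengths)
    list(ord = ord, cand = ends[-length(ends)])
  }
  bin_assign <- function(info, cuts, n) {
    b <- findInterval(seq_len(n), cuts + 1L) + 1L
    out <- integer(n)
    out[info$ord] <- b
    out
  }
  mi_bits <- function(bx, by) {
    tab <- table(bx, by) / length(bx)
    px <- rowSums(tab); py <- colSums(tab)
    s <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
    }
    s
  }
  ix <- cuts_of(x); iy <- cuts_of(y)
  best <- 0
  for (nx in 2:floor(B / 2)) {
    for (ny in 2:floor(B / nx)) {
      if (length(ix$cand) < nx - 1 || length(iy$cand) < ny - 1) next
      cx <- lapply(utils::combn(seq_along(ix$cand), nx - 1,
                                simplify = FALSE), function(i) ix$cand[i])
      cy <- lapply(utils::combn(seq_along(iy$cand), ny - 1,
                                simplify = FALSE), function(i) iy$cand[i])
      for (a in cx) {
        bx <- bin_assign(ix, a, n)
        for (b in cy) {
          by <- bin_assign(iy, b, n)
          val <- unname(mi_bits(bx, by)) / log2(min(nx, ny))
          if (val > best) best <- val
        }
      }
    }
  }
  best
}
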