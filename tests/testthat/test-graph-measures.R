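triangle <- function(w12 = 1, w13 = 1, w23 = 1) {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w12
  w[1, 3] <- w[3, 1] <- w13
  w[2, 3] <- w[3, 2] <- w23
  w
}

test_that("degree is the weighted row sum", {
  expect_equal(unname(node_degree(triangle())), c(2, 2, 2))
  w <- rbind(cbind(triangle(), 0), 0)  # isolated fourth node
  expect_equal(unname(node_degree(w))[4], 0)
  g <- make_random_graph(6, 0.6, seed = 2)
  expect_equal(node_degree(g), rowSums(g))
})

test_that("clustering matches exhaustive triangle enumeration", {
  cl <- clustering_coef(triangle())
  expect_equal(cl$local, rep(1, 3))
  expect_equal(cl$net, 1)
  # star graph: no triangles anywhere
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.7
  expect_equal(clustering_coef(star)$net, 0)
  for (seed in 1:5) {
    g <- make_random_graph(8, 0.5, seed = seed)
    o <- oracle_clustering(g)
    cl <- clustering_coef(g)
    expect_equal(cl$local, o$local, tolerance = 1e-10)
    expect_equal(cl$net, o$net, tolerance = 1e-10)
    expect_true(all(cl$local >= 0 & cl$local <= 1))
  }
})

test_that("shortest paths equal the igraph oracle with 1/w lengths", {
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- chain[2, 3] <- chain[3, 2] <- 1
  d <- shortest_path_matrix(chain)
  expect_equal(d[1, 3], 2)
  two <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(shortest_path_matrix(two)[1, 2], 2)
  for (seed in 1:5) {
    g <- make_random_graph(10, 0.35, seed = seed + 10)
    expect_equal(shortest_path_matrix(g), oracle_distances(g),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("path length and efficiency match hand and oracle values", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(path_length(k4)$net, 1)
  expect_equal(global_efficiency(k4), 1)
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- chain[2, 3] <- chain[3, 2] <- 1
  expect_equal(path_length(chain)$net, 4 / 3)   # (1.5 + 1 + 1.5)/3
  expect_equal(global_efficiency(chain), 5 / 6) # pairs 1, 1, 1/2
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  for (seed in 1:5) {
    g <- make_random_graph(9, 0.4, seed = seed + 20)
    d <- oracle_distances(g)
    pl <- path_length(g)
    expect_equal(pl$local, rowSums(d) / 8, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(global_efficiency(g), oracle_global_efficiency(g),
                 tolerance = 1e-10)
  }
})

test_that("local efficiency is neighbourhood global efficiency", {
  expect_equal(local_efficiency(triangle()), rep(1, 3))
  leaf <- matrix(0, 3, 3)
  leaf[1, 2] <- leaf[2, 1] <- leaf[2, 3] <- leaf[3, 2] <- 1
  expect_equal(local_efficiency(leaf)[1], 0)  # leaf node
  for (seed in 1:3) {
    g <- make_random_graph(8, 0.5, seed = seed + 30)
    ours <- local_efficiency(g)
    oracle <- vapply(1:8, function(i) {
      nb <- which(g[i, ] > 0)
      if (length(nb) < 2) return(0)
      oracle_global_efficiency(g[nb, nb, drop = FALSE])
    }, numeric(1))
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("rewired nulls preserve degrees and weights; sigma composes", {
  g <- make_random_graph(12, 0.4, seed = 42)
  ut <- upper.tri(g)
  n_edges <- sum(g[ut] > 0)
  # single rewiring: degree sequence and weight multiset preserved
  null <- rewire_null(g, n_nulls = 3, seed = 5)
  per <- attr(null, "per_null")
  expect_equal(dim(per), c(3L, 2L))
  expect_identical(rewire_null(g, n_nulls = 3, seed = 5), null)

  # inspect one rewired graph directly through the exported pieces:
  # rebuild from the same RNG path to check invariants
  e0 <- which(ut & g > 0, arr.ind = TRUE)
  wts <- g[e0]
  withr::with_seed(5, {
    e1 <- ctdcsnet:::.ms_rewire(e0, 12L, 10L * n_edges, 100L * n_edges)
  })
  wn <- matrix(0, 12, 12)
  wn[e1] <- wts
  wn[e1[, c(2, 1)]] <- wts
  expect_equal(sort(rowSums(wn > 0)), sort(rowSums(g > 0)))
  expect_equal(sort(wn[upper.tri(wn) & wn > 0]), sort(wts))

  # complete graph admits no swaps: nulls equal the graph
  k5 <- matrix(0.8, 5, 5); diag(k5) <- 0
  expect_warning(nullk <- rewire_null(k5, n_nulls = 2, seed = 1), "budget")
  expect_equal(nullk[["C_R"]], clustering_coef(k5)$net)
  expect_equal(nullk[["L_R"]], path_length(k5)$net)
  suppressWarnings(expect_equal(small_worldness(k5, 2, seed = 1), 1))

  # sigma equals its components recomputed independently
  s <- small_worldness(g, n_nulls = 10, seed = 9)
  null10 <- rewire_null(g, n_nulls = 10, seed = 9)
  expect_equal(s, (clustering_coef(g)$net / null10[["C_R"]]) /
                   (path_length(g)$net / null10[["L_R"]]))
})

test_that("weights scale as expected and sweeps are monotone", {
  g <- make_random_graph(10, 0.5, seed = 3)
  c0 <- 3.7
  expect_equal(node_degree(c0 * g), c0 * node_degree(g))
  expect_equal(shortest_path_matrix(c0 * g), shortest_path_matrix(g) / c0,
               tolerance = 1e-12)
  expect_equal(clustering_coef(c0 * g)$local, clustering_coef(g)$local,
               tolerance = 1e-12)

  set.seed(8)
  ts <- matrix(rnorm(15 * 80), 15, 80)
  z <- correlation_to_z(ts) + 1.5
  diag(z) <- 0
  graphs <- density_sweep(z)
  e <- vapply(graphs, global_efficiency, numeric(1))
  l <- vapply(graphs, function(w) path_length(w)$net, numeric(1))
  expect_true(all(diff(e) >= -1e-12))
  expect_true(all(diff(l[is.finite(l)]) <= 1e-12))
})

test_that("site measures aggregate mapped nodes", {
  vals <- list(K = c(1, 2, 3), L_local = c(1.4, 1.0, 2.0))
  map <- list(A = 1L, B = c(2L, 3L), C = c(1L, 2L))
  expect_equal(site_measures(vals, map, "A")[["L_local"]], 1.4)
  expect_equal(site_measures(vals, map, "B")[["L_local"]], 1.5)
  # two electrodes, three distinct nodes -> mean of the three
  expect_equal(site_measures(vals, map, c("B", "C"))[["K"]], 2)
  expect_error(site_measures(vals, map, "F7"), "F7")
  expect_error(site_measures(vals, list(A = 5L), "A"), "exceeds")
})
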