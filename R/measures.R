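#' Weighted node degree
#'
#' Degree of node i is the sum of the weights of its incident edges.
#'
#' @param w Symmetric non-negative weight matrix (zero = no edge).
#' @return Named numeric vector `K_i`.
#' @export
node_degree <- function(w) {
  rowSums(w)
}

#' Weighted clustering coefficients (Onnela)
#'
#' Weights are first normalised by the network maximum; the triangle
#' intensity around node i is the sum of geometric means of its triangles'
#' weights, \eqn{e_i = 1/2 \sum_{jh} (\hat w_{ij} \hat w_{jh} \hat w_{hi})^{1/3}},
#' and the clustering coefficient divides by the number of possible
#' neighbour pairs `k_i (k_i - 1) / 2` with `k_i` the binary neighbour
#' count. Nodes with fewer than two neighbours get 0. The network-level
#' coefficient `C_net` is the mean over all nodes.
#'
#' @param w Symmetric non-negative weight matrix.
#' @return List: `local` (per-node vector in `[0, 1]`), `net` (mean).
#' @export
clustering_coef <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) {
    return(list(local = rep(0, n), net = 0))
  }
  w3 <- (w / mx)^(1 / 3)
  e_i <- diag(w3 %*% w3 %*% w3) / 2
  k <- rowSums(w > 0)
  local <- ifelse(k >= 2, e_i / (k * (k - 1) / 2), 0)
  list(local = local, net = mean(local))
}

#' Weighted shortest-path distance matrix
#'
#' Edge lengths are reciprocal weights (`1 / w_ij`, the usual mapping for
#' connectivity strengths); distances are minimal summed lengths, `Inf` for
#' unreachable pairs and 0 on the diagonal.
#'
#' @param w Symmetric non-negative weight matrix.
#' @return N x N distance matrix.
#' @export
shortest_path_matrix <- function(w) {
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  .fw_dist(len)
}

#' Nodal mean and characteristic path length
#'
#' `L_local,i` is the mean shortest-path distance from node i to all other
#' nodes; `L_net` is the mean of the nodal values. Unreachable pairs
#' propagate as `Inf`, flagged by `disconnected`.
#'
#' @param w Symmetric non-negative weight matrix (or a precomputed distance
#'   matrix via `dist`).
#' @param dist Optional distance matrix from [shortest_path_matrix()].
#' @return List: `local` (per-node), `net` (scalar), `disconnected` (flag).
#' @export
path_length <- function(w, dist = NULL) {
  d <- dist %||% shortest_path_matrix(w)
  n <- nrow(d)
  diag(d) <- 0
  local <- (rowSums(d)) / (n - 1)
  list(local = local, net = mean(local),
       disconnected = !all(is.finite(local)))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over all ordered pairs; unreachable
#' pairs contribute 0, so the measure is well defined on disconnected
#' graphs.
#'
#' @inheritParams path_length
#' @return Scalar `E_net` in `[0, 1]` for weights bounded by 1.
#' @export
global_efficiency <- function(w, dist = NULL) {
  d <- dist %||% shortest_path_matrix(w)
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  mean(rowSums(inv) / (n - 1))
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by the neighbours of a node
#' (node itself excluded); nodes with fewer than two neighbours get 0.
#'
#' @param w Symmetric non-negative weight matrix.
#' @param nodes Node indices to evaluate (default: all).
#' @return Numeric vector `E_local,i` for the requested nodes.
#' @export
local_efficiency <- function(w, nodes = seq_len(nrow(w))) {
  vapply(nodes, function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(w[nb, nb, drop = FALSE])
  }, numeric(1))
}

#' Degree-preserving rewired null statistics
#'
#' Generates `n_nulls` Maslov-Sneppen randomisations of the graph (double
#' edge swaps preserving the binary degree sequence; weights travel with
#' their edges, so the weight multiset is preserved) and returns the mean
#' clustering coefficient and characteristic path length over the nulls.
#' Each null targets 10 accepted swaps per edge within an attempt budget of
#' 10x that; if the budget is exhausted (e.g. complete graphs admit no
#' swap) the partially rewired graph is kept with a warning.
#'
#' @param w Symmetric non-negative weight matrix with at least 4 edges.
#' @param n_nulls Number of null networks (default 100).
#' @param seed Integer seed; fixed seeds give identical nulls.
#' @return Named vector `c(C_R = , L_R = )`; attribute `"per_null"` holds
#'   the per-null values.
#' @export
rewire_null <- function(w, n_nulls = 100L, seed = 1L) {
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 4) stop("graph needs at least 4 edges to rewire", call. = FALSE)
  wts <- w[ut]
  target <- 10L * m
  budget <- 10L * target
  c_r <- l_r <- numeric(n_nulls)
  short <- FALSE
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_nulls)) {
      e <- .ms_rewire(ut, n, target, budget)
      if (attr(e, "accepted") < target) short <- TRUE
      wn <- matrix(0, n, n)
      wn[e] <- wts
      wn[e[, c(2, 1), drop = FALSE]] <- wts
      c_r[b] <- clustering_coef(wn)$net
      l_r[b] <- path_length(wn)$net
    }
  })
  if (short) {
    warning("rewiring attempt budget exhausted for some nulls; ",
            "partial rewirings kept", call. = FALSE)
  }
  structure(c(C_R = mean(c_r), L_R = mean(l_r)),
            per_null = cbind(C_R = c_r, L_R = l_r))
}

#' Small-worldness
#'
#' `sigma = (C_net / C_R) / (L_net / L_R)` against the degree-preserving
#' rewired nulls of [rewire_null()]. Undefined ratios (zero or non-finite
#' null means) are reported as `NA`.
#'
#' @inheritParams rewire_null
#' @return Scalar sigma (possibly `NA`).
#' @export
small_worldness <- function(w, n_nulls = 100L, seed = 1L) {
  c_net <- clustering_coef(w)$net
  pl <- path_length(w)
  null <- rewire_null(w, n_nulls, seed)
  sigma_from_parts(c_net, pl$net, null[["C_R"]], null[["L_R"]])
}

sigma_from_parts <- function(c_net, l_net, c_r, l_r) {
  if (!is.finite(c_r) || !is.finite(l_r) || c_r <= 0 || l_r <= 0 ||
      !is.finite(l_net)) {
    return(NA_real_)
  }
  (c_net / c_r) / (l_net / l_r)
}

#' All Table-style measures for one graph
#'
#' @param w Symmetric non-negative weight matrix.
#' @param n_nulls Nulls for sigma; set `n_nulls = 0` to skip sigma.
#' @param seed Seed for the rewired nulls.
#' @return List with per-node vectors (`K`, `C_local`, `L_local`,
#'   `E_local`) and globals (`C_net`, `L_net`, `E_net`, `sigma`,
#'   `disconnected`).
#' @export
graph_measures <- function(w, n_nulls = 100L, seed = 1L) {
  d <- shortest_path_matrix(w)
  cl <- clustering_coef(w)
  pl <- path_length(w, dist = d)
  sigma <- NA_real_
  if (n_nulls > 0) {
    null <- rewire_null(w, n_nulls, seed)
    sigma <- sigma_from_parts(cl$net, pl$net, null[["C_R"]], null[["L_R"]])
  }
  list(K = node_degree(w), C_local = cl$local, L_local = pl$local,
       E_local = local_efficiency(w), C_net = cl$net, L_net = pl$net,
       E_net = global_efficiency(w, dist = d), sigma = sigma,
       disconnected = pl$disconnected)
}

#' Aggregate nodal measures at the stimulation sites
#'
#' Maps each electrode to its parcellation regions and averages the nodal
#' measures over the union of mapped regions (a single mapped region returns
#' its own values; two stimulated foci are pooled the same way).
#'
#' @param node_values Named list of per-node vectors, e.g. `K`, `C_local`,
#'   `L_local`, `E_local` (any subset).
#' @param site_map Named list electrode -> integer region indices.
#' @param electrodes Character vector of electrode labels for this subject.
#' @return Named numeric vector, one value per entry of `node_values`.
#' @export
site_measures <- function(node_values, site_map, electrodes) {
  missing_e <- setdiff(electrodes, names(site_map))
  if (length(missing_e)) {
    stop("electrode(s) not in site map: ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  }
  idx <- sort(unique(unlist(site_map[electrodes])))
  n <- length(node_values[[1]])
  if (any(idx > n)) {
    stop("site map index exceeds node count (", n, ")", call. = FALSE)
  }
  vapply(node_values, function(v) mean(v[idx]), numeric(1))
}

#' Measure names produced by the pipeline
#'
#' Four global measures and four stimulation-site aggregates.
#' @return Character vector.
#' @export
measure_names <- function() {
  c("C_net", "L_net", "E_net", "sigma", "K_site", "C_site", "L_site",
    "E_site")
}

#' Compute the tidy measure table across samples and densities
#'
#' For every sample the Fisher-z matrix is built, thresholded across the
#' density grid, and the requested measures computed; stimulation-site
#' aggregates use each subject's electrode labels and the cohort site map.
#' Sigma null seeds fan out deterministically per (sample, density) from
#' `seed`.
#'
#' @param samples Tibble from [prepare_samples()].
#' @param subjects Subject metadata with `subject_id` and
#'   `stimulation_sites` (semicolon-separated), required for site measures.
#' @param densities Density grid (default [density_grid()]).
#' @param site_map Named list electrode -> region indices
#'   (default [default_site_map()] for the region count at hand).
#' @param measures Subset of [measure_names()] to compute.
#' @param n_nulls Null networks per graph for sigma (default 100).
#' @param seed Master seed for the sigma nulls.
#' @return Tidy tibble: `sample_id`, `subject_id`, `condition`, `window`,
#'   `density`, `measure`, `scope` (`global`/`site`), `value`,
#'   `disconnected`.
#' @export
compute_measures <- function(samples, subjects = NULL,
                             densities = density_grid(), site_map = NULL,
                             measures = measure_names(), n_nulls = 100L,
                             seed = 1L) {
  measures <- match.arg(measures, measure_names(), several.ok = TRUE)
  want_site <- any(grepl("_site$", measures))
  want_sigma <- "sigma" %in% measures
  electrodes_of <- NULL
  if (want_site) {
    if (is.null(subjects)) {
      stop("site measures need the subjects table", call. = FALSE)
    }
    electrodes_of <- setNames(
      strsplit(subjects$stimulation_sites, ";", fixed = TRUE),
      subjects$subject_id
    )
  }
  out <- vector("list", nrow(samples))
  for (r in seq_len(nrow(samples))) {
    ts <- samples$data[[r]]
    if (is.null(site_map) && want_site) site_map <- default_site_map(nrow(ts))
    z <- correlation_to_z(ts)
    graphs <- density_sweep(z, densities)
    per_d <- vector("list", length(densities))
    for (k in seq_along(densities)) {
      w <- graphs[[k]]
      d <- shortest_path_matrix(w)
      cl <- clustering_coef(w)
      pl <- path_length(w, dist = d)
      vals <- c(
        C_net = cl$net, L_net = pl$net,
        E_net = global_efficiency(w, dist = d),
        sigma = NA_real_, K_site = NA_real_, C_site = NA_real_,
        L_site = NA_real_, E_site = NA_real_
      )
      if (want_sigma) {
        null <- rewire_null(w, n_nulls,
                            seed = fanout_seed(seed, 5L, r * 37L + k))
        vals[["sigma"]] <- sigma_from_parts(cl$net, pl$net, null[["C_R"]],
                                            null[["L_R"]])
      }
      if (want_site) {
        el <- electrodes_of[[samples$subject_id[r]]]
        missing_e <- setdiff(el, names(site_map))
        if (length(missing_e)) {
          stop("electrode(s) not in site map: ",
               paste(missing_e, collapse = ", "), call. = FALSE)
        }
        idx <- sort(unique(unlist(site_map[el])))
        vals[["K_site"]] <- mean(node_degree(w)[idx])
        vals[["C_site"]] <- mean(cl$local[idx])
        vals[["L_site"]] <- mean(pl$local[idx])
        vals[["E_site"]] <- mean(local_efficiency(w, nodes = idx))
      }
      per_d[[k]] <- tibble::tibble(
        density = densities[k], measure = measures,
        scope = ifelse(grepl("_site$", measures), "site", "global"),
        value = unname(vals[measures]),
        disconnected = pl$disconnected
      )
    }
    meta <- samples[r, c("sample_id", "subject_id", "condition", "window")]
    tbl <- dplyr::bind_rows(per_d)
    out[[r]] <- dplyr::bind_cols(meta[rep(1L, nrow(tbl)), ], tbl)
  }
  dplyr::bind_rows(out)
}
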