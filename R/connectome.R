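#' Fisher-z connectivity matrix from one windowed time series
#'
#' Pearson correlations between all region pairs, variance-stabilised by
#' Fisher's r-to-z (`atanh`). The diagonal is exactly zero. Degenerate
#' correlations with `|r| = 1` (e.g. duplicated regions in synthetic input)
#' are capped at `1 - 1e-7` before the transform, with a warning, so one
#' pathological pair cannot poison the matrix with infinities.
#'
#' @param ts Regions-by-time matrix with at least 3 time points per region;
#'   rows may be named with region labels.
#' @return N x N symmetric matrix of Fisher-z values, zero diagonal,
#'   dimnames carrying the region labels.
#' @export
correlation_to_z <- function(ts) {
  stopifnot(is.matrix(ts), ncol(ts) >= 3)
  sds <- apply(ts, 1, sd)
  if (any(sds == 0)) {
    labs <- rownames(ts) %||% sprintf("R%03d", seq_len(nrow(ts)))
    stop("zero-variance region(s): ",
         paste(labs[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- cor(t(ts))
  diag(r) <- 0
  cap <- 1 - 1e-7
  if (any(abs(r) >= 1)) {
    warning("correlation(s) of magnitude 1 capped before Fisher transform",
            call. = FALSE)
    r[r >= 1] <- cap
    r[r <= -1] <- -cap
  }
  z <- atanh(r)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  labs <- rownames(ts) %||% sprintf("R%03d", seq_len(nrow(ts)))
  dimnames(z) <- list(labs, labs)
  z
}

# round-half-away-from-zero for the proportional edge count
round_half_up <- function(x) floor(x + 0.5)

#' Number of edges retained at a proportional density
#'
#' @param n_regions Node count.
#' @param density Fraction of the `n (n - 1) / 2` possible edges kept.
#' @return Integer edge count, rounded half away from zero so every sample
#'   shares exactly the same edge count at a given density (90 nodes at
#'   density 0.3 give 1202).
#' @export
edge_count_at_density <- function(n_regions, density) {
  as.integer(round_half_up(density * n_regions * (n_regions - 1) / 2))
}

#' Threshold a connectivity matrix to a fixed edge density
#'
#' Keeps the `round(d * N(N-1)/2)` largest Fisher-z entries of the upper
#' triangle as weighted undirected edges and zeroes the rest, so all samples
#' share the same node and edge counts at a given density. Ties at the cut
#' are resolved toward lexicographically smallest `(i, j)`, making the edge
#' set deterministic. Negative connections must never be retained: if the
#' requested density reaches them the call errors (density too high for this
#' matrix).
#'
#' @param z Symmetric Fisher-z matrix with zero diagonal.
#' @param density Fraction in `(0, 1]`.
#' @return Weight matrix of class `thresholded_graph` with attributes
#'   `density`, `edge_count` and `connected`.
#' @export
threshold_by_density <- function(z, density) {
  stopifnot(density > 0, density <= 1)
  n <- nrow(z)
  m <- edge_count_at_density(n, density)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[ut]
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  if (any(vals[keep] <= 0)) {
    stop("density ", density, " would retain non-positive connections; ",
         "use a lower density for this matrix", call. = FALSE)
  }
  w <- matrix(0, n, n, dimnames = dimnames(z))
  ik <- ut[keep, , drop = FALSE]
  w[ik] <- vals[keep]
  w[ik[, c(2, 1), drop = FALSE]] <- vals[keep]
  structure(w, class = c("thresholded_graph", "matrix", "array"),
            density = density, edge_count = m, connected = is_connected(w))
}

# breadth-first connectivity check on a weight matrix
is_connected <- function(w) {
  n <- nrow(w)
  if (n == 0L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(w[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Exact decimal density grid
#'
#' Densities are generated from integer hundredths to avoid floating-point
#' accumulation; the defaults give the 30 values 0.17, 0.18, ..., 0.46 used
#' for the sweep.
#'
#' @param d_min,d_max,step Grid limits and step (multiples of 0.01).
#' @return Numeric vector of densities.
#' @export
density_grid <- function(d_min = 0.17, d_max = 0.46, step = 0.01) {
  stopifnot(d_min <= d_max, step > 0)
  seq(round(d_min * 100), round(d_max * 100), by = round(step * 100)) / 100
}

#' Threshold one matrix across the density sweep
#'
#' @param z Symmetric Fisher-z matrix.
#' @param densities Densities (default [density_grid()]).
#' @param warn_disconnected Emit a warning naming disconnected densities
#'   (default FALSE; the `connected` attribute always records it).
#' @return Named list of `thresholded_graph` objects, one per density. Edge
#'   sets are nested along the grid (larger density is a superset).
#' @export
density_sweep <- function(z, densities = density_grid(),
                          warn_disconnected = FALSE) {
  graphs <- lapply(densities, function(d) threshold_by_density(z, d))
  names(graphs) <- formatC(densities, format = "f", digits = 2)
  disc <- !vapply(graphs, attr, logical(1), "connected")
  if (warn_disconnected && any(disc)) {
    warning("disconnected graph(s) at density ",
            paste(names(graphs)[disc], collapse = ", "), call. = FALSE)
  }
  graphs
}
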