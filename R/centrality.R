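# Node centralities on residue interaction networks. Graphs are unweighted
# for path-based measures (edge minimal distances are annotations, not
# weights). Each measure is standardized per network to a Z-score; residues
# with Z >= 2 are flagged central.

#' Centrality of every residue in a RIN
#'
#' Computes one of the four centrality measures and its per-network Z-score:
#'
#' * `DCA` (degree): neighbor count.
#' * `CCA` (closeness): reciprocal of the sum of unweighted shortest-path
#'   lengths from the node; on disconnected graphs computed within the
#'   node's component and, by default, scaled by (component size - 1)/(n - 1)
#'   so values are comparable across components (singletons get 0).
#' * `BCA` (betweenness): shortest-path betweenness, endpoints excluded,
#'   normalized by (n-1)(n-2)/2.
#' * `ECA` (eigenvector): principal eigenvector of the adjacency matrix,
#'   non-negative and L2-normalized, computed by power iteration on the
#'   largest connected component (other nodes get 0).
#'
#' @param g A `rin` object (see [build_rin()] or [make_graph_fixture()]).
#' @param measure One of `"DCA"`, `"CCA"`, `"BCA"`, `"ECA"`.
#' @param closeness `"corrected"` (component-size scaling, default) or
#'   `"component"` (raw within-component reciprocal sums).
#' @return Tibble with columns `node`, `measure`, `raw`, `z`.
#' @export
rin_centrality <- function(g, measure = c("DCA", "CCA", "BCA", "ECA"),
                           closeness = c("corrected", "component")) {
  measure <- match.arg(measure)
  closeness <- match.arg(closeness)
  ig <- rin_igraph(g)
  n <- igraph::vcount(ig)
  if (n == 0) abort("empty network")
  raw <- switch(
    measure,
    DCA = as.numeric(igraph::degree(ig)),
    BCA = {
      if (n < 3) rep(0, n)
      else as.numeric(igraph::betweenness(ig, directed = FALSE, weights = NA,
                                          normalized = TRUE))
    },
    CCA = closeness_raw(ig, mode = closeness),
    ECA = eigenvector_power(ig)
  )
  tibble(
    node = igraph::V(ig)$name,
    measure = measure,
    raw = raw,
    z = centrality_zscore(raw)
  )
}

closeness_raw <- function(ig, mode = "corrected") {
  n <- igraph::vcount(ig)
  comp <- igraph::components(ig)
  d <- igraph::distances(ig, weights = NA)
  purrr::map_dbl(seq_len(n), function(i) {
    members <- which(comp$membership == comp$membership[i])
    k <- length(members)
    if (k == 1) return(0)
    s <- sum(d[i, setdiff(members, i)])
    val <- 1 / s
    if (mode == "corrected" && n > 1) val <- val * (k - 1) / (n - 1)
    val
  })
}

# Principal adjacency eigenvector by power iteration: L2-normalized,
# non-negative, 1e-10 relative tolerance, at most 1000 iterations. On
# disconnected graphs the largest component carries the vector (ties broken
# by first occurrence); other nodes get 0.
eigenvector_power <- function(ig, tol = 1e-10, max_iter = 1000L) {
  n <- igraph::vcount(ig)
  comp <- igraph::components(ig)
  main <- which.max(comp$csize)
  members <- which(comp$membership == main)
  out <- rep(0, n)
  if (length(members) == 1) {
    out[members] <- 1
    return(out)
  }
  a <- igraph::as_adjacency_matrix(ig, sparse = FALSE)[members, members]
  # shifted iteration (A + I): same eigenvectors, strictly dominant leading
  # eigenvalue even on bipartite graphs, where plain iteration oscillates
  a <- a + diag(nrow(a))
  v <- rep(1 / sqrt(length(members)), length(members))
  for (iter in seq_len(max_iter)) {
    w <- as.numeric(a %*% v)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) break # no edges: keep uniform
    w <- w / nrm
    if (max(abs(w - v)) <= tol * max(abs(v))) {
      v <- w
      out[members] <- abs(v) / sqrt(sum(v^2))
      return(out)
    }
    v <- w
  }
  if (nrm == 0) {
    out[members] <- v
    return(out)
  }
  abort(paste0("eigenvector power iteration did not converge in ",
               max_iter, " iterations"))
}

#' Z-score standardization of centrality values
#'
#' `Z_i = (c_i - mean(c)) / sd(c)` over the network's nodes, with the
#' population (divide-by-n) standard deviation. A constant vector (sd = 0)
#' maps to all zeros.
#'
#' @param values Numeric vector of raw centralities.
#' @return Numeric vector of Z-scores.
#' @export
centrality_zscore <- function(values) {
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) return(rep(0, length(values)))
  (values - m) / s
}

#' Flag central residues
#'
#' A residue with a Z-score at or above the threshold (default 2) is
#' considered central.
#'
#' @param centrality Tibble from [rin_centrality()].
#' @param threshold Z-score cutoff (default 2).
#' @return The flagged subset of rows.
#' @export
central_residues <- function(centrality, threshold = 2) {
  filter(centrality, .data$z >= threshold)
}

#' All four centrality measures at once
#'
#' @param g A `rin` object.
#' @param measures Measures to compute (default all four).
#' @param ... Passed on to [rin_centrality()].
#' @return Long tibble with `node`, `measure`, `raw`, `z`.
#' @export
rin_centralities <- function(g, measures = c("DCA", "CCA", "BCA", "ECA"), ...) {
  purrr::map_dfr(measures, function(m) rin_centrality(g, m, ...))
}
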