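# Independent brute-force oracles, deliberately naive: all-pairs scans, BFS
# by hand, dense eigendecompositions. They never share code with the package
# internals they check.

# all residue pairs x all atom pairs distance scan
oracle_rin_edges <- function(s, d_min = 2.5, d_max = 5.0) {
  s$res_key <- paste0(s$chain_id, ":", s$resno, ifelse(s$icode == "", "", s$icode))
  keys <- unique(s$res_key)
  out <- list()
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (j <= i) next
      a <- as.matrix(s[s$res_key == keys[i], c("x", "y", "z")])
      b <- as.matrix(s[s$res_key == keys[j], c("x", "y", "z")])
      dmin <- Inf
      for (ai in seq_len(nrow(a))) {
        for (bi in seq_len(nrow(b))) {
          dmin <- min(dmin, sqrt(sum((a[ai, ] - b[bi, ])^2)))
        }
      }
      if (dmin >= d_min && dmin <= d_max) {
        out[[length(out) + 1]] <- data.frame(
          node_a = min(keys[i], keys[j]), node_b = max(keys[i], keys[j]),
          distance = dmin
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(node_a = character(0), node_b = character(0),
                      distance = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$node_a, res$node_b), ]
}

rin_adjacency <- function(g) {
  n <- nrow(g$nodes)
  a <- matrix(0, n, n, dimnames = list(g$nodes$node, g$nodes$node))
  for (i in seq_len(nrow(g$edges))) {
    a[g$edges$node_a[i], g$edges$node_b[i]] <- 1
    a[g$edges$node_b[i], g$edges$node_a[i]] <- 1
  }
  a
}

oracle_bfs <- function(a, start) {
  n <- nrow(a)
  dist <- rep(Inf, n)
  dist[start] <- 0
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(a[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

oracle_degree <- function(a) rowSums(a)

oracle_closeness <- function(a, mode = c("corrected", "component")) {
  mode <- match.arg(mode)
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    d <- oracle_bfs(a, i)
    reach <- which(is.finite(d) & seq_len(n) != i)
    if (length(reach) == 0) return(0)
    val <- 1 / sum(d[reach])
    if (mode == "corrected" && n > 1) val <- val * length(reach) / (n - 1)
    val
  })
}

# shortest-path counts sigma[s, t] and the dependency test via distances
oracle_betweenness <- function(a) {
  n <- nrow(a)
  if (n < 3) return(rep(0, n))
  d <- sapply(seq_len(n), function(i) oracle_bfs(a, i))
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(d[, s])) {
      if (t == s || is.infinite(d[t, s])) next
      preds <- which(a[t, ] == 1 & d[, s] == d[t, s] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  b <- sapply(seq_len(n), function(v) {
    total <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (is.infinite(d[t, s])) next
        if (d[v, s] + d[t, v] == d[t, s]) {
          total <- total + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    total
  })
  b / ((n - 1) * (n - 2) / 2)
}

oracle_eigenvector <- function(a) {
  n <- nrow(a)
  # largest component by BFS
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    comp[is.finite(oracle_bfs(a, i))] <- cid
  }
  sizes <- table(comp)
  main <- as.integer(names(sizes)[which.max(sizes)])
  members <- which(comp == main)
  out <- rep(0, n)
  if (length(members) == 1) {
    out[members] <- 1
    return(out)
  }
  sub <- a[members, members]
  e <- eigen(sub, symmetric = TRUE)
  v <- abs(e$vectors[, 1])
  out[members] <- v / sqrt(sum(v^2))
  out
}

# PCA oracle: eigendecomposition of the covariance (or correlation) matrix
oracle_pca <- function(x, center = TRUE, scale = FALSE) {
  if (center) x <- sweep(x, 2, colMeans(x))
  if (scale) x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  cv <- crossprod(x) / (nrow(x) - 1)
  e <- eigen(cv, symmetric = TRUE)
  list(eigenvalues = e$values, vectors = e$vectors)
}

random_rin_graph <- function(n, p = 0.35, seed = 1) {
  withr::with_seed(seed, {
    g <- make_graph_fixture("path", n) # node scaffold
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    edges <- pairs[keep, , drop = FALSE]
    g$edges <- if (nrow(edges) == 0) {
      tibble::tibble(node_a = character(0), node_b = character(0),
                     distance = numeric(0))
    } else {
      tibble::tibble(
        node_a = paste0("A:", edges[, 1]),
        node_b = paste0("A:", edges[, 2]),
        distance = 4.0
      )
    }
    g
  })
}
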