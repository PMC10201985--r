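# PCA over the combinations-by-residues centrality matrix: variance
# explained, individual (combination) coordinates, and per-residue
# contributions computed from squared loadings.

#' Assemble the combinations-by-residues centrality matrix
#'
#' Collects one centrality table per combination model into a wide matrix of
#' Z-scores: rows are combinations (in the order supplied), columns are
#' residues labelled `<number>.<suffix>` with suffix `k` for
#' plastid-compartment and `u` for nuclear-compartment residues, ordered
#' plastid first, then by residue number.
#'
#' @param tables Named list (combination label -> centrality tibble from
#'   [rin_centrality()] or [rin_centralities()]).
#' @param measure Which measure to extract (e.g. `"BCA"`).
#' @param nodes Node annotation tibble (`node`, `resno`, `compartment`), as
#'   in the `nodes` element of a `rin`.
#' @param residues Optional subset of residue labels to keep (default: all
#'   nodes shared by every combination).
#' @return Wide tibble `combination` + residue columns, with attribute
#'   `measure`.
#' @export
assemble_centrality_matrix <- function(tables, measure, nodes, residues = NULL) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("`tables` must be a named list keyed by combination label")
  }
  long <- purrr::imap_dfr(tables, function(tb, label) {
    tb <- tb[tb$measure == measure, ]
    if (nrow(tb) == 0) {
      abort(paste0("combination ", label, " has no ", measure, " centralities"))
    }
    tibble(combination = label, node = tb$node, z = tb$z)
  })
  shared <- purrr::reduce(purrr::map(tables, function(tb) {
    unique(tb$node[tb$measure == measure])
  }), intersect)
  ann <- nodes[nodes$node %in% shared, ]
  ann$suffix <- ifelse(ann$compartment == "plastid", "k",
                       ifelse(ann$compartment == "nuclear", "u", "x"))
  ann$label <- paste0(ann$resno, ".", ann$suffix)
  ann <- ann[order(match(ann$suffix, c("k", "u", "x")), ann$resno), ]
  if (!is.null(residues)) {
    missing_lab <- setdiff(residues, ann$label)
    if (length(missing_lab) > 0) {
      abort(paste0("requested residue(s) not shared by all combinations: ",
                   paste(missing_lab, collapse = ", ")))
    }
    ann <- ann[ann$label %in% residues, ]
  }
  wide <- long |>
    filter(.data$node %in% ann$node) |>
    mutate(label = ann$label[match(.data$node, ann$node)]) |>
    select("combination", "label", "z") |>
    tidyr::pivot_wider(names_from = "label", values_from = "z")
  wide <- wide[match(names(tables), wide$combination), c("combination", ann$label)]
  if (anyNA(wide)) abort("incomplete centrality matrix after assembly")
  attr(wide, "measure") <- measure
  wide
}

#' Principal component analysis of a centrality matrix
#'
#' Column-centered (and by default unit-variance-scaled) singular value
#' decomposition of the combinations-by-residues matrix, with a fixed sign
#' convention: each component's largest-magnitude loading is positive, so
#' results are stable across linear-algebra backends.
#'
#' @param m Wide tibble as from [assemble_centrality_matrix()] or
#'   [table3_fixture()]: a `combination` column plus numeric residue
#'   columns.
#' @param center,scale Centering/scaling flags passed to the decomposition.
#'   Scaling is on by default; with Z-score inputs printed to limited
#'   precision the correlation-matrix form is what reproduces the published
#'   variance shares.
#' @return Object of class `cn_pca`: eigenvalues, `variance_pct`, `scores`
#'   (combinations x components), `loadings` and `contributions_pct`
#'   (residues x components).
#' @export
run_pca <- function(m, center = TRUE, scale = TRUE) {
  m <- as_tibble(m)
  if (!"combination" %in% names(m)) {
    abort("matrix must have a `combination` column")
  }
  x <- as.matrix(m[, setdiff(names(m), "combination")])
  rownames(x) <- m$combination
  if (nrow(x) < 2) abort("PCA needs at least 2 combinations")
  col_var <- apply(x, 2, stats::var)
  if (all(col_var == 0)) abort("degenerate input: all columns are constant")
  if (scale && any(col_var == 0)) {
    abort(paste0("cannot scale constant column(s): ",
                 paste(colnames(x)[col_var == 0], collapse = ", ")))
  }
  p <- prcomp(x, center = center, scale. = scale)
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  eig <- p$sdev^2
  contrib <- sweep(p$rotation^2, 2, colSums(p$rotation^2), "/") * 100
  out <- list(
    eigenvalues = eig,
    variance_pct = eig / sum(eig) * 100,
    scores = bind_cols(tibble(combination = rownames(p$x)),
                       as_tibble(p$x)),
    loadings = bind_cols(tibble(residue = rownames(p$rotation)),
                         as_tibble(p$rotation)),
    contributions_pct = bind_cols(tibble(residue = rownames(contrib)),
                                  as_tibble(contrib)),
    center = center, scale = scale,
    measure = attr(m, "measure"),
    n_combinations = nrow(x), n_residues = ncol(x)
  )
  class(out) <- "cn_pca"
  out
}

#' @export
print.cn_pca <- function(x, ...) {
  cat("<centrality PCA", if (!is.null(x$measure)) paste0(" (", x$measure, ")"),
      ": ", x$n_combinations, " combinations x ", x$n_residues,
      " residues>\n", sep = "")
  v <- round(x$variance_pct[1:min(3, length(x$variance_pct))], 1)
  cat("  variance explained: ", paste0("PC", seq_along(v), " ", v, "%",
                                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-residue contributions to one component
#'
#' Contribution of a residue is its squared loading as a percentage of the
#' component's total squared loadings; the uniform reference is 100 divided
#' by the number of residues (the dashed-line value in contribution plots).
#'
#' @param p A `cn_pca` object.
#' @param component Component index (1-based).
#' @return Tibble `residue`, `contribution_pct`, sorted decreasing, with
#'   attribute `uniform_pct`.
#' @export
variable_contributions <- function(p, component = 1) {
  stopifnot(inherits(p, "cn_pca"))
  if (component < 1 || component > (ncol(p$contributions_pct) - 1)) {
    abort("component out of range")
  }
  col <- paste0("PC", component)
  out <- tibble(residue = p$contributions_pct$residue,
                contribution_pct = p$contributions_pct[[col]]) |>
    arrange(desc(.data$contribution_pct))
  attr(out, "uniform_pct") <- 100 / p$n_residues
  out
}

#' Separation of reciprocal crosses in the PC1-PC2 plane
#'
#' For every unordered lineage pair P != N with both combination labels
#' present, the Euclidean distance between the scores of `P_N` and `N_P` on
#' the first two components. Missing reciprocals are reported with `NA`
#' distance rather than an error.
#'
#' @param p A `cn_pca` object whose rows are `P_N` combination labels.
#' @return Tibble `lineage_a`, `lineage_b`, `label_ab`, `label_ba`,
#'   `distance`.
#' @export
reciprocal_cross_separation <- function(p) {
  stopifnot(inherits(p, "cn_pca"))
  labels <- p$scores$combination
  parts <- strsplit(labels, "_", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort("combination labels must have the form <plastid>_<nuclear>")
  }
  lineages <- sort(unique(unlist(parts)))
  pairs <- utils::combn(lineages, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ab <- paste0(a, "_", b); ba <- paste0(b, "_", a)
    d <- if (ab %in% labels && ba %in% labels) {
      sa <- as.numeric(p$scores[p$scores$combination == ab, c("PC1", "PC2")])
      sb <- as.numeric(p$scores[p$scores$combination == ba, c("PC1", "PC2")])
      sqrt(sum((sa - sb)^2))
    } else {
      NA_real_
    }
    tibble(lineage_a = a, lineage_b = b, label_ab = ab, label_ba = ba,
           distance = d)
  })
}

#' @export
tidy.cn_pca <- function(x, matrix = c("loadings", "scores", "contributions",
                                      "variance"), ...) {
  matrix <- match.arg(matrix)
  switch(
    matrix,
    variance = tibble(
      component = seq_along(x$variance_pct),
      eigenvalue = x$eigenvalues,
      variance_pct = x$variance_pct,
      cumulative_pct = cumsum(x$variance_pct)
    ),
    scores = tidyr::pivot_longer(x$scores, -"combination",
                                 names_to = "component", values_to = "score"),
    loadings = tidyr::pivot_longer(x$loadings, -"residue",
                                   names_to = "component", values_to = "loading"),
    contributions = tidyr::pivot_longer(x$contributions_pct, -"residue",
                                        names_to = "component",
                                        values_to = "contribution_pct")
  )
}

#' @export
glance.cn_pca <- function(x, ...) {
  tibble(
    measure = x$measure %||% NA_character_,
    n_combinations = x$n_combinations,
    n_residues = x$n_residues,
    pc1_variance_pct = x$variance_pct[1],
    pc2_variance_pct = x$variance_pct[2],
    pc1_pc2_total_pct = sum(x$variance_pct[1:2])
  )
}

#' @export
autoplot.cn_pca <- function(object, ...) {
  v <- round(object$variance_pct[1:2], 1)
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$combination)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = paste0("PC1 (", v[1], "%)"), y = paste0("PC2 (", v[2], "%)"),
      title = if (!is.null(object$measure)) {
        paste0("Combination centrality PCA (", object$measure, ")")
      } else {
        "Combination centrality PCA"
      }
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of residue contributions to a component
#'
#' The dashed reference line marks the value expected if contributions were
#' uniform across residues.
#'
#' @param p A `cn_pca` object.
#' @param component Component index.
#' @return A ggplot object.
#' @export
plot_contributions <- function(p, component = 1) {
  contrib <- variable_contributions(p, component)
  uniform <- attr(contrib, "uniform_pct")
  contrib$residue <- factor(contrib$residue, levels = contrib$residue)
  ggplot2::ggplot(contrib, ggplot2::aes(x = .data$residue,
                                        y = .data$contribution_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = uniform, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "Contribution (%)",
                  title = paste0("Residue contributions to PC", component)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a combinations-by-residues centrality matrix
#'
#' @param m Wide matrix tibble (e.g. from [table3_fixture()]).
#' @return A ggplot object.
#' @export
plot_centrality_matrix <- function(m) {
  long <- tidyr::pivot_longer(as_tibble(m), -"combination",
                              names_to = "residue", values_to = "z")
  long$residue <- factor(long$residue, levels = setdiff(names(m), "combination"))
  long$combination <- factor(long$combination, levels = rev(m$combination))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue, y = .data$combination,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
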