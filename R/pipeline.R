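# End-to-end orchestration: template structure -> combination models -> RIN
# per model -> interface typing -> centralities -> combinations-by-residues
# matrices -> PCA. Deterministic: rerunning with the same configuration
# writes byte-identical outputs.

#' Assemble a pipeline configuration
#'
#' @param structure Path to a coordinate file, or a structure tibble.
#' @param chain_map Chain map (path, list or tibble); see [read_chain_map()].
#' @param lineages Lineage labels (L lineages give L^2 combination models).
#' @param substitutions Long substitution table (`lineage`, `gene`,
#'   `ref_number`, `new_aa`), a TSV path with those columns, or the output
#'   of [build_substitution_sets()].
#' @param proteins Optional protein selection (default: all chains mapped to
#'   the plastid or nuclear compartment).
#' @param d_min,d_max Interaction window in Angstrom.
#' @param measures Centrality measures to compute.
#' @param center,scale PCA flags (see [run_pca()]).
#' @param relax Chi-grid relax rebuilt side chains (default `TRUE`).
#' @param out_dir Output directory.
#' @param seed Integer recorded in the run log (the pipeline itself is
#'   deterministic).
#' @param format Structure file format, as in [read_structure()].
#' @return Config list for [run_pipeline()].
#' @export
pipeline_config <- function(structure, chain_map, lineages, substitutions,
                            proteins = NULL, d_min = 2.5, d_max = 5.0,
                            measures = c("BCA", "CCA", "DCA", "ECA"),
                            center = TRUE, scale = TRUE, relax = TRUE,
                            out_dir = "cybrin_run", seed = 1L,
                            format = "auto") {
  list(structure = structure, chain_map = chain_map, lineages = lineages,
       substitutions = substitutions, proteins = proteins,
       d_min = d_min, d_max = d_max, measures = measures,
       center = center, scale = scale, relax = relax,
       out_dir = out_dir, seed = as.integer(seed), format = format)
}

#' Run the full combination-model pipeline
#'
#' For every plastid-by-nuclear lineage combination: builds the mutant model,
#' writes it as PDB, builds the residue interaction network and exports its
#' edge list, types the plastid-nuclear interface contacts, and computes all
#' requested centralities with Z-scores. Per measure, assembles the
#' combinations-by-residues Z-score matrix, runs the PCA and writes scores,
#' loadings, contributions and a JSON summary, plus a run log carrying the
#' configuration hash.
#'
#' @param config Config list from [pipeline_config()], or a path to a YAML
#'   file with the same fields.
#' @return Invisibly, a list with `models`, `rins`, `interface` (typed
#'   contacts per combination), `centralities`, `matrices`, `pca` and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  cm <- stage("chain_map", as_chain_map(cfg$chain_map))
  template <- stage("structure", {
    if (is.data.frame(cfg$structure)) {
      as_structure(cfg$structure)
    } else {
      read_structure(cfg$structure, format = cfg$format %||% "auto",
                     chain_map = cm)
    }
  })
  proteins <- cfg$proteins %||%
    cm$protein[cm$compartment %in% c("plastid", "nuclear")]
  template <- stage("selection", select_chains(template, proteins))
  subs <- stage("substitutions", {
    if (is.character(cfg$substitutions)) {
      readr::read_tsv(cfg$substitutions, show_col_types = FALSE,
                      progress = FALSE)
    } else {
      as_tibble(cfg$substitutions)
    }
  })
  out_dir <- cfg$out_dir %||% "cybrin_run"
  for (d in c("", "models", "edges", "interface", "centrality", "pca")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  combos <- combination_ids(cfg$lineages)
  plastid_prot <- intersect(proteins, cm$protein[cm$compartment == "plastid"])
  nuclear_prot <- intersect(proteins, cm$protein[cm$compartment == "nuclear"])
  models <- list(); rins <- list(); interface <- list(); cents <- list()
  for (i in seq_len(nrow(combos))) {
    label <- combos$label[i]
    model <- stage(paste0("mutagenesis ", label), build_combination_model(
      template, combos$plastid[i], combos$nuclear[i], subs, cm,
      relax = cfg$relax %||% TRUE
    ))
    write_structure(model$structure, file.path(out_dir, "models",
                                               paste0(label, ".pdb")))
    g <- stage(paste0("rin ", label),
               build_rin(model$structure, cfg$d_min %||% 2.5,
                         cfg$d_max %||% 5.0))
    export_edge_list(g, file.path(out_dir, "edges", paste0(label, "_edges.tsv")))
    iface <- stage(paste0("interface ", label), purrr::map_dfr(
      tidyr::expand_grid(pa = plastid_prot, pb = nuclear_prot) |>
        purrr::transpose(),
      function(pr) type_interface(model$structure,
                                  interface_edges(g, pr$pa, pr$pb))
    ))
    readr::write_tsv(iface, file.path(out_dir, "interface",
                                      paste0(label, "_interface.tsv")),
                     progress = FALSE)
    cent <- stage(paste0("centrality ", label),
                  rin_centralities(g, cfg$measures %||% c("BCA", "CCA", "DCA", "ECA")))
    readr::write_csv(cent, file.path(out_dir, "centrality",
                                     paste0(label, "_centrality.csv")),
                     progress = FALSE)
    models[[label]] <- model
    rins[[label]] <- g
    interface[[label]] <- iface
    cents[[label]] <- cent
  }
  nodes <- rins[[1]]$nodes
  matrices <- list(); pcas <- list()
  for (m in (cfg$measures %||% c("BCA", "CCA", "DCA", "ECA"))) {
    mat <- stage(paste0("matrix ", m),
                 assemble_centrality_matrix(cents, m, nodes))
    readr::write_csv(mat, file.path(out_dir,
                                    paste0("centrality_matrix_", tolower(m), ".csv")),
                     progress = FALSE)
    p <- stage(paste0("pca ", m),
               run_pca(mat, center = cfg$center %||% TRUE,
                       scale = cfg$scale %||% TRUE))
    readr::write_csv(p$scores, file.path(out_dir, "pca",
                                         paste0(tolower(m), "_scores.csv")),
                     progress = FALSE)
    readr::write_csv(p$loadings, file.path(out_dir, "pca",
                                           paste0(tolower(m), "_loadings.csv")),
                     progress = FALSE)
    readr::write_csv(p$contributions_pct,
                     file.path(out_dir, "pca",
                               paste0(tolower(m), "_contributions.csv")),
                     progress = FALSE)
    matrices[[m]] <- mat
    pcas[[m]] <- p
  }
  summary <- purrr::imap(pcas, function(p, m) {
    list(pc1_variance_pct = p$variance_pct[1],
         pc2_variance_pct = p$variance_pct[2])
  })
  jsonlite::write_json(summary, file.path(out_dir, "pca", "pca_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- list(
    package = "cybrin",
    version = as.character(utils::packageVersion("cybrin")),
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed %||% NA_integer_,
    n_combinations = nrow(combos),
    pca = list(center = cfg$center %||% TRUE, scale = cfg$scale %||% TRUE)
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(models = models, rins = rins, interface = interface,
                 centralities = cents, matrices = matrices, pca = pcas,
                 paths = list(out_dir = out_dir)))
}
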