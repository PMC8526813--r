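#' Default pipeline configuration
#'
#' Every threshold the pipeline applies, in one place: linear fold-change
#' cutoff 2, minimum absolute stromal correlation 0.2, edge thresholds 0.6
#' (bulk) and 0.2 (single-cell), significance level 0.05,
#' active/inactive state cutoffs 5 and 2, single-cell detection floor 1%,
#' ssGSEA exponent 0.25, gene-counts signature size 200.
#'
#' @param ... overrides for any field.
#' @return named list of parameters.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    fc = 2, r_min = 0.2, r_min_network_bulk = 0.6, r_min_network_sc = 0.2,
    alpha = 0.05, active_min = 5L, inactive_max = 2L,
    sc_expressed_frac = 0.01, ssgsea_alpha = 0.25, top_k = 200L,
    enriched_subgroup = "SHH", suppressed_subgroup = "Group3",
    seed = 1L, outdir = NULL, simulate = TRUE,
    bulk = list(), sc = list(),
    matrix_path = NULL, annotation_path = NULL, sc_matrix_path = NULL,
    sc_annotation_path = NULL, signatures_path = NULL, rl_path = NULL)
  modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' \code{\link{default_run_config}}.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  modifyList(base, user)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full stromal-microenvironment pipeline
#'
#' Executes, in order: signature scoring of the bulk matrix (ssGSEA
#' stromal and immune scores), differential-expression + stromal
#' correlation screens of the enriched and suppressed subgroups against
#' the pooled rest, driver/suppressor classification over the
#' receptor-ligand universe (stromal/immune signature genes excluded,
#' associates restricted to genes detected in at least
#' \code{sc_expressed_frac} of single cells when single-cell data is
#' present), bulk correlation-network construction with closeness
#' centrality, and — when single-cell data is present — per-cell
#' associate counting, state classification, marker detection, metastasis
#' contrast and developmental-potential scoring.
#'
#' With \code{simulate = TRUE} the inputs are produced by
#' \code{\link{generate_bulk}} and \code{\link{generate_sc}} (any
#' \code{bulk}/\code{sc} config overrides applied, seeded from
#' \code{seed}); otherwise the \code{*_path} fields are read.
#'
#' @param config list from \code{\link{default_run_config}} or
#'   \code{\link{read_run_config}}.
#' @return list of stage results: \code{scores}, \code{screen_enriched},
#'   \code{screen_suppressed}, \code{associates}, \code{network},
#'   \code{cellstate} (NULL without single-cell data) and
#'   \code{manifest}.  When \code{config$outdir} is set, every stage
#'   output is written there as TSV/GraphML and the manifest records each
#'   file with its MD5 hash.
#' @export
run_all <- function(config = default_run_config()) {
  cfg <- modifyList(default_run_config(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (isTRUE(cfg$simulate)) {
    bulk_cfg <- do.call(bulk_sim_config, c(cfg$bulk, list(seed = cfg$seed)))
    bulk <- stage("simulate", generate_bulk(bulk_cfg))
    mat <- bulk$matrix; ann <- bulk$annotation
    sigs <- bulk$signatures; rl <- bulk$rl
    sc_cfg <- do.call(sc_sim_config,
                      c(cfg$sc, list(n_genes = bulk_cfg$n_genes,
                                     seed = cfg$seed + 1L)))
    sc <- stage("simulate", generate_sc(sc_cfg, associate_genes = names(rl$roles)))
    sc_mat <- sc$matrix; sc_ann <- sc$annotation
  } else {
    for (p in c("matrix_path", "annotation_path", "signatures_path", "rl_path"))
      if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
        stop("required input missing: ", p, " = ",
             if (is.null(cfg[[p]])) "<unset>" else cfg[[p]])
    mat <- read_matrix(cfg$matrix_path, "tsv", "bulk-log2")
    ann <- read_annotation(cfg$annotation_path)
    sigs <- read_gmt(cfg$signatures_path)
    rl <- read_rl_pairs(cfg$rl_path)
    sc_mat <- sc_ann <- NULL
    if (!is.null(cfg$sc_matrix_path)) {
      sc_mat <- read_matrix(cfg$sc_matrix_path, "tsv", "sc-lognorm")
      sc_ann <- read_annotation(cfg$sc_annotation_path)
    }
  }
  if (!all(c("stromal", "immune") %in% names(sigs)))
    stop("signatures must include 'stromal' and 'immune' sets")

  scores <- stage("score",
                  score_table(mat, sigs, method = "ssgsea",
                              alpha = cfg$ssgsea_alpha))
  scr_enr <- stage("screen",
                   screen_subgroup(mat, ann, cfg$enriched_subgroup, scores))
  scr_sup <- stage("screen",
                   screen_subgroup(mat, ann, cfg$suppressed_subgroup, scores))
  assoc <- stage("associates",
                 classify_associates(scr_enr, scr_sup, rl, exclude = sigs,
                                     fc = cfg$fc, r_min = cfg$r_min,
                                     alpha = cfg$alpha))
  if (!is.null(sc_mat) && nrow(assoc)) {
    keep <- filter_sc_expressed(assoc$gene, sc_mat,
                                min_frac = cfg$sc_expressed_frac)
    assoc <- assoc[assoc$gene %in% keep, , drop = FALSE]
  }
  network <- if (nrow(assoc) >= 2L)
    stage("network", build_network(mat, assoc,
                                   r_min = cfg$r_min_network_bulk,
                                   alpha = cfg$alpha))
  else NULL

  cellstate <- NULL
  if (!is.null(sc_mat) && nrow(assoc)) {
    cellstate <- stage("cellstate", {
      counts <- count_associates(sc_mat, assoc)
      states <- classify_state(counts, active_min = cfg$active_min,
                               inactive_max = cfg$inactive_max)
      markers <- if (sum(states == "active") >= 3L &&
                     sum(states == "inactive") >= 3L)
        find_markers(sc_mat, states, min_frac = cfg$sc_expressed_frac,
                     alpha = cfg$alpha)
      else NULL
      contrast <- if ("metastasis" %in% names(sc_ann))
        metastasis_contrast(counts, sc_ann)
      else NULL
      pot <- dev_potential(sc_mat, top_k = cfg$top_k)
      list(counts = counts, states = states, markers = markers,
           metastasis = contrast, potential = pot,
           potential_vs_activity = potential_vs_activity(pot, counts),
           sc_network = if (nrow(assoc) >= 2L)
             build_network(sc_mat, assoc, r_min = cfg$r_min_network_sc,
                           alpha = cfg$alpha)
           else NULL)
    })
  }

  result <- list(scores = scores, screen_enriched = scr_enr,
                 screen_suppressed = scr_sup, associates = assoc,
                 network = network, cellstate = cellstate)

  manifest <- list(version = as.character(packageVersion("stromascope")),
                   seed = cfg$seed,
                   parameters = cfg[c("fc", "r_min", "r_min_network_bulk",
                                      "r_min_network_sc", "alpha",
                                      "active_min", "inactive_max",
                                      "sc_expressed_frac", "ssgsea_alpha",
                                      "top_k", "enriched_subgroup",
                                      "suppressed_subgroup")])
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- character()
    fp <- function(f) file.path(cfg$outdir, f)
    out <- c(out, write_tsv(scores, fp("scores.tsv")),
             write_tsv(scr_enr, fp("screen_enriched.tsv")),
             write_tsv(scr_sup, fp("screen_suppressed.tsv")),
             write_tsv(assoc, fp("associates.tsv")))
    if (!is.null(network)) {
      out <- c(out, write_tsv(network$nodes, fp("network_nodes.tsv")),
               write_edge_list(network, fp("network_edges.tsv")),
               write_graphml(network, fp("network.graphml")))
    }
    if (!is.null(cellstate)) {
      percell <- cellstate$counts
      percell$state <- unname(cellstate$states[percell$cell_id])
      percell$potential <- unname(cellstate$potential[percell$cell_id])
      out <- c(out, write_tsv(percell, fp("cellstate.tsv")))
      if (!is.null(cellstate$markers))
        out <- c(out, write_tsv(cellstate$markers, fp("markers.tsv")))
    }
    manifest$files <- data.frame(path = basename(out),
                                 md5 = unname(tools::md5sum(out)),
                                 stringsAsFactors = FALSE)
    yaml::write_yaml(manifest, fp("manifest.yaml"))
  }
  result$manifest <- manifest
  result
}
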