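#' Classify receptor/ligand genes into stroma-drivers and stroma-suppressors
#'
#' A gene is a \emph{driver} when it is a known receptor or ligand,
#' positively correlated with the stromal score (\code{r_stroma > r_min},
#' \code{p_corr < alpha}) and either upregulated in the stroma-enriched
#' subgroup or downregulated in the stroma-suppressed subgroup
#' (\code{|log2fc| > log2(fc)}, \code{p_dge < alpha}).  A
#' \emph{suppressor} is the mirror image: negative stromal correlation and
#' either up in the suppressed subgroup or down in the enriched one.  All
#' threshold comparisons are strict.  Genes belonging to any excluded
#' signature (typically the stromal signature panel itself) are removed,
#' as are genes with undefined correlation; a gene qualifying for both
#' classes is dropped with a warning.
#'
#' @param dge_enriched screen of the stroma-enriched subgroup vs pooled
#'   rest (see \code{\link{screen_subgroup}}).
#' @param dge_suppressed screen of the stroma-suppressed subgroup vs
#'   pooled rest.
#' @param rl receptor-ligand table (see \code{\link{read_rl_pairs}}).
#' @param exclude list of gene sets to remove (e.g. the stromal/immune
#'   signatures), or NULL.
#' @param fc linear fold-change cutoff (applied as \code{|log2fc| >
#'   log2(fc)}).
#' @param r_min minimum absolute stromal correlation.
#' @param alpha significance level for both the DGE and correlation
#'   p-values.
#' @return data.frame: \code{gene}, \code{class}
#'   (\code{driver}/\code{suppressor}), \code{role}, the qualifying
#'   evidence (\code{log2fc_enriched}, \code{p_enriched},
#'   \code{log2fc_suppressed}, \code{p_suppressed}, \code{r_stroma},
#'   \code{p_corr}) and the provenance flags \code{up_in_enriched},
#'   \code{down_in_suppressed} (drivers) or their mirrors.
#' @export
classify_associates <- function(dge_enriched, dge_suppressed, rl,
                                exclude = NULL, fc = 2, r_min = 0.2,
                                alpha = 0.05) {
  if (is.null(rl$pairs) || nrow(rl$pairs) == 0L)
    stop("receptor-ligand table is empty")
  stopifnot(fc > 0, r_min > 0, alpha > 0)
  lfc_min <- log2(fc)

  ev <- merge(dge_enriched, dge_suppressed, by = "gene",
              suffixes = c("_enriched", "_suppressed"), sort = FALSE)
  # correlation columns are cohort-level, identical in both screens
  ev$r_stroma <- ev$r_stroma_enriched
  ev$p_corr <- ev$p_corr_enriched
  ev$defined <- ev$defined_enriched

  ev <- ev[ev$gene %in% names(rl$roles) & ev$defined, , drop = FALSE]
  excl <- unique(unlist(exclude))
  ev <- ev[!ev$gene %in% excl, , drop = FALSE]

  up_enr <- ev$log2fc_enriched > lfc_min & ev$p_dge_enriched < alpha
  dn_enr <- ev$log2fc_enriched < -lfc_min & ev$p_dge_enriched < alpha
  up_sup <- ev$log2fc_suppressed > lfc_min & ev$p_dge_suppressed < alpha
  dn_sup <- ev$log2fc_suppressed < -lfc_min & ev$p_dge_suppressed < alpha
  pos <- ev$r_stroma > r_min & ev$p_corr < alpha
  neg <- ev$r_stroma < -r_min & ev$p_corr < alpha

  is_driver <- pos & (up_enr | dn_sup)
  is_suppressor <- neg & (up_sup | dn_enr)
  both <- is_driver & is_suppressor
  if (any(both)) {
    warning(sum(both), " gene(s) qualified as both driver and suppressor; dropped: ",
            paste(head(ev$gene[both], 5), collapse = ", "))
    is_driver[both] <- is_suppressor[both] <- FALSE
  }

  keep <- is_driver | is_suppressor
  out <- data.frame(
    gene = ev$gene[keep],
    class = ifelse(is_driver[keep], "driver", "suppressor"),
    role = unname(rl$roles[ev$gene[keep]]),
    log2fc_enriched = ev$log2fc_enriched[keep],
    p_enriched = ev$p_dge_enriched[keep],
    log2fc_suppressed = ev$log2fc_suppressed[keep],
    p_suppressed = ev$p_dge_suppressed[keep],
    r_stroma = ev$r_stroma[keep],
    p_corr = ev$p_corr[keep],
    up_in_enriched = up_enr[keep],
    down_in_suppressed = dn_sup[keep],
    up_in_suppressed = up_sup[keep],
    down_in_enriched = dn_enr[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter genes by single-cell expression prevalence
#'
#' Keeps genes with nonzero (normalised) expression in at least
#' \code{min_frac} of cells; the boundary is inclusive, so a gene detected
#' in exactly the threshold fraction is kept.
#'
#' @param genes character vector of candidate genes.
#' @param sc_mat single-cell expression matrix (genes x cells).
#' @param min_frac minimum detection fraction in \[0, 1\] (default 0.01,
#'   i.e. 1\% of cells).
#' @return the retained subset of \code{genes}; candidates absent from the
#'   matrix are dropped.
#' @export
filter_sc_expressed <- function(genes, sc_mat, min_frac = 0.01) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  present <- intersect(genes, rownames(sc_mat))
  frac <- rowMeans(sc_mat[present, , drop = FALSE] > 0)
  present[frac >= min_frac]
}
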