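#' Count expressed stroma-associates per cell
#'
#' For each cell, the number of associate genes with nonzero normalised
#' expression, split by receptor/ligand role (genes with role
#' \code{"both"} count towards both role tallies but once in the total).
#'
#' @param sc_mat single-cell expression matrix (genes x cells).
#' @param associates associate table from
#'   \code{\link{classify_associates}}, or a character vector of genes
#'   (then roles are unknown and only \code{n_total} is meaningful).
#' @return data.frame: \code{cell_id}, \code{n_ligands},
#'   \code{n_receptors}, \code{n_total}.
#' @export
count_associates <- function(sc_mat, associates) {
  if (is.data.frame(associates)) {
    genes <- associates$gene
    roles <- setNames(associates$role, associates$gene)
  } else {
    genes <- as.character(associates)
    roles <- setNames(rep(NA_character_, length(genes)), genes)
  }
  present <- intersect(genes, rownames(sc_mat))
  if (!length(present))
    stop("no associate gene present in the single-cell matrix")
  det <- sc_mat[present, , drop = FALSE] > 0
  is_lig <- roles[present] %in% c("ligand", "both")
  is_rec <- roles[present] %in% c("receptor", "both")
  data.frame(
    cell_id = colnames(sc_mat),
    n_ligands = as.integer(colSums(det[is_lig, , drop = FALSE])),
    n_receptors = as.integer(colSums(det[is_rec, , drop = FALSE])),
    n_total = as.integer(colSums(det)),
    stringsAsFactors = FALSE)
}

#' Classify cells as stroma-active, stroma-inactive or intermediate
#'
#' Strict cutoffs as published: a cell expressing more than
#' \code{active_min} associates is \code{"active"}, fewer than
#' \code{inactive_max} is \code{"inactive"}, anything else (including the
#' boundary counts themselves) is \code{"intermediate"}.  Defaults 5 and 2
#' follow the "> 5" / "< 2" driver-count convention.
#'
#' @param counts count table from \code{\link{count_associates}} or an
#'   integer vector of per-cell counts.
#' @param active_min strict lower cutoff for the active state.
#' @param inactive_max strict upper cutoff for the inactive state.
#' @param role which count column to classify on when \code{counts} is a
#'   table: \code{"total"}, \code{"ligands"} or \code{"receptors"}.
#' @return character vector of states, named by cell when available.
#' @export
classify_state <- function(counts, active_min = 5L, inactive_max = 2L,
                           role = c("total", "ligands", "receptors")) {
  role <- match.arg(role)
  if (inactive_max > active_min)
    stop("inactive_max must not exceed active_min")
  nm <- NULL
  if (is.data.frame(counts)) {
    nm <- counts$cell_id
    counts <- counts[[paste0("n_", if (role == "total") "total" else role)]]
  }
  state <- ifelse(counts > active_min, "active",
                  ifelse(counts < inactive_max, "inactive", "intermediate"))
  if (!is.null(nm)) names(state) <- nm
  state
}

#' Marker genes of stroma-active versus stroma-inactive cells
#'
#' Two-sided Wilcoxon rank-sum test per gene between active and inactive
#' cells, Benjamini-Hochberg adjusted across the tested genes.  Genes
#' detected in fewer than \code{min_frac} of cells in both states are not
#' tested.  Markers are the upregulated genes with adjusted p below
#' \code{alpha}.
#'
#' @param sc_mat single-cell expression matrix.
#' @param states per-cell state vector (named by cell, as returned by
#'   \code{\link{classify_state}}); only \code{"active"} and
#'   \code{"inactive"} cells are used.
#' @param min_frac detection-fraction floor below which a gene is skipped.
#' @param alpha adjusted-p cutoff defining \code{marker}.
#' @return data.frame: \code{gene}, \code{log2fc} (active minus inactive
#'   mean on the log scale), \code{p}, \code{p_adj}, \code{marker}
#'   (logical: upregulated with \code{p_adj < alpha}).  Untested genes are
#'   absent.
#' @export
find_markers <- function(sc_mat, states, min_frac = 0.01, alpha = 0.05) {
  if (is.null(names(states))) names(states) <- colnames(sc_mat)
  act <- names(states)[states == "active"]
  ina <- names(states)[states == "inactive"]
  if (length(act) < 3L || length(ina) < 3L)
    stop("need at least 3 cells in each of the active and inactive states (",
         length(act), " active, ", length(ina), " inactive)")
  a <- sc_mat[, act, drop = FALSE]
  b <- sc_mat[, ina, drop = FALSE]
  testable <- rowMeans(a > 0) >= min_frac | rowMeans(b > 0) >= min_frac
  genes <- rownames(sc_mat)[testable]
  p <- vapply(genes, function(g)
    suppressWarnings(wilcox.test(a[g, ], b[g, ], exact = FALSE)$p.value),
    numeric(1))
  p[is.nan(p)] <- 1   # identical tied samples
  lfc <- rowMeans(a[genes, , drop = FALSE]) - rowMeans(b[genes, , drop = FALSE])
  out <- data.frame(gene = genes, log2fc = unname(lfc), p = unname(p),
                    p_adj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$marker <- out$log2fc > 0 & out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Compare per-cell associate counts between metastatic and
#' non-metastatic tumours
#'
#' Wilcoxon rank-sum test on per-cell associate counts grouped by the
#' tumour-level metastasis flag.  Because cells of a tumour are not
#' independent, the per-tumour mean counts are reported alongside so the
#' pseudoreplication in the cell-level test is visible.
#'
#' @param counts count table from \code{\link{count_associates}}.
#' @param ann annotation with \code{sample_id} (cell), \code{tumour_id}
#'   and \code{metastasis}.
#' @param role count column to compare (as in
#'   \code{\link{classify_state}}).
#' @return list: \code{difference} (metastatic minus non-metastatic mean
#'   count), \code{p} (cell-level Wilcoxon), \code{per_tumour}
#'   (data.frame of per-tumour means with metastasis flag),
#'   \code{p_tumour} (Wilcoxon on per-tumour means).
#' @export
metastasis_contrast <- function(counts, ann,
                                role = c("total", "ligands", "receptors")) {
  role <- match.arg(role)
  col <- paste0("n_", if (role == "total") "total" else role)
  m <- match(counts$cell_id, ann$sample_id)
  if (anyNA(m)) stop("cells missing from annotation")
  met <- ann$metastasis[m]
  tum <- ann$tumour_id[m]
  if (!any(met, na.rm = TRUE) || !any(!met, na.rm = TRUE))
    stop("both metastatic and non-metastatic tumours are required")
  x <- counts[[col]]
  pt_means <- tapply(x, tum, mean)
  pt_met <- tapply(met, tum, function(z) z[1L])
  per_tumour <- data.frame(tumour_id = names(pt_means),
                           mean_count = as.numeric(pt_means),
                           metastasis = as.logical(pt_met),
                           stringsAsFactors = FALSE)
  cell_test <- suppressWarnings(wilcox.test(x[met], x[!met], exact = FALSE))
  tum_test <- if (sum(per_tumour$metastasis) >= 1 &&
                  sum(!per_tumour$metastasis) >= 1)
    suppressWarnings(wilcox.test(per_tumour$mean_count[per_tumour$metastasis],
                                 per_tumour$mean_count[!per_tumour$metastasis],
                                 exact = FALSE))$p.value
  else NA_real_
  list(difference = mean(x[met]) - mean(x[!met]),
       p = cell_test$p.value,
       per_tumour = per_tumour,
       p_tumour = tum_test)
}

#' Gene-counts developmental-potential score
#'
#' A simplified per-cell stemness proxy built from the number of
#' detectably expressed genes: the gene count \code{g_c} of each cell is
#' correlated (Pearson) against every gene's expression, the \code{top_k}
#' most positively correlated genes form the gene-counts signature, and
#' the per-cell mean expression of that signature is rank-transformed to
#' \[0, 1\] (1 = least differentiated).  The final rank step makes the
#' score invariant to monotone per-cell transforms that preserve
#' detection and signature ordering.  This omits the expression-similarity
#' smoothing of the full published pipeline and is validated only against
#' synthetic activity gradients.
#'
#' @param sc_mat single-cell expression matrix (genes x cells, >= 10
#'   cells).
#' @param top_k signature size (default 200).
#' @return named numeric vector of per-cell potential scores in \[0, 1\].
#' @export
dev_potential <- function(sc_mat, top_k = 200L) {
  ncell <- ncol(sc_mat)
  if (ncell < 10L) stop("need at least 10 cells")
  g_c <- colSums(sc_mat > 0)
  if (sd(g_c) == 0) stop("gene counts are constant across cells")
  r <- suppressWarnings(as.vector(cor(t(sc_mat), g_c)))
  r[is.na(r)] <- -Inf
  top_k <- min(as.integer(top_k), sum(is.finite(r)))
  sig_idx <- order(r, decreasing = TRUE)[seq_len(top_k)]
  sig_score <- colMeans(sc_mat[sig_idx, , drop = FALSE])
  pot <- (rank(sig_score, ties.method = "average") - 1) / (ncell - 1)
  setNames(pot, colnames(sc_mat))
}

#' Correlate developmental potential with stroma-associate counts
#'
#' Pearson correlation (with p-value) between the per-cell potential and
#' the per-cell associate count, plus a binned summary over the count
#' strata \code{< 2}, \code{2-5} and \code{> 5}.
#'
#' @param potential named per-cell potential vector
#'   (\code{\link{dev_potential}}).
#' @param counts count table (\code{\link{count_associates}}) or integer
#'   vector aligned to \code{potential}.
#' @param role count column (as in \code{\link{classify_state}}).
#' @return list: \code{r}, \code{p}, \code{bins} (data.frame \code{bin},
#'   \code{n}, \code{mean_potential}).
#' @export
potential_vs_activity <- function(potential, counts,
                                  role = c("total", "ligands", "receptors")) {
  role <- match.arg(role)
  if (is.data.frame(counts)) {
    x <- counts[[paste0("n_", if (role == "total") "total" else role)]]
    if (!is.null(names(potential)))
      x <- x[match(names(potential), counts$cell_id)]
  } else x <- counts
  if (length(x) != length(potential)) stop("potential and counts misaligned")
  if (length(x) < 3L) stop("need at least 3 cells")
  ct <- cor.test(potential, x)
  bin <- cut(x, breaks = c(-Inf, 1.5, 5.5, Inf),
             labels = c("<2", "2-5", ">5"))
  bins <- data.frame(bin = levels(bin),
                     n = as.integer(table(bin)),
                     mean_potential = as.numeric(tapply(potential, bin, mean)),
                     stringsAsFactors = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, bins = bins)
}
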