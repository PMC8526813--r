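#' Single-sample gene-set enrichment (ssGSEA-style) score
#'
#' For each sample independently, genes are ranked by expression (ties get
#' the average rank) and a running sum is walked down the ranking from the
#' most to the least expressed gene.  At each position the in-set increment
#' is the gene's rank statistic raised to \code{alpha}, normalised by the
#' total over all in-set genes; the out-of-set increment is a uniform step
#' \code{1 / (N - |S|)}.  The score is the sum over all positions of the
#' difference between the in-set and out-of-set cumulative fractions — the
#' unnormalised per-sample enrichment sum used by ESTIMATE's stromal and
#' immune scores.
#'
#' The score depends on the expression values only through their
#' within-sample ranks, so it is invariant under any rank-preserving
#' monotone transform and under gene reordering.
#'
#' @param mat expression matrix (genes x samples).
#' @param sig character vector of signature genes.
#' @param alpha rank-weight exponent; 0.25 is the ssGSEA/ESTIMATE
#'   convention, 0 gives the classic unweighted Kolmogorov-Smirnov walk.
#' @return named numeric vector, one enrichment score per sample.
#' @export
ssgsea_score <- function(mat, sig, alpha = 0.25) {
  n <- nrow(mat)
  in_set <- rownames(mat) %in% sig
  if (!any(in_set)) stop("no signature gene present in the matrix")
  if (all(in_set)) stop("signature covers every gene; out-of-set walk undefined")
  n_out <- n - sum(in_set)
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    r <- rank(mat[, j], ties.method = "average")   # high expression = high rank
    ord <- order(r, decreasing = TRUE)
    inw <- in_set[ord]
    w <- abs(r[ord])^alpha
    w[!inw] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inw) / n_out
    sum(p_in - p_out)
  }, numeric(1))
  setNames(scores, colnames(mat))
}

#' Scaled-average signature score
#'
#' Each gene is z-scored across samples (zero-variance genes get z = 0);
#' the score of a sample is the mean z of the signature genes minus the
#' mean z of all remaining genes.  This is the "scaled average expression
#' of genes within the signature minus the scaled average expression of
#' the remaining genes" construction used for stemness/cycling signatures.
#'
#' @inheritParams ssgsea_score
#' @return named numeric vector of per-sample scores.
#' @export
scaled_average_score <- function(mat, sig) {
  in_set <- rownames(mat) %in% sig
  if (!any(in_set)) stop("no signature gene present in the matrix")
  if (all(in_set)) stop("no non-signature genes present")
  mu <- rowMeans(mat)
  sdev <- apply(mat, 1L, sd)
  z <- (mat - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  setNames(colMeans(z[in_set, , drop = FALSE]) -
             colMeans(z[!in_set, , drop = FALSE]),
           colnames(mat))
}

#' Module meta-gene (first principal component of a gene module)
#'
#' The per-sample value of the first principal component of the module
#' submatrix (genes centred, not scaled), the standard module "eigengene"
#' summary of co-expression-module activity.  The PC sign is anchored so
#' that the meta-gene correlates non-negatively with the mean module
#' expression.
#'
#' @param mat expression matrix (genes x samples).
#' @param module_genes character vector of module member genes.
#' @return named numeric vector of per-sample meta-gene values.
#' @export
metagene <- function(mat, module_genes) {
  keep <- intersect(module_genes, rownames(mat))
  if (!length(keep)) stop("no module gene present in the matrix")
  x <- mat[keep, , drop = FALSE]
  xc <- x - rowMeans(x)
  if (all(abs(xc) < .Machine$double.eps * 100))
    stop("all module genes are constant; meta-gene undefined")
  sv <- La.svd(xc, nu = 0, nv = 1)
  pc1 <- drop(sv$vt[1L, ]) * sv$d[1L]
  m <- colMeans(x)
  if (sd(m) > 0 && cor(pc1, m) < 0) pc1 <- -pc1
  setNames(pc1, colnames(mat))
}

#' Score a matrix against multiple signatures
#'
#' Convenience wrapper producing a score table: one row per sample, one
#' column per signature.
#'
#' @param mat expression matrix.
#' @param sigs named list of gene sets.
#' @param method \code{"ssgsea"}, \code{"scaled"} or \code{"metagene"}.
#' @param alpha rank-weight exponent for \code{method = "ssgsea"}.
#' @return data.frame with \code{sample_id} and one numeric column per
#'   signature.
#' @export
score_table <- function(mat, sigs, method = c("ssgsea", "scaled", "metagene"),
                        alpha = 0.25) {
  method <- match.arg(method)
  f <- switch(method,
              ssgsea = function(s) ssgsea_score(mat, s, alpha = alpha),
              scaled = function(s) scaled_average_score(mat, s),
              metagene = function(s) metagene(mat, s))
  out <- data.frame(sample_id = colnames(mat), stringsAsFactors = FALSE)
  for (nm in names(sigs)) out[[nm]] <- unname(f(sigs[[nm]]))
  out
}
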