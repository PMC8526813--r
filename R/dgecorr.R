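#' Differential expression of one subgroup against the pooled remainder
#'
#' Per-gene log2 fold-change (target mean minus pooled-rest mean, computed
#' directly on the log2-scale matrix) and a two-sided Welch two-sample
#' t-test p-value.  Genes with zero variance in both groups and equal
#' means get p = 1; zero-variance genes with unequal means get p = 0 (the
#' separation is exact).
#'
#' @param mat expression matrix (genes x samples, log2 scale).
#' @param ann annotation data.frame with \code{sample_id} and
#'   \code{subgroup}; must cover the matrix columns.
#' @param target_subgroup subgroup compared against the pooled rest.
#' @param adjust apply Benjamini-Hochberg to the p-values in an extra
#'   \code{p_adj} column (off by default; the screen's published criterion
#'   is on unadjusted p).
#' @return data.frame: \code{gene}, \code{log2fc}, \code{p_dge},
#'   \code{direction} (\code{up}/\code{down} in the target).
#' @export
dge <- function(mat, ann, target_subgroup, adjust = FALSE) {
  idx <- match(colnames(mat), ann$sample_id)
  if (anyNA(idx))
    stop("samples missing from annotation: ",
         paste(head(colnames(mat)[is.na(idx)], 5), collapse = ", "))
  grp <- ann$subgroup[idx]
  if (!target_subgroup %in% grp) stop("target subgroup absent: ", target_subgroup)
  a <- mat[, grp == target_subgroup, drop = FALSE]
  b <- mat[, grp != target_subgroup, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (target ", n1, ", rest ", n2, ")")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1L)
  v2 <- rowSums((b - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  out <- data.frame(gene = rownames(mat), log2fc = m1 - m2, p_dge = p,
                    direction = ifelse(m1 - m2 >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- p.adjust(out$p_dge, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-gene Pearson correlation with the stromal score
#'
#' Correlates every gene's expression with a per-sample score (typically
#' the ssGSEA stromal score), reporting the Pearson r and its two-sided
#' t-distribution p-value.  Constant genes have undefined correlation and
#' are returned with \code{NA} and \code{defined = FALSE}; downstream
#' classification never treats them as associates.
#'
#' @param mat expression matrix.
#' @param scores either a named numeric vector or a score-table data.frame
#'   (see \code{\link{score_table}}); matched to matrix columns by label.
#' @param score_col column to use when \code{scores} is a data.frame.
#' @return data.frame: \code{gene}, \code{r_stroma}, \code{p_corr},
#'   \code{defined}.
#' @export
stroma_correlation <- function(mat, scores, score_col = "stromal") {
  if (is.data.frame(scores)) {
    if (!score_col %in% names(scores))
      stop("score column not found: ", score_col)
    scores <- setNames(scores[[score_col]], scores$sample_id)
  }
  unmatched <- setdiff(colnames(mat), names(scores))
  if (length(unmatched))
    stop("samples without scores: ", paste(head(unmatched, 5), collapse = ", "))
  s <- scores[colnames(mat)]
  n <- ncol(mat)
  if (n < 3L) stop("need at least 3 samples for a correlation p-value")
  sdev <- apply(mat, 1L, sd)
  r <- suppressWarnings(as.vector(cor(t(mat), s)))
  r[sdev == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  data.frame(gene = rownames(mat), r_stroma = r, p_corr = p,
             defined = !is.na(r), stringsAsFactors = FALSE)
}

#' Run the differential-expression + stroma-correlation screen
#'
#' Joins \code{\link{dge}} against a target subgroup with
#' \code{\link{stroma_correlation}} on the full cohort, the per-gene
#' evidence table feeding \code{\link{classify_associates}}.
#'
#' @inheritParams dge
#' @inheritParams stroma_correlation
#' @return data.frame with the columns of both screens.
#' @export
screen_subgroup <- function(mat, ann, target_subgroup, scores,
                            score_col = "stromal", adjust = FALSE) {
  d <- dge(mat, ann, target_subgroup, adjust = adjust)
  r <- stroma_correlation(mat, scores, score_col = score_col)
  merge(d, r, by = "gene", sort = FALSE)
}
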