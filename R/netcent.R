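#' Build a thresholded Pearson co-expression network
#'
#' All-pairs Pearson correlations among the given genes; an undirected
#' edge is kept when \code{|r| >= r_min} and its two-sided t-distribution
#' p-value is below \code{alpha}.  The correlation sign is retained as an
#' edge attribute (negative edges participate in the topology).  Constant
#' genes cannot be correlated and become isolated nodes.
#'
#' @param mat expression matrix (bulk or single-cell).
#' @param genes character vector of node genes, or an associate table from
#'   \code{\link{classify_associates}} (its \code{class}/\code{role}
#'   columns become node attributes).
#' @param r_min minimum absolute correlation for an edge (0.6 is the bulk
#'   convention, 0.2 the single-cell one).
#' @param alpha significance level for edges.
#' @return a \code{gene_network}: list with \code{nodes} (data.frame
#'   \code{gene}, \code{class}, \code{role}, \code{closeness}) and
#'   \code{edges} (data.frame \code{gene1}, \code{gene2}, \code{r},
#'   \code{p}, \code{sign}).
#' @export
build_network <- function(mat, genes, r_min = 0.6, alpha = 0.05) {
  attrs <- NULL
  if (is.data.frame(genes)) {
    attrs <- genes
    genes <- genes$gene
  }
  present <- intersect(genes, rownames(mat))
  if (length(present) < 2L)
    stop("need at least 2 node genes present in the matrix")
  x <- t(mat[present, , drop = FALSE])
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples to test correlations")
  sdev <- apply(x, 2L, sd)
  if (any(sdev == 0))
    message(sum(sdev == 0), " constant gene(s) kept as isolated nodes")
  r <- suppressWarnings(cor(x))
  r[is.na(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  keep <- upper.tri(r) & abs(r) >= r_min & p < alpha & sdev > 0 &
    rep(sdev > 0, each = length(sdev))
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene1 = present[idx[, 1L]], gene2 = present[idx[, 2L]],
                      r = r[keep], p = p[keep],
                      sign = ifelse(r[keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(gene = present, stringsAsFactors = FALSE)
  if (!is.null(attrs)) {
    m <- match(nodes$gene, attrs$gene)
    if ("class" %in% names(attrs)) nodes$class <- attrs$class[m]
    if ("role" %in% names(attrs)) nodes$role <- attrs$role[m]
  }
  net <- list(nodes = nodes, edges = edges, r_min = r_min, alpha = alpha)
  class(net) <- "gene_network"
  net$nodes$closeness <- closeness_centrality(net)
  net
}

as_igraph <- function(net, weighted = FALSE) {
  g <- igraph::graph_from_data_frame(net$edges[, c("gene1", "gene2")],
                                     directed = FALSE,
                                     vertices = net$nodes$gene)
  if (weighted && nrow(net$edges))
    igraph::E(g)$weight <- 1 - abs(net$edges$r)
  g
}

#' Closeness centrality with component scaling
#'
#' Shortest-path closeness on the thresholded graph, scaled for
#' disconnected graphs in the Wasserman-Faust way: for a node \code{v}
#' reaching \code{R} other nodes at total distance \code{D},
#' \code{closeness = (R / (n - 1)) * (R / D)}.  The value lies in
#' \[0, 1\], equals 1 only for a node adjacent to every other node of a
#' connected graph, and is 0 for isolates.  Distances are hop counts by
#' default; \code{weighted = TRUE} uses \code{1 - |r|} edge lengths
#' instead (the value is then not bounded by 1).
#'
#' @param net a \code{gene_network} from \code{\link{build_network}}.
#' @param weighted use correlation-derived edge lengths.
#' @return named numeric vector of per-node closeness values.
#' @export
closeness_centrality <- function(net, weighted = FALSE) {
  n <- nrow(net$nodes)
  if (n == 1L) return(setNames(0, net$nodes$gene))
  g <- as_igraph(net, weighted = weighted)
  d <- igraph::distances(g, weights = if (weighted) NULL else NA)
  vals <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (!length(reach)) return(0)
    (length(reach) / (n - 1)) * (length(reach) / sum(reach))
  }, numeric(1))
  setNames(vals, net$nodes$gene)
}

#' Export a network as an edge-list TSV
#' @param net gene network.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML with node attributes
#' @param net gene network.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::V(g)$closeness <- net$nodes$closeness
  if ("class" %in% names(net$nodes)) igraph::V(g)$class <- net$nodes$class
  if ("role" %in% names(net$nodes)) igraph::V(g)$role <- net$nodes$role
  if (nrow(net$edges)) {
    igraph::E(g)$r <- net$edges$r
    igraph::E(g)$p <- net$edges$p
    igraph::E(g)$sign <- net$edges$sign
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @exportS3Method base::print
print.gene_network <- function(x, ...) {
  cat("gene_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (|r| >=", x$r_min, ", p <", x$alpha, ")\n")
  invisible(x)
}
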