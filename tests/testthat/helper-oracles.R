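# Independent oracles used across test files.  Deliberately written as
# plain position-by-position loops / first-principles formulas so they share
# no code path with the package implementations they check.

# direct-summation enrichment score for one sample (named expression vector)
oracle_es <- function(x, sig, alpha) {
  n <- length(x)
  rk <- rank(x, ties.method = "average")
  ord <- order(rk, decreasing = TRUE)
  genes <- names(x)[ord]
  in_set <- genes %in% sig
  denom_in <- sum(rk[ord][in_set]^alpha)
  n_out <- n - sum(in_set)
  es <- 0; cum_in <- 0; cum_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cum_in <- cum_in + rk[ord][i]^alpha
    else cum_out <- cum_out + 1
    es <- es + cum_in / denom_in - cum_out / n_out
  }
  es
}

# breadth-first-search closeness with component scaling, from an edge list
oracle_closeness <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- edges$gene1[k]; b <- edges$gene2[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  n <- length(nodes)
  vapply(nodes, function(v) {
    dist <- setNames(rep(NA_real_, n), nodes)
    dist[v] <- 0
    queue <- v
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[cur]]) if (is.na(dist[w])) {
        dist[w] <- dist[cur] + 1
        queue <- c(queue, w)
      }
    }
    d <- dist[names(dist) != v]
    d <- d[!is.na(d)]
    if (!length(d)) return(0)
    (length(d) / (n - 1)) * (length(d) / sum(d))
  }, numeric(1))
}

# two-sided rank-sum p-value, normal approximation with tie correction and
# continuity correction
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie <- table(c(x, y))
  sig2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sig2 == 0) return(1)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5)
}

# build a gene_network object directly from an edge list (for centrality
# tests that need arbitrary topologies, bypassing correlation thresholding)
make_net <- function(nodes, edges = data.frame(gene1 = character(),
                                               gene2 = character())) {
  net <- list(nodes = data.frame(gene = nodes, stringsAsFactors = FALSE),
              edges = edges, r_min = NA, alpha = NA)
  class(net) <- "gene_network"
  net
}

# small labelled matrix with reproducible random content
rand_mat <- function(ng, ns, seed, scale_tag = "bulk-log2") {
  set.seed(seed)
  expression_matrix(matrix(rnorm(ng * ns), nrow = ng,
                           dimnames = list(sprintf("g%03d", seq_len(ng)),
                                           sprintf("s%03d", seq_len(ns)))),
                    scale_tag = scale_tag)
}

# annotation table reproducing the discovery cohort's printed composition:
# subgroup sizes 144/326/223/70 and per-subgroup metastasis annotation
# 43/109, 101/255, 26/160, 6/49 (NA beyond the annotated denominators)
demo_annotation <- function() {
  blocks <- list(
    c("Group3", 144, 109, 43), c("Group4", 326, 255, 101),
    c("SHH", 223, 160, 26), c("WNT", 70, 49, 6))
  do.call(rbind, lapply(blocks, function(b) {
    n <- as.integer(b[2]); ann <- as.integer(b[3]); met <- as.integer(b[4])
    data.frame(
      sample_id = paste0(b[1], "_", seq_len(n)),
      subgroup = b[1],
      metastasis = c(rep(TRUE, met), rep(FALSE, ann - met), rep(NA, n - ann)),
      stringsAsFactors = FALSE)
  }))
}
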