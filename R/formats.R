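#' Construct a validated expression matrix
#'
#' An expression matrix is an ordinary numeric \code{matrix} with genes as
#' rows and samples (or cells) as columns, unique dimnames, and a
#' \code{"scale_tag"} attribute recording the scale the values live on:
#' \code{"bulk-log2"} for log2-transformed array/bulk data or
#' \code{"sc-lognorm"} for library-size-normalised, log-transformed
#' single-cell data.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids optional dimname overrides.
#' @param scale_tag one of \code{"bulk-log2"}, \code{"sc-lognorm"}.
#' @param allow_na permit NA values (default FALSE).
#' @return the validated matrix with \code{scale_tag} attribute.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale_tag = c("bulk-log2", "sc-lognorm"),
                              allow_na = FALSE) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimnames length does not match matrix dimensions")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(head(dup_g, 5), collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(head(dup_s, 5), collapse = ", "))
  if (!allow_na && anyNA(values))
    stop("matrix contains NA values (set allow_na = TRUE to permit)")
  if (any(is.infinite(values)))
    stop("matrix contains non-finite values")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  attr(values, "scale_tag") <- scale_tag
  values
}

#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV: tab-delimited with a header row of sample identifiers and gene
#' identifiers in the first column.  MatrixMarket (\code{format = "mtx"}):
#' the coordinate file plus \code{features.tsv} and \code{barcodes.tsv}
#' sidecars in the same directory (first column of each used as labels).
#' Genes are rows in both dialects.
#'
#' @param path path to the \code{.tsv} or \code{.mtx} file.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param scale_tag scale annotation to attach (see
#'   \code{\link{expression_matrix}}).
#' @return expression matrix.
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"),
                        scale_tag = c("bulk-log2", "sc-lognorm")) {
  format <- match.arg(format)
  scale_tag <- match.arg(scale_tag)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    expression_matrix(m, gene_ids = genes, sample_ids = colnames(df)[-1L],
                      scale_tag = scale_tag)
  } else {
    dir <- dirname(path)
    feat <- file.path(dir, "features.tsv")
    barc <- file.path(dir, "barcodes.tsv")
    if (!file.exists(feat) || !file.exists(barc))
      stop("mtx sidecars missing: need features.tsv and barcodes.tsv next to ", path)
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double"   # pattern matrices read back as logical
    genes <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    cells <- read.delim(barc, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("mtx dimensions (", nrow(m), "x", ncol(m),
           ") do not match sidecars (", length(genes), " features, ",
           length(cells), " barcodes)")
    expression_matrix(m, gene_ids = genes, sample_ids = cells,
                      scale_tag = scale_tag)
  }
}

#' Write an expression matrix
#'
#' @param mat expression matrix.
#' @param path output path; for \code{"mtx"} the sidecar files
#'   \code{features.tsv}/\code{barcodes.tsv} are written alongside.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(mat, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(mat), file.path(dir, "features.tsv"))
    writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Broad dialect: one set per line, \code{name TAB description TAB gene...}.
#' Duplicate genes within a line are collapsed with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors (one element per signature).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(setNames(list(), character()))
  sigs <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- f[-c(1L, 2L)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " (", f[1L], "): duplicate genes collapsed")
      genes <- unique(genes)
    }
    if (!length(genes)) stop("GMT line ", i, " (", f[1L], "): empty gene set")
    nms[i] <- f[1L]
    sigs[[i]] <- genes
  }
  setNames(sigs, nms)
}

#' Write gene signatures to a GMT file
#'
#' @param sigs named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sigs, path, description = "na") {
  description <- rep_len(description, length(sigs))
  lines <- vapply(seq_along(sigs), function(i)
    paste(c(names(sigs)[i], description[i], sigs[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a receptor-ligand pair table
#'
#' Two-column tab-delimited file (ligand, receptor), FANTOM5 style, with an
#' optional header.  Duplicate pairs are collapsed; self-pairs are dropped
#' with a warning.  The role index assigns \code{"both"} to genes appearing
#' in both columns.
#'
#' @param path TSV file.
#' @return list with \code{pairs} (data.frame \code{ligand}, \code{receptor})
#'   and \code{roles} (named character vector:
#'   \code{ligand}/\code{receptor}/\code{both}).
#' @export
read_rl_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("ligand", "receptor"))
  # tolerate a header row
  if (nrow(df) && tolower(df$ligand[1L]) %in% c("ligand", "ligand_gene"))
    df <- df[-1L, , drop = FALSE]
  rl_table(df$ligand, df$receptor)
}

#' Construct a receptor-ligand table from vectors
#'
#' @param ligand,receptor character vectors of equal length.
#' @return see \code{\link{read_rl_pairs}}.
#' @export
rl_table <- function(ligand, receptor) {
  stopifnot(length(ligand) == length(receptor))
  ligand <- as.character(ligand); receptor <- as.character(receptor)
  self <- ligand == receptor
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped: ",
            paste(head(unique(ligand[self]), 5), collapse = ", "))
    ligand <- ligand[!self]; receptor <- receptor[!self]
  }
  pairs <- unique(data.frame(ligand = ligand, receptor = receptor,
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  genes <- unique(c(pairs$ligand, pairs$receptor))
  roles <- setNames(ifelse(genes %in% pairs$ligand & genes %in% pairs$receptor,
                           "both",
                    ifelse(genes %in% pairs$ligand, "ligand", "receptor")),
                    genes)
  list(pairs = pairs, roles = roles)
}

#' Write a receptor-ligand table
#' @param rl receptor-ligand table.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
write_rl_pairs <- function(rl, path) {
  write.table(rl$pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample/cell annotation table
#'
#' Tab-delimited with a header; must contain \code{sample_id} and
#' \code{subgroup} columns; \code{subtype}, \code{tumour_id} and
#' \code{metastasis} (logical or 0/1) are recognised when present.
#'
#' @param path TSV file.
#' @return data.frame keyed by \code{sample_id}.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "subgroup") %in% names(ann)))
    stop("annotation must contain sample_id and subgroup columns")
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id values in annotation")
  if ("metastasis" %in% names(ann) && !is.logical(ann$metastasis))
    ann$metastasis <- as.logical(as.integer(ann$metastasis))
  ann
}

# round half-up to `digits` decimals (base round() is banker's rounding)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize a cohort annotation table
#'
#' Counts and percentages per molecular subgroup, metastasis rates overall
#' and per subgroup (denominators exclude samples with missing metastasis
#' status), and per-tumour cell counts when \code{tumour_id} is present.
#' Percentages are \code{100 * count / denominator} rounded half-up to one
#' decimal.
#'
#' @param ann annotation data.frame with at least a \code{subgroup} column.
#' @return list with data.frames \code{subgroups} (\code{subgroup},
#'   \code{n}, \code{pct}), optionally \code{metastasis} (overall +
#'   per-subgroup rates) and \code{tumours} (per-tumour cell counts with
#'   mean and range).
#' @export
summarize_cohort <- function(ann) {
  if (!"subgroup" %in% names(ann)) stop("annotation lacks a subgroup column")
  n_total <- nrow(ann)
  tab <- table(ann$subgroup)
  subgroups <- data.frame(
    subgroup = names(tab),
    n = as.integer(tab),
    pct = round_half_up(100 * as.integer(tab) / n_total, 1),
    stringsAsFactors = FALSE)
  out <- list(subgroups = subgroups, n_total = n_total)

  if ("metastasis" %in% names(ann) && any(!is.na(ann$metastasis))) {
    known <- ann[!is.na(ann$metastasis), , drop = FALSE]
    overall <- data.frame(subgroup = "all",
                          n_annotated = nrow(known),
                          n_metastatic = sum(known$metastasis),
                          stringsAsFactors = FALSE)
    per <- do.call(rbind, lapply(split(known, known$subgroup), function(d)
      data.frame(subgroup = d$subgroup[1L], n_annotated = nrow(d),
                 n_metastatic = sum(d$metastasis), stringsAsFactors = FALSE)))
    met <- rbind(overall, per)
    met$pct <- round_half_up(100 * met$n_metastatic / met$n_annotated, 1)
    rownames(met) <- NULL
    out$metastasis <- met
  }

  if ("tumour_id" %in% names(ann) && any(!is.na(ann$tumour_id))) {
    ct <- table(ann$tumour_id)
    out$tumours <- data.frame(tumour_id = names(ct), n_cells = as.integer(ct),
                              stringsAsFactors = FALSE)
    out$cells_per_tumour <- c(mean = mean(as.integer(ct)),
                              min = min(as.integer(ct)),
                              max = max(as.integer(ct)))
  }
  out
}
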