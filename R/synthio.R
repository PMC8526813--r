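#' Configuration for the synthetic bulk cohort generator
#'
#' The generator emulates a multi-subgroup bulk expression cohort on the
#' log2 scale: each sample carries a latent stromal fraction drawn from a
#' subgroup-specific Beta distribution (the stroma-enriched subgroup gets a
#' high-mean Beta, the stroma-suppressed subgroup a low-mean one), stromal
#' and immune signature genes track their latent fraction linearly, and a
#' set of planted receptor/ligand "driver" genes is both shifted in the
#' enriched subgroup and coupled to the stromal fraction.
#'
#' @param n_genes total gene universe size.
#' @param n_samples number of samples.
#' @param subgroup_props named fractions per subgroup, summing to 1.
#' @param stroma_beta_params named list of \code{c(a, b)} Beta shape pairs,
#'   one per subgroup, for the latent stromal fraction.
#' @param n_signature_genes genes per signature (stromal and immune each).
#' @param n_driver_genes planted receptor/ligand drivers (up in
#'   \code{driver_subgroup} and stroma-coupled).
#' @param n_rl_background receptor/ligand genes with no planted effect
#'   (the false-positive pool for the downstream classifier).
#' @param driver_subgroup subgroup in which drivers are upregulated.
#' @param driver_log2fc planted shift, log2 units.
#' @param driver_stroma_coupling slope (log2 units per unit stromal
#'   fraction) tying driver expression to the latent fraction.
#' @param signature_coupling slope for signature genes on their latent
#'   fraction.
#' @param noise_sd residual SD on the log2 scale.
#' @param seed integer seed; all draws flow from it.
#' @return a \code{bulk_sim_config} list.
#' @export
bulk_sim_config <- function(n_genes = 2000L,
                            n_samples = 200L,
                            subgroup_props = c(WNT = 0.092, SHH = 0.292,
                                               Group3 = 0.188, Group4 = 0.428),
                            stroma_beta_params = list(
                              WNT = c(3, 5), SHH = c(6, 3),
                              Group3 = c(2, 7), Group4 = c(3, 5)),
                            n_signature_genes = 100L,
                            n_driver_genes = 30L,
                            n_rl_background = 60L,
                            driver_subgroup = "SHH",
                            driver_log2fc = 1.5,
                            driver_stroma_coupling = 3,
                            signature_coupling = 2,
                            noise_sd = 1,
                            seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              subgroup_props = subgroup_props,
              stroma_beta_params = stroma_beta_params,
              n_signature_genes = as.integer(n_signature_genes),
              n_driver_genes = as.integer(n_driver_genes),
              n_rl_background = as.integer(n_rl_background),
              driver_subgroup = driver_subgroup,
              driver_log2fc = driver_log2fc,
              driver_stroma_coupling = driver_stroma_coupling,
              signature_coupling = signature_coupling,
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_bulk_config(cfg)
  cfg
}

validate_bulk_config <- function(cfg) {
  if (abs(sum(cfg$subgroup_props) - 1) > 1e-9)
    stop("subgroup_props must sum to 1")
  if (is.null(names(cfg$subgroup_props)) || any(!nzchar(names(cfg$subgroup_props))))
    stop("subgroup_props must be named")
  if (any(cfg$subgroup_props < 0)) stop("subgroup_props must be non-negative")
  if (!all(names(cfg$subgroup_props) %in% names(cfg$stroma_beta_params)))
    stop("stroma_beta_params must cover every subgroup")
  counts <- c(cfg$n_genes, cfg$n_samples, cfg$n_signature_genes,
              cfg$n_driver_genes)
  if (any(counts <= 0L)) stop("all counts must be positive")
  if (2L * cfg$n_signature_genes + cfg$n_driver_genes + cfg$n_rl_background >=
      cfg$n_genes)
    stop("signature + driver + receptor/ligand genes must be fewer than n_genes")
  if (!cfg$driver_subgroup %in% names(cfg$subgroup_props))
    stop("driver_subgroup not among subgroup_props names")
  invisible(cfg)
}

gene_universe <- function(n) sprintf("gene_%05d", seq_len(n))

#' Generate a synthetic bulk cohort
#'
#' See \code{\link{bulk_sim_config}} for the generative model.  Gene roles
#' are assigned from the front of the universe: stromal signature, immune
#' signature, planted drivers, background receptor/ligand genes, then
#' unstructured background.  Planted drivers and background
#' receptor/ligand genes are paired into a ligand-receptor table
#' (alternating roles) so the downstream classifier can be run as-is.
#'
#' @param config a \code{\link{bulk_sim_config}}.
#' @return list with \code{matrix} (log2 expression), \code{annotation}
#'   (\code{sample_id}, \code{subgroup}), \code{signatures} (named list:
#'   \code{stromal}, \code{immune}), \code{rl} (receptor-ligand table) and
#'   \code{truth} (planted drivers, latent stromal/immune fractions,
#'   role assignment per gene).
#' @export
generate_bulk <- function(config = bulk_sim_config()) {
  validate_bulk_config(config)
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples
  genes <- gene_universe(ng)
  samples <- sprintf("sample_%04d", seq_len(ns))

  subgroups <- sample(names(config$subgroup_props), ns, replace = TRUE,
                      prob = config$subgroup_props)
  s <- numeric(ns)   # latent stromal fraction
  u <- numeric(ns)   # latent immune fraction (independent)
  for (g in unique(subgroups)) {
    idx <- which(subgroups == g)
    ab <- config$stroma_beta_params[[g]]
    s[idx] <- rbeta(length(idx), ab[1L], ab[2L])
  }
  u <- rbeta(ns, 3, 3)

  nsig <- config$n_signature_genes
  nd <- config$n_driver_genes
  nbg <- config$n_rl_background
  role <- rep("background", ng)
  role[seq_len(nsig)] <- "stromal_signature"
  role[nsig + seq_len(nsig)] <- "immune_signature"
  role[2L * nsig + seq_len(nd)] <- "driver"
  role[2L * nsig + nd + seq_len(nbg)] <- "rl_background"

  baseline <- rnorm(ng, mean = 7, sd = 1.5)
  mat <- matrix(rnorm(ng * ns, sd = config$noise_sd), nrow = ng) + baseline
  dimnames(mat) <- list(genes, samples)

  bsig <- config$signature_coupling
  mat[role == "stromal_signature", ] <-
    mat[role == "stromal_signature", , drop = FALSE] +
    rep(bsig * s, each = nsig)
  mat[role == "immune_signature", ] <-
    mat[role == "immune_signature", , drop = FALSE] +
    rep(bsig * u, each = nsig)
  in_target <- as.numeric(subgroups == config$driver_subgroup)
  driver_shift <- config$driver_log2fc * in_target +
    config$driver_stroma_coupling * (s - mean(s))
  mat[role == "driver", ] <-
    mat[role == "driver", , drop = FALSE] + rep(driver_shift, each = nd)

  rl_genes <- genes[role %in% c("driver", "rl_background")]
  # alternate ligand/receptor roles, then pair ligands with receptors
  lig <- rl_genes[seq_along(rl_genes) %% 2L == 1L]
  rec <- rl_genes[seq_along(rl_genes) %% 2L == 0L]
  npair <- max(length(lig), length(rec))
  rl <- rl_table(lig[((seq_len(npair) - 1L) %% length(lig)) + 1L],
                 rec[((seq_len(npair) - 1L) %% length(rec)) + 1L])

  ann <- data.frame(sample_id = samples, subgroup = subgroups,
                    stringsAsFactors = FALSE)
  list(
    matrix = expression_matrix(mat, scale_tag = "bulk-log2"),
    annotation = ann,
    signatures = list(stromal = genes[role == "stromal_signature"],
                      immune = genes[role == "immune_signature"]),
    rl = rl,
    truth = list(drivers = genes[role == "driver"],
                 rl_background = genes[role == "rl_background"],
                 stromal_fraction = setNames(s, samples),
                 immune_fraction = setNames(u, samples),
                 gene_role = setNames(role, genes),
                 config = config))
}

#' Configuration for the synthetic single-cell generator
#'
#' Emulates per-tumour single-cell data carrying a latent stroma-activity
#' gradient in \[0, 1\]: each tumour draws a mean activity (metastatic
#' tumours from a higher range), each cell draws its activity around that
#' mean, stroma-associate genes are detected with a probability that rises
#' logistically with activity, and the detection rate of every other gene
#' also rises with activity so that total detected-gene counts (the
#' developmental-potential proxy) track the gradient.  Detected counts are
#' negative-binomial, then library-size normalised and log-transformed.
#'
#' @param n_genes gene universe size.
#' @param n_tumours number of tumours.
#' @param cells_per_tumour length-2 range; per-tumour cell counts drawn
#'   uniformly in it (a single value fixes the count).
#' @param activity_concentration Beta concentration for per-cell activity
#'   around the tumour mean.
#' @param activity_mean_range,activity_mean_range_met Uniform ranges for
#'   the per-tumour mean activity (non-metastatic / metastatic).
#' @param detection_coupling logistic slope: associate gene detected with
#'   probability \code{plogis(detection_coupling * (a - 0.5))}.
#' @param potential_coupling logit shift per unit activity applied to every
#'   non-associate gene's baseline detection rate.
#' @param metastatic_tumours integer indices of metastatic tumours.
#' @param nb_size negative-binomial dispersion for detected counts.
#' @param seed integer seed.
#' @return an \code{sc_sim_config} list.
#' @export
sc_sim_config <- function(n_genes = 2000L,
                          n_tumours = 10L,
                          cells_per_tumour = c(300L, 300L),
                          activity_concentration = 8,
                          activity_mean_range = c(0.25, 0.5),
                          activity_mean_range_met = c(0.5, 0.75),
                          detection_coupling = 6,
                          potential_coupling = 2,
                          metastatic_tumours = seq_len(max(1L, n_tumours %/% 2L)),
                          nb_size = 2,
                          seed = 1L) {
  if (length(cells_per_tumour) == 1L)
    cells_per_tumour <- rep(cells_per_tumour, 2L)
  cfg <- list(n_genes = as.integer(n_genes), n_tumours = as.integer(n_tumours),
              cells_per_tumour = as.integer(cells_per_tumour),
              activity_concentration = activity_concentration,
              activity_mean_range = activity_mean_range,
              activity_mean_range_met = activity_mean_range_met,
              detection_coupling = detection_coupling,
              potential_coupling = potential_coupling,
              metastatic_tumours = as.integer(metastatic_tumours),
              nb_size = nb_size, seed = as.integer(seed))
  if (any(cfg$cells_per_tumour <= 0L)) stop("cells_per_tumour must be positive")
  if (cfg$cells_per_tumour[1L] > cfg$cells_per_tumour[2L])
    stop("cells_per_tumour range must be non-decreasing")
  if (cfg$n_genes <= 0L || cfg$n_tumours <= 0L) stop("counts must be positive")
  if (length(cfg$metastatic_tumours) &&
      any(cfg$metastatic_tumours < 1L | cfg$metastatic_tumours > cfg$n_tumours))
    stop("metastatic_tumours out of range")
  cfg
}

#' Generate a synthetic single-cell cohort
#'
#' See \code{\link{sc_sim_config}} for the generative model.
#'
#' @param config an \code{\link{sc_sim_config}}.
#' @param associate_genes character vector of stroma-associate genes; must
#'   be a subset of the gene universe \code{gene_00001...}.
#' @return list with \code{matrix} (log-normalised expression, genes x
#'   cells), \code{annotation} (\code{sample_id}, \code{subgroup},
#'   \code{tumour_id}, \code{metastasis}) and \code{truth}
#'   (per-cell latent \code{activity}, per-tumour means, config).
#' @export
generate_sc <- function(config = sc_sim_config(),
                        associate_genes = gene_universe(config$n_genes)[1:30]) {
  set.seed(config$seed)
  genes <- gene_universe(config$n_genes)
  missing <- setdiff(associate_genes, genes)
  if (length(missing))
    stop("associate genes not in universe: ", paste(head(missing, 5), collapse = ", "))
  nt <- config$n_tumours
  met <- seq_len(nt) %in% config$metastatic_tumours
  ncells_t <- if (config$cells_per_tumour[1L] == config$cells_per_tumour[2L])
    rep(config$cells_per_tumour[1L], nt)
  else
    sample(seq(config$cells_per_tumour[1L], config$cells_per_tumour[2L]),
           nt, replace = TRUE)

  mean_t <- numeric(nt)
  for (t in seq_len(nt)) {
    rng <- if (met[t]) config$activity_mean_range_met else config$activity_mean_range
    mean_t[t] <- runif(1, rng[1L], rng[2L])
  }
  k <- config$activity_concentration
  tumour_id <- rep(sprintf("T%02d", seq_len(nt)), ncells_t)
  activity <- unlist(lapply(seq_len(nt), function(t)
    rbeta(ncells_t[t], mean_t[t] * k, (1 - mean_t[t]) * k)))
  ncell <- length(activity)
  cells <- sprintf("cell_%05d", seq_len(ncell))

  is_assoc <- genes %in% associate_genes
  # gene-specific baseline detection rate (logit scale) and NB mean
  base_logit <- qlogis(pmin(pmax(rbeta(length(genes), 1.5, 3), 1e-3), 1 - 1e-3))
  mu <- exp(rnorm(length(genes), mean = 1, sd = 0.8))

  p <- matrix(0, nrow = length(genes), ncol = ncell)
  p[is_assoc, ] <- plogis(config$detection_coupling *
                            rep(activity - 0.5, each = sum(is_assoc)))
  p[!is_assoc, ] <- plogis(base_logit[!is_assoc] +
                             config$potential_coupling *
                               rep(activity - 0.5, each = sum(!is_assoc)))
  detected <- matrix(rbinom(length(p), 1L, p), nrow = nrow(p))
  counts <- matrix(0, nrow = length(genes), ncol = ncell)
  nz <- which(detected == 1L)
  counts[nz] <- 1L + rnbinom(length(nz), size = config$nb_size,
                             mu = mu[(nz - 1L) %% length(genes) + 1L])
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  norm <- log1p(sweep(counts, 2L, 1e4 / lib, `*`))
  dimnames(norm) <- list(genes, cells)

  ann <- data.frame(sample_id = cells, subgroup = "SHH",
                    tumour_id = tumour_id,
                    metastasis = rep(met, ncells_t),
                    stringsAsFactors = FALSE)
  list(matrix = expression_matrix(norm, scale_tag = "sc-lognorm"),
       annotation = ann,
       truth = list(activity = setNames(activity, cells),
                    tumour_mean_activity = setNames(mean_t, sprintf("T%02d", seq_len(nt))),
                    metastatic = setNames(met, sprintf("T%02d", seq_len(nt))),
                    associate_genes = associate_genes,
                    config = config))
}
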