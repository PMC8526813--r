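toy_assoc <- data.frame(
  gene = c("L1", "L2", "R1", "R2", "B1"),
  class = "driver",
  role = c("ligand", "ligand", "receptor", "receptor", "both"),
  stringsAsFactors = FALSE)

toy_sc <- function(vals) {
  expression_matrix(vals, scale_tag = "sc-lognorm")
}

test_that("associate counts per cell match a brute-force scan", {
  set.seed(66)
  vals <- matrix(rbinom(5 * 20, 1, 0.4) * runif(100, 0.5, 2), nrow = 5,
                 dimnames = list(toy_assoc$gene, paste0("c", 1:20)))
  vals[, 1] <- 0            # all-zero cell
  vals[, 2] <- 1            # cell expressing everything
  cnt <- count_associates(toy_sc(vals), toy_assoc)
  expect_equal(cnt$n_total[1], 0L)
  expect_equal(cnt$n_ligands[1], 0L)
  expect_equal(cnt$n_total[2], 5L)
  expect_equal(cnt$n_ligands[2], 3L)    # two ligands + the dual-role gene
  expect_equal(cnt$n_receptors[2], 3L)
  for (j in seq_len(ncol(vals))) {      # brute-force per-cell scan
    expect_equal(cnt$n_total[j], sum(vals[, j] > 0))
    expect_equal(cnt$n_ligands[j], sum(vals[c("L1", "L2", "B1"), j] > 0))
  }
  expect_error(count_associates(toy_sc(vals), data.frame(gene = "absent",
                                                         role = "ligand")),
               "no associate gene")
})

test_that("state cutoffs are strict exactly as worded", {
  counts <- c(c1 = 6, c2 = 1, c3 = 5, c4 = 2, c5 = 0, c6 = 30)
  st <- classify_state(counts, active_min = 5, inactive_max = 2)
  expect_equal(unname(st[c("c1", "c6")]), c("active", "active"))    # > 5
  expect_equal(unname(st[c("c2", "c5")]), c("inactive", "inactive")) # < 2
  expect_equal(unname(st[c("c3", "c4")]), rep("intermediate", 2))   # 5 and 2
  expect_equal(length(st), 6L)                    # states partition the cells
  expect_error(classify_state(counts, active_min = 2, inactive_max = 5),
               "must not exceed")
})

test_that("marker detection agrees with an independent rank-sum oracle", {
  set.seed(77)
  n_each <- 30
  ng <- 40
  vals <- matrix(rpois(ng * 2 * n_each, 2) * 0.5, nrow = ng,
                 dimnames = list(sprintf("g%02d", 1:ng),
                                 paste0("c", 1:(2 * n_each))))
  shift <- 1:5                               # planted active-state markers
  vals[shift, 1:n_each] <- vals[shift, 1:n_each] + 3
  m <- toy_sc(vals)
  states <- setNames(rep(c("active", "inactive"), each = n_each), colnames(vals))
  mk <- find_markers(m, states)
  # oracle: first-principles rank-sum p per gene + BH, marker = up & q<0.05
  p_or <- vapply(rownames(vals), function(g)
    oracle_ranksum_p(vals[g, 1:n_each], vals[g, (n_each + 1):(2 * n_each)]),
    numeric(1))
  up <- rowMeans(vals[, 1:n_each]) > rowMeans(vals[, (n_each + 1):(2 * n_each)])
  q_or <- p.adjust(p_or[rownames(vals) %in% mk$gene], method = "BH")
  want <- names(q_or)[q_or < 0.05 & up[names(q_or)]]
  expect_setequal(mk$gene[mk$marker], want)
  expect_true(all(sprintf("g%02d", shift) %in% mk$gene[mk$marker]))
})

test_that("identical state distributions yield no markers; separation forces one", {
  set.seed(78)
  base <- matrix(rpois(20 * 50, 1), nrow = 20,
                 dimnames = list(paste0("g", 1:20), NULL))
  vals <- cbind(base, base)
  colnames(vals) <- paste0("c", 1:100)
  states <- setNames(rep(c("active", "inactive"), each = 50), colnames(vals))
  mk <- find_markers(toy_sc(vals), states)
  expect_equal(sum(mk$marker), 0L)

  vals["g1", 1:50] <- 5; vals["g1", 51:100] <- 0
  mk <- find_markers(toy_sc(vals), states)
  expect_true(mk$marker[mk$gene == "g1"])

  expect_error(find_markers(toy_sc(vals), setNames(rep("active", 100),
                                                   colnames(vals))),
               "at least 3 cells")
})

test_that("shuffled state labels produce markers at the false-positive rate", {
  set.seed(79)
  vals <- matrix(rpois(200 * 60, 2) * 0.7, nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), paste0("c", 1:60)))
  states <- setNames(sample(rep(c("active", "inactive"), each = 30)),
                     colnames(vals))
  mk <- find_markers(toy_sc(vals), states)
  # BH at q<0.05 under the global null: essentially no discoveries expected
  expect_lte(sum(mk$marker), 2L)
})

test_that("metastasis contrast detects a planted shift and reports per-tumour means", {
  cells <- paste0("c", 1:120)
  ann <- data.frame(sample_id = cells,
                    subgroup = "SHH",
                    tumour_id = rep(paste0("T", 1:6), each = 20),
                    metastasis = rep(c(TRUE, FALSE), each = 60),
                    stringsAsFactors = FALSE)
  set.seed(88)
  base <- rpois(120, 3)
  counts <- data.frame(cell_id = cells, n_ligands = 0L, n_receptors = 0L,
                       n_total = base, stringsAsFactors = FALSE)
  res <- metastasis_contrast(counts, ann)
  expect_gt(res$p, 0.05)
  expect_lt(abs(res$difference), 1)

  counts$n_total <- base + rep(c(3L, 0L), each = 60)
  res <- metastasis_contrast(counts, ann)
  expect_lt(res$p, 0.05)
  expect_gt(res$difference, 0)
  expect_equal(nrow(res$per_tumour), 6L)
  expect_equal(sum(res$per_tumour$metastasis), 3L)

  ann$metastasis <- TRUE
  expect_error(metastasis_contrast(counts, ann), "both metastatic")
})

test_that("developmental potential is monotone on a nested detection chain", {
  ng <- 30; nc <- 12
  vals <- matrix(0, ng, nc, dimnames = list(paste0("g", 1:ng), paste0("c", 1:nc)))
  for (j in seq_len(nc)) vals[seq_len(2 * j), j] <- 1   # strict superset chain
  pot <- dev_potential(toy_sc(vals), top_k = 25)  # capped to correlatable genes
  expect_true(all(diff(pot) > 0))
  expect_equal(unname(range(pot)), c(0, 1))

  flat <- toy_sc(matrix(1, 4, 12, dimnames = list(paste0("g", 1:4),
                                                  paste0("c", 1:12))))
  expect_error(dev_potential(flat), "constant")
  expect_error(dev_potential(toy_sc(vals[, 1:5, drop = FALSE])), "10 cells")
})

test_that("potential is invariant to detection-preserving monotone transforms", {
  set.seed(91)
  vals <- matrix(rpois(50 * 40, 1) * runif(2000, 0.5, 1.5), nrow = 50,
                 dimnames = list(paste0("g", 1:50), paste0("c", 1:40)))
  m <- toy_sc(vals)
  pot <- dev_potential(m, top_k = 15)
  # global positive rescaling preserves detection, all correlations and the
  # per-cell signature ranking, so the rank-based score is unchanged
  pot2 <- dev_potential(toy_sc(vals * 7), top_k = 15)
  expect_equal(pot, pot2, tolerance = 1e-12)
})

test_that("potential-versus-activity reports correlation and count bins", {
  set.seed(92)
  x <- rpois(100, 4)
  pot <- (rank(x, ties.method = "average") - 1) / 99
  res <- potential_vs_activity(pot, x)
  expect_gt(res$r, 0.95)
  expect_lt(res$p, 1e-10)
  expect_equal(res$bins$bin, c("<2", "2-5", ">5"))
  expect_equal(sum(res$bins$n), 100L)

  res_null <- potential_vs_activity(runif(100), rpois(100, 4))
  expect_lt(abs(res_null$r), 0.3)
  expect_error(potential_vs_activity(pot[1:2], x[1:2]), "at least 3")
})
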