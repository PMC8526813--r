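# hand-built evidence tables with the screen's column contract
ev_row <- function(gene, lfc, p, r, pc, defined = TRUE) {
  data.frame(gene = gene, log2fc = lfc, p_dge = p,
             direction = ifelse(lfc >= 0, "up", "down"),
             r_stroma = r, p_corr = pc, defined = defined,
             stringsAsFactors = FALSE)
}
null_row <- function(gene, r, pc, defined = TRUE)
  ev_row(gene, 0, 1, r, pc, defined)

toy_rl <- rl_table(c("ligA", "ligB", "ligC"), c("recA", "recB", "recC"))

test_that("driver and suppressor rules follow the published thresholds", {
  enr <- rbind(ev_row("recA", 1.5, 0.01, 0.35, 0.001),   # up in enriched, r+
               ev_row("ligA", 1.5, 0.01, -0.30, 0.001),  # up in enriched, r-
               ev_row("ligB", -1.4, 0.02, -0.4, 0.001),  # down in enriched, r-
               ev_row("recB", 0.1, 0.9, 0.5, 0.001))     # no DGE evidence
  sup <- rbind(null_row("recA", 0.35, 0.001),
               null_row("ligA", -0.30, 0.001),
               null_row("ligB", -0.4, 0.001),
               null_row("recB", 0.5, 0.001))
  out <- classify_associates(enr, sup, toy_rl)
  expect_equal(out$class[out$gene == "recA"], "driver")
  expect_equal(out$role[out$gene == "recA"], "receptor")
  # up in enriched but anticorrelated: fits neither definition
  expect_false("ligA" %in% out$gene)
  # down in enriched with negative correlation: suppressor
  expect_equal(out$class[out$gene == "ligB"], "suppressor")
  # correlated but not differential: excluded
  expect_false("recB" %in% out$gene)
})

test_that("suppressed-subgroup evidence feeds both classes", {
  enr <- rbind(null_row("recA", 0.35, 0.001), null_row("ligB", -0.4, 0.001))
  sup <- rbind(ev_row("recA", -1.5, 0.01, 0.35, 0.001),   # down in suppressed
               ev_row("ligB", 1.5, 0.01, -0.4, 0.001))    # up in suppressed
  out <- classify_associates(enr, sup, toy_rl)
  expect_equal(out$class[out$gene == "recA"], "driver")
  expect_equal(out$class[out$gene == "ligB"], "suppressor")
})

test_that("exclusion lists, non-RL genes and undefined correlations are removed", {
  enr <- rbind(ev_row("recA", 1.5, 0.01, 0.35, 0.001),
               ev_row("other", 2, 0.001, 0.9, 1e-6),     # not a receptor/ligand
               ev_row("ligC", 1.5, 0.01, NA, NA, defined = FALSE))
  sup <- rbind(null_row("recA", 0.35, 0.001), null_row("other", 0.9, 1e-6),
               null_row("ligC", NA, NA, defined = FALSE))
  out <- classify_associates(enr, sup, toy_rl,
                             exclude = list(stromal = "recA"))
  expect_equal(nrow(out), 0L)   # recA excluded, other not RL, ligC undefined
  out <- classify_associates(enr, sup, toy_rl)
  expect_equal(out$gene, "recA")
})

test_that("boundary values are strict and thresholds filter monotonically", {
  at_cut <- rbind(ev_row("recA", 1.0, 0.01, 0.35, 0.001),   # |log2fc| == 1
                  ev_row("ligB", 1.5, 0.01, 0.2, 0.001))    # r == 0.2
  sup <- rbind(null_row("recA", 0.35, 0.001), null_row("ligB", 0.2, 0.001))
  expect_equal(nrow(classify_associates(at_cut, sup, toy_rl)), 0L)

  set.seed(5)
  enr <- ev_row(c("ligA", "ligB", "ligC", "recA", "recB", "recC"),
                runif(6, 0.5, 3), runif(6, 0, 0.1),
                runif(6, 0.1, 0.6), runif(6, 0, 0.1))
  sup <- null_row(enr$gene, enr$r_stroma, enr$p_corr)
  base <- classify_associates(enr, sup, toy_rl)$gene
  for (th in list(list(fc = 4), list(r_min = 0.4), list(alpha = 0.01))) {
    strict <- do.call(classify_associates,
                      c(list(enr, sup, toy_rl), th))$gene
    expect_true(all(strict %in% base))
  }
  expect_true(all(base %in% names(toy_rl$roles)))
})

test_that("classes are exclusive and consistent with the correlation sign", {
  # a gene up in BOTH screens with r > 0 is a driver only: the suppressor
  # rule needs r < -r_min, which the shared correlation column forbids
  enr <- ev_row("recA", 1.5, 0.01, 0.35, 0.001)
  sup <- ev_row("recA", 1.5, 0.01, 0.35, 0.001)
  out <- classify_associates(enr, sup, toy_rl)
  expect_equal(out$class, "driver")
  expect_gt(out$r_stroma, 0)
  expect_error(classify_associates(enr, sup, rl_table(character(), character())),
               "empty")
})

test_that("single-cell prevalence filter keeps the boundary gene", {
  set.seed(9)
  vals <- matrix(0, 3, 100, dimnames = list(c("never", "always", "exact"),
                                            paste0("c", 1:100)))
  vals["always", ] <- 1
  vals["exact", 1] <- 1   # expressed in exactly 1% of cells
  m <- expression_matrix(vals, scale_tag = "sc-lognorm")
  keep <- filter_sc_expressed(rownames(m), m, min_frac = 0.01)
  expect_setequal(keep, c("always", "exact"))
  expect_equal(filter_sc_expressed("absent", m), character())
})

test_that("planted drivers are recovered on a single synthetic cohort", {
  b <- generate_bulk(bulk_sim_config(seed = 42, n_genes = 1000,
                                     n_samples = 150))
  sc <- score_table(b$matrix, b$signatures, method = "ssgsea")
  enr <- screen_subgroup(b$matrix, b$annotation, "SHH", sc)
  sup <- screen_subgroup(b$matrix, b$annotation, "Group3", sc)
  out <- classify_associates(enr, sup, b$rl, exclude = b$signatures)
  tp <- sum(out$gene %in% b$truth$drivers)
  expect_gte(tp / length(b$truth$drivers), 0.9)
  expect_lte((nrow(out) - tp) / max(1, nrow(out)), 0.1)
})
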