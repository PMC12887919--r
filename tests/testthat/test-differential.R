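test_that("comparison enumeration is the within-batch cartesian product", {
  cmp <- build_comparisons(toy_design())
  expect_equal(nrow(cmp), 8)
  expect_equal(sum(cmp$batch == "group1"), 4)
  d2 <- specimen_design(c("T1", "C1", "T2", "C2"),
                        c("group1", "group1", "group2", "group2"),
                        c("treatment", "control", "treatment", "control"),
                        c("L1", "L1", "L2", "L2"))
  expect_equal(nrow(build_comparisons(d2)), 2)
  d3 <- specimen_design(c("T1", "T2", "T3", "C1", "C2"), rep("group1", 5),
                        c("treatment", "treatment", "treatment",
                          "control", "control"), rep("L1", 5))
  expect_equal(nrow(build_comparisons(d3)), 6)
})

test_that("normalization equalizes per-specimen totals and fixes doubling", {
  ds <- random_batch(n = 40, seed = 17)
  norm <- normalize_abundances(ds)
  totals <- colSums(norm$abundance, na.rm = TRUE)
  expect_lt(max(totals) - min(totals), 1e-9 * max(totals))
  # a dataset whose totals are already equal is untouched
  again <- normalize_abundances(norm)
  expect_equal(again$abundance, norm$abundance, tolerance = 1e-12)
  # doubling one specimen's intensities is undone
  doubled <- ds
  doubled$abundance[, 2] <- ds$abundance[, 2] * 2
  nd <- normalize_abundances(doubled)$abundance
  t2 <- colSums(nd, na.rm = TRUE)
  expect_lt(max(t2) - min(t2), 1e-9 * max(t2))
  # cross-specimen abundance ratios are restored to the undoubled values
  expect_equal(nd[, 2] / nd[, 1], norm$abundance[, 2] / norm$abundance[, 1],
               tolerance = 1e-9)
})

test_that("censored log2 clamps at the sentinel and flags censoring", {
  expect_equal(censored_log2(1), list(log2_ratio = 0, censored = FALSE))
  expect_equal(censored_log2(0.5), list(log2_ratio = -1, censored = FALSE))
  r <- censored_log2(12)
  expect_equal(r$log2_ratio, 3.32)
  expect_true(r$censored)
  r2 <- censored_log2(1 / 12)
  expect_equal(r2$log2_ratio, -3.32)
  expect_true(r2$censored)
  expect_error(censored_log2(-1), class = "dentproteo_validation_error")
  expect_error(censored_log2(0), class = "dentproteo_validation_error")
  expect_true(is.na(censored_log2(NA_real_)$log2_ratio))
})

make_ratio_batch <- function(lr_by_protein, seed = 1) {
  # peptide table where protein i's T1/C1 peptide log2 ratios are exactly
  # lr_by_protein[[i]]
  design <- toy_design()
  acc <- names(lr_by_protein)
  pep <- do.call(rbind, lapply(acc, function(a) {
    lr <- lr_by_protein[[a]]
    base <- 2^seq(20, 20.5, length.out = length(lr))
    data.frame(accession = a, peptide_id = sprintf("p%d", seq_along(lr)),
               T1 = base * 2^lr, T2 = base, C1 = base, C2 = base,
               stringsAsFactors = FALSE)
  }))
  ab <- do.call(rbind, lapply(acc, function(a)
    colSums(as.matrix(pep[pep$accession == a, c("T1", "T2", "C1", "C2")]))))
  dimnames(ab) <- list(acc, c("T1", "T2", "C1", "C2"))
  quant <- data.frame(accession = acc, gene = acc, description = "x",
                      q_value = 0.01, n_peptides = lengths(lr_by_protein),
                      n_psms = 10L, stringsAsFactors = FALSE)
  group_dataset("group1", quant, ab, design, peptides = pep)
}

test_that("peptide-ratio t-test matches the closed form and handles degeneracy", {
  ds <- make_ratio_batch(list(
    A = c(1.0, 1.1, 0.9, 1.2, 0.8),  # t = 14.14 on 4 df
    B = c(0, 0, 0, 0),               # zero variance at the null: p = 1
    C = c(0.7, 0.7, 0.7),            # zero variance off the null: p missing
    D = 1.5))                        # single peptide: p missing
  pv <- comparison_pvalues(ds, list(treatment = "T1", control = "C1"),
                           adjust = "none")
  p <- setNames(pv$p_value, pv$accession)
  expect_equal(p[["A"]], 2 * pt(-1 / (sd(c(1, 1.1, .9, 1.2, .8)) / sqrt(5)), 4),
               tolerance = 1e-9)
  expect_lt(p[["A"]], 1e-3)
  expect_equal(p[["B"]], 1)
  expect_true(is.na(p[["C"]]))
  expect_true(is.na(p[["D"]]))
})

test_that("vectorized peptide t-test agrees with stats::t.test", {
  set.seed(42)
  lrs <- lapply(1:30, function(i) rnorm(sample(2:8, 1), rnorm(1), 0.5))
  names(lrs) <- sprintf("P%02d", 1:30)
  ds <- make_ratio_batch(lrs)
  pv <- comparison_pvalues(ds, list(treatment = "T1", control = "C1"),
                           adjust = "none")
  for (a in names(lrs)) {
    expect_equal(pv$p_value[pv$accession == a],
                 t.test(lrs[[a]], mu = 0)$p.value, tolerance = 1e-6)
  }
})

test_that("adjusted p-values are BH within the comparison", {
  set.seed(5)
  lrs <- lapply(1:20, function(i) rnorm(5, 0, 0.5))
  names(lrs) <- sprintf("P%02d", 1:20)
  ds <- make_ratio_batch(lrs)
  pv <- comparison_pvalues(ds, list(treatment = "T1", control = "C1"))
  expect_equal(pv$adj_p_value, p.adjust(pv$p_value, "BH"))
  expect_true(all(pv$adj_p_value >= pv$p_value, na.rm = TRUE))
})

test_that("swapping treatment and control negates the ratio, keeps p", {
  ds <- generate_quant_experiment(synthetic_config(n_proteins = 150,
                                                   seed = 13))$group1
  fwd <- compute_ratios(ds, comparisons = data.frame(
    comparison_id = "f", batch = "group1", treatment = "T1", control = "C1",
    stringsAsFactors = FALSE))
  rev <- compute_ratios(ds, comparisons = data.frame(
    comparison_id = "r", batch = "group1", treatment = "C1", control = "T1",
    stringsAsFactors = FALSE))
  unc <- !fwd$censored & !rev$censored & !fwd$missing
  expect_equal(fwd$log2_ratio[unc], -rev$log2_ratio[unc], tolerance = 1e-9)
  expect_equal(fwd$p_value[unc], rev$p_value[unc], tolerance = 1e-9)
  cen <- fwd$censored & !fwd$missing
  expect_equal(fwd$log2_ratio[cen], -rev$log2_ratio[cen], tolerance = 1e-12)
})

test_that("ratio results respect missing-data semantics", {
  ds <- generate_quant_experiment(synthetic_config(n_proteins = 300,
                                                   seed = 19))$group1
  r <- compute_ratios(ds)
  m <- r$missing
  expect_true(all(is.na(r$raw_ratio[m]) & is.na(r$log2_ratio[m]) &
                    is.na(r$p_value[m]) & is.na(r$adj_p_value[m])))
  expect_true(all(abs(r$log2_ratio[!m]) <= 3.32))
  expect_true(all(r$censored[!m] == (abs(r$log2_ratio[!m]) == 3.32)))
})

test_that("CGSig selection enforces both-batch significance and missingness", {
  cg <- c("A", "B", "C")
  g1 <- rbind(ratio_row("A", "g1:T1/C1", "group1", 1, 0.01),
              ratio_row("B", "g1:T1/C1", "group1", 1, 0.01),
              ratio_row("C", "g1:T1/C1", "group1", 1, 0.01),
              ratio_row("A", "g1:T2/C1", "group1", 1, 0.5),
              ratio_row("B", "g1:T2/C1", "group1", 1, 0.5),
              ratio_row("C", "g1:T2/C1", "group1", missing = TRUE))
  g2 <- rbind(ratio_row("A", "g2:T3/C3", "group2", 1, 0.2),   # never sig in g2
              ratio_row("B", "g2:T3/C3", "group2", 1, 0.04),
              ratio_row("C", "g2:T3/C3", "group2", 1, 0.04),
              ratio_row("A", "g2:T4/C3", "group2", 1, 0.9),
              ratio_row("B", "g2:T4/C3", "group2", 1, 0.9),
              ratio_row("C", "g2:T4/C3", "group2", missing = TRUE))
  sel <- select_cgsig(g1, g2, cg)
  expect_identical(as.character(sel), "B")       # A: one batch only; C: 2 missing
  expect_equal(attr(sel, "n_retained"), 2)       # B and C pass significance
  expect_equal(attr(sel, "n_discarded"), 1)      # C discarded for missingness
  # relaxing the missingness tolerance readmits C
  expect_identical(as.character(select_cgsig(g1, g2, cg, max_missing = 2)),
                   c("B", "C"))
})

test_that("CGSig grows with alpha and max_missing, stays inside CG", {
  set.seed(23)
  exp <- generate_quant_experiment(synthetic_config(n_proteins = 400,
                                                    seed = 23))
  q1 <- apply_qc(exp$group1); q2 <- apply_qc(exp$group2)
  cg <- intersect_groups(q1, q2)
  r1 <- compute_ratios(q1); r2 <- compute_ratios(q2)
  prev <- character(0)
  for (a in c(0.01, 0.05, 0.2, 0.999)) {
    cur <- select_cgsig(r1, r2, cg, alpha = a)
    expect_true(all(prev %in% cur))
    expect_true(all(cur %in% cg))
    prev <- cur
  }
  small <- select_cgsig(r1, r2, cg, max_missing = 0)
  large <- select_cgsig(r1, r2, cg, max_missing = 8)
  expect_true(all(small %in% large))
  expect_error(select_cgsig(r1, r2, cg, alpha = 0),
               class = "dentproteo_validation_error")
})
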