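test_that("the generator is a pure function of its configuration", {
  cfg <- synthetic_config(n_proteins = 300, seed = 5)
  a <- generate_quant_experiment(cfg)
  b <- generate_quant_experiment(cfg)
  expect_identical(a, b)
  c <- generate_quant_experiment(synthetic_config(n_proteins = 300, seed = 6))
  expect_false(identical(a$group1$abundance, c$group1$abundance))
})

test_that("frac_de = 0 plants nothing; planted accessions always surface", {
  none <- generate_quant_experiment(synthetic_config(n_proteins = 200,
                                                     frac_de = 0, seed = 2))
  expect_length(none$truth$planted, 0)
  # low detection probabilities stress the at-least-one-batch guarantee
  some <- generate_quant_experiment(synthetic_config(
    n_proteins = 400, detect_prob_g1 = 0.4, detect_prob_g2 = 0.4,
    frac_de = 0.2, seed = 3))
  present <- union(some$group1$quant$accession, some$group2$quant$accession)
  expect_true(all(names(some$truth$planted) %in% present))
})

test_that("batch overlap matches the binomial detection expectation", {
  p1 <- 0.95; p2 <- 0.75; n <- 2000; n_seeds <- 20
  overlaps <- vapply(seq_len(n_seeds), function(s) {
    e <- generate_quant_experiment(synthetic_config(
      n_proteins = n, detect_prob_g1 = p1, detect_prob_g2 = p2,
      frac_de = 0, seed = 100 + s))
    length(intersect(e$group1$quant$accession, e$group2$quant$accession)) / n
  }, 0)
  expected <- p1 * p2
  mc_se <- sqrt(expected * (1 - expected) / (n * n_seeds))
  expect_lt(abs(mean(overlaps) - expected), 3 * mc_se)
})

test_that("dropout is monotone in abundance (MNAR)", {
  e <- generate_quant_experiment(synthetic_config(
    n_proteins = 1500, mnar_threshold = 21, mnar_slope = 1, seed = 8))
  ab <- e$group1$abundance
  # reconstruct each protein's typical log2 abundance from observed cells
  lvl <- log2(apply(ab, 1, function(r) mean(r, na.rm = TRUE)))
  miss_rate <- rowMeans(is.na(ab))
  terciles <- cut(lvl, quantile(lvl, c(0, 1/3, 2/3, 1)),
                  include.lowest = TRUE)
  rates <- tapply(miss_rate, terciles, mean)
  expect_gt(rates[[1]], rates[[3]])
  expect_true(all(diff(rates) <= 0))
})

test_that("qc-failure fractions translate into filterable records", {
  e <- generate_quant_experiment(synthetic_config(
    n_proteins = 1000, frac_fail_q = 0.1, frac_fail_peptides = 0.1,
    frac_fail_psms = 0.1, seed = 12))
  q <- e$group1$quant
  expect_gt(sum(q$q_value > 0.05), 0)
  expect_gt(sum(q$n_peptides < 2), 0)
  expect_gt(sum(q$n_psms < 4), 0)
  flagged <- e$truth$qc_fail$group1
  survivors <- apply_qc(e$group1)$quant$accession
  expect_length(intersect(flagged, survivors), 0)
})

test_that("pathway generation honours sizes, enrichment and determinism", {
  expect_length(generate_pathway_sets(letters, letters[1:5], 0)$pathways, 0)
  expect_error(generate_pathway_sets(letters, letters[1:3], 5,
                                     size_range = c(2, 100)),
               class = "dentproteo_validation_error")
  uni <- sprintf("U%03d", 1:200)
  planted <- uni[1:40]
  ps <- generate_pathway_sets(uni, planted, 10, size_range = c(10, 30),
                              n_enriched = 3, enriched_frac = 1, seed = 4)
  expect_length(ps$enriched_ids, 3)
  for (id in ps$enriched_ids) {
    pw <- ps$pathways[[match(id, vapply(ps$pathways, `[[`, "", "pathway_id"))]]
    expect_true(all(pw$members %in% planted))
  }
  again <- generate_pathway_sets(uni, planted, 10, size_range = c(10, 30),
                                 n_enriched = 3, enriched_frac = 1, seed = 4)
  expect_identical(ps, again)
})

test_that("noise-free landmark sets hit their configured geometry exactly", {
  gen <- generate_landmark_sets(n_treatment = 3, n_control = 3,
                                skull_effect = 0, skull_noise_sd = 0,
                                crown_effect = 0, crown_area_sd = 0,
                                seed = 9)
  lens <- vapply(gen$skull, interlandmark_distance, 0)
  expect_equal(lens, rep(19.02755, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  areas <- vapply(gen$molar, crown_area, 0)
  expect_equal(areas, rep(1.021672, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(gen, generate_landmark_sets(
    n_treatment = 3, n_control = 3, skull_effect = 0, skull_noise_sd = 0,
    crown_effect = 0, crown_area_sd = 0, seed = 9))
})

test_that("planted landmark effects are recovered within sampling error", {
  gen <- generate_landmark_sets(n_treatment = 30, n_control = 30,
                                skull_noise_sd = 0.5, crown_area_sd = 0.03,
                                seed = 21)
  res <- phenotype_table(gen$skull, gen$molar, gen$design)
  for (tr in res$trait) {
    row <- res[res$trait == tr, ]
    diff_hat <- row$mean_treatment - row$mean_control
    sd_tr <- if (tr == "skull_length_mm") 0.5 else 0.03
    expect_lt(abs(diff_hat - gen$effects[[tr]]), 3 * sd_tr / sqrt(30) * 2)
  }
})
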