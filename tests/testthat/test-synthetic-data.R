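test_that("every generator is bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 1, n_proteins = 60, n_features = 80,
                    n_analytes = 10)
  lay <- make_array_layout(n_analytes = 10)
  expect_identical(generate_protein_abundances(cfg),
                   generate_protein_abundances(cfg))
  expect_identical(generate_mirna_counts(cfg), generate_mirna_counts(cfg))
  expect_identical(generate_cytokine_membranes(cfg, lay),
                   generate_cytokine_membranes(cfg, lay))
  expect_identical(generate_survival_cohort(cfg, 50, 10),
                   generate_survival_cohort(cfg, 50, 10))
  expect_identical(generate_cellline_panel(cfg),
                   generate_cellline_panel(cfg))
})

test_that("ground truth aligns one-to-one with generated features", {
  cfg <- sim_config(seed = 2, n_proteins = 50, n_features = 40)
  prot <- generate_protein_abundances(cfg)
  expect_identical(prot$table$accession, prot$truth$accession)
  mir <- generate_mirna_counts(cfg)
  expect_identical(rownames(mir$counts), mir$truth$feature)
  expect_equal(sum(mir$truth$is_de), round(cfg$de_fraction * 40))
})

test_that("zero-noise null proteins share group means exactly", {
  cfg <- sim_config(seed = 3, n_proteins = 30, noise_cv = 0,
                    de_fraction = 0)
  sim <- generate_protein_abundances(cfg)
  trt <- as.matrix(sim$table[, grep("^treated_", names(sim$table))])
  ctl <- as.matrix(sim$table[, grep("^control_", names(sim$table))])
  expect_equal(rowMeans(trt), rowMeans(ctl))
  expect_equal(apply(trt, 1, stats::sd), rep(0, 30))
})

test_that("planted protein effects are recovered by direct averaging", {
  cfg <- sim_config(seed = 7, n_proteins = 2000, de_fraction = 0.1)
  sim <- generate_protein_abundances(cfg)
  trt <- as.matrix(sim$table[, grep("^treated_", names(sim$table))])
  ctl <- as.matrix(sim$table[, grep("^control_", names(sim$table))])
  obs_l2 <- log2(rowMeans(trt) / rowMeans(ctl))
  de <- sim$truth$is_de
  err <- abs(obs_l2[de]) - abs(sim$truth$true_log2fc[de])
  se <- stats::sd(err) / sqrt(sum(de))
  expect_lt(abs(mean(err)), 3 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
  expect_error(sim_config(censoring_rate = 1), "censoring_rate")
  expect_error(sim_config(effect_log2fc_range = c(2, 1)), "ordered")
  expect_error(sim_config(library_size_range = c(10.5, 100)), "integer")
  expect_error(sim_config(floor = 0), "floor")
  expect_error(sim_config(n_replicates_per_group = 1),
               "n_replicates_per_group")
})

test_that("count generator respects degenerate means and integer libraries", {
  cfg <- sim_config(seed = 4, n_features = 20, de_fraction = 0)
  zero <- generate_mirna_counts(cfg, baseline_means = rep(0, 20))
  expect_true(all(zero$counts == 0))
  expect_error(
    generate_mirna_counts(cfg, library_sizes = rep(1000.5, 6)),
    "integer")
})

test_that("Poisson-limit null counts give calibrated two-sample t-tests", {
  cfg <- sim_config(seed = 17, n_features = 2000, de_fraction = 0,
                    nb_dispersion = 0)
  sim <- generate_mirna_counts(cfg, baseline_means = rep(1, 2000),
                               library_sizes = rep(5e5L, 6))
  lc <- log2(sim$counts + 0.5)
  g <- sim$groups
  p <- apply(lc, 1, function(v) {
    stats::t.test(v[g == "treated"], v[g == "control"],
                  var.equal = TRUE)$p.value
  })
  rate <- mean(p < 0.05)
  ci <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})

test_that("survival generator honours censoring and the null", {
  cfg0 <- sim_config(seed = 5, censoring_rate = 0)
  coh0 <- generate_survival_cohort(cfg0, 200, 10)
  expect_true(all(coh0$survival$event == 1))

  cfg_null <- sim_config(seed = 6, hazard_log_hr = 0)
  coh <- generate_survival_cohort(cfg_null, 1500, 20)
  sc <- signature_score(coh$expression, coh$truth$signature_genes)
  sr <- km_logrank_cox(coh$survival$time, coh$survival$event,
                       median_split(sc), score = sc)
  expect_lt(abs(sr$score_beta), 3 * sr$score_se)
})

test_that("membrane generator: nulls, planted fold changes, duplicate CV", {
  lay <- make_array_layout(n_analytes = 8)
  cfg0 <- sim_config(seed = 1, n_analytes = 8, noise_cv = 0,
                     de_fraction = 0)
  mem0 <- generate_cytokine_membranes(cfg0, lay)
  wide <- summarize_membrane(mem0$spots, lay)
  expect_equal(wide[, "treated_1"], wide[, "control_1"])

  # single planted doubling, zero noise: normalised ratio exactly 2
  cfg1 <- sim_config(seed = 2, n_analytes = 8, noise_cv = 0,
                     de_fraction = 1 / 8, effect_log2fc_range = c(1, 1))
  mem1 <- generate_cytokine_membranes(cfg1, lay)
  w1 <- summarize_membrane(mem1$spots, lay)
  ratio <- rowMeans(w1[, grep("treated", colnames(w1))]) /
    rowMeans(w1[, grep("control", colnames(w1))])
  de <- mem1$truth$analyte[mem1$truth$is_de]
  expect_equal(unname(ratio[de]),
               2^mem1$truth$true_log2fc[mem1$truth$is_de])
  expect_equal(unname(ratio[setdiff(names(ratio), de)]),
               rep(1, 7))

  # duplicate-spot CV recovered by direct computation on bg-subtracted spots
  cfg2 <- sim_config(seed = 3, n_analytes = 8, noise_cv = 0.1,
                     de_fraction = 0)
  mem2 <- generate_cytokine_membranes(cfg2, lay)
  sp <- merge(mem2$spots, lay, by = c("row", "col"))
  sp <- sp[sp$role == "analyte", ]
  sp$net <- sp$intensity - 50
  cvs <- tapply(sp$net, paste(sp$membrane_id, sp$name), function(v) {
    stats::sd(v) / mean(v)
  })
  expect_gt(mean(cvs), 0.05)
  expect_lt(mean(cvs), 0.15)
})

test_that("membrane generator requires POS controls", {
  lay <- make_array_layout(n_analytes = 4, n_pos = 1)
  lay$role[lay$role == "POS"] <- "BLANK"
  cfg <- sim_config(seed = 1, n_analytes = 4)
  expect_error(generate_cytokine_membranes(cfg, lay), "POS")
})

test_that("cell-line panel plants exact linear links", {
  cfg <- sim_config(seed = 9, noise_cv = 0)
  planted <- data.frame(gene = "GENE0003", drug = "drug01", slope = 1,
                        intercept = 0)
  pan <- generate_cellline_panel(cfg, n_lines = 10, n_genes = 5,
                                 n_drugs = 1, planted = planted)
  fit <- expression_response_regression(pan$expression, pan$responses)
  row <- fit[fit$gene == "GENE0003" & fit$drug == "drug01", ]
  expect_equal(row$r_squared, 1)
  expect_equal(row$slope, 1)
  expect_error(generate_cellline_panel(cfg, n_lines = 2), "n_lines")
})
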