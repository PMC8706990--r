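sim_counts <- function(seed, n = 400, de = 0.1, disp = 0.1) {
  cfg <- sim_config(seed = seed, n_features = n, de_fraction = de,
                    nb_dispersion = disp)
  sim <- generate_mirna_counts(cfg)
  keep <- rowSums(sim$counts) > 0
  list(counts = sim$counts[keep, , drop = FALSE], groups = sim$groups,
       truth = sim$truth[keep, ])
}

test_that("TMM factors: identity, library-scale invariance, product one", {
  x <- matrix(rpois(200, 50) + 1, ncol = 2)
  x[, 2] <- x[, 1]
  expect_equal(tmm_factors(x), c(1, 1))

  # doubling every count changes the library size, not the TMM factor
  y <- cbind(x[, 1], 2 * x[, 1])
  expect_equal(tmm_factors(y), c(1, 1))

  s <- sim_counts(41)
  f <- tmm_factors(s$counts)
  expect_equal(prod(f), 1, tolerance = 1e-12)
  # M-values and trims are exactly scale invariant; the precision weights
  # depend on the raw counts, so invariance is approximate
  scaled <- t(t(s$counts) * c(3, 1, 7, 2, 5, 1))
  expect_equal(tmm_factors(scaled), f, tolerance = 0.02)

  bad <- s$counts
  bad[, 1] <- 0
  expect_error(tmm_factors(bad), "all-zero sample")
})

test_that("a contaminated sample's factor matches the brute-force trimmed mean", {
  set.seed(31)
  n <- 1000
  base <- rpois(n, 60) + 1
  x <- cbind(a = base + rpois(n, 5), b = base + rpois(n, 5))
  infl <- sample(n, 50)
  x[infl, "b"] <- x[infl, "b"] * 8
  f <- tmm_factors(x)
  # the clean sample is scaled up relative to the contaminated one
  expect_gt(f[1], f[2])

  # literal recomputation of the trimmed weighted mean of M against sample 1
  lib <- colSums(x)
  pos <- x[, 1] > 0 & x[, 2] > 0
  m <- log2((x[pos, 2] / lib[2]) / (x[pos, 1] / lib[1]))
  a <- 0.5 * log2((x[pos, 2] / lib[2]) * (x[pos, 1] / lib[1]))
  v <- (lib[2] - x[pos, 2]) / (lib[2] * x[pos, 2]) +
    (lib[1] - x[pos, 1]) / (lib[1] * x[pos, 1])
  nn <- length(m)
  lo_m <- floor(nn * 0.3) + 1; hi_m <- nn + 1 - lo_m
  lo_a <- floor(nn * 0.05) + 1; hi_a <- nn + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  f_b_raw <- 2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  f_pair <- c(1, f_b_raw)
  expect_equal(unname(tmm_factors(x)), unname(f_pair / exp(mean(log(f_pair)))),
               tolerance = 1e-10)
})

test_that("TMM and the full moderated chain match the reference packages", {
  skip_if_not_installed("edgeR")
  skip_if_not_installed("limma")
  s <- sim_counts(11, n = 500)
  f <- tmm_factors(s$counts)
  f_ref <- edgeR::calcNormFactors(edgeR::DGEList(s$counts),
                                  method = "TMM")$samples$norm.factors
  expect_equal(f, f_ref, tolerance = 1e-10)

  design <- stats::model.matrix(~ s$groups)
  vm <- voom_transform(s$counts, f, design)
  d <- edgeR::DGEList(s$counts)
  d$samples$norm.factors <- f_ref
  vl <- limma::voom(d, design)
  expect_equal(vm$E, vl$E, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(vm$weights, vl$weights, tolerance = 1e-8,
               ignore_attr = TRUE)

  fit <- moderated_t_fit(vm)
  fl <- limma::eBayes(limma::lmFit(vl))
  expect_equal(attr(fit, "d0"), fl$df.prior, tolerance = 1e-6)
  expect_equal(attr(fit, "s0_2"), fl$s2.prior, tolerance = 1e-6)
  expect_equal(fit$logFC, unname(fl$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(fit$t, unname(fl$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$p_value, unname(fl$p.value[, 2]), tolerance = 1e-8)
})

test_that("voom closed forms and degenerate inputs", {
  # count 0 at library size 1e6, factor 1
  x <- rbind(a = c(0, 10), b = c(1e6 - 10, 1e6 - 20), c = c(20, 30))
  lib <- colSums(x)
  vm <- voom_transform(x, rep(1, 2) * (1e6 / lib),
                       design = matrix(1, 2, 1))
  expect_equal(as.numeric(vm$E["a", 1]), log2(0.5 / (1e6 + 1) * 1e6),
               tolerance = 1e-9)

  # constant counts: equal log-CPM and equal weights
  xc <- matrix(50, nrow = 4, ncol = 4)
  vmc <- voom_transform(xc, rep(1, 4), design = matrix(1, 4, 1))
  expect_true(all(vmc$E == vmc$E[1, 1]))
  expect_true(all(vmc$weights == vmc$weights[1, 1]))

  expect_error(voom_transform(x[, 1, drop = FALSE], 1, matrix(1, 1, 1)),
               "residual df")
})

test_that("voom weights fall with decreasing mean count", {
  s <- sim_counts(13, n = 600, de = 0)
  design <- stats::model.matrix(~ s$groups)
  vm <- voom_transform(s$counts, tmm_factors(s$counts), design)
  rho <- stats::cor(rowMeans(s$counts), apply(vm$weights, 1, stats::median),
                    method = "spearman")
  expect_gt(rho, 0)
})

test_that("moderated t reduces to ordinary t when all variances are equal", {
  # features that are permutations of one replicate pattern share s2 exactly
  base <- c(-1, 0, 1, -1, 0, 1)
  shifts <- seq(0, 2, length.out = 8)
  e <- t(vapply(shifts, function(d) base + rep(c(0, d), each = 3),
                numeric(6)))
  rownames(e) <- paste0("f", seq_len(8))
  design <- cbind(1, rep(0:1, each = 3))
  vm <- structure(list(E = e, weights = matrix(1, 8, 6), design = design,
                       lib_size = rep(1e6, 6), trend = NULL),
                  class = "voom_output")
  fit <- moderated_t_fit(vm)
  expect_true(is.infinite(attr(fit, "d0")))
  expect_equal(fit$s2_post, fit$s2)
  ord_t <- apply(e, 1, function(y) {
    unname(stats::t.test(y[4:6], y[1:3], var.equal = TRUE)$statistic)
  })
  expect_equal(fit$t, unname(ord_t), tolerance = 1e-10)
  # equal weights: logFC is the difference of group means
  expect_equal(fit$logFC, unname(rowMeans(e[, 4:6]) - rowMeans(e[, 1:3])))
})

test_that("null simulation keeps the moderated-t size near nominal", {
  rates <- vapply(1:3, function(s) {
    sc <- sim_counts(300 + s, n = 1000, de = 0)
    vm <- voom_transform(sc$counts, tmm_factors(sc$counts),
                         stats::model.matrix(~ sc$groups))
    mean(moderated_t_fit(vm)$p_value < 0.05)
  }, numeric(1))
  ci <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / 3000)
  expect_gt(mean(rates), ci[1])
  expect_lt(mean(rates), ci[2])
})

test_that("fold-change/p gate retains the published screen and is strict", {
  tab <- mirna_screen()
  res <- data.frame(feature = tab$mirna, logFC = tab$logFC,
                    p_value = tab$p_value)
  kept <- filter_mirnas(res)
  expect_identical(nrow(kept), 9L)
  expect_identical(kept$feature[1], "hsa-mir-130a-3p")   # strongest up
  expect_identical(kept$feature[kept$direction == "down"][1],
                   "hsa-mir-4787-3p")                    # strongest down
  up <- kept$logFC[kept$direction == "up"]
  dn <- kept$logFC[kept$direction == "down"]
  expect_true(all(diff(up) <= 0))
  expect_true(all(diff(dn) >= 0))

  boundary <- rbind(res, data.frame(feature = "edge", logFC = log2(1.5),
                                    p_value = 0.01))
  expect_false("edge" %in% filter_mirnas(boundary)$feature)
  expect_true(all(filter_mirnas(boundary)$feature %in% boundary$feature))
})

test_that("planted two-fold-change features are recovered with high power", {
  cfg <- sim_config(seed = 31, n_features = 2000, de_fraction = 0.1,
                    effect_log2fc_range = c(2, 2))
  sim <- generate_mirna_counts(cfg)
  counts <- sim$counts[rowSums(sim$counts) > 0, ]
  vm <- voom_transform(counts, tmm_factors(counts),
                       stats::model.matrix(~ sim$groups))
  kept <- filter_mirnas(moderated_t_fit(vm))$feature
  de <- sim$truth$feature[sim$truth$is_de]
  expect_gte(mean(de %in% kept), 0.7)
})
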