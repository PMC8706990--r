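#' Simulate a label-free protein quantification table
#'
#' Draws per-protein abundances for two conditions (`control`, `treated`)
#' with `n_replicates_per_group` replicates each. Abundances are log-normal
#' on the log2 scale with a replicate SD derived from `noise_cv`. A fraction
#' `de_fraction` of proteins carries a planted log2 fold change with
#' magnitude uniform in `effect_log2fc_range` and random sign; all other
#' proteins share their group means. Unique-peptide counts and a
#' high-confidence identification flag are attached so the downstream filter
#' cascade can be exercised end to end. Missing values are injected
#' completely at random (or low-abundance biased when `mnar = TRUE`).
#'
#' @param config A [sim_config()].
#' @return A list with `table` (data frame: `accession`, `unique_peptides`,
#'   `high_conf`, then abundance columns `control_1..k`, `treated_1..k`) and
#'   `truth` (data frame: `accession`, `is_de`, `true_log2fc`).
#' @examples
#' sim <- generate_protein_abundances(sim_config(seed = 7, n_proteins = 50))
#' head(sim$truth)
#' @export
generate_protein_abundances <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_proteins
  k <- config$n_replicates_per_group
  sd2 <- log2_sd_from_cv(config$noise_cv)

  accession <- sprintf("PROT%04d", seq_len(n))
  base_log2 <- stats::rnorm(n, mean = 20, sd = 2)
  n_de <- round(config$de_fraction * n)
  is_de <- rep(FALSE, n)
  if (n_de > 0) is_de[sample.int(n, n_de)] <- TRUE
  mag <- stats::runif(n, config$effect_log2fc_range[1],
                      config$effect_log2fc_range[2])
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  true_log2fc <- ifelse(is_de, sgn * mag, 0)

  draw <- function(mu) {
    m <- matrix(stats::rnorm(n * k, mean = rep(mu, k), sd = sd2), nrow = n)
    2^m
  }
  ctrl <- draw(base_log2)
  trt <- draw(base_log2 + true_log2fc)
  colnames(ctrl) <- paste0("control_", seq_len(k))
  colnames(trt) <- paste0("treated_", seq_len(k))

  abund <- cbind(ctrl, trt)
  if (config$missing_fraction > 0) {
    n_cells <- length(abund)
    n_miss <- round(config$missing_fraction * n_cells)
    if (n_miss > 0) {
      if (config$mnar) {
        # low-abundance biased: sampling weight decreasing in intensity rank
        w <- rank(-abund)
        idx <- sample.int(n_cells, n_miss, prob = w)
      } else {
        idx <- sample.int(n_cells, n_miss)
      }
      abund[idx] <- NA_real_
    }
  }

  table <- data.frame(
    accession = accession,
    unique_peptides = 1L + stats::rpois(n, 2),
    high_conf = stats::runif(n) > 0.02,
    abund,
    check.names = FALSE
  )
  truth <- data.frame(accession = accession, is_de = is_de,
                      true_log2fc = true_log2fc)
  list(table = table, truth = truth)
}

#' Simulate a miRNA count matrix
#'
#' Integer counts for two groups of `n_replicates_per_group` samples,
#' negative-binomial around per-feature group means scaled by per-sample
#' library sizes drawn uniformly (as integers) from `library_size_range`.
#' With `nb_dispersion = 0` counts are Poisson. A `de_fraction` of features
#' carries a planted log2 fold change in the treated group.
#'
#' @param config A [sim_config()].
#' @param baseline_means Optional vector of per-feature expected relative
#'   abundances (length `n_features`); zero means give all-zero counts for
#'   that feature. Default: log-normal relative abundances.
#' @param library_sizes Optional integer vector of per-sample library sizes
#'   (length `2 * n_replicates_per_group`); non-integer values are an error.
#' @return A list with `counts` (integer matrix, features x samples),
#'   `groups` (factor `control`/`treated` per sample) and `truth`.
#' @export
generate_mirna_counts <- function(config, baseline_means = NULL,
                                  library_sizes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_features
  k <- config$n_replicates_per_group
  n_samp <- 2L * k

  if (is.null(baseline_means)) {
    rel <- exp(stats::rnorm(n, mean = 0, sd = 1.5))
    rel <- rel / sum(rel)
  } else {
    stopifnot(length(baseline_means) == n, all(baseline_means >= 0))
    rel <- baseline_means / max(sum(baseline_means), .Machine$double.eps)
    if (sum(baseline_means) == 0) rel <- baseline_means
  }
  if (is.null(library_sizes)) {
    library_sizes <- sample(seq(config$library_size_range[1],
                                config$library_size_range[2]), n_samp,
                            replace = TRUE)
  }
  if (any(library_sizes != round(library_sizes))) {
    stop("configuration error: library sizes must be integers", call. = FALSE)
  }

  n_de <- round(config$de_fraction * n)
  is_de <- rep(FALSE, n)
  if (n_de > 0) is_de[sample.int(n, n_de)] <- TRUE
  mag <- stats::runif(n, config$effect_log2fc_range[1],
                      config$effect_log2fc_range[2])
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  true_log2fc <- ifelse(is_de, sgn * mag, 0)

  groups <- factor(rep(c("control", "treated"), each = k),
                   levels = c("control", "treated"))
  fc <- 2^true_log2fc
  counts <- matrix(0L, nrow = n, ncol = n_samp)
  for (j in seq_len(n_samp)) {
    mu <- rel * library_sizes[j] * (if (groups[j] == "treated") fc else 1)
    counts[, j] <- if (config$nb_dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(n, lambda = mu)
    }
  }
  rownames(counts) <- sprintf("mir%04d", seq_len(n))
  colnames(counts) <- paste0(groups, "_", rep(seq_len(k), 2))
  truth <- data.frame(feature = rownames(counts), is_de = is_de,
                      true_log2fc = true_log2fc)
  list(counts = counts, groups = groups,
       library_sizes = as.integer(library_sizes), truth = truth)
}

#' Simulate a survival cohort with a prognostic expression signature
#'
#' Gene expression is standard normal; the signature score is the mean of
#' the planted signature genes, standardised across samples. Survival times
#' are exponential with hazard `baseline_hazard * exp(hazard_log_hr * z)`
#' (a proportional-hazards model with constant baseline). Censoring is
#' independent of the covariate: each sample is censored with probability
#' `censoring_rate`, at a uniform fraction of its event time.
#'
#' @param config A [sim_config()].
#' @param n_samples Cohort size.
#' @param n_genes Number of genes in the expression matrix.
#' @param signature_size Number of planted signature genes (default 10,
#'   capped at `n_genes`).
#' @return A list with `survival` (data frame: `sample_id`, `time`,
#'   `event`), `expression` (gene x sample matrix) and `truth` (signature
#'   gene names and true log hazard ratio).
#' @export
generate_survival_cohort <- function(config, n_samples, n_genes,
                                     signature_size = 10L) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  signature_size <- min(as.integer(signature_size), n_genes)
  expr <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
  rownames(expr) <- sprintf("GENE%04d", seq_len(n_genes))
  colnames(expr) <- sprintf("S%04d", seq_len(n_samples))
  sig_genes <- rownames(expr)[seq_len(signature_size)]

  z <- as.numeric(scale(colMeans(expr[sig_genes, , drop = FALSE])))
  rate <- config$baseline_hazard * exp(config$hazard_log_hr * z)
  t_event <- stats::rexp(n_samples, rate = rate)
  censored <- stats::runif(n_samples) < config$censoring_rate
  time <- ifelse(censored, stats::runif(n_samples) * t_event, t_event)
  event <- as.integer(!censored)

  list(
    survival = data.frame(sample_id = colnames(expr), time = time,
                          event = event),
    expression = expr,
    truth = list(signature_genes = sig_genes,
                 true_log_hr = config$hazard_log_hr)
  )
}

#' Simulate a cell-line panel with planted expression--response links
#'
#' Expression values are standard normal across cell lines. For planted
#' gene--drug pairs the drug response is `slope * expression + intercept`
#' plus Gaussian noise with SD `noise_cv`; all other responses are pure
#' standard-normal noise.
#'
#' @param config A [sim_config()].
#' @param n_lines Number of cell lines (>= 3).
#' @param n_genes Number of genes.
#' @param n_drugs Number of drugs.
#' @param planted Optional data frame (`gene`, `drug`, `slope`,
#'   `intercept`); each drug may appear at most once (a drug's response
#'   vector is linear in a single gene). Default: up to
#'   `round(de_fraction * n_genes)` gene--drug links, one per drug, with
#'   slope magnitudes uniform in `effect_log2fc_range`.
#' @return A list with `expression` (gene x line), `responses`
#'   (drug x line) and `truth` (the planted pair table).
#' @export
generate_cellline_panel <- function(config, n_lines = 20L, n_genes = 20L,
                                    n_drugs = 2L, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (n_lines < 3L) {
    stop("configuration error: n_lines must be >= 3", call. = FALSE)
  }
  set.seed(config$seed)
  expr <- matrix(stats::rnorm(n_genes * n_lines), nrow = n_genes)
  rownames(expr) <- sprintf("GENE%04d", seq_len(n_genes))
  colnames(expr) <- sprintf("LINE%02d", seq_len(n_lines))
  drugs <- sprintf("drug%02d", seq_len(n_drugs))

  if (is.null(planted)) {
    n_link <- min(round(config$de_fraction * n_genes), n_drugs)
    planted <- if (n_link > 0) {
      data.frame(
        gene = rownames(expr)[sample.int(n_genes, n_link)],
        drug = drugs[seq_len(n_link)],
        slope = sample(c(-1, 1), n_link, replace = TRUE) *
          stats::runif(n_link, config$effect_log2fc_range[1],
                       config$effect_log2fc_range[2]),
        intercept = stats::rnorm(n_link)
      )
    } else {
      data.frame(gene = character(), drug = character(),
                 slope = numeric(), intercept = numeric())
    }
  }
  if (anyDuplicated(planted$drug)) {
    stop("configuration error: each drug may appear at most once in 'planted'",
         call. = FALSE)
  }

  resp <- matrix(stats::rnorm(n_drugs * n_lines), nrow = n_drugs,
                 dimnames = list(drugs, colnames(expr)))
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      g <- planted$gene[i]
      d <- planted$drug[i]
      resp[d, ] <- planted$slope[i] * expr[g, ] + planted$intercept[i] +
        stats::rnorm(n_lines, sd = config$noise_cv)
    }
  }
  list(expression = expr, responses = resp, truth = planted)
}
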