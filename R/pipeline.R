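#' Default pipeline configuration
#'
#' A flat configuration driving [run_pipeline()]: simulation settings (or
#' paths to user-supplied tables), stage toggles and every numeric
#' threshold used downstream. Can be written to / read from YAML so a run
#' is fully described by one file.
#'
#' @param seed Master seed for all synthetic stages.
#' @param stages Named logical vector toggling stages (`cytokines`,
#'   `proteins`, `mirna`, `enrichment`, `survival`, `drugs`).
#' @param thresholds Named list of thresholds: `q_max`, `var_max`,
#'   `fc_min`, `mirna_fc`, `mirna_p`, `alpha`, `floor`, `gsea_fdr`.
#' @param sim Named list of [sim_config()] overrides.
#' @param n_perm GSEA permutation count.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c(cytokines = TRUE, proteins = TRUE,
                                       mirna = TRUE, enrichment = TRUE,
                                       survival = TRUE, drugs = TRUE),
                            thresholds = list(q_max = 0.05, var_max = 30,
                                              fc_min = 1.5, mirna_fc = 1.5,
                                              mirna_p = 0.05, alpha = 0.01,
                                              floor = 0.01, gsea_fdr = 0.05),
                            sim = list(),
                            n_perm = 500L) {
  structure(list(seed = as.integer(seed), stages = as.list(stages),
                 thresholds = thresholds, sim = sim,
                 n_perm = as.integer(n_perm)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file with (any subset of) the
#'   [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (nm in intersect(names(raw), c("seed", "n_perm"))) {
    base[[nm]] <- as.integer(raw[[nm]])
  }
  for (nm in intersect(names(raw), c("stages", "thresholds", "sim"))) {
    base[[nm]] <- utils::modifyList(base[[nm]], as.list(raw[[nm]]))
  }
  base
}

#' Run the secretome differential pipeline end to end
#'
#' Generates synthetic inputs from the configuration seed, then runs the
#' enabled stages in dependency order: cytokine-array scoring, label-free
#' protein differential statistics with the filter cascade, miRNA count
#' differential expression, gene-set enrichment on the miRNA ranking plus
#' overrepresentation of selected proteins, median-split signature
#' survival analysis and expression--drug-response regression. Every stage
#' writes plain TSV/JSON outputs under `output_dir`, and a run manifest
#' records the configuration hash and the MD5 checksum of every output so
#' deterministic re-runs are verifiable.
#'
#' @param config A [pipeline_config()], or a path to a YAML file.
#' @param output_dir Output directory (created if needed).
#' @return The manifest (invisibly), a list with `version`,
#'   `config_hash`, `thresholds`, `outputs` (file -> md5) and `created`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  st <- config$stages
  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  outputs <- character()
  emit <- function(obj, file) {
    path <- file.path(output_dir, file)
    if (is.data.frame(obj) || is.matrix(obj)) {
      write_tsv_file(obj, path)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    outputs <<- c(outputs, path)
    path
  }

  mirna_fit <- NULL
  cascade <- NULL

  if (isTRUE(st$cytokines)) {
    layout <- make_array_layout(n_analytes = cfg$n_analytes)
    mem <- generate_cytokine_membranes(cfg, layout)
    norm <- summarize_membrane(mem$spots, layout, floor = th$floor)
    trt <- norm[, grep("^treated_", colnames(norm)), drop = FALSE]
    ctl <- norm[, grep("^control_", colnames(norm)), drop = FALSE]
    stats_tab <- differential_cytokine_stats(trt, ctl, floor = th$floor)
    stats_tab$n_hits <- count_hits(stats_tab, hit_criteria(),
                                   treated = trt, control = ctl)
    emit(stats_tab, "cytokine_stats.tsv")
    emit(select_candidates(stats_tab, min_hits = 1), "cytokine_candidates.tsv")
  }

  if (isTRUE(st$proteins)) {
    prot <- generate_protein_abundances(cfg)
    stats_p <- compute_ratio_stats(prot$table)
    cascade <- filter_cascade(stats_p, q_max = th$q_max,
                              var_max = th$var_max, fc_min = th$fc_min)
    emit(cascade$results, "protein_results.tsv")
    emit(cascade$report, "protein_cascade.json")
    emit(volcano_table(cascade$results), "protein_volcano.tsv")
    abu <- as.matrix(prot$table[, grep("^(treated|control)_",
                                       names(prot$table))])
    rownames(abu) <- prot$table$accession
    pca <- pca_scores(abu)
    emit(data.frame(sample = rownames(pca$scores),
                    pca$scores[, 1:2, drop = FALSE]), "protein_pca.tsv")
  }

  if (isTRUE(st$mirna)) {
    mir <- generate_mirna_counts(cfg)
    counts <- mir$counts[rowSums(mir$counts) > 0, , drop = FALSE]
    design <- stats::model.matrix(~mir$groups)
    vm <- voom_transform(counts, tmm_factors(counts), design)
    mirna_fit <- moderated_t_fit(vm)
    emit(mirna_fit, "mirna_results.tsv")
    emit(filter_mirnas(mirna_fit, fc_threshold = th$mirna_fc,
                       p_threshold = th$mirna_p), "mirna_filtered.tsv")
  }

  if (isTRUE(st$enrichment) && !is.null(mirna_fit)) {
    metric <- stats::setNames(mirna_fit$t, mirna_fit$feature)
    # seeded demonstration collection drawn from the measured universe
    set.seed(config$seed + 1L)
    sets <- lapply(seq_len(8), function(i) {
      sample(names(metric), min(25, max(5, length(metric) %/% 20)))
    })
    names(sets) <- sprintf("SET%02d", seq_along(sets))
    gs <- gsea_preranked(metric, sets, n_perm = config$n_perm,
                         seed = config$seed, fdr_threshold = th$gsea_fdr)
    emit(gs, "gsea_results.tsv")
    if (!is.null(cascade)) {
      quantified <- cascade$results$accession[cascade$results$quantified]
      if (length(cascade$selected) > 0 && length(quantified) > 20) {
        set.seed(config$seed + 2L)
        psets <- lapply(seq_len(5), function(i) {
          sample(quantified, min(30, length(quantified) %/% 10))
        })
        names(psets) <- sprintf("PSET%02d", seq_along(psets))
        emit(ora_test(cascade$selected, quantified, psets),
             "ora_results.tsv")
      }
    }
  }

  if (isTRUE(st$survival)) {
    coh <- generate_survival_cohort(cfg, n_samples = 300, n_genes = 50)
    score <- signature_score(coh$expression, coh$truth$signature_genes)
    arms <- median_split(score)
    sr <- km_logrank_cox(coh$survival$time, coh$survival$event, arms)
    emit(sr$km, "survival_km.tsv")
    emit(list(hr = sr$hr, hr_ci = sr$hr_ci, logrank_chisq = sr$logrank_chisq,
              logrank_p = sr$logrank_p,
              arm_sizes = as.list(sr$arm_sizes)), "survival_summary.json")
  }

  if (isTRUE(st$drugs)) {
    panel <- generate_cellline_panel(cfg)
    assoc <- expression_response_regression(panel$expression,
                                            panel$responses,
                                            alpha = th$alpha)
    emit(assoc, "drug_associations.tsv")
  }

  manifest <- list(
    version = as.character(utils::packageVersion("secretodiff")),
    config_hash = hash_config(config),
    thresholds = th,
    seed = config$seed,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

# plain TSV writers/readers used across stage interfaces
write_tsv_file <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
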