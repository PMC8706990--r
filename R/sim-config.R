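#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into a single
#' validated object. A fixed `seed` makes every generator bit-reproducible.
#'
#' The defaults describe the study conditions the generators emulate: 3
#' biological replicates per group for label-free proteomics, 2 membranes per
#' condition for antibody arrays, a 10\% replicate coefficient of variation on
#' protein intensities (within the 10--20\% range typical of label-free
#' replicate quantification), negative-binomial miRNA counts with common
#' dispersion 0.1, exponential survival times under a proportional-hazards
#' effect of log 2 for the planted signature, and an intensity floor of 0.01
#' on normalised array values.
#'
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @param n_analytes Number of cytokine analytes on a membrane array.
#' @param n_proteins Number of proteins in the label-free table.
#' @param n_features Number of miRNA features in the count matrix.
#' @param n_replicates_per_group Biological replicates per condition for the
#'   proteomics and count generators (default 3).
#' @param array_replicates_per_group Independent membranes per condition for
#'   the cytokine-array generator (default 2).
#' @param de_fraction Proportion of features with a planted effect, in
#'   \[0, 1\]. `round(de_fraction * n)` is the planted-positive count.
#' @param effect_log2fc_range Length-2 ordered range of |log2 fold change|
#'   magnitudes for planted effects; the sign is random.
#' @param noise_cv Replicate-level coefficient of variation of intensities
#'   (proportion); also the residual standard deviation of planted
#'   gene--drug linear responses.
#' @param missing_fraction Fraction of protein abundances set missing.
#' @param mnar If `TRUE`, missingness is intensity-dependent (low-abundance
#'   biased) instead of completely at random.
#' @param library_size_range Length-2 ordered range of integer per-sample
#'   library sizes for the count generator.
#' @param nb_dispersion Negative-binomial dispersion (>= 0; 0 means Poisson).
#' @param baseline_hazard Constant baseline hazard of the survival generator.
#' @param hazard_log_hr True log hazard ratio per standard deviation of the
#'   signature score.
#' @param censoring_rate Expected fraction of censored samples, in \[0, 1).
#' @param floor Minimum normalised array intensity (positive; default 0.01).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_proteins = 100, de_fraction = 0.2)
#' cfg$n_proteins
#' @export
sim_config <- function(seed = 1L,
                       n_analytes = 80L,
                       n_proteins = 2000L,
                       n_features = 2000L,
                       n_replicates_per_group = 3L,
                       array_replicates_per_group = 2L,
                       de_fraction = 0.1,
                       effect_log2fc_range = c(1, 2.5),
                       noise_cv = 0.1,
                       missing_fraction = 0,
                       mnar = FALSE,
                       library_size_range = c(1e5L, 1e6L),
                       nb_dispersion = 0.1,
                       baseline_hazard = 0.1,
                       hazard_log_hr = log(2),
                       censoring_rate = 0.2,
                       floor = 0.01) {
  cfg <- list(
    seed = as.integer(seed),
    n_analytes = as.integer(n_analytes),
    n_proteins = as.integer(n_proteins),
    n_features = as.integer(n_features),
    n_replicates_per_group = as.integer(n_replicates_per_group),
    array_replicates_per_group = as.integer(array_replicates_per_group),
    de_fraction = de_fraction,
    effect_log2fc_range = as.numeric(effect_log2fc_range),
    noise_cv = noise_cv,
    missing_fraction = missing_fraction,
    mnar = isTRUE(mnar),
    library_size_range = as.numeric(library_size_range),
    nb_dispersion = nb_dispersion,
    baseline_hazard = baseline_hazard,
    hazard_log_hr = hazard_log_hr,
    censoring_rate = censoring_rate,
    floor = floor
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("configuration error: ", msg, call. = FALSE)
  if (is.na(cfg$seed)) stop_cfg("seed must be an integer")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop_cfg("de_fraction must be in [0, 1]")
  }
  if (cfg$missing_fraction < 0 || cfg$missing_fraction > 1) {
    stop_cfg("missing_fraction must be in [0, 1]")
  }
  for (nm in c("effect_log2fc_range", "library_size_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2]) {
      stop_cfg(paste(nm, "must be an ordered (low <= high) pair"))
    }
  }
  if (any(cfg$library_size_range != round(cfg$library_size_range))) {
    stop_cfg("library sizes must be integers")
  }
  if (cfg$library_size_range[1] < 1) stop_cfg("library sizes must be positive")
  if (cfg$noise_cv < 0) stop_cfg("noise_cv must be >= 0")
  if (cfg$nb_dispersion < 0) stop_cfg("nb_dispersion must be >= 0")
  if (cfg$baseline_hazard <= 0) stop_cfg("baseline_hazard must be positive")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    stop_cfg("censoring_rate must be in [0, 1)")
  }
  if (cfg$floor <= 0) stop_cfg("floor must be positive")
  if (cfg$n_replicates_per_group < 2L) {
    stop_cfg("n_replicates_per_group must be >= 2")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed", x$seed, ")\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ", "), "")
  for (nm in names(flat)) cat(sprintf("  %-26s %s\n", nm, flat[[nm]]))
  invisible(x)
}

# log2-scale SD giving a multiplicative coefficient of variation `cv`
# (log-normal identity CV^2 = exp(sigma_ln^2) - 1)
log2_sd_from_cv <- function(cv) {
  if (cv <= 0) return(0)
  sqrt(log(1 + cv^2)) / log(2)
}
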