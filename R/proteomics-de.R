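#' Per-protein ratio statistics for a label-free quantification table
#'
#' A protein is "quantified" when it has at least one valid abundance in
#' each group. For quantified proteins:
#' \itemize{
#'   \item `abundance_ratio` = mean(treated) / mean(control), with
#'     `log2_ratio` its log2;
#'   \item `ratio_variability_pct` = 100 * sd / mean of the treated/control
#'     ratios over all cross-group replicate pairs, a percent dispersion of
#'     replicate-level ratios (`NA` when fewer than two pairs exist);
#'   \item `anova_p` = one-way ANOVA p-value on log2 abundances across the
#'     two groups (for two groups this equals the squared pooled t-test,
#'     F = t^2). Identical groups give p = 1; `NA` when either group has
#'     fewer than two valid values.
#' }
#'
#' @param table Data frame with columns `accession`, `unique_peptides`,
#'   `high_conf`, and abundance columns named `<group>_<rep>` for groups
#'   `treated` and `control`; missing abundances as `NA`.
#' @param treated_cols,control_cols Optional explicit column names;
#'   defaults to columns matching `^treated_` / `^control_`.
#' @return Data frame with one row per protein: `accession`,
#'   `unique_peptides`, `high_conf`, `quantified`, `abundance_ratio`,
#'   `log2_ratio`, `ratio_variability_pct`, `anova_p`.
#' @export
compute_ratio_stats <- function(table, treated_cols = NULL,
                                control_cols = NULL) {
  if (is.null(treated_cols)) {
    treated_cols <- grep("^treated_", names(table), value = TRUE)
  }
  if (is.null(control_cols)) {
    control_cols <- grep("^control_", names(table), value = TRUE)
  }
  if (length(treated_cols) < 1 || length(control_cols) < 1) {
    stop("need at least one replicate column per group", call. = FALSE)
  }
  if (anyDuplicated(table$accession)) {
    stop("accessions must be unique", call. = FALSE)
  }
  tm <- as.matrix(table[, treated_cols, drop = FALSE])
  cm <- as.matrix(table[, control_cols, drop = FALSE])
  n <- nrow(table)

  res <- data.frame(
    accession = table$accession,
    unique_peptides = if (!is.null(table$unique_peptides)) {
      table$unique_peptides
    } else rep(NA_integer_, n),
    high_conf = if (!is.null(table$high_conf)) {
      as.logical(table$high_conf)
    } else rep(NA, n),
    quantified = rep(FALSE, n),
    abundance_ratio = rep(NA_real_, n),
    log2_ratio = rep(NA_real_, n),
    ratio_variability_pct = rep(NA_real_, n),
    anova_p = rep(NA_real_, n)
  )
  for (i in seq_len(n)) {
    tv <- tm[i, !is.na(tm[i, ])]
    cv <- cm[i, !is.na(cm[i, ])]
    if (length(tv) < 1 || length(cv) < 1) next
    res$quantified[i] <- TRUE
    r <- mean(tv) / mean(cv)
    res$abundance_ratio[i] <- r
    res$log2_ratio[i] <- log2(r)
    pairs <- as.vector(outer(tv, cv, "/"))
    if (length(pairs) >= 2) {
      res$ratio_variability_pct[i] <- 100 * stats::sd(pairs) / mean(pairs)
    }
    if (length(tv) >= 2 && length(cv) >= 2) {
      res$anova_p[i] <- oneway_anova_p(log2(tv), log2(cv))
    }
  }
  res
}

# One-way ANOVA p for two groups with degenerate-input handling:
# no between-group signal -> p = 1; zero within-group variance with
# different means -> p = 0.
oneway_anova_p <- function(x, y) {
  vals <- c(x, y)
  grp <- factor(rep(c("a", "b"), c(length(x), length(y))))
  if (mean(x) == mean(y)) return(1)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) return(0)
  p <- tryCatch(stats::oneway.test(vals ~ grp, var.equal = TRUE)$p.value,
                error = function(e) NA_real_)
  if (is.nan(p)) p <- NA_real_
  p
}

#' Benjamini--Hochberg adjusted p-values (q-values)
#'
#' Step-up false-discovery-rate adjustment. `NA` p-values are propagated
#' (they do not enter the adjustment of the others); p-values outside
#' \[0, 1\] are an error. Adjusted values are monotone non-decreasing in
#' p-rank and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\], `NA` allowed.
#' @return Numeric vector of adjusted values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Apply the differential-abundance filter cascade
#'
#' Stages, each strict and applied on top of the previous one:
#' identification (high-confidence flag and a minimum unique-peptide
#' count), quantification (valid abundances in both groups), q-value
#' (Benjamini--Hochberg over the quantified proteins' ANOVA p-values)
#' `< q_max`, ratio variability `< var_max` percent, and a symmetric fold
#' change `max(ratio, 1/ratio) > fc_min`. Selected proteins split into
#' up- (ratio > 1) and downregulated (ratio < 1).
#'
#' @param results Data frame as from [compute_ratio_stats()].
#' @param q_max q-value threshold (default 0.05, strict `<`).
#' @param var_max Ratio-variability threshold in percent (default 30,
#'   strict `<`).
#' @param fc_min Fold-change threshold (default 1.5, strict `>` on
#'   `max(ratio, 1/ratio)`).
#' @param min_unique_peptides Minimum unique peptides (default 1).
#' @param require_high_confidence Require the high-confidence flag
#'   (default TRUE).
#' @return A list with `results` (input plus `q_value`, stage flags
#'   `identified`, `q_pass`, `var_pass`, `fc_pass`, `selected` and
#'   `direction`), `selected` (accessions) and `report` (stage counts:
#'   `identified`, `quantified`, `q_lt`, `var_lt`, `selected`, `up`,
#'   `down`).
#' @export
filter_cascade <- function(results, q_max = 0.05, var_max = 30,
                           fc_min = 1.5, min_unique_peptides = 1,
                           require_high_confidence = TRUE) {
  r <- results
  n <- nrow(r)
  identified <- rep(TRUE, n)
  if (require_high_confidence && !is.null(r$high_conf)) {
    identified <- identified & !is.na(r$high_conf) & r$high_conf
  }
  if (!is.null(r$unique_peptides)) {
    identified <- identified & !is.na(r$unique_peptides) &
      r$unique_peptides >= min_unique_peptides
  }
  quantified <- identified & r$quantified

  r$q_value <- rep(NA_real_, n)
  r$q_value[quantified] <- benjamini_hochberg(r$anova_p[quantified])

  q_pass <- quantified & !is.na(r$q_value) & r$q_value < q_max
  var_pass <- q_pass & !is.na(r$ratio_variability_pct) &
    r$ratio_variability_pct < var_max
  fc_sym <- pmax(r$abundance_ratio, 1 / r$abundance_ratio)
  fc_pass <- var_pass & !is.na(fc_sym) & fc_sym > fc_min
  selected <- fc_pass

  r$identified <- identified
  r$q_pass <- q_pass
  r$var_pass <- var_pass
  r$fc_pass <- fc_pass
  r$selected <- selected
  r$direction <- ifelse(!selected, "none",
                        ifelse(r$abundance_ratio > 1, "up", "down"))

  report <- list(
    identified = sum(identified),
    quantified = sum(quantified),
    q_lt = sum(q_pass),
    var_lt = sum(var_pass),
    selected = sum(selected),
    up = sum(selected & r$abundance_ratio > 1),
    down = sum(selected & r$abundance_ratio < 1)
  )
  list(results = r, selected = r$accession[selected], report = report)
}

#' Principal-component scores of an abundance matrix
#'
#' Column-centred SVD (no scaling) of the sample-by-protein matrix.
#' Missing abundances are imputed with the protein-wise minimum (a
#' left-censoring-flavoured default for label-free data) or the protein is
#' dropped (`missing = "drop"`). The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making the rotation
#' deterministic.
#'
#' @param abundance Numeric matrix, proteins x samples.
#' @param missing Either `"impute_min"` (default) or `"drop"`.
#' @return A list with `scores` (samples x PCs), `loadings`
#'   (proteins x PCs) and `variance_explained` (non-increasing, sums
#'   to <= 1).
#' @export
pca_scores <- function(abundance, missing = c("impute_min", "drop")) {
  missing <- match.arg(missing)
  m <- as.matrix(abundance)
  if (missing == "drop") {
    m <- m[stats::complete.cases(m), , drop = FALSE]
  } else if (anyNA(m)) {
    for (i in which(apply(m, 1, anyNA))) {
      v <- m[i, ]
      if (all(is.na(v))) next
      v[is.na(v)] <- min(v, na.rm = TRUE)
      m[i, ] <- v
    }
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  x <- t(m)
  if (all(apply(x, 2, stats::sd) == 0)) {
    stop("zero variance: abundance matrix is constant", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    l[which.max(abs(l))] < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip, drop = FALSE]
  pc$x[, flip] <- -pc$x[, flip, drop = FALSE]
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Volcano-plot coordinates
#'
#' Maps each protein to `(log2_ratio, -log10 p)` with its selection label,
#' ready for plotting.
#'
#' @param results Data frame with `accession`, `log2_ratio`, a p-value
#'   column and optionally `selected`.
#' @param p_col Name of the p-value column (default `"anova_p"`).
#' @return Data frame with `accession`, `log2_ratio`, `neg_log10_p`,
#'   `selected`.
#' @export
volcano_table <- function(results, p_col = "anova_p") {
  data.frame(
    accession = results$accession,
    log2_ratio = results$log2_ratio,
    neg_log10_p = -log10(results[[p_col]]),
    selected = if (!is.null(results$selected)) results$selected else FALSE
  )
}
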