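#' Trimmed-mean-of-M-values normalisation factors
#'
#' Between-sample scaling factors for a count matrix. The reference sample
#' is the one whose 75th-percentile counts-per-million is closest to the
#' mean of those percentiles. For every sample, per-feature log2 expression
#' ratios against the reference (M-values) and average log2 expressions
#' (A-values) are computed on features with positive counts in both
#' samples; the upper and lower 30\% of M and 5\% of A are trimmed, and the
#' factor is 2 to the power of the weighted mean of the remaining M-values,
#' weighted by the inverse asymptotic (binomial) variance of M. Factors are
#' rescaled so their product is 1, which makes them invariant to arbitrary
#' per-sample count scaling.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param logratio_trim Two-sided trim fraction on M (default 0.3).
#' @param sum_trim Two-sided trim fraction on A (default 0.05).
#' @return Numeric vector of per-sample factors, product 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample in count matrix", call. = FALSE)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]

  cpm <- t(t(counts) / lib) * 1e6
  uq <- apply(cpm, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, sum_trim)
  }, numeric(1))
  f / exp(mean(log(f)))
}

# trimmed weighted mean of M-values of one sample against the reference
tmm_pair <- function(y, yr, n, nr, logratio_trim, sum_trim) {
  pos <- y > 0 & yr > 0
  y <- y[pos]; yr <- yr[pos]
  if (length(y) == 0) return(1)
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  # asymptotic (delta-method binomial) variance of M; weights are 1/v
  v <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  if (max(abs(m)) < 1e-6) return(1)
  nn <- length(m)
  lo_m <- floor(nn * logratio_trim) + 1
  hi_m <- nn + 1 - lo_m
  lo_a <- floor(nn * sum_trim) + 1
  hi_a <- nn + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  f <- 2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  if (!is.finite(f)) 1 else f
}

#' Precision-weight transformation of counts
#'
#' Converts counts to log2 counts-per-million,
#' `log2((count + 0.5) / (libsize * factor + 1) * 1e6)`, fits the group
#' design per feature by least squares, estimates the mean--variance trend
#' by a locally weighted regression (lowess, span 0.5) of the square-root
#' residual standard deviation on average log2 count, and assigns each
#' observation the inverse fourth power of the trend value at its fitted
#' log2 count as a precision weight.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @param factors Per-sample normalisation factors (e.g. [tmm_factors()]).
#' @param design Design matrix (samples x coefficients), e.g.
#'   `model.matrix(~ group)`; must leave at least one residual degree of
#'   freedom.
#' @return A list of class `voom_output` with `E` (log2-CPM matrix),
#'   `weights` (same shape), `design`, `lib_size` (effective library
#'   sizes) and `trend` (the lowess curve points).
#' @export
voom_transform <- function(counts, factors, design) {
  counts <- as.matrix(counts)
  design <- as.matrix(design)
  n_samp <- ncol(counts)
  if (nrow(design) != n_samp) {
    stop("design rows must match samples", call. = FALSE)
  }
  if (n_samp <= ncol(design)) {
    stop("fewer samples than design columns leaves no residual df",
         call. = FALSE)
  }
  lib <- colSums(counts) * factors
  y <- t(log2(t(counts + 0.5) / (lib + 1) * 1e6))

  fit <- stats::lm.fit(design, t(y))
  coefs <- t(fit$coefficients)               # features x p
  df_resid <- n_samp - fit$rank
  res <- t(fit$residuals)                    # features x samples
  sigma <- sqrt(rowSums(res^2) / df_resid)

  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  if (length(unique(sx)) < 2 || diff(range(sy)) == 0) {
    # degenerate trend (e.g. constant matrix): uninformative equal weights
    const <- max(mean(sy), 1)
    l <- list(x = range(sx), y = rep(const, 2))
    trend_fun <- function(z) rep(const, length(z))
  } else {
    l <- stats::lowess(sx, sy, f = 0.5)
    trend_fun <- stats::approxfun(l, rule = 2, ties = mean)
  }

  fitted_logcpm <- coefs %*% t(design)
  fitted_count <- 1e-6 * t(t(2^fitted_logcpm) * (lib + 1))
  fitted_logcount <- log2(fitted_count)
  w <- matrix(trend_fun(fitted_logcount), nrow = nrow(counts))^(-4)
  dimnames(y) <- dimnames(counts)
  dimnames(w) <- dimnames(counts)
  structure(list(E = y, weights = w, design = design, lib_size = lib,
                 trend = l),
            class = "voom_output")
}

#' Empirical-Bayes moderated t-statistics
#'
#' Per-feature weighted least squares on the precision-weighted log2-CPM,
#' followed by empirical-Bayes variance moderation: the prior degrees of
#' freedom `d0` and prior variance `s0^2` are estimated by moment matching
#' on the log residual variances (the scaled-F / log-variance identities,
#' with the trigamma equation inverted by bisection to 1e-8), the
#' posterior variance is `(d0 s0^2 + d s^2) / (d0 + d)` and the moderated
#' t for the chosen coefficient is referred to a t distribution on
#' `d0 + d` degrees of freedom (two-tailed). Adjusted p-values are
#' Benjamini--Hochberg.
#'
#' @param voom A `voom_output` from [voom_transform()].
#' @param coef Index of the design coefficient to test (default 2, the
#'   group effect in `~ group` designs).
#' @return Data frame with one row per feature: `feature`, `logFC`, `t`,
#'   `p_value`, `adj_p_value`, `s2`, `s2_post`, `residual_df`; attributes
#'   `d0` (prior df) and `s0_2` (prior variance).
#' @export
moderated_t_fit <- function(voom, coef = 2L) {
  stopifnot(inherits(voom, "voom_output"))
  y <- voom$E
  w <- voom$weights
  x <- voom$design
  n <- ncol(y)
  p <- ncol(x)
  df <- n - p
  if (df < 1) stop("no residual degrees of freedom", call. = FALSE)

  ng <- nrow(y)
  beta <- numeric(ng)
  v_unscaled <- numeric(ng)
  s2 <- numeric(ng)
  for (g in seq_len(ng)) {
    wg <- w[g, ]
    fitg <- stats::lm.wfit(x, y[g, ], wg)
    beta[g] <- fitg$coefficients[coef]
    xtwx_inv <- chol2inv(chol(crossprod(x * sqrt(wg))))
    v_unscaled[g] <- xtwx_inv[coef, coef]
    s2[g] <- sum(wg * fitg$residuals^2) / df
  }

  ok <- s2 > 0
  if (!any(ok)) stop("cannot moderate: all residual variances are zero",
                     call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- stats::var(e) - trigamma(df / 2)
  if (is.finite(e_var) && e_var > 0) {
    d0 <- 2 * trigamma_inverse(e_var)
    s0_2 <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion in the log variances: infinite prior df, the
    # prior variance is the plain average of the sample variances
    d0 <- Inf
    s0_2 <- mean(s2[ok])
  }

  s2_post <- if (is.infinite(d0)) {
    rep(s0_2, ng)
  } else {
    (d0 * s0_2 + df * s2) / (d0 + df)
  }
  t_mod <- beta / sqrt(s2_post * v_unscaled)
  df_total <- min(d0 + df, 1e300)
  p_val <- 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- data.frame(
    feature = if (!is.null(rownames(y))) rownames(y) else
      sprintf("f%05d", seq_len(ng)),
    logFC = beta, t = t_mod, p_value = p_val,
    adj_p_value = benjamini_hochberg(p_val),
    s2 = s2, s2_post = s2_post, residual_df = df
  )
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

# solve trigamma(x) = y by bisection (trigamma is strictly decreasing)
trigamma_inverse <- function(y, tol = 1e-8) {
  if (y <= 0) return(Inf)
  lo <- 1e-8
  hi <- 1e8
  # expand bounds defensively (trigamma(1e-8) is huge, trigamma(1e8) tiny)
  if (trigamma(lo) < y || trigamma(hi) > y) return(1 / sqrt(y))
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Filter differential miRNAs by fold change and p-value
#'
#' Keeps features with `|logFC| > log2(fc_threshold)` and raw
#' `p < p_threshold` (both strict; raw rather than adjusted p is gated
#' here, with the adjusted value still reported). Upregulated features are
#' sorted by descending logFC, downregulated by ascending logFC
#' (strongest effects first on both sides).
#'
#' @param results Data frame as from [moderated_t_fit()] (needs `logFC`
#'   and `p_value`).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @return Filtered, ordered data frame with a `direction` column.
#' @export
filter_mirnas <- function(results, fc_threshold = 1.5, p_threshold = 0.05) {
  keep <- abs(results$logFC) > log2(fc_threshold) &
    !is.na(results$p_value) & results$p_value < p_threshold
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  up <- out[out$direction == "up", , drop = FALSE]
  dn <- out[out$direction == "down", , drop = FALSE]
  up <- up[order(-up$logFC), , drop = FALSE]
  dn <- dn[order(dn$logFC), , drop = FALSE]
  out <- rbind(up, dn)
  rownames(out) <- NULL
  out
}

#' Published secreted-miRNA differential-expression screen
#'
#' The nine miRNAs reported as differentially secreted (|FC| > 1.5, raw
#' p < 0.05) by treated fibroblasts, with their log2 fold changes and
#' p-values as printed. Used as a worked reference for the filter gate of
#' this module.
#'
#' @return Data frame with columns `mirna`, `logFC`, `p_value`.
#' @examples
#' mirna_screen()
#' @export
mirna_screen <- function() {
  path <- system.file("extdata", "mirna_screen_table.tsv",
                      package = "secretodiff", mustWork = TRUE)
  utils::read.delim(path)
}
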