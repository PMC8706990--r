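#' Per-sample signature score
#'
#' The arithmetic mean expression of the listed genes in each sample.
#' Listed genes absent from the matrix are reported via a message and
#' skipped; if none are present this is an error.
#'
#' @param expression Numeric matrix, genes x samples, with row names.
#' @param gene_list Character vector of gene identifiers.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expression, gene_list) {
  present <- intersect(gene_list, rownames(expression))
  if (length(present) == 0) {
    stop("none of the listed genes are present in the expression matrix",
         call. = FALSE)
  }
  missing <- setdiff(gene_list, present)
  if (length(missing) > 0) {
    message("signature_score: ", length(missing),
            " listed gene(s) absent: ", paste(missing, collapse = ", "))
  }
  colMeans(expression[present, , drop = FALSE])
}

#' Split samples at the median score
#'
#' Samples strictly above the median are labelled `high`, the rest `low`
#' (median ties go to the low arm, the deterministic convention of
#' median-split survival plotters). Constant scores cannot be split.
#'
#' @param scores Numeric vector (length >= 2).
#' @return Factor with levels `low`, `high`, same length and names.
#' @examples
#' median_split(c(1, 2, 2, 4))  # low, low, low, high
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples", call. = FALSE)
  med <- stats::median(scores)
  if (all(scores == scores[1])) {
    stop("constant scores: median split impossible", call. = FALSE)
  }
  arms <- factor(ifelse(scores > med, "high", "low"),
                 levels = c("low", "high"))
  names(arms) <- names(scores)
  arms
}

#' Kaplan--Meier curves, log-rank test and Cox hazard ratio for two arms
#'
#' Product-limit survival estimate per arm, the two-sample log-rank test
#' (1-df chi-square, two-sided), and a univariate Cox proportional-hazards
#' fit on the arm indicator (Efron tie handling) giving the high-vs-low
#' hazard ratio with a 95\% Wald confidence interval.
#'
#' When a continuous `score` is supplied, a second univariate Cox fit on
#' the (standardised) score is returned alongside the arm-level fit. The
#' arm-level hazard ratio is a between-arm contrast and is attenuated
#' relative to the per-standard-deviation effect of the underlying score
#' (dichotomisation discards within-arm variation), so recovery of a
#' planted per-SD log hazard ratio must use the score fit.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (0 = censored, 1 = event).
#' @param arms Factor with levels `low`, `high` (see [median_split()]).
#' @param score Optional continuous per-sample score; adds `score_beta`
#'   and `score_se` (Cox coefficient per SD of the score) to the result.
#' @return A list of class `survival_result`: `km` (data frame of
#'   step-function points `arm`, `time`, `surv`, `n_risk`),
#'   `logrank_chisq`, `logrank_p`, `hr`, `hr_ci` (length-2), `cox_beta`,
#'   `cox_se`, `arm_sizes`, and optionally `score_beta`, `score_se`.
#' @export
km_logrank_cox <- function(time, event, arms, score = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(arms))
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  arms <- factor(arms, levels = c("low", "high"))
  if (any(table(arms) == 0)) stop("both arms must be non-empty",
                                  call. = FALSE)
  ev_by_arm <- tapply(event, arms, sum)
  if (any(ev_by_arm == 0)) {
    stop("both arms must contain at least one event", call. = FALSE)
  }

  sf <- survival::survfit(survival::Surv(time, event) ~ arms)
  strata_arm <- sub("^arms=", "", rep(names(sf$strata), sf$strata))
  km <- data.frame(arm = strata_arm, time = sf$time, surv = sf$surv,
                   n_risk = sf$n.risk)

  sd <- survival::survdiff(survival::Surv(time, event) ~ arms)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  cx <- survival::coxph(survival::Surv(time, event) ~ arms,
                        ties = "efron")
  beta <- unname(stats::coef(cx)[1])
  se <- sqrt(stats::vcov(cx)[1, 1])

  score_beta <- score_se <- NULL
  if (!is.null(score)) {
    z <- as.numeric(scale(score))
    cz <- survival::coxph(survival::Surv(time, event) ~ z, ties = "efron")
    score_beta <- unname(stats::coef(cz)[1])
    score_se <- sqrt(stats::vcov(cz)[1, 1])
  }

  structure(list(
    km = km,
    score_beta = score_beta,
    score_se = score_se,
    logrank_chisq = chisq,
    logrank_p = p,
    hr = exp(beta),
    hr_ci = exp(beta + c(-1, 1) * 1.96 * se),
    cox_beta = beta,
    cox_se = se,
    arm_sizes = table(arms)
  ), class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("median-split survival: n(low)=%d n(high)=%d\n",
              x$arm_sizes[["low"]], x$arm_sizes[["high"]]))
  cat(sprintf("  HR (high vs low) = %.3f [%.3f, %.3f]\n",
              x$hr, x$hr_ci[1], x$hr_ci[2]))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g\n",
              x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' Gene-by-drug linear regression of expression on drug response
#'
#' Ordinary least squares of each drug's response on each gene's
#' expression across the common cell lines, with the regression F test:
#' `F = (R^2 / (1 - R^2)) * (n - 2)` on (1, n - 2) degrees of freedom.
#' Pairs are flagged significant at `p < alpha`. Zero-variance predictors
#' give an undefined (NA) fit and are never flagged.
#'
#' @param expression Numeric matrix, genes x cell lines.
#' @param responses Numeric matrix, drugs x cell lines.
#' @param alpha Significance threshold on the ANOVA p-value (default
#'   0.01).
#' @return Data frame with one row per gene--drug pair: `gene`, `drug`,
#'   `n`, `slope`, `intercept`, `r_squared`, `f_statistic`, `p_value`,
#'   `significant`.
#' @export
expression_response_regression <- function(expression, responses,
                                           alpha = 0.01) {
  lines_common <- intersect(colnames(expression), colnames(responses))
  if (length(lines_common) < 3) {
    stop("need at least 3 cell lines with both expression and response",
         call. = FALSE)
  }
  expression <- expression[, lines_common, drop = FALSE]
  responses <- responses[, lines_common, drop = FALSE]

  grid <- expand.grid(gene = rownames(expression),
                      drug = rownames(responses),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- as.numeric(expression[grid$gene[i], ])
    y <- as.numeric(responses[grid$drug[i], ])
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || stats::var(x) == 0) {
      return(data.frame(gene = grid$gene[i], drug = grid$drug[i], n = n,
                        slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, f_statistic = NA_real_,
                        p_value = NA_real_, significant = FALSE))
    }
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    slope <- sxy / sxx
    intercept <- mean(y) - slope * mean(x)
    syy <- sum((y - mean(y))^2)
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
    f <- if (r2 < 1) r2 / (1 - r2) * (n - 2) else Inf
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
    data.frame(gene = grid$gene[i], drug = grid$drug[i], n = n,
               slope = slope, intercept = intercept, r_squared = r2,
               f_statistic = f, p_value = p,
               significant = !is.na(p) & p < alpha)
  })
  do.call(rbind, rows)
}
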