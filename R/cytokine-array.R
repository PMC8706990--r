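#' Summarise raw membrane spots into per-analyte normalised intensities
#'
#' For every membrane: duplicate spots of each analyte are averaged, the
#' mean NEG-spot background is subtracted, and the result is divided by the
#' background-corrected mean POS-spot intensity, so POS maps to 1 and the
#' values are comparable between membranes regardless of exposure. Values
#' are clipped below at `floor`, the minimum reportable normalised
#' intensity (this truncation protects the subsequent log2 fold changes
#' from vanishing denominators).
#'
#' Because of the POS scaling, multiplying all raw intensities of a
#' membrane by any k > 0 leaves the result unchanged.
#'
#' @param spots Data frame of raw spot intensities with columns
#'   `membrane_id`, `row`, `col`, `intensity` (non-negative).
#' @param layout Array layout (see [make_array_layout()]).
#' @param floor Minimum normalised intensity (default 0.01).
#' @return Numeric matrix, analytes x membranes, of normalised floored
#'   intensities.
#' @export
summarize_membrane <- function(spots, layout, floor = 0.01) {
  layout <- validate_layout(layout)
  req <- c("membrane_id", "row", "col", "intensity")
  if (!all(req %in% names(spots))) {
    stop("spots must have columns membrane_id, row, col, intensity",
         call. = FALSE)
  }
  if (any(spots$intensity < 0, na.rm = TRUE)) {
    stop("raw spot intensities must be non-negative", call. = FALSE)
  }
  key <- paste(layout$row, layout$col)
  analytes <- unique(layout$name[layout$role == "analyte"])
  membranes <- unique(spots$membrane_id)
  out <- matrix(NA_real_, nrow = length(analytes), ncol = length(membranes),
                dimnames = list(analytes, membranes))
  for (m in membranes) {
    sub <- spots[spots$membrane_id == m, ]
    idx <- match(paste(sub$row, sub$col), key)
    if (anyNA(idx)) stop("spot coordinates not covered by layout",
                         call. = FALSE)
    role <- layout$role[idx]
    name <- layout$name[idx]
    bg <- if (any(role == "NEG")) mean(sub$intensity[role == "NEG"]) else 0
    pos <- mean(sub$intensity[role == "POS"])
    if (!is.finite(pos) || pos <= bg) {
      stop("normalization error: POS mean <= NEG background on membrane ", m,
           call. = FALSE)
    }
    is_an <- role == "analyte"
    means <- tapply(sub$intensity[is_an], name[is_an], mean)
    out[names(means), m] <- pmax((means - bg) / (pos - bg), floor)
  }
  out
}

#' Differential metrics from treated and control mean intensities
#'
#' Vectorised closed-form metrics used throughout the cytokine module:
#' differential intensity (treated - control), fold change
#' (treated / control), relative fold change (fold change - 1) and log2
#' fold change. Means are floored at `floor` first, so the identities
#' `relative_fold_change == 2^log2_fc - 1` and
#' `differential_intensity == mean_control * relative_fold_change` hold
#' exactly.
#'
#' @param mean_treated,mean_control Numeric vectors of mean normalised
#'   intensities.
#' @param floor Minimum intensity (default 0.01).
#' @return Data frame with columns `mean_treated`, `mean_control`,
#'   `differential_intensity`, `fold_change`, `relative_fold_change`,
#'   `log2_fc`.
#' @examples
#' cytokine_metrics(0.3199, 0.4530)  # differential -0.1331, log2 FC -0.5019
#' @export
cytokine_metrics <- function(mean_treated, mean_control, floor = 0.01) {
  mt <- pmax(mean_treated, floor)
  mc <- pmax(mean_control, floor)
  fc <- mt / mc
  data.frame(
    mean_treated = mt,
    mean_control = mc,
    differential_intensity = mt - mc,
    fold_change = fc,
    relative_fold_change = fc - 1,
    log2_fc = log2(fc)
  )
}

#' Per-analyte differential statistics between treated and control membranes
#'
#' Computes, for every analyte, the mean normalised intensity of the
#' treated and control replicates (floored), a two-tailed two-sample
#' Student t-test p-value (pooled variance by default; Welch via
#' `welch = TRUE`) and the differential metrics of [cytokine_metrics()].
#' The p-value is `NA` when either condition has fewer than two replicates
#' or when both conditions are constant (e.g. both sitting at the floor),
#' in which case no variance estimate exists.
#'
#' @param treated,control Numeric matrices (analytes x replicates) of
#'   normalised intensities, with matching row names; values >= `floor`.
#' @param floor Minimum intensity (default 0.01).
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance Student test.
#' @return Data frame with one row per analyte: `analyte`, `mean_treated`,
#'   `mean_control`, `p_value`, `differential_intensity`, `fold_change`,
#'   `relative_fold_change`, `log2_fc`.
#' @export
differential_cytokine_stats <- function(treated, control, floor = 0.01,
                                        welch = FALSE) {
  treated <- as.matrix(treated)
  control <- as.matrix(control)
  if (nrow(treated) == 0 || ncol(treated) < 1 || ncol(control) < 1) {
    stop("at least one replicate per condition is required", call. = FALSE)
  }
  if (!identical(rownames(treated), rownames(control))) {
    stop("treated and control must have identical analyte row names",
         call. = FALSE)
  }
  p <- vapply(seq_len(nrow(treated)), function(i) {
    t_i <- treated[i, ]
    c_i <- control[i, ]
    if (length(t_i) < 2 || length(c_i) < 2) return(NA_real_)
    if (stats::sd(t_i) == 0 && stats::sd(c_i) == 0) return(NA_real_)
    tryCatch(stats::t.test(t_i, c_i, var.equal = !welch)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  met <- cytokine_metrics(rowMeans(treated), rowMeans(control), floor = floor)
  data.frame(
    analyte = rownames(treated),
    mean_treated = met$mean_treated,
    mean_control = met$mean_control,
    p_value = p,
    differential_intensity = met$differential_intensity,
    fold_change = met$fold_change,
    relative_fold_change = met$relative_fold_change,
    log2_fc = met$log2_fc,
    row.names = NULL
  )
}

#' Hit-count criteria for differential cytokines
#'
#' Thresholds for the parameters on which an analyte can score a "hit":
#' t-test p-value, |differential intensity|, |relative fold change|,
#' |log2 fold change|, fold-change magnitude (`max(FC, 1/FC)`), and
#' replicate sign agreement (every treated replicate differs from every
#' control replicate in the same direction; requires replicate matrices).
#' Set any threshold to `NA` to disable that criterion. The defaults are a
#' documented convention, fully configurable; they are not claimed to
#' regenerate any published hit column.
#'
#' @param p_max Maximum p-value (default 0.05).
#' @param min_abs_differential Minimum |differential intensity| (0.05).
#' @param min_abs_relative_fc Minimum |relative fold change| (0.20).
#' @param min_abs_log2_fc Minimum |log2 FC| (0.32, i.e. FC 1.25).
#' @param require_sign_agreement Count a hit when all treated-vs-control
#'   replicate differences share one sign (default TRUE).
#' @return An object of class `hit_criteria`.
#' @export
hit_criteria <- function(p_max = 0.05,
                         min_abs_differential = 0.05,
                         min_abs_relative_fc = 0.20,
                         min_abs_log2_fc = 0.32,
                         require_sign_agreement = TRUE) {
  chk <- function(x, nm) {
    if (!is.na(x) && x < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  if (!is.na(p_max) && (p_max <= 0 || p_max > 1)) {
    stop("p_max must be in (0, 1]", call. = FALSE)
  }
  chk(min_abs_differential, "min_abs_differential")
  chk(min_abs_relative_fc, "min_abs_relative_fc")
  chk(min_abs_log2_fc, "min_abs_log2_fc")
  structure(list(p_max = p_max,
                 min_abs_differential = min_abs_differential,
                 min_abs_relative_fc = min_abs_relative_fc,
                 min_abs_log2_fc = min_abs_log2_fc,
                 require_sign_agreement = isTRUE(require_sign_agreement)),
            class = "hit_criteria")
}

#' Count the criteria each analyte satisfies
#'
#' @param stats Data frame as from [differential_cytokine_stats()].
#' @param criteria A [hit_criteria()] object.
#' @param treated,control Optional replicate matrices (analytes x
#'   replicates) enabling the sign-agreement criterion; when omitted that
#'   criterion is skipped.
#' @return Integer vector of hit counts, one per row of `stats`; each count
#'   is between 0 and the number of enabled criteria.
#' @export
count_hits <- function(stats, criteria = hit_criteria(), treated = NULL,
                       control = NULL) {
  stopifnot(inherits(criteria, "hit_criteria"))
  n <- nrow(stats)
  hits <- integer(n)
  if (!is.na(criteria$p_max)) {
    hits <- hits + as.integer(!is.na(stats$p_value) &
                                stats$p_value < criteria$p_max)
  }
  if (!is.na(criteria$min_abs_differential)) {
    hits <- hits + as.integer(abs(stats$differential_intensity) >=
                                criteria$min_abs_differential)
  }
  if (!is.na(criteria$min_abs_relative_fc)) {
    hits <- hits + as.integer(abs(stats$relative_fold_change) >=
                                criteria$min_abs_relative_fc)
  }
  if (!is.na(criteria$min_abs_log2_fc)) {
    hits <- hits + as.integer(abs(stats$log2_fc) >= criteria$min_abs_log2_fc)
  }
  if (criteria$require_sign_agreement && !is.null(treated) &&
      !is.null(control)) {
    agree <- vapply(seq_len(n), function(i) {
      d <- as.vector(outer(as.numeric(treated[i, ]),
                           as.numeric(control[i, ]), "-"))
      all(d > 0) || all(d < 0)
    }, logical(1))
    hits <- hits + as.integer(agree)
  }
  hits
}

#' Rank and select candidate analytes
#'
#' Deterministic ranking by descending hit count, then descending
#' |log2 fold change|, with remaining ties broken by analyte name
#' (ascending). Optionally caps the list at `n_max` and/or requires a
#' minimum hit count.
#'
#' @param stats Data frame with at least `analyte`, `log2_fc` and `n_hits`
#'   columns (add `n_hits` with [count_hits()] if absent; missing `n_hits`
#'   is treated as all-zero).
#' @param n_max Optional cap on the number of analytes returned.
#' @param min_hits Optional minimum `n_hits` to be eligible.
#' @return The selected rows of `stats`, ranked.
#' @export
select_candidates <- function(stats, n_max = NULL, min_hits = NULL) {
  if (nrow(stats) == 0) return(stats)
  if (is.null(stats$n_hits)) stats$n_hits <- 0L
  ord <- order(-stats$n_hits, -abs(stats$log2_fc), stats$analyte)
  out <- stats[ord, , drop = FALSE]
  if (!is.null(min_hits)) out <- out[out$n_hits >= min_hits, , drop = FALSE]
  if (!is.null(n_max)) out <- utils::head(out, n_max)
  rownames(out) <- NULL
  out
}

#' Published cytokine membrane-array screen
#'
#' An 80-analyte membrane antibody-array screen of fibroblast conditioned
#' medium under combined anti-HER2/taxane treatment, as printed (4 decimal
#' places, normalised intensities floored at 0.01): treated mean intensity,
#' two-tailed t-test p-value (NA where no variance existed), differential
#' intensity, relative fold change, log2 fold change and hit count. Used as
#' a worked reference for the metric algebra of this module.
#'
#' @return Data frame with 80 rows and columns `cytokine`, `intensity`,
#'   `p_value`, `differential_intensity`, `relative_fold_change`,
#'   `log2_fc`, `n_hits`.
#' @examples
#' head(cytokine_screen())
#' @export
cytokine_screen <- function() {
  path <- system.file("extdata", "cytokine_screen_table.tsv",
                      package = "secretodiff", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}
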