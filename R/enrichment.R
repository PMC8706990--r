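#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: name, description, then member
#' identifiers. Empty member fields are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set members), with the
#'   per-set descriptions as attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT", call. = FALSE)
  desc <- vapply(parts, `[[`, "", 2)
  sets <- lapply(parts, function(x) {
    m <- x[-(1:2)]
    m[nzchar(m)]
  })
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT", call. = FALSE)
  names(sets) <- nm
  names(desc) <- nm
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Overrepresentation analysis by the hypergeometric tail
#'
#' For each gene set, the one-sided hypergeometric probability of an
#' overlap at least as large as observed between the query and the set
#' (both intersected with the universe), with the expected overlap, fold
#' enrichment and a Benjamini--Hochberg FDR across sets.
#'
#' @param query Character vector of query identifiers; must be a subset
#'   of `universe`.
#' @param universe Character vector, the background.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @return Data frame with one row per set: `set`, `set_size` (within the
#'   universe), `overlap`, `expected`, `fold_enrichment`, `p_value`,
#'   `fdr`.
#' @export
ora_test <- function(query, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe", call. = FALSE)
  }
  big_n <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k_set <- length(s)
    ov <- length(intersect(query, s))
    expected <- n_q * k_set / big_n
    p <- stats::phyper(ov - 1, k_set, big_n - k_set, n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = k_set, overlap = ov,
               expected = expected,
               fold_enrichment = if (expected > 0) ov / expected else
                 NA_real_,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p_value)
  out
}

# running-sum enrichment score of a hit indicator along a ranked metric
# (weight_exponent = 0 reduces to the classic Kolmogorov--Smirnov form)
running_es <- function(values, is_hit, weight_exponent = 1) {
  n <- length(values)
  k <- sum(is_hit)
  wts <- abs(values[is_hit])^weight_exponent
  total <- sum(wts)
  step <- numeric(n)
  if (total > 0) {
    step[is_hit] <- wts / total
  } else {
    step[is_hit] <- 1 / k
  }
  step[!is_hit] <- -1 / (n - k)
  run <- cumsum(step)
  i_max <- which.max(abs(run))
  list(es = run[i_max], at = i_max, run = run)
}

#' Preranked gene-set enrichment (running-sum statistic)
#'
#' Features are ordered by decreasing rank metric (ties broken by
#' identifier). For each set, hits increment a running sum in proportion
#' to `|metric|^weight_exponent` and misses decrement it uniformly; the
#' enrichment score (ES) is the signed extreme deviation. The null
#' distribution comes from random feature-label sets of the same size
#' (permutation with a fixed seed; nulls are shared between sets of equal
#' size). NES is the ES divided by the mean |null ES| of the same sign;
#' the nominal p-value is the (add-one-corrected) fraction of same-sign
#' null ES at least as extreme; the FDR follows the sign-stratified
#' convention, comparing each |NES| against the pooled null NES
#' distribution relative to the observed NES of that sign.
#'
#' @param metric Named numeric vector of rank statistics (e.g. moderated
#'   t); names are the feature identifiers, no duplicates.
#' @param sets Named list of character vectors.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Mandatory integer seed for the permutations.
#' @param weight_exponent Hit-weight exponent (default 1; 0 gives the
#'   unweighted Kolmogorov--Smirnov statistic).
#' @param fdr_threshold Sets at FDR below this are flagged `enriched`
#'   (default 0.05).
#' @return Data frame with one row per (overlapping) set: `set`, `size`,
#'   `es`, `nes`, `p_value`, `fdr`, `enriched`, `leading_edge`
#'   (semicolon-separated members up to the ES extremum).
#' @export
gsea_preranked <- function(metric, sets, n_perm = 1000L, seed,
                           weight_exponent = 1, fdr_threshold = 0.05) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (is.null(names(metric)) || anyDuplicated(names(metric))) {
    stop("metric must be named with unique identifiers", call. = FALSE)
  }
  ord <- order(-metric, names(metric))
  v <- as.numeric(metric[ord])
  ids <- names(metric)[ord]
  n <- length(v)

  keep <- vapply(sets, function(s) any(s %in% ids), logical(1))
  if (any(!keep)) {
    warning("skipping set(s) with no overlap: ",
            paste(names(sets)[!keep], collapse = ", "))
  }
  sets <- sets[keep]
  if (length(sets) == 0) {
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p_value = numeric(), fdr = numeric(),
                      enriched = logical(), leading_edge = character()))
  }

  set.seed(as.integer(seed))
  sizes <- vapply(sets, function(s) sum(ids %in% s), integer(1))
  null_by_size <- list()
  for (k in sort(unique(sizes))) {
    nulls <- vapply(seq_len(n_perm), function(i) {
      hit <- logical(n)
      hit[sample.int(n, k)] <- TRUE
      running_es(v, hit, weight_exponent)$es
    }, numeric(1))
    null_by_size[[as.character(k)]] <- nulls
  }

  res <- lapply(names(sets), function(nm) {
    hit <- ids %in% sets[[nm]]
    r <- running_es(v, hit, weight_exponent)
    nulls <- null_by_size[[as.character(sum(hit))]]
    same <- nulls[sign(nulls) == sign(r$es) | r$es == 0]
    if (length(same) == 0) same <- abs(nulls)
    p <- (1 + sum(abs(same) >= abs(r$es))) / (1 + length(same))
    nes <- r$es / mean(abs(same))
    le <- if (r$es >= 0) {
      ids[seq_len(r$at)][hit[seq_len(r$at)]]
    } else {
      ids[r$at:n][hit[r$at:n]]
    }
    null_nes <- nulls / ifelse(nulls >= 0,
                               mean(abs(nulls[nulls >= 0])),
                               mean(abs(nulls[nulls < 0])))
    data.frame(set = nm, size = sum(hit), es = r$es, nes = nes,
               p_value = p, leading_edge = paste(le, collapse = ";"),
               stringsAsFactors = FALSE,
               null_nes = I(list(null_nes)))
  })
  out <- do.call(rbind, res)

  pooled_null <- unlist(out$null_nes)
  obs <- out$nes
  out$fdr <- vapply(seq_along(obs), function(i) {
    s <- sign(obs[i])
    if (s == 0) return(1)
    null_side <- pooled_null[sign(pooled_null) == s]
    obs_side <- obs[sign(obs) == s]
    num <- if (length(null_side)) {
      mean(abs(null_side) >= abs(obs[i]))
    } else 0
    den <- mean(abs(obs_side) >= abs(obs[i]))
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  out$null_nes <- NULL
  out$enriched <- out$fdr < fdr_threshold
  out[, c("set", "size", "es", "nes", "p_value", "fdr", "enriched",
          "leading_edge")]
}
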