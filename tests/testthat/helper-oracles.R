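# Independent brute-force oracles used across the suite. These deliberately
# follow the textbook definitions step by step and share no code with the
# package implementations they check.

# Benjamini-Hochberg step-up by definition: q_(i) = min_{j >= i} m * p_(j) / j
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# running-sum enrichment score by literal loop over every position
brute_force_es <- function(values, is_hit, weight_exponent = 1) {
  n <- length(values)
  k <- sum(is_hit)
  denom_hit <- sum(abs(values[is_hit])^weight_exponent)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      run <- run + if (denom_hit > 0) {
        abs(values[i])^weight_exponent / denom_hit
      } else 1 / k
    } else {
      run <- run - 1 / (n - k)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# hypergeometric upper tail by direct combinatorial enumeration
hyper_tail_oracle <- function(overlap, set_size, universe_size, query_size) {
  js <- overlap:min(set_size, query_size)
  sum(choose(set_size, js) *
        choose(universe_size - set_size, query_size - js)) /
    choose(universe_size, query_size)
}

# two-sample log-rank chi-square from the 2x2 table at each event time
logrank_chisq_oracle <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o <- o + d1
    e <- e + d_tot * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  (o - e)^2 / v
}

# quick two-condition layout + spot table builders for the array module
toy_layout <- function(analytes = c("A1", "A2"), dup = 2, n_pos = 2,
                       n_neg = 2) {
  make_array_layout(n_analytes = length(analytes),
                    analyte_names = analytes, n_cols = 4,
                    n_pos = n_pos, n_neg = n_neg, dup = dup)
}

spots_from_values <- function(layout, values, pos = 1000, neg = 50,
                              membrane_id = "m1") {
  intensity <- vapply(seq_len(nrow(layout)), function(i) {
    switch(layout$role[i],
           POS = pos, NEG = neg, BLANK = neg,
           analyte = neg + values[[layout$name[i]]] * (pos - neg))
  }, numeric(1))
  data.frame(membrane_id = membrane_id, row = layout$row, col = layout$col,
             intensity = intensity)
}
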