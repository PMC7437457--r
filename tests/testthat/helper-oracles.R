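# Independent oracles and fixture builders used across the suite.

# Naive step-by-step running-sum enrichment score: explicit loop, kept
# deliberately separate from the package's vectorized implementation.
# Returns the whole running-sum path plus the maximal deviation (earliest
# index on exact ties).
naive_es <- function(stats, member_idx, alpha) {
  n <- length(stats)
  is_member <- seq_len(n) %in% member_idx
  n_hit <- sum(is_member)
  weighted <- sum(abs(stats[is_member])^alpha) > 0
  n_r <- if (weighted) sum(abs(stats[is_member])^alpha) else n_hit
  running <- 0
  best <- 0
  best_idx <- 0L
  path <- numeric(n)
  for (i in seq_len(n)) {
    if (is_member[i]) {
      w <- if (weighted) abs(stats[i])^alpha else 1
      running <- running + w / n_r
    } else {
      running <- running - 1 / (n - n_hit)
    }
    path[i] <- running
    if (abs(running) > abs(best)) {
      best <- running
      best_idx <- i
    }
  }
  list(es = best, index = best_idx, path = path)
}

# Float-tolerant agreement between an enrichment_score() result and the
# naive oracle: the reported score must sit on the oracle's running-sum
# path at the reported index, and its magnitude must attain the path's
# maximal deviation. (Bitwise index agreement is not required: when two
# deviations tie to within rounding, cumsum- and loop-accumulated paths
# may break the tie differently.)
expect_es_matches_oracle <- function(got, want, tol = 1e-12) {
  expect_lt(abs(got$es - want$path[got$index]), tol)
  expect_lt(abs(abs(got$es) - max(abs(want$path))), tol)
}

# Exhaustive pair-counting AUC with half credit for ties.
pair_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(cases) * length(controls))
}

write_expression_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

make_ranked <- function(stats, ids = sprintf("g%02d", seq_along(stats))) {
  tibble::tibble(gene_id = ids, stat = stats)
}

# Small blocks with sample IDs, for screen/CCA tests.
random_block <- function(n, vars, prefix = "V") {
  m <- matrix(rnorm(n * vars), n, vars)
  colnames(m) <- paste0(prefix, seq_len(vars))
  rownames(m) <- sprintf("S%03d", seq_len(n))
  m
}
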