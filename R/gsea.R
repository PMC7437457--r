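# Enrichment-score machinery: the weighted Kolmogorov-Smirnov running-sum
# statistic, computed either per sample (abundance estimation) or against a
# two-class phenotype ranking.

#' Enrichment score of a gene set along a ranked list
#'
#' Walks down a ranked gene list, incrementing a running sum by
#' `|r_j|^alpha / N_R` at each signature gene (N_R = sum of `|r|^alpha` over
#' signature genes) and decrementing by `1 / (N - N_H)` at every other gene.
#' The enrichment score (ES) is the running-sum value at the index where its
#' absolute deviation from zero is largest; exact ties go to the earliest
#' index. ES lies in \[-1, 1\]: +1 when the signature occupies the top of
#' the list, -1 when it occupies the bottom.
#'
#' If every signature gene has a zero ranking statistic (N_R = 0) the score
#' falls back to unweighted steps (`alpha = 0`) with a warning.
#'
#' @param ranked A ranked list: tibble with columns `gene_id` and `stat`
#'   sorted by non-increasing `stat` (as from [rank_per_sample()] or
#'   [rank_two_class()]), or a named numeric vector already in rank order.
#' @param set_members Character vector of signature gene IDs. Members absent
#'   from the ranked list are dropped; the effective set must be a nonempty
#'   proper subset of the list.
#' @param weight Exponent `alpha` on `|stat|` (0 = classic unweighted KS;
#'   0.25 is the single-sample default used by [score_cohort()]).
#' @return A list with `es` (signed score) and `index` (1-based position in
#'   the ranked list where the maximal deviation is attained).
#' @examples
#' ranked <- tibble::tibble(gene_id = paste0("G", 1:5), stat = c(5, 4, 3, 2, 1))
#' enrichment_score(ranked, c("G1", "G2"), weight = 1) # top-loaded set: ES = 1
#' @export
enrichment_score <- function(ranked, set_members, weight = 0.25) {
  if (is.data.frame(ranked)) {
    ids <- as.character(ranked$gene_id)
    stat <- as.numeric(ranked$stat)
  } else {
    ids <- names(ranked)
    stat <- as.numeric(ranked)
  }
  if (is.null(ids) || anyDuplicated(ids)) abort("ranked list needs unique gene IDs")
  if (is.unsorted(rev(stat))) abort("ranked list must be sorted by non-increasing stat")
  if (weight < 0) abort("`weight` must be non-negative")
  is_member <- ids %in% set_members
  n <- length(ids)
  n_hit <- sum(is_member)
  if (n_hit == 0) abort("no signature genes present in the ranked list")
  if (n_hit == n) abort("signature covers the whole list; miss step undefined")
  w <- abs(stat)^weight
  n_r <- sum(w[is_member])
  if (n_r == 0) {
    warn("all signature genes have zero ranking statistic; using unweighted steps")
    w <- rep(1, n)
    n_r <- n_hit
  }
  step <- ifelse(is_member, w / n_r, -1 / (n - n_hit))
  rs <- cumsum(step)
  idx <- which.max(abs(rs))
  list(es = rs[[idx]], index = idx)
}

#' Rank genes within one sample by expression
#'
#' Orders genes by descending expression in the given sample; ties are
#' broken by gene ID so the ranking is deterministic.
#'
#' @param expression Genes x samples numeric matrix.
#' @param sample Sample ID (column name).
#' @return Tibble with `gene_id`, `stat` (the expression values), sorted.
#' @export
rank_per_sample <- function(expression, sample) {
  stopifnot(is.matrix(expression))
  if (!sample %in% colnames(expression)) {
    abort(sprintf("sample '%s' not in expression matrix", sample))
  }
  v <- expression[, sample]
  if (!all(is.finite(v))) abort("expression column contains non-finite values")
  o <- order(-v, rownames(expression), method = "radix")
  tibble(gene_id = rownames(expression)[o], stat = unname(v[o]))
}

# Signal-to-noise statistic with the conventional variance floor:
# each class sd is floored at 0.2 * |class mean| (at 0.2 when the mean is 0).
signal_to_noise <- function(case, control) {
  floor_sd <- function(s, m) max(s, if (m == 0) 0.2 else 0.2 * abs(m))
  m1 <- mean(case); m0 <- mean(control)
  (m1 - m0) / (floor_sd(sd(case), m1) + floor_sd(sd(control), m0))
}

#' Rank genes by a two-class signal-to-noise statistic
#'
#' Ranks genes by the signal-to-noise ratio between cases and controls,
#' `(mu1 - mu0) / (sd1 + sd0)`, with each class standard deviation floored
#' at `0.2 * |mu|` (0.2 when the class mean is zero), descending. Ties are
#' broken by gene ID.
#'
#' @param expression Genes x samples numeric matrix.
#' @param labels Tibble (`sample_id`, `diagnosis`) or named 0/1 vector
#'   aligned with the matrix columns; both classes need >= 2 samples.
#' @return Tibble with `gene_id`, `stat`, sorted by decreasing `stat`.
#' @export
rank_two_class <- function(expression, labels) {
  stopifnot(is.matrix(expression))
  lab <- as_label_vector(labels)
  if (!is.null(names(lab))) lab <- lab[colnames(expression)]
  if (length(lab) != ncol(expression) || anyNA(lab)) {
    abort("labels must cover every expression sample")
  }
  if (sum(lab == 1) < 2 || sum(lab == 0) < 2) {
    abort("each class needs at least 2 samples for the signal-to-noise ranking")
  }
  case <- expression[, lab == 1, drop = FALSE]
  control <- expression[, lab == 0, drop = FALSE]
  s <- vapply(seq_len(nrow(expression)), function(i)
    signal_to_noise(case[i, ], control[i, ]), numeric(1))
  o <- order(-s, rownames(expression), method = "radix")
  tibble(gene_id = rownames(expression)[o], stat = s[o])
}

#' Per-sample immune-cell abundance scores for a whole cohort
#'
#' Computes the enrichment score of every signature in every sample, using
#' the within-sample expression ranking ([rank_per_sample()]). The ES of a
#' cell-type signature in a sample is interpreted as that cell type's
#' relative abundance. Signature genes absent from the matrix are dropped
#' (overlap counts are retained in the result); signatures with no overlap
#' at all are removed with a warning.
#'
#' @param x A `csf_cohort` or a genes x samples numeric matrix.
#' @param gene_sets Named list of signature gene vectors (see [read_gmt()]).
#' @param weight Running-sum exponent `alpha`; default 0.25, the
#'   single-sample GSEA convention.
#' @return An `abundance_matrix`: numeric matrix (cell types x samples) of
#'   ES values in \[-1, 1\], with attribute `n_genes_used` (named vector of
#'   per-signature overlap counts) and `weight`.
#' @export
score_cohort <- function(x, gene_sets, weight = 0.25) {
  expression <- if (inherits(x, "csf_cohort")) x$expression else x
  stopifnot(is.matrix(expression))
  if (!length(gene_sets)) abort("`gene_sets` is empty")
  present <- lapply(gene_sets, intersect, x = rownames(expression))
  overlap <- lengths(present)
  if (all(overlap == 0)) abort("no signature has any gene in the expression matrix")
  if (any(overlap == 0)) {
    warn(sprintf("dropping %d signature(s) with no genes in the matrix: %s",
                 sum(overlap == 0),
                 paste(names(gene_sets)[overlap == 0], collapse = ", ")))
    present <- present[overlap > 0]
  }
  samples <- colnames(expression)
  es <- matrix(NA_real_, length(present), length(samples),
               dimnames = list(names(present), samples))
  for (s in samples) {
    ranked <- rank_per_sample(expression, s)
    for (cs in names(present)) {
      es[cs, s] <- enrichment_score(ranked, present[[cs]], weight)$es
    }
  }
  structure(es, n_genes_used = lengths(present), weight = weight,
            class = c("abundance_matrix", class(es)))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d cell type(s) x %d sample(s), ES range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Abundance matrix in long (tidy) form
#'
#' @param x An `abundance_matrix` from [score_cohort()].
#' @param ... Unused.
#' @return Tibble with `cell_type`, `sample_id`, `abundance`, `n_genes_used`.
#' @export
tidy.abundance_matrix <- function(x, ...) {
  tibble(
    cell_type = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    abundance = as.vector(unclass(x)[, , drop = FALSE]),
    n_genes_used = rep(unname(attr(x, "n_genes_used")), times = ncol(x))
  )
}

#' Two-class enrichment scores per signature
#'
#' Phenotype-level variant: one ES per signature against the case/control
#' signal-to-noise ranking ([rank_two_class()]), with an optional seeded
#' gene-label permutation null (off by default -- the abundance use of the
#' ES reports the raw statistic).
#'
#' @inheritParams score_cohort
#' @param labels Case/control labels (see [rank_two_class()]).
#' @param weight Running-sum exponent; default 1, the two-class convention.
#' @param n_permutations Number of gene-label shuffles for an empirical
#'   two-sided p-value; 0 disables.
#' @param seed RNG seed for the permutations.
#' @return Tibble with `cell_type`, `es`, `index`, `n_genes_used` and, when
#'   permuting, `p_perm`.
#' @export
score_classes <- function(x, gene_sets, labels = NULL, weight = 1,
                          n_permutations = 0, seed = NULL) {
  expression <- if (inherits(x, "csf_cohort")) x$expression else x
  if (inherits(x, "csf_cohort") && is.null(labels)) labels <- x$labels
  ranked <- rank_two_class(expression, labels)
  present <- lapply(gene_sets, intersect, x = ranked$gene_id)
  overlap <- lengths(present)
  if (all(overlap == 0)) abort("no signature has any gene in the expression matrix")
  if (any(overlap == 0)) {
    warn(sprintf("dropping %d signature(s) with no overlapping genes", sum(overlap == 0)))
    present <- present[overlap > 0]
  }
  res <- purrr::map(present, ~enrichment_score(ranked, .x, weight))
  out <- tibble(
    cell_type = names(present),
    es = purrr::map_dbl(res, "es"),
    index = purrr::map_int(res, ~as.integer(.x$index)),
    n_genes_used = lengths(present)
  )
  if (n_permutations > 0) {
    out$p_perm <- with_seed(seed, {
      purrr::map2_dbl(present, out$es, function(genes, es_obs) {
        null_es <- replicate(n_permutations, {
          enrichment_score(ranked, sample(ranked$gene_id, length(genes)), weight)$es
        })
        (1 + sum(abs(null_es) >= abs(es_obs))) / (n_permutations + 1)
      })
    })
  }
  out
}
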