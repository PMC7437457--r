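test_that("enrichment score matches the hand-enumerated running sum", {
  ranked <- make_ranked(c(5, 4, 3, 2, 1))
  # members at ranks 2 and 4, alpha = 1: running sum (-1/3, 1/3, 0, 1/3, 0);
  # |deviation| ties at ranks 1 and 2, earliest index wins -> -1/3 at 1
  r <- enrichment_score(ranked, ranked$gene_id[c(2, 4)], weight = 1)
  o <- naive_es(ranked$stat, c(2, 4), 1)
  expect_equal(r$es, o$es)
  expect_equal(r$index, o$index)
  expect_equal(r$es, -1 / 3)
  expect_equal(r$index, 1L)

  # top-loaded set peaks at N_R / N_R = 1
  expect_equal(enrichment_score(ranked, ranked$gene_id[1:2], weight = 1)$es, 1)
  expect_equal(enrichment_score(ranked, ranked$gene_id[1:2], weight = 0)$es, 1)

  # bottom-loaded set, alpha = 0: three leading misses at -1/3 each -> -1
  r2 <- enrichment_score(ranked, ranked$gene_id[4:5], weight = 0)
  expect_equal(r2$es, naive_es(ranked$stat, 4:5, 0)$es)
  expect_equal(r2$es, -1)
  expect_equal(r2$index, 3L)
})

test_that("vectorized ES equals the naive oracle on exhaustive small lists", {
  set.seed(42)
  for (n in 3:6) {
    stats <- sort(rnorm(n), decreasing = TRUE)
    ranked <- make_ranked(stats)
    for (mask in 1:(2^n - 2)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      if (length(idx) == 0 || length(idx) == n) next
      for (alpha in c(0, 0.25, 1)) {
        got <- enrichment_score(ranked, ranked$gene_id[idx], weight = alpha)
        expect_es_matches_oracle(got, naive_es(stats, idx, alpha))
      }
    }
  }
})

test_that("ES respects its invariants: range, monotone invariance, symmetry", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    ranked <- make_ranked(stats)
    idx <- sort(sample(n, sample(seq_len(n - 1), 1)))
    es <- enrichment_score(ranked, ranked$gene_id[idx], weight = 0.5)$es
    expect_gte(es, -1); expect_lte(es, 1)

    # alpha = 0: any strictly monotone transform of the stats is irrelevant
    ranked2 <- make_ranked(exp(stats / 2), ids = ranked$gene_id)
    expect_identical(enrichment_score(ranked, ranked$gene_id[idx], weight = 0)$es,
                     enrichment_score(ranked2, ranked$gene_id[idx], weight = 0)$es)

    # reversing the list and negating stats mirrors the deviation profile
    rev_ranked <- make_ranked(rev(-stats), ids = rev(ranked$gene_id))
    rev_idx <- n + 1 - rev(idx)
    es_fwd <- enrichment_score(ranked, ranked$gene_id[idx], weight = 1)
    es_rev <- enrichment_score(rev_ranked, rev_ranked$gene_id[rev_idx], weight = 1)
    # same member genes seen from the other end: deviations negate
    expect_equal(abs(es_rev$es), abs(es_fwd$es), tolerance = 1e-12)
  }
})

test_that("ES errors on degenerate sets and warns on all-zero weights", {
  ranked <- make_ranked(c(3, 2, 1))
  expect_error(enrichment_score(ranked, "absent"), "no signature genes")
  expect_error(enrichment_score(ranked, ranked$gene_id), "whole list")
  zr <- make_ranked(c(1, 0, 0, -1))
  expect_warning(r <- enrichment_score(zr, zr$gene_id[2:3], weight = 1),
                 "zero ranking statistic")
  expect_equal(r$es, naive_es(zr$stat, 2:3, 0)$es)
})

test_that("per-sample ranking is descending with lexicographic tie-break", {
  m <- matrix(c(1, 3, 2), 3, 1, dimnames = list(c("G1", "G2", "G3"), "S1"))
  expect_equal(rank_per_sample(m, "S1")$gene_id, c("G2", "G3", "G1"))
  tied <- matrix(5, 3, 1, dimnames = list(c("Gb", "Ga", "Gc"), "S1"))
  expect_equal(rank_per_sample(tied, "S1")$gene_id, c("Ga", "Gb", "Gc"))
  nan <- matrix(c(1, NaN), 2, 1, dimnames = list(c("G1", "G2"), "S1"))
  expect_error(rank_per_sample(nan, "S1"), "non-finite")
})

test_that("signal-to-noise ranking applies the variance floor and is antisymmetric", {
  m <- rbind(Ga = c(2, 2, 1, 1), Gb = c(1, 2, 1, 2), Gc = c(0, 1, 2, 3))
  colnames(m) <- paste0("S", 1:4)
  lab <- c(S1 = 1, S2 = 1, S3 = 0, S4 = 0)
  ranked <- rank_two_class(m, lab)
  # Ga: means 2 and 1, sds 0 floored at 0.4 and 0.2 -> (2-1)/0.6
  expect_equal(ranked$stat[ranked$gene_id == "Ga"], (2 - 1) / 0.6)
  # Gb: identical class distributions -> 0
  expect_equal(ranked$stat[ranked$gene_id == "Gb"], 0)
  flipped <- rank_two_class(m, 1 - lab)
  expect_equal(sort(flipped$stat), sort(-ranked$stat))
  expect_error(rank_two_class(m, c(S1 = 1, S2 = 0, S3 = 0, S4 = 0)),
               "at least 2 samples")
})

test_that("two-class ES agrees with fgsea's statistic on random cases", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  stats <- sort(rnorm(50), decreasing = TRUE)
  ranked <- make_ranked(stats)
  for (rep in 1:10) {
    idx <- sort(sample(50, 8))
    ours <- enrichment_score(ranked, ranked$gene_id[idx], weight = 1)$es
    theirs <- fgsea::calcGseaStat(setNames(stats, ranked$gene_id), idx,
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("cohort scoring recovers planted abundances and honors bounds", {
  co <- simulate_cohort(n_case = 50, n_control = 50, n_genes = 1200,
                        cell_types = default_cell_types[1:8],
                        genes_per_signature = 30, seed = 20)
  es <- score_cohort(co, co$truth$signatures)
  expect_identical(dim(es), c(8L, 100L))
  expect_true(all(es >= -1 & es <= 1))
  sp <- vapply(rownames(es), function(ct)
    cor(es[ct, ], co$truth$abundance[ct, ], method = "spearman"), numeric(1))
  expect_true(all(sp > 0.7))

  # a signature made of a sample's top-k genes scores exactly 1 there
  s <- co$labels$sample_id[1]
  topk <- rank_per_sample(co$expression, s)$gene_id[1:10]
  es_top <- score_cohort(co$expression, list(top = topk))
  expect_equal(unname(es_top["top", s]), 1)

  expect_warning(
    es2 <- score_cohort(co$expression, c(co$truth$signatures[1],
                                         list(ghost = c("nope1", "nope2")))),
    "no genes")
  expect_equal(nrow(es2), 1)
  expect_error(score_cohort(co$expression, list(ghost = "nope")), "no signature")
})

test_that("tidy() flattens an abundance matrix with overlap counts", {
  co <- simulate_cohort(n_case = 3, n_control = 3, n_genes = 40,
                        cell_types = c("T cell", "B cell"),
                        genes_per_signature = 10, seed = 3)
  es <- score_cohort(co, co$truth$signatures)
  td <- tidy(es)
  expect_equal(nrow(td), 2 * 6)
  expect_equal(unique(td$n_genes_used), 10L)
  expect_equal(td$abundance[td$cell_type == "T cell" & td$sample_id == "S001"],
               unname(es["T cell", "S001"]))
})
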