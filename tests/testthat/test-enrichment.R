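test_that("contingency counts per-base deduplicated motif coverage", {
  nr <- itbl("c", seq(0, 9000, by = 1000), seq(100, 9100, by = 1000))  # 10 x 100 bp
  ndr <- itbl("c", seq(20000, 29000, by = 1000), seq(20100, 29100, by = 1000))
  hits <- itbl("c", c(0L, 1000L, 2000L, 20000L), c(100L, 1200L, 2100L, 20100L))
  ct <- motif_contingency(hits, nr, ndr)
  expect_equal(ct$a, 300L)  # 100 + 100 + 100 on NR
  expect_equal(ct$b, 700L)
  expect_equal(ct$c, 100L)
  expect_equal(ct$d, 900L)
  # duplicated hits over the same bases count once
  dup <- itbl("c", c(0L, 0L), c(10L, 10L))
  expect_equal(motif_contingency(dup, nr, ndr)$a, 10L)
  # no hits
  none <- motif_contingency(hits[0, ], nr, ndr)
  expect_equal(unlist(none), c(a = 0L, b = 1000L, c = 0L, d = 1000L))
  expect_error(motif_contingency(hits, nr[0, ], ndr), "empty region set")
})

test_that("enrichment score follows the odds-ratio formula with zero-cell correction", {
  expect_equal(enrichment_score(300, 700, 100, 900), (300 / 100) / (700 / 900))
  expect_equal(enrichment_score(300, 700, 100, 900), 3.857142857, tolerance = 1e-9)
  expect_equal(enrichment_score(100, 900, 100, 900), 1)
  expect_equal(enrichment_score(10, 90, 0, 100),
               (10.5 / 0.5) / (90.5 / 100.5), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:200) {
    t <- sample(1:500, 4, replace = TRUE)
    expect_equal(enrichment_score(t[1], t[2], t[3], t[4]),
                 t[1] * t[4] / (t[2] * t[3]))
  }
  # NR <-> NDR swap inverts the score
  expect_equal(enrichment_score(30, 70, 10, 90),
               1 / enrichment_score(10, 90, 30, 70))
})

test_that("Fisher p-values match worked examples and stats::fisher.test", {
  expect_equal(fisher_p(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_p(0, 0, 0, 0), 1)
  set.seed(29)
  for (rep in 1:50) {
    t <- sample(0:40, 4, replace = TRUE)
    m <- matrix(t, 2, 2, byrow = TRUE)
    if (sum(m) == 0) next
    expect_equal(fisher_p(t[1], t[2], t[3], t[4]),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(fisher_p(t[1], t[2], t[3], t[4], alternative = "greater"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    # one-sided tail is contained in the two-sided sum when a is enriched
    if (t[1] * t[4] >= t[2] * t[3]) {
      expect_lte(fisher_p(t[1], t[2], t[3], t[4], alternative = "greater"),
                 fisher_p(t[1], t[2], t[3], t[4]) + 1e-12)
    }
  }
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(41)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15) && all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("candidate ranking filters by expression and FDR without dropping rows", {
  rec <- tibble::tibble(tf_name = c("T1", "T2", "T3", "T4"),
                        score = c(2.5, 1.8, 3.5, 0.4),
                        q_value = c(0.001, 0.002, 0.2, 0.01))
  rpkm <- tibble::tibble(tf_name = c("T1", "T2", "T3"), rpkm = c(12, 3, 50))
  out <- rank_candidates(rec, rpkm)
  expect_equal(out$rank[out$tf_name == "T1"], 1L)
  expect_equal(out$flag[out$tf_name == "T2"], "low_expression")
  expect_equal(out$flag[out$tf_name == "T3"], "q_value")
  expect_equal(out$flag[out$tf_name == "T4"], "no_rpkm")
  expect_equal(sum(!is.na(out$rank)), 1L)
  expect_equal(nrow(out), 4L)
  empty <- rank_candidates(rec[0, ], rpkm)
  expect_equal(nrow(empty), 0L)
})

test_that("planted pioneer/canonical coverage contrast yields separable scores", {
  # direct construction: pioneers put 70% of motif bases on NRs, canonical 10%
  set.seed(53)
  nr_bp <- 50000L; ndr_bp <- 30000L
  mk_scores <- function(n, p_nr) {
    vapply(seq_len(n), function(i) {
      tot <- 1600L
      a <- rbinom(1, tot, p_nr)
      enrichment_score(a, nr_bp - a, tot - a, ndr_bp - (tot - a))
    }, numeric(1))
  }
  pio <- mk_scores(10, 0.7)
  can <- mk_scores(30, 0.1)
  sc <- c(pio, can)
  lab <- rep(c(TRUE, FALSE), c(10, 30))
  expect_gte(roc_auc(sc, lab), 0.95)
  expect_lt(mann_whitney(pio, can, alternative = "greater")$p_value, 0.01)
})
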