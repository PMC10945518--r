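jaspar_text <- c(
  ">MA0001.1 TFA",
  "A  [ 4 19  0  0  0  0  4  5 ]",
  "C  [16  0 20  0  0  0  2  5 ]",
  "G  [ 0  1  0 20  0 20 10  5 ]",
  "T  [ 0  0  0  0 20  0  4  5 ]",
  ">MA0002.1 TFB",
  "A [ 10 0 ]",
  "C [ 0 10 ]",
  "G [ 0 0 ]",
  "T [ 0 0 ]"
)

test_that("JASPAR parsing validates shape and reads multiple records", {
  f <- withr::local_tempfile()
  writeLines(jaspar_text, f)
  pfms <- read_jaspar(f)
  expect_length(pfms, 2L)
  expect_equal(ncol(pfms[[1]]$matrix), 8L)
  expect_equal(pfms[[1]]$tf_name, "TFA")
  expect_equal(unname(pfms[[2]]$matrix["A", ]), c(10, 0))
  writeLines(">MA0003.1 TFC", f)
  expect_error(read_jaspar(f), "4 matrix rows")
  writeLines(c(">X T", "A [1 2]", "C [1]", "G [1 2]", "T [1 2]"), f)
  expect_error(read_jaspar(f), "ragged")
})

test_that("JASPAR write -> read round-trips the count matrices", {
  set.seed(2)
  pfms <- lapply(1:3, function(i) random_pfm(6, paste0("T", i)))
  f <- withr::local_tempfile()
  write_jaspar(pfms, f)
  back <- read_jaspar(f)
  for (i in 1:3) expect_equal(back[[i]]$matrix, pfms[[i]]$matrix)
})

test_that("PWM log-odds construction matches the closed form", {
  pfm <- structure(list(tf_name = "t", id = "t",
                        matrix = matrix(c(100, 0, 0, 0), 4, 1,
                                        dimnames = list(c("A", "C", "G", "T"), NULL))),
                   class = "pfm")
  pwm0 <- build_pwm(pfm, pseudocount = 0)
  expect_equal(unname(pwm0$matrix["A", 1]), 2)          # log2(4)
  expect_equal(unname(pwm0$matrix["C", 1]), -Inf)
  pwm1 <- build_pwm(pfm, pseudocount = 0.1)
  expect_true(all(is.finite(pwm1$matrix)))
  # uniform counts, uniform background -> all zero scores
  pfm_u <- structure(list(tf_name = "u", id = "u",
                          matrix = matrix(25, 4, 3,
                                          dimnames = list(c("A", "C", "G", "T"), NULL))),
                     class = "pfm")
  expect_equal(max(abs(build_pwm(pfm_u, pseudocount = 0)$matrix)), 0)
  expect_error(build_pwm(pfm, background = c(0, 0.5, 0.25, 0.25)), "background")
})

test_that("DP score p-values match exhaustive enumeration over 4^L words", {
  set.seed(19)
  for (rep in 1:6) {
    L <- sample(3:6, 1)
    pwm <- build_pwm(random_pfm(L), pseudocount = 0.1)
    pv <- score_pvalues(pwm)
    # probe the whole attainable grid range plus the extremes
    probes <- unique(c(pv$min_int, pv$min_int + length(pv$surv) - 1L,
                       sample(pv$min_int + seq_along(pv$surv) - 1L,
                              min(25, length(pv$surv)))))
    got <- nucpioneer:::pwm_pvalue_int(pv, probes)
    want <- enumerate_pvalue(pwm, probes)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("p-value function is a survival function with the consensus extreme", {
  pwm <- build_pwm(random_pfm(8, strong = 100, weak = 0), pseudocount = 1e-9)
  pv <- score_pvalues(pwm)
  max_score <- sum(apply(pwm$matrix, 2, max))
  expect_equal(pwm_pvalue(pv, max_score), 0.25^8, tolerance = 1e-6)
  expect_equal(pwm_pvalue(pv, -Inf), 1)
  s <- seq(-10, 20, by = 0.37)
  p <- pwm_pvalue(pv, s)
  expect_true(all(diff(p) <= 0))
})

test_that("scanning finds a planted consensus on both strands at its coordinates", {
  set.seed(3)
  pfm <- random_pfm(8)
  pwm <- build_pwm(pfm)
  bg <- paste0(sample(c("A", "C"), 60, replace = TRUE), collapse = "")
  seqf <- paste0(substr(bg, 1, 12), pfm$consensus, substr(bg, 21, 60))
  g <- tiny_genome(chr1 = seqf)
  peaks <- itbl("chr1", 0, nchar(seqf))
  hits <- scan_motifs(pwm, peaks, g)
  fwd <- hits[hits$strand == "+", ]
  expect_true(any(fwd$start == 12 & fwd$end == 20))
  expect_true(all(hits$p_value < 1e-4))
  # reverse-complemented genome: same interval, minus strand
  grc <- tiny_genome(chr1 = revcomp(seqf))
  hits_rc <- scan_motifs(pwm, peaks, grc)
  n <- nchar(seqf)
  expect_true(any(hits_rc$strand == "-" &
                    hits_rc$start == n - 20 & hits_rc$end == n - 12))
})

test_that("scan of a sequence and its reverse complement mirror each other", {
  set.seed(8)
  pwm <- build_pwm(random_pfm(6, strong = 40, weak = 10))
  s <- paste0(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  n <- nchar(s)
  h1 <- scan_motifs(pwm, itbl("c", 0, n), tiny_genome(c = s), p_threshold = 0.01)
  h2 <- scan_motifs(pwm, itbl("c", 0, n), tiny_genome(c = revcomp(s)), p_threshold = 0.01)
  m1 <- h1 |> dplyr::mutate(rs = n - end, re = n - start,
                            st = ifelse(strand == "+", "-", "+"))
  expect_equal(
    dplyr::arrange(tibble::tibble(start = m1$rs, end = m1$re, strand = m1$st,
                                  score = m1$score), start, strand),
    dplyr::arrange(h2[c("start", "end", "strand", "score")], start, strand)
  )
})

test_that("hit count grows monotonically with the p-value threshold and skips N", {
  set.seed(9)
  pwm <- build_pwm(random_pfm(6, strong = 40, weak = 10))
  s <- paste0(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  g <- tiny_genome(c = s)
  pk <- itbl("c", 0, 500)
  n1 <- nrow(scan_motifs(pwm, pk, g, p_threshold = 1e-4))
  n2 <- nrow(scan_motifs(pwm, pk, g, p_threshold = 1e-2))
  n3 <- nrow(scan_motifs(pwm, pk, g, p_threshold = 0.5))
  expect_true(n1 <= n2 && n2 <= n3)
  gN <- tiny_genome(c = gsub("A", "N", s))
  hN <- scan_motifs(pwm, pk, gN, p_threshold = 0.999999)
  # every window holds an N somewhere or not: windows with N never emitted
  seqs <- genome_sequence(gN, hN[, c("chrom", "start", "end")])
  expect_false(any(grepl("N", seqs)))
})
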