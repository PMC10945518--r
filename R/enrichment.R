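#' Motif-coverage contingency table on NRs vs NDRs
#'
#' Counts genome base pairs, not hit bases: `a` is the number of nucleosome
#' region (NR) bases covered by at least one motif hit (overlapping hits are
#' deduplicated per base), `c` the same on nucleosome-depleted regions
#' (NDRs); `b` and `d` are the remaining NR and NDR bases. NR and NDR totals
#' use the per-base union of each set, so mutually overlapping 147 bp NRs are
#' not double-counted.
#'
#' @param hits motif-hit interval tibble (one TF).
#' @param nr nucleosome-region interval tibble.
#' @param ndr NDR interval tibble.
#' @return one-row tibble (a, b, c, d).
#' @export
motif_contingency <- function(hits, nr, ndr) {
  if (nrow(nr) == 0L || nrow(ndr) == 0L) abort("empty region set")
  nr <- merge_intervals(nr)
  ndr <- merge_intervals(ndr)
  nr_bp <- sum(nr$end - nr$start)
  ndr_bp <- sum(ndr$end - ndr$start)
  if (nrow(hits) == 0L) {
    return(tibble(a = 0L, b = nr_bp, c = 0L, d = ndr_bp))
  }
  gp <- granges_common(hits, nr, ndr)
  hg <- GenomicRanges::reduce(gp[[1]], ignore.strand = TRUE)
  a <- sum(GenomicRanges::width(
    GenomicRanges::intersect(hg, gp[[2]], ignore.strand = TRUE)))
  c_ <- sum(GenomicRanges::width(
    GenomicRanges::intersect(hg, gp[[3]], ignore.strand = TRUE)))
  tibble(a = a, b = nr_bp - a, c = c_, d = ndr_bp - c_)
}

#' Nucleosome-binding enrichment score (odds ratio)
#'
#' `(a/c) / (b/d)`, algebraically `ad / bc`: how much more densely a TF's
#' motif bases cover nucleosome regions than nucleosome-depleted regions.
#' Scores above 1 indicate pioneer-like preference for nucleosomal DNA. Any
#' zero cell triggers the Haldane-Anscombe correction (+0.5 to every cell)
#' before the ratio, keeping scores finite and rankable.
#'
#' @param a,b,c,d contingency cells (vectors allowed), or a one-row tibble
#'   passed as `a`.
#' @return numeric enrichment score(s), > 0.
#' @export
enrichment_score <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.data.frame(a)) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  (a / c) / (b / d)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact hypergeometric p-value; the two-sided p sums the probabilities of
#' all tables with the same margins at least as improbable as the observed
#' one. Cells must be raw (uncorrected) integers.
#'
#' @inheritParams enrichment_score
#' @param alternative `"two_sided"` (default) or `"greater"` (enrichment of
#'   `a` relative to its margin expectation).
#' @return numeric p-value(s).
#' @export
fisher_p <- function(a, b = NULL, c = NULL, d = NULL,
                     alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(a)) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  vapply(seq_along(a), function(i) {
    n <- a[i] + b[i] + c[i] + d[i]
    r1 <- a[i] + b[i]
    c1 <- a[i] + c[i]
    if (n == 0) return(1)
    if (alternative == "greater") {
      return(stats::phyper(a[i] - 1, c1, n - c1, r1, lower.tail = FALSE))
    }
    supp <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- stats::dhyper(supp, c1, n - c1, r1)
    # probability-based two-sided definition, with the conventional relative
    # slack so ties in table probability are counted as "at least as extreme"
    min(1, sum(probs[probs <= probs[a[i] - supp[1] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * n / j`, clipped to 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Score TF motif enrichment on nucleosome regions
#'
#' Runs [motif_contingency()], [enrichment_score()], [fisher_p()] and
#' [bh_fdr()] over a table of per-TF motif hits, producing one enrichment
#' record per TF.
#'
#' @param hits motif-hit tibble for all TFs (column `tf_name`).
#' @param nr,ndr interval tibbles defining the NR and NDR sets.
#' @param alternative Fisher sidedness, see [fisher_p()].
#' @return tibble (tf_name, a, b, c, d, score, p_value, q_value), sorted by
#'   descending score; class `nuc_enrichment`.
#' @export
enrichment_table <- function(hits, nr, ndr,
                             alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  tfs <- sort(unique(hits$tf_name))
  tab <- list_rbind(lapply(tfs, function(tf) {
    ct <- motif_contingency(hits[hits$tf_name == tf, , drop = FALSE], nr, ndr)
    mutate(ct, tf_name = tf, .before = 1L)
  }))
  tab$score <- enrichment_score(tab)
  tab$p_value <- fisher_p(tab, alternative = alternative)
  tab$q_value <- bh_fdr(tab$p_value)
  out <- arrange(tab, desc(.data$score))
  class(out) <- c("nuc_enrichment", class(out))
  out
}

#' Rank expressed candidate pioneer factors
#'
#' Filters enrichment records to TFs expressed at `rpkm >= rpkm_min` with
#' `q_value < q_max` and ranks the survivors by descending enrichment score.
#' Nothing is dropped from the returned table: excluded records keep their
#' rows with `rank = NA` and a `flag` saying why (`"low_expression"`,
#' `"q_value"`, or `"no_rpkm"` for TFs absent from the expression table).
#'
#' @param records enrichment tibble (from [enrichment_table()]), one row per
#'   TF with `tf_name`, `score`, `q_value`.
#' @param rpkm expression tibble with columns `tf_name` and `rpkm` (optional
#'   `cell_line` is carried through).
#' @param rpkm_min expression threshold (default 10).
#' @param q_max FDR threshold (default 0.05).
#' @return `records` with columns `rpkm`, `expressed`, `flag`, `rank`,
#'   ordered with ranked candidates first.
#' @export
rank_candidates <- function(records, rpkm, rpkm_min = 10, q_max = 0.05) {
  if (nrow(records) == 0L) {
    return(mutate(records, rpkm = numeric(0), expressed = logical(0),
                  flag = character(0), rank = integer(0)))
  }
  out <- left_join(records, rpkm[c("tf_name", "rpkm")], by = "tf_name")
  out$expressed <- !is.na(out$rpkm) & out$rpkm >= rpkm_min
  out$flag <- case_when(
    is.na(out$rpkm) ~ "no_rpkm",
    !out$expressed ~ "low_expression",
    out$q_value >= q_max ~ "q_value",
    .default = "ok"
  )
  keep <- out$flag == "ok"
  out$rank <- NA_integer_
  out$rank[keep] <- rank(-out$score[keep], ties.method = "first")
  arrange(out, is.na(.data$rank), .data$rank, desc(.data$score))
}
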