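DNA_BASES <- c("A", "C", "G", "T")

#' Parse JASPAR-format position frequency matrices
#'
#' Reads the JASPAR text format: a `>ID NAME` header followed by four rows
#' `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]` of non-negative counts.
#'
#' @param path JASPAR-format file (may hold several records).
#' @return list of `pfm` objects: `list(tf_name, id, matrix)` with a 4 x L
#'   count matrix (rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) abort("no JASPAR records found")
  ends <- c(heads[-1] - 1L, length(lines))
  lapply(seq_along(heads), function(k) {
    block <- lines[heads[k]:ends[k]]
    hdr <- strsplit(sub("^>", "", block[1]), "\\s+")[[1]]
    body <- block[-1]
    if (length(body) < 4L) abort(sprintf("record '%s': expected 4 matrix rows", hdr[1]))
    rows <- lapply(DNA_BASES, function(b) {
      ln <- grep(paste0("^", b, "\\b"), body, value = TRUE)
      if (length(ln) != 1L) {
        abort(sprintf("record '%s': missing or duplicated row %s", hdr[1], b))
      }
      nums <- gsub("[][]", " ", sub(paste0("^", b), "", ln))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1L) abort(sprintf("record '%s': ragged matrix rows", hdr[1]))
    m <- do.call(rbind, rows)
    rownames(m) <- DNA_BASES
    if (any(m < 0)) abort(sprintf("record '%s': negative counts", hdr[1]))
    if (any(colSums(m) == 0)) abort(sprintf("record '%s': zero column sum", hdr[1]))
    structure(list(tf_name = if (length(hdr) > 1) hdr[2] else hdr[1],
                   id = hdr[1], matrix = m),
              class = "pfm")
  })
}

#' Write PFMs in JASPAR text format
#'
#' @param pfms list of `pfm` objects.
#' @param path output file.
#' @export
write_jaspar <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(sprintf(">%s %s", p$id, p$tf_name), con)
    for (b in DNA_BASES) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p$matrix[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Build a log-odds position weight matrix
#'
#' Entry for base b at column j is
#' `log2( (count_bj + pseudocount * bg_b) / (colsum_j + pseudocount) / bg_b )`.
#' With pseudocount 0, zero counts give `-Inf`; any positive pseudocount makes
#' all scores finite.
#'
#' @param pfm a `pfm` object.
#' @param background length-4 base probabilities (A, C, G, T), each > 0.
#' @param pseudocount total pseudocount distributed by background (>= 0).
#' @return a `pwm` object: `list(tf_name, id, matrix, background, pseudocount)`
#'   with a 4 x L matrix of log2-odds scores (bits).
#' @export
build_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.1) {
  if (length(background) != 4L || any(background <= 0)) {
    abort("background must be 4 positive probabilities")
  }
  background <- background / sum(background)
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  cs <- colSums(pfm$matrix)
  prob <- sweep(pfm$matrix + pseudocount * background, 2L, cs + pseudocount, `/`)
  mat <- log2(prob / background)
  rownames(mat) <- DNA_BASES
  structure(list(tf_name = pfm$tf_name, id = pfm$id, matrix = mat,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

# integerized PWM at granularity eps (bits); scores become integer sums
pwm_int_matrix <- function(pwm, granularity) {
  m <- round(pwm$matrix / granularity)
  if (any(!is.finite(m))) {
    abort("PWM has -Inf entries; use a positive pseudocount before computing p-values")
  }
  storage.mode(m) <- "integer"
  m
}

#' Exact PWM score p-values by dynamic programming
#'
#' Computes the full null distribution of the PWM score of a random sequence
#' of motif length drawn from the background model, by convolving the
#' per-column score distributions over an integer grid (PWM entries rounded
#' to `granularity` bits, default 1e-3). `p(s)` is the probability of a score
#' `>= s` on that grid, so `p(-Inf) = 1` and `p` is non-increasing.
#'
#' @param pwm a `pwm` object.
#' @param granularity score grid step in bits.
#' @return a `pwm_pvals` object with the survival function of the score
#'   distribution; query it with [pwm_pvalue()].
#' @export
score_pvalues <- function(pwm, granularity = 1e-3) {
  M <- pwm_int_matrix(pwm, granularity)
  bg <- pwm$background
  L <- ncol(M)
  dp <- 1
  off <- 0L
  for (l in seq_len(L)) {
    col <- M[, l]
    cmin <- min(col)
    new <- numeric(length(dp) + (max(col) - cmin))
    for (b in 1:4) {
      sh <- col[b] - cmin
      idx <- (1L + sh):(length(dp) + sh)
      new[idx] <- new[idx] + dp * bg[b]
    }
    dp <- new
    off <- off + cmin
  }
  surv <- rev(cumsum(rev(dp)))
  structure(list(granularity = granularity, min_int = off, surv = surv,
                 int_matrix = M, L = L),
            class = "pwm_pvals")
}

# p-value for integer grid scores (vectorized)
pwm_pvalue_int <- function(pv, s_int) {
  idx <- s_int - pv$min_int + 1L
  p <- numeric(length(idx))
  p[idx < 1L] <- 1
  inr <- idx >= 1L & idx <= length(pv$surv)
  p[inr] <- pv$surv[idx[inr]]
  # idx beyond the top of the distribution: score unattainable, p = 0
  p
}

#' @rdname score_pvalues
#' @param pv a `pwm_pvals` object.
#' @param score numeric score(s) in bits; rounded onto the p-value grid.
#' @return numeric p-value(s).
#' @export
pwm_pvalue <- function(pv, score) {
  p <- numeric(length(score))
  p[score == -Inf] <- 1
  fin <- is.finite(score)
  p[fin] <- pwm_pvalue_int(pv, as.integer(round(score[fin] / pv$granularity)))
  p
}

# encode DNA string as integer codes 1..4 (A,C,G,T), NA for anything else
encode_dna <- function(s) {
  code <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
  code
}

# reverse-complement of an integer PWM-like matrix: scores the minus strand
revcomp_matrix <- function(m) {
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- rownames(m)
  out
}

scan_one_strand <- function(codes, M) {
  L <- ncol(M)
  n <- length(codes)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  si <- rep(0L, nw)
  na <- rep(FALSE, nw)
  for (l in seq_len(L)) {
    cl <- codes[l:(nw + l - 1L)]
    na <- na | is.na(cl)
    v <- unname(M[, l][cl])
    v[is.na(v)] <- 0L
    si <- si + v
  }
  si[na] <- NA_integer_
  si
}

#' Scan peak sequences with a PWM
#'
#' Scores every window of every peak on both strands (minus-strand windows are
#' scored against the reverse-complemented PWM and reported on the forward
#' coordinates they cover) and emits hits with p-value below the threshold.
#' Overlapping peaks are unioned before scanning so shared bases are scanned
#' once; windows containing N are skipped.
#'
#' @param pwm a `pwm` object.
#' @param peaks interval tibble of regions to scan.
#' @param genome a [genome_model()] with sequence.
#' @param p_threshold emit hits with `p_value < p_threshold` (default 1e-4).
#' @param granularity p-value grid step in bits (see [score_pvalues()]).
#' @return motif-hit tibble: chrom, start, end, strand, tf_name, score (bits,
#'   on the p-value grid), p_value.
#' @export
scan_motifs <- function(pwm, peaks, genome, p_threshold = 1e-4,
                        granularity = 1e-3) {
  if (is.null(genome$sequence)) abort("genome has no sequence")
  regions <- clip_to_genome(merge_intervals(peaks), genome)
  pv <- score_pvalues(pwm, granularity)
  M <- pv$int_matrix
  Mrc <- revcomp_matrix(M)
  L <- pv$L
  hits <- vector("list", nrow(regions) * 2L)
  hi <- 0L
  seqs <- if (nrow(regions)) genome_sequence(genome, regions) else character(0)
  for (r in seq_len(nrow(regions))) {
    codes <- encode_dna(seqs[r])
    for (strand in c("+", "-")) {
      si <- scan_one_strand(codes, if (strand == "+") M else Mrc)
      if (!length(si)) next
      p <- rep(1, length(si))
      ok <- !is.na(si)
      p[ok] <- pwm_pvalue_int(pv, si[ok])
      keep <- ok & p < p_threshold
      if (!any(keep)) next
      w <- which(keep)
      hi <- hi + 1L
      hits[[hi]] <- tibble(
        chrom = regions$chrom[r],
        start = regions$start[r] + w - 1L,
        end = regions$start[r] + w - 1L + L,
        strand = strand,
        score = si[w] * pv$granularity,
        p_value = p[w]
      )
    }
  }
  out <- if (hi) list_rbind(hits[seq_len(hi)]) else {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), score = numeric(), p_value = numeric())
  }
  out$tf_name <- rep(pwm$tf_name, nrow(out))
  out[c("chrom", "start", "end", "strand", "tf_name", "score", "p_value")] |>
    arrange(.data$chrom, .data$start, .data$strand)
}
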