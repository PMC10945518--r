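#' Dyad-anchored binding-motif profile
#'
#' Assigns each motif hit to the representative dyad closest to the hit
#' midpoint (ties to the lower-coordinate dyad) and counts, for every base of
#' the hit within `flank` of its dyad, one at the offset `base - dyad`. Both
#' strands are counted in genomic orientation (no flipping); the nucleosome's
#' two-fold symmetry is handled later by [symmetrize_profile()].
#'
#' @param hits motif-hit interval tibble (one TF).
#' @param dyads dyad map tibble (chrom, pos).
#' @param flank half-width of the profile (default 1000 bp).
#' @return tibble (offset, count) over offsets `-flank..flank`, with
#'   attributes `tf_name`, `n_motif_bp` (total counted bases) and class
#'   `motif_profile`.
#' @export
build_profile <- function(hits, dyads, flank = 1000L) {
  if (nrow(dyads) == 0L) abort("empty dyad map")
  offs <- -flank:flank
  counts <- integer(length(offs))
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    dp <- sort(dyads$pos[dyads$chrom == ch])
    if (length(dp) == 0L || nrow(h) == 0L) next
    mid <- interval_midpoint(h$start, h$end)
    j <- findInterval(mid, dp)
    lo <- pmax(j, 1L)
    hi <- pmin(j + 1L, length(dp))
    # nearest dyad; exact midpoint ties go to the lower-coordinate dyad
    d_lo <- abs(mid - dp[lo])
    d_hi <- abs(dp[hi] - mid)
    dyad <- ifelse(d_lo <= d_hi, dp[lo], dp[hi])
    for (k in seq_len(nrow(h))) {
      o <- (h$start[k]:(h$end[k] - 1L)) - dyad[k]
      o <- o[abs(o) <= flank]
      if (length(o)) {
        idx <- o + flank + 1L
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  structure(tibble(offset = offs, count = counts),
            tf_name = if (nrow(hits)) hits$tf_name[1] else NA_character_,
            n_motif_bp = sum(counts),
            flank = flank,
            class = c("motif_profile", class(tibble())))
}

#' Min-max normalize a profile
#'
#' `(x - min) / (max - min)`, mapping a profile into `[0, 1]`; a constant
#' profile maps to all zeros.
#'
#' @param x numeric vector, or a profile tibble with a `count` column.
#' @return numeric vector in `[0, 1]` (same length).
#' @export
normalize_profile <- function(x) {
  if (is.data.frame(x)) x <- x$count
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Correlation between a motif profile and nucleosome occupancy
#'
#' Pearson correlation over offsets `-flank..flank` (default 400 bp) between
#' a TF's binding-motif profile and the dyad-aligned occupancy profile, with
#' a two-sided p-value from the t distribution on `2*flank - 1` degrees of
#' freedom. TFs with `pcc >= 0.2` and `p < 0.05` are the positive-correlation
#' nucleosome binders in the downstream classification.
#'
#' @param profile `motif_profile` tibble (offsets must cover `-flank..flank`).
#' @param occupancy tibble (offset, occupancy) from [occupancy_profile()].
#' @param flank correlation window half-width (bp).
#' @return one-row tibble (pcc, p_value, n).
#' @export
occupancy_correlation <- function(profile, occupancy, flank = 400L) {
  offs <- -flank:flank
  x <- profile$count[match(offs, profile$offset)]
  y <- occupancy$occupancy[match(offs, occupancy$offset)]
  if (anyNA(x) || anyNA(y)) abort("profiles do not cover the requested window")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(pcc = unname(ct$estimate), p_value = ct$p.value, n = length(offs))
}

#' Base-pair offsets of a superhelical-location window
#'
#' Superhelical locations (SHLs) count helical turns from the dyad (SHL 0) to
#' the DNA ends (SHL +-7, i.e. +-73 bp); bp offset = round(SHL * 73/7), with
#' halves rounded away from zero. The window covers both nucleosome halves.
#'
#' @param shl_lo,shl_hi window bounds in SHL units, `0 <= shl_lo < shl_hi <= 7`
#'   (equal bounds allowed for a single-position window).
#' @return sorted integer vector of offsets i with
#'   `round(shl_lo*73/7) <= |i| <= round(shl_hi*73/7)`.
#' @export
shl_to_offsets <- function(shl_lo, shl_hi) {
  if (shl_lo < 0 || shl_hi > 7 || shl_lo > shl_hi) {
    abort("need 0 <= shl_lo <= shl_hi <= 7")
  }
  lo_bp <- as.integer(round_half_away(shl_lo * 73 / 7))
  hi_bp <- as.integer(round_half_away(shl_hi * 73 / 7))
  sort(unique(c(-(hi_bp:lo_bp), lo_bp:hi_bp)))
}

#' End/dyad binding ratio
#'
#' Motif-base count within the DNA-end windows (SHL +-5.5 to +-7) divided by
#' the count near the dyad (SHL 0 to +-1.5). Ratios above 1 mark TFs binding
#' at nucleosomal DNA ends; below 1, near the dyad.
#'
#' @param profile `motif_profile` tibble.
#' @param end_window,dyad_window SHL bounds `c(lo, hi)` of the two windows.
#' @param inf_on_zero return `Inf` instead of erroring when the dyad-window
#'   count is zero.
#' @return the ratio (single number).
#' @export
end_dyad_ratio <- function(profile, end_window = c(5.5, 7),
                           dyad_window = c(0, 1.5), inf_on_zero = FALSE) {
  sum_window <- function(w) {
    offs <- shl_to_offsets(w[1], w[2])
    sum(profile$count[match(offs, profile$offset)], na.rm = TRUE)
  }
  e <- sum_window(end_window)
  d <- sum_window(dyad_window)
  if (d == 0) {
    if (inf_on_zero) return(Inf)
    abort("dyad-window count is zero")
  }
  e / d
}
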