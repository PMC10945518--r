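#' Count nucleosome dyads from mono-nucleosome fragments
#'
#' The dyad of a nucleosome-protected fragment is taken as the fragment
#' midpoint `start + floor(len/2)`. Only fragments whose length falls in
#' `[len_min, len_max]` contribute; the tight default 146-148 bp keeps
#' fragments that protect one full nucleosome wrap, giving the sharpest dyad
#' estimates.
#'
#' @param fragments interval tibble of paired-end fragments.
#' @param len_min,len_max inclusive fragment-length filter (bp).
#' @return tibble (chrom, pos, count): per-position dyad counts, sorted,
#'   counts >= 1.
#' @examples
#' count_dyads(interval_tbl("chr1", 100, 247))  # length 147 -> dyad at 173
#' @export
count_dyads <- function(fragments, len_min = 146L, len_max = 148L) {
  if (len_min > len_max) abort("len_min must be <= len_max")
  fragments <- validate_intervals(fragments, "fragments")
  len <- fragments$end - fragments$start
  keep <- len >= len_min & len <= len_max
  f <- fragments[keep, , drop = FALSE]
  if (nrow(f) == 0L) {
    return(tibble(chrom = character(), pos = integer(), count = integer()))
  }
  mid <- interval_midpoint(f$start, f$end)
  count(tibble(chrom = f$chrom, pos = mid), .data$chrom, .data$pos,
        name = "count") |>
    arrange(.data$chrom, .data$pos)
}

#' Triweight kernel
#'
#' `K(u) = (1 - (u/h)^2)^3` for `|u| <= h`, else 0.
#'
#' @param u offset(s) in bp.
#' @param h bandwidth in bp.
#' @return kernel weight(s) in `[0, 1]`.
#' @export
triweight_kernel <- function(u, h) {
  ifelse(abs(u) <= h, (1 - (u / h)^2)^3, 0)
}

#' Kernel-smooth dyad counts
#'
#' Smoothed count at coordinate i is `D(i) = (1/h) * sum_j K(i - j) d(j)`
#' with the triweight kernel. A small bandwidth (default h = 15) trades
#' smoothness for positional accuracy of the subsequent maxima search. The
#' track is evaluated sparsely: only positions within `h` of an observed dyad
#' are materialized (everywhere else `D` is exactly 0 since `K(+-h) = 0`).
#'
#' @param counts dyad-count tibble from [count_dyads()].
#' @param h bandwidth in bp (>= 1).
#' @return tibble (chrom, island, pos, D) of smoothed counts over contiguous
#'   islands of support, with attribute `h`.
#' @export
smooth_counts <- function(counts, h = 15L) {
  stopifnot_scalar_number(h, "h", min = 1)
  kern <- triweight_kernel(-h:h, h)
  out <- counts |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$pos)
      island <- cumsum(c(0L, as.integer(diff(d$pos) > 2L * h)))
      list_rbind(lapply(split(seq_len(nrow(d)), island), function(idx) {
        pos <- d$pos[idx]; cnt <- d$count[idx]
        a <- max(0L, min(pos) - as.integer(h))
        b <- max(pos) + as.integer(h)
        D <- numeric(b - a + 1L)
        for (k in seq_along(pos)) {
          lo <- pos[k] - as.integer(h)
          sl <- (max(lo, a) - a + 1L):(pos[k] + as.integer(h) - a + 1L)
          D[sl] <- D[sl] + cnt[k] * kern[sl - (lo - a + 1L) + 1L]
        }
        tibble(island = island[idx[1]], pos = a:b, D = D / h)
      }))
    }) |>
    ungroup()
  attr(out, "h") <- h
  out
}

#' Local maxima of the smoothed dyad track
#'
#' Finds positions where the smoothed count is a positive local maximum, then
#' enforces a minimum separation greedily by descending height: when two
#' candidates are closer than `min_sep`, the taller one survives (ties broken
#' toward the lower coordinate). A flat plateau maximum reports its lowest
#' coordinate.
#'
#' @param smoothed output of [smooth_counts()].
#' @param min_sep minimum distance between retained maxima (bp).
#' @return tibble (chrom, pos, D) of retained maxima, sorted by position.
#' @export
find_local_maxima <- function(smoothed, min_sep = 150L) {
  stopifnot_scalar_number(min_sep, "min_sep", min = 1)
  cand <- smoothed |>
    group_by(.data$chrom, .data$island) |>
    group_modify(function(d, key) {
      r <- rle(d$D)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      v <- r$values
      nprev <- c(-Inf, v[-length(v)])
      nnext <- c(v[-1], -Inf)
      is_max <- v > 0 & v > nprev & v > nnext
      tibble(pos = d$pos[starts[is_max]], D = v[is_max])
    }) |>
    ungroup() |>
    select("chrom", "pos", "D")
  cand |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      d <- d[order(-d$D, d$pos), , drop = FALSE]
      kept <- integer(0)
      keep_row <- logical(nrow(d))
      for (i in seq_len(nrow(d))) {
        p <- d$pos[i]
        if (length(kept)) {
          j <- findInterval(p, kept)
          near <- c(if (j >= 1L) kept[j], if (j < length(kept)) kept[j + 1L])
          if (any(abs(near - p) < min_sep)) next
        }
        kept <- sort(c(kept, p))
        keep_row[i] <- TRUE
      }
      d[keep_row, , drop = FALSE]
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$pos)
}

#' Select representative dyads around smoothed maxima
#'
#' Within a window (default 60 bp) centered at each local maximum, the raw
#' dyad position with the highest count becomes the representative dyad.
#' Count ties go to the position closest to the maximum, remaining ties to
#' the lower coordinate. Windows without raw dyads yield nothing; duplicate
#' selections are collapsed.
#'
#' @param counts raw dyad counts from [count_dyads()].
#' @param maxima tibble (chrom, pos) from [find_local_maxima()].
#' @param window full window width in bp (even).
#' @return dyad map: tibble (chrom, pos, count), strictly increasing per
#'   chromosome.
#' @export
select_representative_dyads <- function(counts, maxima, window = 60L) {
  if (window %% 2L != 0L) abort("window must be even")
  half <- window %/% 2L
  reps <- maxima |>
    group_by(.data$chrom) |>
    group_modify(function(mx, key) {
      d <- counts[counts$chrom == key$chrom, , drop = FALSE]
      if (nrow(d) == 0L) return(tibble(pos = integer(), count = integer()))
      d <- arrange(d, .data$pos)
      sel <- lapply(mx$pos, function(m) {
        i0 <- findInterval(m - half - 1L, d$pos) + 1L
        i1 <- findInterval(m + half, d$pos)
        if (i0 > i1) return(NULL)
        p <- d$pos[i0:i1]; cnt <- d$count[i0:i1]
        ord <- order(-cnt, abs(p - m), p)
        tibble(pos = p[ord[1]], count = cnt[ord[1]])
      })
      sel <- sel[!vapply(sel, is.null, TRUE)]
      if (length(sel) == 0L) return(tibble(pos = integer(), count = integer()))
      list_rbind(sel)
    }) |>
    ungroup() |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)
  reps
}

#' Call representative nucleosome dyads from fragments
#'
#' Convenience wrapper: dyad counting (146-148 bp fragments), triweight
#' smoothing (h = 15), local-maxima search (min separation 150 bp), and
#' representative-dyad selection (60 bp windows).
#'
#' @inheritParams count_dyads
#' @inheritParams smooth_counts
#' @inheritParams find_local_maxima
#' @inheritParams select_representative_dyads
#' @return dyad map tibble (chrom, pos, count) with a `params` attribute
#'   recording the parameters used.
#' @export
call_dyads <- function(fragments, len_min = 146L, len_max = 148L, h = 15L,
                       min_sep = 150L, window = 60L) {
  raw <- count_dyads(fragments, len_min, len_max)
  dm <- if (nrow(raw) == 0L) {
    tibble(chrom = character(), pos = integer(), count = integer())
  } else {
    sm <- smooth_counts(raw, h)
    mx <- find_local_maxima(sm, min_sep)
    select_representative_dyads(raw, mx, window)
  }
  attr(dm, "params") <- list(len_min = len_min, len_max = len_max, h = h,
                             min_sep = min_sep, window = window)
  dm
}

#' Nucleosome regions from a dyad map
#'
#' Each representative dyad defines a 147 bp nucleosome region
#' `[dyad - 73, dyad + 74)`, clipped to chromosome bounds. Neighbouring
#' regions may overlap (dyads can be as close as 90 bp).
#'
#' @param dyads dyad map tibble (chrom, pos, ...).
#' @param genome a [genome_model()].
#' @return interval tibble of nucleosome regions with a `dyad` column.
#' @export
nucleosome_regions <- function(dyads, genome) {
  if (nrow(dyads) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  dyad = integer()))
  }
  x <- tibble(chrom = dyads$chrom, start = dyads$pos - 73L,
              end = dyads$pos + 74L, dyad = dyads$pos)
  sizes <- genome$chrom_sizes
  x$start <- pmax(x$start, 0L)
  x$end <- pmin(x$end, unname(sizes[x$chrom]))
  x[x$start < x$end, , drop = FALSE]
}

#' Dyad-aligned nucleosome occupancy profile
#'
#' Mean, over representative dyads, of the number of size-filtered fragments
#' (default 120-180 bp, the mono-nucleosome range) covering each position at
#' offsets `-flank..+flank` from the dyad. An alternative estimator based on
#' the smoothed dyad-count density is available behind `method`.
#'
#' @param fragments interval tibble of fragments.
#' @param dyads dyad map tibble.
#' @param flank half-width of the profile (bp).
#' @param len_min,len_max fragment-length filter for the coverage track.
#' @param method `"coverage"` (fragment coverage, default) or
#'   `"dyad_density"` (triweight-smoothed dyad counts of the same fragments).
#' @param h bandwidth for `method = "dyad_density"`.
#' @return tibble (offset, occupancy), offsets `-flank..flank`.
#' @export
occupancy_profile <- function(fragments, dyads, flank = 400L,
                              len_min = 120L, len_max = 180L,
                              method = c("coverage", "dyad_density"),
                              h = 15L) {
  method <- match.arg(method)
  if (nrow(dyads) == 0L) abort("no dyads")
  offs <- -flank:flank
  acc <- numeric(length(offs))
  n_dyads <- 0L
  if (method == "coverage") {
    fragments <- validate_intervals(fragments, "fragments")
    len <- fragments$end - fragments$start
    f <- fragments[len >= len_min & len <= len_max, , drop = FALSE]
    for (ch in unique(dyads$chrom)) {
      dp <- dyads$pos[dyads$chrom == ch]
      fc <- f[f$chrom == ch, , drop = FALSE]
      n_dyads <- n_dyads + length(dp)
      if (nrow(fc) == 0L) next
      cov <- IRanges::coverage(IRanges::IRanges(fc$start + 1L, fc$end))
      covlen <- length(cov)
      idx <- outer(dp, offs, `+`) + 1L
      ok <- idx >= 1L & idx <= covlen
      vals <- matrix(0, nrow(idx), ncol(idx))
      vals[ok] <- as.numeric(cov[idx[ok]])
      acc <- acc + colSums(vals)
    }
  } else {
    raw <- count_dyads(fragments, len_min, len_max)
    sm <- smooth_counts(raw, h)
    for (ch in unique(dyads$chrom)) {
      dp <- dyads$pos[dyads$chrom == ch]
      n_dyads <- n_dyads + length(dp)
      smc <- sm[sm$chrom == ch, , drop = FALSE]
      if (nrow(smc) == 0L) next
      m <- match(as.vector(outer(dp, offs, `+`)), smc$pos)
      vals <- matrix(smc$D[m] %-na% 0, length(dp), length(offs))
      acc <- acc + colSums(vals)
    }
  }
  tibble(offset = offs, occupancy = acc / n_dyads)
}
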