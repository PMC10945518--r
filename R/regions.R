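#' Open chromatin regions from DNase-seq peaks
#'
#' Each peak contributes the window `[center - flank, center + flank + 1)`
#' around its center (summit when present, otherwise the interval midpoint),
#' clipped to chromosome bounds; overlapping windows are merged.
#'
#' @param dnase_peaks interval tibble (narrowPeak-style `summit` honoured).
#' @param genome a [genome_model()].
#' @param flank half-width in bp (default 1000).
#' @return canonical interval tibble of open chromatin regions.
#' @export
open_chromatin <- function(dnase_peaks, genome, flank = 1000L) {
  stopifnot_scalar_number(flank, "flank", min = 0)
  if (nrow(dnase_peaks) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  ctr <- peak_centers(dnase_peaks)
  x <- tibble(chrom = dnase_peaks$chrom,
              start = ctr - as.integer(flank),
              end = ctr + as.integer(flank) + 1L)
  merge_intervals(clip_to_genome(x, genome))
}

#' Nucleosome-depleted regions
#'
#' NDRs are the open-chromatin bases free of mono-nucleosome fragments
#' (120-180 bp by default) across all replicate fragment sets. In the default
#' `subtract` mode the uncovered sub-intervals of each open region are
#' returned; `strict` mode keeps only whole open regions untouched by any
#' size-filtered fragment.
#'
#' @param open canonical open-chromatin interval tibble.
#' @param fragment_sets a single fragment tibble or a list of them (one per
#'   replicate); their union defines nucleosome coverage.
#' @param len_min,len_max mono-nucleosome fragment-length filter.
#' @param mode `"subtract"` (default) or `"strict"`.
#' @return interval tibble of NDRs.
#' @export
ndr_regions <- function(open, fragment_sets, len_min = 120L, len_max = 180L,
                        mode = c("subtract", "strict")) {
  mode <- match.arg(mode)
  if (is.data.frame(fragment_sets)) fragment_sets <- list(fragment_sets)
  frags <- list_rbind(lapply(fragment_sets, function(f) {
    f <- validate_intervals(f, "fragments")[c("chrom", "start", "end")]
    len <- f$end - f$start
    f[len >= len_min & len <= len_max, , drop = FALSE]
  }))
  if (mode == "subtract") {
    out <- subtract_coverage(open, frags)
    out[c("chrom", "start", "end")]
  } else {
    st <- overlap_stats(open, frags)
    st[st$overlap_bp == 0L, c("chrom", "start", "end"), drop = FALSE]
  }
}

#' Active enhancer regions
#'
#' Open chromatin regions overlapping (>= 1 bp) at least one H3K27ac peak AND
#' at least one H3K4me1 peak.
#'
#' @param open canonical open-chromatin interval tibble.
#' @param h3k27ac,h3k4me1 peak interval tibbles.
#' @return interval tibble of active enhancers.
#' @export
active_enhancers <- function(open, h3k27ac, h3k4me1) {
  a <- overlap_stats(open, h3k27ac)$overlap_bp > 0L
  b <- overlap_stats(open, h3k4me1)$overlap_bp > 0L
  open[a & b, , drop = FALSE]
}

#' Conserved open chromatin
#'
#' Reference open regions sharing strictly more than `min_share` of their
#' bases with the open set of at least one other cell line.
#'
#' @param reference_open canonical interval tibble (e.g. embryonic line).
#' @param other_open a single interval tibble or list of them (one per other
#'   cell line).
#' @param min_share strict lower bound on the shared fraction (default 0.8).
#' @return interval tibble of conserved regions.
#' @export
conserved_open <- function(reference_open, other_open, min_share = 0.8) {
  if (!(min_share > 0 && min_share <= 1)) abort("min_share must be in (0, 1]")
  if (is.data.frame(other_open)) other_open <- list(other_open)
  keep <- rep(FALSE, nrow(reference_open))
  for (oo in other_open) {
    keep <- keep | overlap_stats(reference_open, oo)$overlap_frac > min_share
  }
  reference_open[keep, , drop = FALSE]
}

#' Differentially open chromatin
#'
#' Regions of `open_in` with strictly less than `max_overlap` of their bases
#' shared with `open_other`: open in one condition, closed in the other.
#' Directionality is chosen by which set is passed as `open_in`.
#'
#' @param open_in canonical interval tibble (regions open in the focal line).
#' @param open_other canonical interval tibble (the comparison line).
#' @param max_overlap strict upper bound on the shared fraction (default 0.2).
#' @return interval tibble of differentially open regions.
#' @export
differential_open <- function(open_in, open_other, max_overlap = 0.2) {
  if (!(max_overlap >= 0 && max_overlap < 1)) abort("max_overlap must be in [0, 1)")
  frac <- overlap_stats(open_in, open_other)$overlap_frac
  open_in[frac < max_overlap, , drop = FALSE]
}

#' Annotate a cell line's chromatin regions
#'
#' Bundles [open_chromatin()], [ndr_regions()] and [active_enhancers()] for
#' one cell line.
#'
#' @param cell_line label.
#' @param dnase_peaks DNase-seq peak tibble.
#' @param fragment_sets fragments (tibble or list of replicate tibbles).
#' @param genome a [genome_model()].
#' @param h3k27ac,h3k4me1 optional histone-mark peak tibbles; when both are
#'   given, enhancers are annotated.
#' @param flank,len_min,len_max,ndr_mode passed through.
#' @return list with elements `cell_line`, `open`, `ndr`, `enhancers` (NULL
#'   without histone marks) and `params`.
#' @export
annotate_cell_line <- function(cell_line, dnase_peaks, fragment_sets, genome,
                               h3k27ac = NULL, h3k4me1 = NULL, flank = 1000L,
                               len_min = 120L, len_max = 180L,
                               ndr_mode = "subtract") {
  open <- open_chromatin(dnase_peaks, genome, flank)
  ndr <- ndr_regions(open, fragment_sets, len_min, len_max, ndr_mode)
  enh <- if (!is.null(h3k27ac) && !is.null(h3k4me1)) {
    active_enhancers(open, h3k27ac, h3k4me1)
  }
  list(cell_line = cell_line, open = open, ndr = ndr, enhancers = enh,
       params = list(flank = flank, len_min = len_min, len_max = len_max,
                     ndr_mode = ndr_mode))
}
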