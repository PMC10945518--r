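#' Genomic interval tables
#'
#' All genomic spans in nucpioneer (fragments, peaks, nucleosome regions,
#' NDRs, motif hits) are plain tibbles with at least the columns `chrom`
#' (character), `start` and `end` (0-based half-open integers, BED
#' convention), and optionally `strand` plus any metadata columns. These
#' helpers validate, read, write and do arithmetic on such tables.
#'
#' @param chrom,start,end,strand vectors defining the intervals.
#' @param ... further metadata columns.
#' @return A tibble of class `tbl_df` with one row per interval.
#' @examples
#' interval_tbl("chr1", 100, 250)
#' @export
interval_tbl <- function(chrom, start, end, strand = NULL, ...) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end)
  )
  if (!is.null(strand)) x$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) x[[nm]] <- extra[[nm]]
  validate_intervals(x)
}

validate_intervals <- function(x, what = "interval table") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(sprintf("%s lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }
  bad <- which(!(x$start >= 0L & x$start < x$end))
  if (length(bad)) {
    abort(sprintf(
      "invalid interval (need 0 <= start < end) at row %d: %s:%d-%d",
      bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  if (any(is.na(x$chrom) | x$chrom == "" | grepl("\\s", x$chrom))) {
    abort("chromosome names must be non-empty tokens without whitespace")
  }
  as_tibble(x)
}

# ---- conversion to/from Bioconductor ranges (internal) ----------------------

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) {
      ifelse(x$strand %in% c("+", "-"), x$strand, "*")
    } else "*"
  )
}

# build GRanges for several tables on a shared seqlevels universe, so
# cross-table operations never warn about disjoint sequence levels
granges_common <- function(...) {
  dfs <- list(...)
  lv <- unique(unlist(lapply(dfs, function(d) unique(d$chrom))))
  if (length(lv) == 0L) lv <- "__none__"
  lapply(dfs, function(d) {
    GenomicRanges::GRanges(
      seqnames = factor(d$chrom, levels = lv),
      ranges = IRanges::IRanges(start = d$start + 1L, end = d$end)
    )
  })
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Canonicalize an interval table
#'
#' Sorts by (chrom, start) and merges overlapping or bookended intervals into
#' their union, dropping metadata columns. Region annotations (open chromatin,
#' NDRs) are kept canonical; nucleosome-region sets are the one deliberate
#' exception since neighbouring 147 bp regions may genuinely overlap.
#'
#' @param x interval tibble.
#' @return canonical interval tibble (chrom, start, end).
#' @export
merge_intervals <- function(x) {
  x <- validate_intervals(x)
  if (nrow(x) == 0L) return(tibble(chrom = character(), start = integer(), end = integer()))
  granges_to_tbl(GenomicRanges::reduce(as_granges0(x))) |>
    arrange(.data$chrom, .data$start)
}

#' Per-interval overlap statistics
#'
#' For each query interval, the number of its bases covered by at least one
#' target interval and the covered fraction of the query.
#'
#' @param query interval tibble (rows preserved in output order).
#' @param targets interval tibble; overlapping targets are unioned first.
#' @return `query` with columns `overlap_bp` (integer) and `overlap_frac`.
#' @examples
#' overlap_stats(interval_tbl("chr1", 100, 200), interval_tbl("chr1", 150, 250))
#' @export
overlap_stats <- function(query, targets) {
  query <- validate_intervals(query, "query")
  red <- merge_intervals(targets)
  out <- query
  out$overlap_bp <- 0L
  if (nrow(query) && nrow(red)) {
    gp <- granges_common(query, red)
    qg <- gp[[1]]
    tg <- gp[[2]]
    hits <- GenomicRanges::findOverlaps(qg, tg, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(
        qg[S4Vectors::queryHits(hits)], tg[S4Vectors::subjectHits(hits)],
        ignore.strand = TRUE
      )
      bp <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
      out$overlap_bp[as.integer(names(bp))] <- as.integer(bp)
    }
  }
  out$overlap_frac <- out$overlap_bp / (out$end - out$start)
  out
}

#' Subtract covered bases from regions
#'
#' Returns the maximal sub-intervals of each region not covered by any cover
#' interval; used to carve nucleosome-depleted regions out of open chromatin.
#' Region order is preserved; a fully covered region contributes nothing.
#'
#' @param regions,covers interval tibbles.
#' @return interval tibble of uncovered sub-intervals, with a `region_id`
#'   column giving the originating row of `regions`.
#' @export
subtract_coverage <- function(regions, covers) {
  regions <- validate_intervals(regions, "regions")
  if (nrow(regions) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  region_id = integer()))
  }
  covers <- validate_intervals(covers, "covers")
  gp <- granges_common(regions, covers)
  rg <- gp[[1]]
  if (nrow(covers) == 0L) {
    out <- granges_to_tbl(rg)
    out$region_id <- seq_len(nrow(regions))
    return(out)
  }
  pieces <- GenomicRanges::subtract(rg, gp[[2]], ignore.strand = TRUE)
  n_piece <- S4Vectors::elementNROWS(pieces)
  flat <- unlist(pieces, use.names = FALSE)
  out <- granges_to_tbl(flat)
  out$region_id <- rep(seq_len(nrow(regions)), n_piece)
  out
}

#' Clip intervals to chromosome bounds
#'
#' @param x interval tibble (starts may be negative, ends may exceed the
#'   chromosome; rows emptied by clipping are dropped).
#' @param genome a [genome_model()].
#' @return clipped interval tibble.
#' @export
clip_to_genome <- function(x, genome) {
  sizes <- genome$chrom_sizes
  unknown <- setdiff(unique(x$chrom), names(sizes))
  if (length(unknown)) {
    abort(sprintf("unknown chromosome(s): %s", paste(unknown, collapse = ", ")))
  }
  x$start <- pmax(x$start, 0L)
  x$end <- pmin(x$end, unname(sizes[x$chrom]))
  x[x$start < x$end, , drop = FALSE]
}

# ---- file I/O ---------------------------------------------------------------

read_tab_lines <- function(path, min_fields) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    abort(sprintf("line %d has %d field(s), expected >= %d",
                  bad[1], nf[bad[1]], min_fields))
  }
  fields
}

parse_coord <- function(s, line_no, col) {
  v <- suppressWarnings(as.integer(s))
  bad <- which(is.na(v) | suppressWarnings(v != as.numeric(s)))
  if (length(bad)) {
    abort(sprintf("non-integer coordinate '%s' in column %d at line %d",
                  s[bad[1]], col, line_no[bad[1]]))
  }
  v
}

check_start_end <- function(x, line_no) {
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(sprintf("start >= end at line %d", line_no[bad[1]]))
  }
  bad <- which(x$start < 0L)
  if (length(bad)) abort(sprintf("negative start at line %d", line_no[bad[1]]))
  x
}

#' Read genomic intervals from standard flat formats
#'
#' `read_bed()` reads BED3+ (extra columns name/score/strand retained when
#' present); `read_narrowpeak()` reads 10-column ENCODE narrowPeak, keeping the
#' summit offset (column 10, -1 when absent) as a `summit` column;
#' `read_fragments()` is BED3 where each record is one paired-end fragment.
#' All return 0-based half-open interval tibbles.
#'
#' @param path file path.
#' @return interval tibble.
#' @export
read_bed <- function(path) {
  fields <- read_tab_lines(path, 3L)
  if (length(fields) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  ln <- seq_along(fields)
  x <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = parse_coord(vapply(fields, `[[`, "", 2L), ln, 2L),
    end = parse_coord(vapply(fields, `[[`, "", 3L), ln, 3L)
  )
  nf <- min(lengths(fields))
  if (nf >= 4L) x$name <- vapply(fields, `[[`, "", 4L)
  if (nf >= 5L) x$score <- as.numeric(vapply(fields, `[[`, "", 5L))
  if (nf >= 6L) x$strand <- vapply(fields, `[[`, "", 6L)
  check_start_end(x, ln)
}

#' @rdname read_bed
#' @export
read_narrowpeak <- function(path) {
  fields <- read_tab_lines(path, 10L)
  if (length(fields) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer()))
  }
  ln <- seq_along(fields)
  x <- tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = parse_coord(vapply(fields, `[[`, "", 2L), ln, 2L),
    end = parse_coord(vapply(fields, `[[`, "", 3L), ln, 3L),
    name = vapply(fields, `[[`, "", 4L),
    score = as.numeric(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 6L),
    signal = as.numeric(vapply(fields, `[[`, "", 7L)),
    p_log10 = as.numeric(vapply(fields, `[[`, "", 8L)),
    q_log10 = as.numeric(vapply(fields, `[[`, "", 9L)),
    summit = parse_coord(vapply(fields, `[[`, "", 10L), ln, 10L)
  )
  check_start_end(x, ln)
}

#' @rdname read_bed
#' @export
read_fragments <- function(path) read_bed(path)

#' Write intervals as BED
#'
#' Emits tab-separated, newline-terminated records without header. Columns
#' beyond chrom/start/end are written in BED order (name, score, strand) when
#' present, followed by any other metadata columns.
#'
#' @param x interval tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  lead <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  cols <- c(lead, setdiff(names(x), lead))
  readr::write_tsv(x[cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write intervals as ENCODE narrowPeak
#'
#' Missing narrowPeak columns are filled with the conventional placeholders
#' (name ".", score 0, strand ".", signal 0, -log10 p/q -1, summit -1).
#'
#' @inheritParams write_bed
#' @export
write_narrowpeak <- function(x, path) {
  x <- validate_intervals(x)
  n <- nrow(x)
  out <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$name %||% rep(".", n),
    score = x$score %||% rep(0, n),
    strand = x$strand %||% rep(".", n),
    signal = x$signal %||% rep(0, n),
    p_log10 = x$p_log10 %||% rep(-1, n),
    q_log10 = x$q_log10 %||% rep(-1, n),
    summit = x$summit %||% rep(-1L, n)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Peak center positions
#'
#' The anchor used when widening peaks into open-chromatin windows: the summit
#' (start + summit offset) when a non-negative `summit` column is present,
#' otherwise the interval midpoint `floor((start + end) / 2)`.
#'
#' @param peaks interval tibble, optionally with a `summit` column.
#' @return integer vector of center coordinates (0-based).
#' @export
peak_centers <- function(peaks) {
  mid <- (peaks$start + peaks$end) %/% 2L
  if ("summit" %in% names(peaks)) {
    s <- peaks$summit
    ifelse(!is.na(s) & s >= 0L, peaks$start + as.integer(s), mid)
  } else {
    mid
  }
}
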