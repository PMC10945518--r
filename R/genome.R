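#' Genome model
#'
#' A lightweight container for chromosome sizes and (optionally) the genome
#' sequence. Sequences are stored as plain upper-case A/C/G/T/N strings so
#' that substring arithmetic stays in base R; FASTA I/O goes through
#' Biostrings.
#'
#' @param chrom_sizes named integer vector (chromosome -> length in bp) or a
#'   two-column data frame (chrom, size).
#' @param sequence optional named character vector of chromosome sequences;
#'   names must match `chrom_sizes` and lengths must agree.
#' @return an object of class `genome_model` with elements `chrom_sizes`
#'   (named integer vector) and `sequence` (named character vector or NULL).
#' @examples
#' genome_model(c(chrI = 1000L))
#' @export
genome_model <- function(chrom_sizes, sequence = NULL) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes[[2]]),
                                   as.character(chrom_sizes[[1]]))
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    abort("chrom_sizes must be named by chromosome")
  }
  chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  if (any(chrom_sizes <= 0L)) abort("chromosome sizes must be positive")
  if (!is.null(sequence)) {
    sequence <- toupper(unlist(sequence))
    miss <- setdiff(names(chrom_sizes), names(sequence))
    if (length(miss)) {
      abort(sprintf("sequence missing for chromosome(s): %s",
                    paste(miss, collapse = ", ")))
    }
    lens <- nchar(sequence[names(chrom_sizes)])
    if (any(lens != chrom_sizes)) {
      abort("sequence lengths disagree with chrom_sizes")
    }
    sequence <- sequence[names(chrom_sizes)]
  }
  structure(list(chrom_sizes = chrom_sizes, sequence = sequence),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosome(s), %s bp total, sequence: %s\n",
              length(x$chrom_sizes),
              format(sum(as.numeric(x$chrom_sizes)), big.mark = ","),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Read a chromosome-sizes table
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  fields <- read_tab_lines(path, 2L)
  stats::setNames(
    parse_coord(vapply(fields, `[[`, "", 2L), seq_along(fields), 2L),
    vapply(fields, `[[`, "", 1L)
  )
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' @param path FASTA file.
#' @return `read_genome_fasta()` returns a [genome_model()] with sequence.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  chars <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  genome_model(stats::setNames(nchar(chars), names(chars)), chars)
}

#' @rdname read_genome_fasta
#' @param genome a [genome_model()] carrying sequence.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) abort("genome has no sequence")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequence), path, width = 70L
  )
  invisible(path)
}

#' Extract interval sequences from a genome model
#'
#' @param genome a [genome_model()] with sequence.
#' @param x interval tibble (0-based half-open, must lie within the genome).
#' @return character vector of sequences, one per row of `x`.
#' @export
genome_sequence <- function(genome, x) {
  if (is.null(genome$sequence)) abort("genome has no sequence")
  x <- validate_intervals(x)
  bad <- setdiff(unique(x$chrom), names(genome$chrom_sizes))
  if (length(bad)) abort(sprintf("unknown chromosome(s): %s", paste(bad, collapse = ", ")))
  if (any(x$end > unname(genome$chrom_sizes[x$chrom]))) {
    abort("interval extends beyond chromosome end")
  }
  substring(genome$sequence[x$chrom], x$start + 1L, x$end)
}

#' Reverse-complement DNA strings
#'
#' @param s character vector of A/C/G/T/N strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
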