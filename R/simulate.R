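#' Simulation configuration
#'
#' Defines a fully synthetic chromatin study: a random genome tiled with
#' nucleosomes at known dyads, per-cell-line open/closed chromatin blocks
#' with nucleosome-free holes (future NDRs), MNase-like fragments jittered
#' around dyads, and TF motif instances planted preferentially inside
#' nucleosome regions (pioneers) or NDRs (canonical TFs). Defaults follow the
#' pipeline's operating assumptions: ~200 bp nucleosome spacing, 147+-5 bp
#' fragments with 10 bp dyad jitter and 30 fragments per nucleosome, 40 TFs
#' of which 25% are pioneers with a 0.7 NR placement bias versus 0.1 for
#' canonical TFs.
#'
#' @param seed integer seed; every simulated byte is a deterministic function
#'   of the configuration.
#' @param genome_length,n_chromosomes genome dimensions (bp, count).
#' @param nuc_spacing_mean,nuc_spacing_sd nucleosome spacing (bp); mean must
#'   be >= 147.
#' @param fragments_per_nucleosome Poisson mean fragment count per retained
#'   nucleosome.
#' @param frag_len_mean,frag_len_sd,frag_len_min,frag_len_max fragment-length
#'   model (Gaussian, truncated).
#' @param dyad_jitter_sd positional jitter of fragment midpoints (bp).
#' @param n_tfs,pioneer_fraction TF panel size and pioneer share.
#' @param pioneer_nr_bias,canonical_nr_bias probability that a motif instance
#'   is planted inside a nucleosome region rather than an NDR.
#' @param shl_targets optional named list `tf_name -> c(shl_lo, shl_hi)`
#'   constraining that TF's in-NR placements to a superhelical window.
#' @param motif_length,n_instances motif width and instances per TF.
#' @param n_cell_lines number of cell lines (>= 1; the first plays the
#'   embryonic role, holding extra differentially open chromatin).
#' @param block_length,p_conserved_open,p_diff_open chromatin block model:
#'   the genome is tiled into blocks labelled conserved-open (open in every
#'   line), diff-open (open only in the first line) or closed.
#' @param ndr_drop probability that a nucleosome inside an open block is
#'   absent in a given cell line, leaving a nucleosome-free hole.
#' @param open_fuzz_sd extra positional dispersion (bp) of nucleosomes in
#'   open chromatin, emulating the fuzzier positioning of accessible-region
#'   nucleosomes relative to the regularly spaced arrays of closed chromatin.
#' @param ww_period optional period (bp) of planted WW dinucleotides inside
#'   nucleosomes (NA = off); used by dinucleotide QC tests.
#' @param ww_prob probability that any given comb position actually receives
#'   a WW dinucleotide: rotational sequence preferences are a statistical
#'   enrichment, not a deterministic pattern.
#' @param rpkm_meanlog,rpkm_sdlog log-normal expression model.
#' @param low_expression_fraction fraction of canonical TFs forced below the
#'   RPKM threshold, to exercise the expression filter.
#' @param enhancer_fraction fraction of open blocks receiving both histone
#'   marks (H3K27ac + H3K4me1 proxies).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6, n_chromosomes = 1L,
                       nuc_spacing_mean = 200, nuc_spacing_sd = 20,
                       fragments_per_nucleosome = 30,
                       frag_len_mean = 147, frag_len_sd = 5,
                       frag_len_min = 100, frag_len_max = 200,
                       dyad_jitter_sd = 10,
                       n_tfs = 40L, pioneer_fraction = 0.25,
                       pioneer_nr_bias = 0.7, canonical_nr_bias = 0.1,
                       shl_targets = NULL,
                       motif_length = 8L, n_instances = 200L,
                       n_cell_lines = 2L,
                       block_length = 2000L,
                       p_conserved_open = 0.35, p_diff_open = 0.25,
                       ndr_drop = 0.5,
                       open_fuzz_sd = 30,
                       ww_period = NA, ww_prob = 0.5,
                       rpkm_meanlog = log(50), rpkm_sdlog = 0.5,
                       low_expression_fraction = 0.1,
                       enhancer_fraction = 0.6) {
  if (nuc_spacing_mean < 147) abort("nucleosome spacing must be >= 147 bp")
  if (p_conserved_open + p_diff_open > 1) abort("block probabilities exceed 1")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

cell_line_names <- function(n) paste0("cell", LETTERS[seq_len(n)])

with_seed <- function(seed, code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  force(code)
}

#' Simulate the nucleosome / chromatin landscape
#'
#' Generates the genome sequence, nucleosome dyad slots, chromatin block
#' labels, per-cell-line nucleosome retention (holes become NDRs), MNase-like
#' fragments, DNase-like peaks over open blocks, and histone-mark proxy
#' peaks.
#'
#' @param cfg a [sim_config()].
#' @return a `nuc_landscape` list; see Details in [simulate_bundle()].
#' @export
simulate_landscape <- function(cfg) {
  with_seed(cfg$seed, {
    lines <- cell_line_names(cfg$n_cell_lines)
    chroms <- paste0("synth", seq_len(cfg$n_chromosomes))
    L <- as.integer(cfg$genome_length)
    seq_chars <- list()
    slots <- list()
    blocks <- list()
    for (ch in chroms) {
      seq_chars[[ch]] <- sample(DNA_BASES, L, replace = TRUE)
      # chromatin blocks
      n_block <- ceiling(L / cfg$block_length)
      lab <- sample(c("conserved", "diff", "closed"), n_block, replace = TRUE,
                    prob = c(cfg$p_conserved_open, cfg$p_diff_open,
                             1 - cfg$p_conserved_open - cfg$p_diff_open))
      bl <- tibble(chrom = ch, block_id = seq_len(n_block),
                   start = (seq_len(n_block) - 1L) * cfg$block_length,
                   end = pmin(seq_len(n_block) * cfg$block_length, L),
                   label = lab)
      blocks[[ch]] <- bl
      # nucleosome dyad slots
      n_guess <- ceiling(L / (cfg$nuc_spacing_mean - 3 * cfg$nuc_spacing_sd)) + 10L
      gaps <- pmax(round(stats::rnorm(n_guess, cfg$nuc_spacing_mean,
                                      cfg$nuc_spacing_sd)), 160)
      pos <- 150L + cumsum(as.integer(gaps))
      pos <- pos[pos < L - 150L]
      block_of <- pmin(pos %/% cfg$block_length + 1L, n_block)
      if (cfg$open_fuzz_sd > 0) {
        in_open <- lab[block_of] != "closed"
        pos <- pos + ifelse(in_open, as.integer(round(
          stats::rnorm(length(pos), 0, cfg$open_fuzz_sd))), 0L)
        pos <- sort(pmin(pmax(pos, 150L), L - 150L))
        block_of <- pmin(pos %/% cfg$block_length + 1L, n_block)
      }
      if (!is.na(cfg$ww_period) && cfg$ww_period > 0) {
        wchar <- c("A", "T")
        for (d in pos) {
          for (off in seq(-70L, 70L, by = as.integer(cfg$ww_period))) {
            if (stats::runif(1) >= cfg$ww_prob) next
            b <- d + off + 1L  # 1-based index of the first base
            seq_chars[[ch]][b:(b + 1L)] <- sample(wchar, 2L, replace = TRUE)
          }
        }
      }
      slots[[ch]] <- tibble(chrom = ch, slot_id = seq_along(pos), dyad = pos,
                            block_id = block_of,
                            block_label = bl$label[block_of])
    }
    slots <- list_rbind(slots)
    blocks <- list_rbind(blocks)

    open_in_line <- function(label, line) {
      label == "conserved" | (label == "diff" & line == lines[1])
    }

    # per-line nucleosome retention: open-block slots drop out with ndr_drop
    retained <- list_rbind(lapply(lines, function(ln) {
      open <- open_in_line(slots$block_label, ln)
      keep <- !open | stats::runif(nrow(slots)) >= cfg$ndr_drop
      mutate(slots, cell_line = ln, open_block = open, retained = keep)
    }))

    fragments <- lapply(stats::setNames(lines, lines), function(ln) {
      r <- retained[retained$cell_line == ln & retained$retained, , drop = FALSE]
      nper <- stats::rpois(nrow(r), cfg$fragments_per_nucleosome)
      idx <- rep(seq_len(nrow(r)), nper)
      n <- length(idx)
      centers <- r$dyad[idx] +
        as.integer(round(stats::rnorm(n, 0, cfg$dyad_jitter_sd)))
      lens <- as.integer(pmin(pmax(round(stats::rnorm(n, cfg$frag_len_mean,
                                                      cfg$frag_len_sd)),
                                   cfg$frag_len_min), cfg$frag_len_max))
      start <- centers - lens %/% 2L
      f <- tibble(chrom = r$chrom[idx], start = start, end = start + lens)
      f <- f[f$start >= 0L & f$end <= L, , drop = FALSE]
      arrange(f, .data$chrom, .data$start)
    })

    dnase <- lapply(stats::setNames(lines, lines), function(ln) {
      b <- blocks[open_in_line(blocks$label, ln), , drop = FALSE]
      ctr <- (b$start + b$end) %/% 2L
      tibble(chrom = b$chrom, start = ctr - 75L, end = ctr + 75L,
             name = paste0("dnase_", b$block_id), score = 1000,
             strand = ".", signal = 10, p_log10 = 5, q_log10 = 3,
             summit = 75L)
    })

    # histone-mark proxies over open blocks of the first line
    openA <- blocks[open_in_line(blocks$label, lines[1]), , drop = FALSE]
    u <- stats::runif(nrow(openA))
    mark_peak <- function(b, half) {
      ctr <- (b$start + b$end) %/% 2L
      tibble(chrom = b$chrom, start = pmax(ctr - half, 0L), end = ctr + half,
             name = "mark", score = 1000, strand = ".", signal = 5,
             p_log10 = 5, q_log10 = 3, summit = half)
    }
    h3k27ac <- mark_peak(openA[u < cfg$enhancer_fraction + 0.15, , drop = FALSE], 300L)
    h3k4me1 <- mark_peak(openA[u < cfg$enhancer_fraction, , drop = FALSE], 400L)

    structure(list(config = cfg, cell_lines = lines, chroms = chroms,
                   seq_chars = seq_chars, blocks = blocks, slots = slots,
                   retained = retained, fragments = fragments, dnase = dnase,
                   h3k27ac = h3k27ac, h3k4me1 = h3k4me1),
              class = "nuc_landscape")
  })
}

# feasible centered offsets keeping the whole motif inside [dyad-73, dyad+74)
contained_offsets <- function(mlen) {
  (-73L + mlen %/% 2L):(74L - mlen + mlen %/% 2L)
}

# nucleosome-free holes of one cell line: maximal runs of dropped slots
# flanked by retained nucleosomes, shrunk by `clear` bp on each side so
# placements stay clear of the flanking nucleosomes' fragment coverage
ndr_hole_pool <- function(retained_line, clear = 110L, min_width = 20L) {
  list_rbind(lapply(split(retained_line, retained_line$chrom), function(d) {
    d <- arrange(d, .data$dyad)
    r <- rle(d$retained)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(!r$values & starts > 1L & ends < nrow(d))
    if (!length(runs)) return(NULL)
    tibble(chrom = d$chrom[1],
           lo = d$dyad[starts[runs] - 1L] + clear,
           hi = d$dyad[ends[runs] + 1L] - clear,
           n_dropped = r$lengths[runs],
           block_label = d$block_label[starts[runs]])
  })) |>
    filter(.data$hi - .data$lo >= min_width)
}

#' Plant TF motifs into a simulated landscape
#'
#' For each TF, builds a high-information PFM around a random consensus and
#' writes `n_instances` copies of the consensus (random strand) into the
#' genome sequence: inside a nucleosome region with probability
#' `pioneer_nr_bias` (pioneers) or `canonical_nr_bias` (canonical TFs),
#' otherwise into a nucleosome-free hole in open chromatin. Pioneer in-NR
#' placements use nucleosomes in differentially open blocks (open in the
#' first cell line only), so that restricting the analysis to differential
#' chromatin sharpens their enrichment. Emits a ~200 bp ChIP-like peak per
#' instance and a per-cell-line RPKM table.
#'
#' @param cfg a [sim_config()].
#' @param landscape result of [simulate_landscape()] (modified in place:
#'   planted motifs are written into its sequence).
#' @return the landscape extended with `pfms`, `peaks` (per-TF tibbles),
#'   `tf_truth`, `instances` and `rpkm`.
#' @export
simulate_tfs <- function(cfg, landscape) {
  with_seed(cfg$seed + 1L, {
    lines <- landscape$cell_lines
    lineA <- lines[1]
    if (cfg$motif_length > 147L) abort("motif longer than a nucleosome region")
    n_pio <- round(cfg$n_tfs * cfg$pioneer_fraction)
    tf_names <- sprintf("TF%02d", seq_len(cfg$n_tfs))
    labels <- rep(c("pioneer", "canonical"), c(n_pio, cfg$n_tfs - n_pio))

    retA <- landscape$retained[landscape$retained$cell_line == lineA, ,
                               drop = FALSE]
    nr_pool_pio <- retA[retA$retained & retA$block_label == "diff", , drop = FALSE]
    nr_pool_can <- retA[retA$retained & retA$open_block, , drop = FALSE]
    ndr_pool <- ndr_hole_pool(retA)
    if (nrow(ndr_pool) == 0L || nrow(nr_pool_can) == 0L) {
      abort("landscape has no usable NR/NDR placement pools")
    }
    ndr_w <- (ndr_pool$hi - ndr_pool$lo) / sum(ndr_pool$hi - ndr_pool$lo)
    if (nrow(nr_pool_pio) == 0L) nr_pool_pio <- nr_pool_can

    mlen <- as.integer(cfg$motif_length)
    planted <- lapply(landscape$seq_chars, function(s) logical(length(s)))
    sizes <- vapply(landscape$seq_chars, length, 1L)

    pfms <- list()
    instances <- list()
    rpkm_rows <- list()
    peak_list <- list()

    for (ti in seq_len(cfg$n_tfs)) {
      tf <- tf_names[ti]
      consensus <- sample(DNA_BASES, mlen, replace = TRUE)
      m <- matrix(5, 4L, mlen, dimnames = list(DNA_BASES, NULL))
      m[cbind(match(consensus, DNA_BASES), seq_len(mlen))] <- 85
      pfms[[tf]] <- structure(list(tf_name = tf, id = tf, matrix = m),
                              class = "pfm")
      bias <- if (labels[ti] == "pioneer") cfg$pioneer_nr_bias else cfg$canonical_nr_bias
      nr_pool <- if (labels[ti] == "pioneer") nr_pool_pio else nr_pool_can
      shl <- cfg$shl_targets[[tf]]
      off_pool <- if (is.null(shl)) contained_offsets(mlen) else
        shl_to_offsets(shl[1], shl[2])
      pool_chrom <- nr_pool$chrom; pool_dyad <- nr_pool$dyad
      pool_blab <- nr_pool$block_label
      hole_chrom <- ndr_pool$chrom; hole_lo <- ndr_pool$lo
      hole_hi <- ndr_pool$hi; hole_blab <- ndr_pool$block_label
      n_inst <- cfg$n_instances
      r_chrom <- character(n_inst); r_start <- integer(n_inst)
      r_strand <- character(n_inst); r_host <- character(n_inst)
      r_dyad <- integer(n_inst); r_off <- integer(n_inst)
      r_blab <- character(n_inst); placed_ok <- logical(n_inst)
      for (k in seq_len(n_inst)) {
        host <- if (stats::runif(1) < bias) "nr" else "ndr"
        for (try in 1:50) {
          if (host == "nr") {
            i <- sample.int(length(pool_dyad), 1L)
            off <- off_pool[sample.int(length(off_pool), 1L)]
            center <- pool_dyad[i] + off
            ch <- pool_chrom[i]; host_dyad <- pool_dyad[i]; blab <- pool_blab[i]
          } else {
            # uniform per-bp placement within a nucleosome-free hole
            i <- sample.int(length(hole_lo), 1L, prob = ndr_w)
            center <- as.integer(round(stats::runif(1, hole_lo[i], hole_hi[i])))
            off <- NA_integer_
            ch <- hole_chrom[i]; host_dyad <- NA_integer_; blab <- hole_blab[i]
          }
          s <- center - mlen %/% 2L
          if (s < 0L || s + mlen > sizes[[ch]]) next
          span <- (s + 1L):(s + mlen)
          if (any(planted[[ch]][span])) next
          strand <- sample(c("+", "-"), 1L)
          word <- if (strand == "+") consensus else
            rev(c(A = "T", C = "G", G = "C", T = "A")[consensus])
          landscape$seq_chars[[ch]][span] <- word
          planted[[ch]][span] <- TRUE
          r_chrom[k] <- ch; r_start[k] <- s; r_strand[k] <- strand
          r_host[k] <- host; r_dyad[k] <- host_dyad; r_off[k] <- off
          r_blab[k] <- blab; placed_ok[k] <- TRUE
          break
        }
      }
      inst <- tibble(tf_name = tf, chrom = r_chrom, start = r_start,
                     end = r_start + mlen, strand = r_strand, host = r_host,
                     host_dyad = r_dyad, offset = r_off,
                     block_label = r_blab)[placed_ok, , drop = FALSE]
      instances[[tf]] <- inst
      ctr <- interval_midpoint(inst$start, inst$end)
      peak_list[[tf]] <- tibble(
        chrom = inst$chrom, start = pmax(ctr - 100L, 0L),
        end = pmin(ctr + 100L, sizes[inst$chrom]),
        name = paste0(tf, "_pk", seq_len(nrow(inst))), score = 1000,
        strand = ".", signal = 8, p_log10 = 6, q_log10 = 4,
        summit = ctr - pmax(ctr - 100L, 0L)
      )
    }

    # expression: log-normal, with a forced low-expression canonical subset
    n_low <- floor(sum(labels == "canonical") * cfg$low_expression_fraction)
    low_set <- utils::tail(tf_names[labels == "canonical"], n_low)
    for (tf in tf_names) {
      base_rpkm <- if (tf %in% low_set) stats::runif(1, 0, 9) else
        max(10, stats::rlnorm(1, cfg$rpkm_meanlog, cfg$rpkm_sdlog))
      rpkm_rows[[tf]] <- tibble(tf_name = tf, cell_line = lines,
                                rpkm = base_rpkm)
    }

    landscape$pfms <- pfms
    landscape$peaks <- peak_list
    landscape$instances <- list_rbind(instances)
    landscape$tf_truth <- tibble(
      tf_name = tf_names, label = labels,
      shl_lo = vapply(tf_names, function(tf)
        if (is.null(cfg$shl_targets[[tf]])) NA_real_ else cfg$shl_targets[[tf]][1], 1),
      shl_hi = vapply(tf_names, function(tf)
        if (is.null(cfg$shl_targets[[tf]])) NA_real_ else cfg$shl_targets[[tf]][2], 1)
    )
    landscape$rpkm <- list_rbind(rpkm_rows)
    landscape
  })
}

#' Simulate a complete synthetic study
#'
#' [simulate_landscape()] followed by [simulate_tfs()], finishing with the
#' assembled [genome_model()]. The result holds everything the pipeline
#' consumes: genome, fragments and DNase peaks per cell line, histone-mark
#' proxies, PFMs, per-TF peaks, the expression table, and ground truth
#' (planted dyads, TF labels, planted instances).
#'
#' @param cfg a [sim_config()].
#' @return a `nuc_sim` object (list).
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  sim <- simulate_tfs(cfg, simulate_landscape(cfg))
  seqs <- vapply(sim$seq_chars, paste0, "", collapse = "")
  sim$genome <- genome_model(vapply(sim$seq_chars, length, 1L), seqs)
  sim$seq_chars <- NULL
  class(sim) <- "nuc_sim"
  sim
}

#' @export
print.nuc_sim <- function(x, ...) {
  cat(sprintf(
    "<nuc_sim> %d chromosome(s) (%s bp), %d cell line(s), %d TFs (%d pioneer)\n",
    length(x$chroms), format(sum(as.numeric(x$genome$chrom_sizes)), big.mark = ","),
    length(x$cell_lines), nrow(x$tf_truth), sum(x$tf_truth$label == "pioneer")))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes genome FASTA, chrom.sizes, per-cell-line fragment BEDs and DNase
#' narrowPeaks, histone-mark narrowPeaks, one JASPAR file with all PFMs,
#' per-TF peak narrowPeaks, the RPKM table and truth TSVs. Returns a manifest
#' with an md5 digest per file, so reruns can be compared byte-wise.
#'
#' @param sim a `nuc_sim` from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return tibble (file, md5), invisibly sorted by file name.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_chrom_sizes(sim$genome$chrom_sizes, file.path(dir, "chrom.sizes"))
  for (ln in sim$cell_lines) {
    write_bed(sim$fragments[[ln]], file.path(dir, paste0("fragments_", ln, ".bed")))
    write_narrowpeak(sim$dnase[[ln]], file.path(dir, paste0("dnase_", ln, ".narrowPeak")))
  }
  write_narrowpeak(sim$h3k27ac, file.path(dir, "h3k27ac.narrowPeak"))
  write_narrowpeak(sim$h3k4me1, file.path(dir, "h3k4me1.narrowPeak"))
  write_jaspar(sim$pfms, file.path(dir, "motifs.jaspar"))
  for (tf in names(sim$peaks)) {
    write_narrowpeak(sim$peaks[[tf]],
                     file.path(dir, "peaks", paste0(tf, ".narrowPeak")))
  }
  readr::write_tsv(sim$rpkm, file.path(dir, "rpkm.tsv"), progress = FALSE)
  readr::write_tsv(sim$tf_truth, file.path(dir, "truth_tfs.tsv"), progress = FALSE)
  readr::write_tsv(sim$instances, file.path(dir, "truth_instances.tsv"), progress = FALSE)
  readr::write_tsv(sim$slots, file.path(dir, "truth_dyads.tsv"), progress = FALSE)
  readr::write_tsv(sim$retained, file.path(dir, "truth_retention.tsv"), progress = FALSE)
  readr::write_tsv(sim$blocks, file.path(dir, "truth_blocks.tsv"), progress = FALSE)
  files <- sort(list.files(dir, recursive = TRUE))
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(dir, files))))
  readr::write_tsv(manifest, file.path(dir, "MANIFEST.tsv"), progress = FALSE)
  invisible(manifest)
}
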