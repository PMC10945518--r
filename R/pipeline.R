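# per-base intersection of two interval tables
intersect_intervals <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gp <- granges_common(merge_intervals(x), merge_intervals(y))
  granges_to_tbl(GenomicRanges::intersect(gp[[1]], gp[[2]],
                                          ignore.strand = TRUE))
}

# total bases of x (per-base union) overlapping the union of y
bases_overlapping <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) return(0L)
  gp <- granges_common(x, y)
  sum(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(gp[[1]]), GenomicRanges::reduce(gp[[2]]),
    ignore.strand = TRUE)))
}

#' Scan all TF peak sets of a simulated or loaded study
#'
#' Builds a PWM per PFM and scans that TF's (merged) peaks against the
#' genome.
#'
#' @param sim a `nuc_sim` (or any list with `pfms`, `peaks`, `genome`).
#' @param p_threshold FIMO-style hit threshold (default 1e-4).
#' @param pseudocount,background PWM construction parameters.
#' @return motif-hit tibble for all TFs.
#' @export
scan_all_tfs <- function(sim, p_threshold = 1e-4, pseudocount = 0.1,
                         background = rep(0.25, 4)) {
  list_rbind(lapply(names(sim$pfms), function(tf) {
    pwm <- build_pwm(sim$pfms[[tf]], background, pseudocount)
    scan_motifs(pwm, sim$peaks[[tf]], sim$genome, p_threshold)
  }))
}

#' Run the pioneer-factor enrichment analysis
#'
#' End-to-end: dyad calling from the cell line's fragments, nucleosome
#' regions, open chromatin and NDRs, per-TF motif scanning, the NR-vs-NDR
#' odds-ratio enrichment with Fisher tests and BH correction, and
#' expression-filtered ranking. In `mode = "differential"` the NRs are
#' restricted to differentially open chromatin (open in `cell_line`, closed
#' in `other_line`) and the NDRs to conserved open chromatin. When the study
#' carries truth labels, ROC/PR/MCC and a Mann-Whitney comparison of pioneer
#' versus canonical scores are attached.
#'
#' @param sim a `nuc_sim` from [simulate_bundle()].
#' @param mode `"all_open"` (default) or `"differential"`.
#' @param cell_line focal cell line (default the study's first).
#' @param other_line comparison line for `mode = "differential"` (default the
#'   study's second).
#' @param hits optional precomputed motif hits from [scan_all_tfs()].
#' @param p_threshold,open_flank,min_share,max_overlap,rpkm_min,q_max,alternative
#'   analysis parameters with standard defaults.
#' @return a `nuc_enrichment_run`: list with `table` (ranked enrichment
#'   records), `metrics` (or NULL), `dyads`, `nr`, `ndr`, `hits`, `params`.
#' @export
run_enrichment <- function(sim, mode = c("all_open", "differential"),
                           cell_line = NULL, other_line = NULL, hits = NULL,
                           p_threshold = 1e-4, open_flank = 1000L,
                           min_share = 0.8, max_overlap = 0.2,
                           rpkm_min = 10, q_max = 0.05,
                           alternative = "two_sided") {
  mode <- match.arg(mode)
  cell_line <- cell_line %||% sim$cell_lines[1]
  if (!cell_line %in% sim$cell_lines) abort("unknown cell line")
  fragments <- sim$fragments[[cell_line]]
  dyads <- call_dyads(fragments)
  nr <- nucleosome_regions(dyads, sim$genome)
  open <- open_chromatin(sim$dnase[[cell_line]], sim$genome, open_flank)
  ndr <- ndr_regions(open, fragments)
  if (mode == "differential") {
    other_line <- other_line %||% (if (length(sim$cell_lines) >= 2L) sim$cell_lines[2])
    if (is.null(other_line) || !other_line %in% sim$cell_lines ||
        other_line == cell_line) {
      abort("mode 'differential' needs a distinct second cell line")
    }
    open_other <- open_chromatin(sim$dnase[[other_line]], sim$genome, open_flank)
    diff_regions <- differential_open(open, open_other, max_overlap)
    cons_regions <- conserved_open(open, list(open_other), min_share)
    nr_use <- nr[overlap_stats(nr, diff_regions)$overlap_bp > 0L, , drop = FALSE]
    ndr_use <- intersect_intervals(ndr, cons_regions)
  } else {
    nr_use <- nr
    ndr_use <- ndr
  }
  if (nrow(nr_use) == 0L || nrow(ndr_use) == 0L) {
    abort("no NR/NDR bases available in the requested mode")
  }
  if (is.null(hits)) hits <- scan_all_tfs(sim, p_threshold)
  tab <- enrichment_table(hits, nr_use, ndr_use, alternative = alternative)
  rpkm <- sim$rpkm[sim$rpkm$cell_line == cell_line, , drop = FALSE]
  ranked <- rank_candidates(tab, rpkm, rpkm_min, q_max)
  metrics <- NULL
  if (!is.null(sim$tf_truth)) {
    lab <- sim$tf_truth$label[match(ranked$tf_name, sim$tf_truth$tf_name)]
    pos <- lab == "pioneer"
    if (any(pos) && any(!pos)) {
      mw <- mann_whitney(ranked$score[pos], ranked$score[!pos],
                         alternative = "greater")
      metrics <- tibble(
        roc_auc = roc_auc(ranked$score, pos),
        pr_auc = pr_auc(ranked$score, pos),
        max_mcc = max_mcc(ranked$score, pos)$mcc,
        mw_p = mw$p_value,
        n_tf = nrow(ranked), n_pos = sum(pos)
      )
    }
  }
  structure(list(table = ranked, metrics = metrics, dyads = dyads, nr = nr_use,
                 ndr = ndr_use, hits = hits, cell_line = cell_line,
                 params = list(mode = mode, p_threshold = p_threshold,
                               open_flank = open_flank, min_share = min_share,
                               max_overlap = max_overlap, rpkm_min = rpkm_min,
                               q_max = q_max, alternative = alternative)),
            class = "nuc_enrichment_run")
}

#' @export
print.nuc_enrichment_run <- function(x, ...) {
  cat(sprintf("<nuc_enrichment_run> %s mode, cell line %s, %d TFs, %d ranked\n",
              x$params$mode, x$cell_line, nrow(x$table),
              sum(!is.na(x$table$rank))))
  if (!is.null(x$metrics)) {
    cat(sprintf("  ROC AUC %.3f | PR AUC %.3f | max MCC %.3f | MW p %.2e\n",
                x$metrics$roc_auc, x$metrics$pr_auc, x$metrics$max_mcc,
                x$metrics$mw_p))
  }
  invisible(x)
}

#' Run the binding-profile and clustering analysis
#'
#' Builds the dyad-anchored motif profile of every TF, correlates each with
#' the nucleosome occupancy profile (flagging `pcc >= 0.2` and `p < 0.05` as
#' positive-correlation nucleosome binders), computes the end/dyad binding
#' ratio, and clusters the quality-filtered profiles by binding mode.
#'
#' @inheritParams run_enrichment
#' @param occ_flank occupancy-correlation window half-width (bp).
#' @param profile_flank profile half-width (bp).
#' @param k,seed,perplexity,min_nr_bp,min_sym_pcc,max_sil clustering
#'   parameters, see [cluster_profiles()].
#' @param cluster run the clustering stage (default TRUE).
#' @return a `nuc_profiles_run`: list with `summary` (per-TF tibble:
#'   `nr_motif_bp`, `pcc`, `pcc_p`, `positive_binder`, `r_end_dyad`),
#'   `profiles`, `clusters` (a `nuc_clusters` or NULL), `occupancy`,
#'   `dyads`, `params`.
#' @export
run_profiles <- function(sim, cell_line = NULL, hits = NULL,
                         p_threshold = 1e-4, profile_flank = 1000L,
                         occ_flank = 400L, k = 6L, seed = 1234L,
                         perplexity = 30, min_nr_bp = 500L,
                         min_sym_pcc = 0.4, max_sil = 0.25, cluster = TRUE) {
  cell_line <- cell_line %||% sim$cell_lines[1]
  fragments <- sim$fragments[[cell_line]]
  dyads <- call_dyads(fragments)
  nr <- nucleosome_regions(dyads, sim$genome)
  occ <- occupancy_profile(fragments, dyads, occ_flank)
  if (is.null(hits)) hits <- scan_all_tfs(sim, p_threshold)
  tfs <- sort(unique(hits$tf_name))
  rows <- lapply(tfs, function(tf) {
    h <- hits[hits$tf_name == tf, , drop = FALSE]
    prof <- build_profile(h, dyads, profile_flank)
    nr_bp <- bases_overlapping(h, nr)
    oc <- tryCatch(occupancy_correlation(prof, occ, occ_flank),
                   error = function(e) tibble(pcc = NA_real_,
                                              p_value = NA_real_, n = NA_integer_))
    red <- tryCatch(end_dyad_ratio(prof, inf_on_zero = TRUE),
                    error = function(e) NA_real_)
    tibble(tf_name = tf, cell_line = cell_line, profile = list(prof),
           nr_motif_bp = nr_bp, pcc = oc$pcc, pcc_p = oc$p_value,
           positive_binder = !is.na(oc$pcc) & oc$pcc >= 0.2 & oc$p_value < 0.05,
           r_end_dyad = red)
  })
  profiles <- list_rbind(rows)
  clusters <- NULL
  if (cluster) {
    clusters <- cluster_profiles(profiles, k = k, seed = seed,
                                 perplexity = perplexity,
                                 min_nr_bp = min_nr_bp,
                                 min_sym_pcc = min_sym_pcc, max_sil = max_sil)
  }
  structure(list(summary = select(profiles, -"profile"), profiles = profiles,
                 clusters = clusters, occupancy = occ, dyads = dyads,
                 cell_line = cell_line,
                 params = list(p_threshold = p_threshold,
                               profile_flank = profile_flank,
                               occ_flank = occ_flank, k = k, seed = seed,
                               perplexity = perplexity, min_nr_bp = min_nr_bp,
                               min_sym_pcc = min_sym_pcc, max_sil = max_sil)),
            class = "nuc_profiles_run")
}

#' @export
print.nuc_profiles_run <- function(x, ...) {
  cat(sprintf("<nuc_profiles_run> cell line %s, %d TF profiles, %d positive binders\n",
              x$cell_line, nrow(x$summary), sum(x$summary$positive_binder)))
  invisible(x)
}
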