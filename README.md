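# nucpioneer

Pioneer transcription factor (PTF) detection from nucleosome-resolved
chromatin maps.

Most transcription factors need nucleosome-free DNA; pioneer factors can
recognize their motif on DNA still wrapped around the histone octamer and
initiate chromatin opening. `nucpioneer` scores every TF's propensity to
bind nucleosomal DNA by integrating MNase-seq (nucleosome dyads), DNase-seq
(open chromatin) and ChIP-seq + JASPAR motifs (binding sites), then
characterizes *where* on the nucleosome each TF binds and clusters TFs by
binding mode.

## The statistic at the core

For one TF, count genome base pairs covered by its motif hits on nucleosome
regions (NRs, 147 bp windows around representative dyads) and on
nucleosome-depleted regions (NDRs, open-chromatin bases free of
mono-nucleosome fragments):

|            | NR  | NDR |
|------------|-----|-----|
| motif      | a   | c   |
| non-motif  | b   | d   |

```
enrichment score (odds ratio) = (a/c) / (b/d) = ad / bc
```

Scores above 1 flag pioneer-like nucleosome binding; Fisher's exact test and
Benjamini–Hochberg FDR give significance, and an RPKM ≥ 10 expression filter
keeps the ranking biologically meaningful. Upstream, dyads are called from
146–148 bp fragment midpoints smoothed with a triweight kernel
`K(u) = (1-(u/h)^2)^3` (h = 15 bp); downstream, dyad-anchored motif profiles
yield an end/dyad binding ratio over superhelical locations (SHL ±5.5–7 vs
0–±1.5) and k-medoids clusters of binding modes.

## Worked example

```r
library(nucpioneer)

sim  <- simulate_bundle(sim_config(seed = 42, genome_length = 3e5,
                                   n_tfs = 10, n_instances = 100))
hits <- scan_all_tfs(sim)                 # FIMO-style PWM scan, p < 1e-4
er   <- run_enrichment(sim, hits = hits)  # dyads -> regions -> Eq. above
er
#> <nuc_enrichment_run> all_open mode, cell line cellA, 10 TFs, 10 ranked
#>   ROC AUC 1.000 | PR AUC 1.000 | max MCC 1.000 | MW p 2.22e-02
head(tidy(er)[, c("tf_name", "a", "c", "score", "q_value", "rank", "flag")], 5)
#> # A tibble: 5 x 7
#>   tf_name     a     c  score   q_value  rank flag
#> 1 TF02      487   248 1.24   5.56e-  3     1 ok
#> 2 TF01      510   272 1.19   2.26e-  2     2 ok
#> 3 TF07      132   672 0.124  4.21e-151     3 ok
#> 4 TF10       64   728 0.0553 3.85e-219     4 ok
#> 5 TF05       64   732 0.0550 1.39e-220     5 ok
```

TF01 and TF02 are the two planted pioneers: ~70% of their motif bases sit on
nucleosome regions, so their odds ratios exceed 1 while the canonical TFs —
planted into nucleosome-free holes — are strongly depleted (scores ≪ 1,
two-sided Fisher q-values near machine zero). The attached metrics compare
scores against the planted labels: perfect separation here (ROC AUC 1.0).

The binding-geometry side:

```r
pr <- run_profiles(sim, hits = hits, cluster = FALSE)
head(tidy(pr)[, c("tf_name", "nr_motif_bp", "pcc", "positive_binder", "r_end_dyad")], 5)
#> # A tibble: 5 x 5
#>   tf_name nr_motif_bp      pcc positive_binder r_end_dyad
#> 1 TF01            510  0.538   TRUE                 0.625
#> 2 TF02            487  0.522   TRUE                 0.980
#> 3 TF03             48  0.00108 FALSE                2.29
#> 4 TF04             50 -0.107   FALSE                0.75
#> 5 TF05             64 -0.00273 FALSE                2
```

The pioneers correlate positively (pcc ≥ 0.2, p < 0.05) with the
dyad-aligned occupancy profile — their motifs live where nucleosomes are —
and their end/dyad ratios report where on the wrap they sit.
`run_profiles(..., cluster = TRUE)` adds t-SNE + k-medoids clustering of the
normalized half-profiles with silhouette-based outlier removal.

A thin command-line wrapper (`inst/cli/nucpioneer.R`) exposes `simulate`,
`dyads`, `enrich` and `profiles` subcommands over the same functions.

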