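---
title: "Detecting pioneer transcription factors from nucleosome-resolved chromatin maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pioneer transcription factors from nucleosome-resolved chromatin maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucpioneer)
```

## The problem

Pioneer transcription factors (PTFs) are the minority of TFs that can engage
their binding motif while the DNA is still wrapped around a histone octamer,
initiating local chromatin opening. Most TFs ("canonical" binders) require
nucleosome-free DNA. nucpioneer scores this distinction genome-wide by
integrating three data types:

* **MNase-seq** paired-end fragments, which report nucleosome footprints and,
  through fragment midpoints, nucleosome dyad positions;
* **DNase-seq** narrowPeaks, which mark open chromatin;
* **ChIP-seq** peaks plus **JASPAR** position frequency matrices, which
  localize each TF's sequence-specific binding.

The package covers the full chain: dyad calling, region annotation, motif
scanning, the enrichment statistic, dyad-anchored binding profiles with
superhelical-location (SHL) summaries, clustering of binding modes, and a
synthetic-data generator that makes every stage testable without external
downloads.

## Dyad calling from MNase-seq fragments

Fragments of 146–148 bp protect exactly one nucleosome wrap, so their
midpoints estimate dyads sharply. Per-coordinate midpoint counts $d(j)$ are
smoothed with a triweight kernel,

$$K(u) = \left(1 - (u/h)^2\right)^3 \;\; (|u| \le h), \qquad
D(i) = \frac{1}{h}\sum_j K(i-j)\, d(j),$$

with bandwidth $h = 15$ bp: small enough to keep positional accuracy, large
enough to merge midpoint jitter. Local maxima of $D$ at least 150 bp apart
(greedy by height; plateau ties resolved to the lowest coordinate) seed a
60 bp window in which the raw position with the highest count becomes the
*representative dyad* (count ties go to the position closest to the maximum,
then to the lower coordinate). Each representative dyad defines a 147 bp
nucleosome region (NR), $[d-73, d+74)$. The construction guarantees
representative dyads at least 90 bp apart, so neighbouring NRs can overlap by
at most 57 bp; all base-pair totals therefore use per-base unions.

Smoothing is evaluated sparsely: $K(\pm h) = 0$, so $D$ is exactly zero more
than $h$ bp from any observed midpoint, and only "islands" of support are
materialized. The result is identical to the dense double loop (the test
suite asserts agreement to $10^{-12}$) at a fraction of the memory.

Two QC views validate the calls: the dyad-aligned occupancy profile (mean
coverage by 120–180 bp fragments at offsets ±400 bp) and WW/SS dinucleotide
profiles, whose ~10 bp periodicity reflects the rotational positioning of
real nucleosomal DNA. "Occupancy" is deliberately defined as mean fragment
coverage — the standard MNase-seq estimator; a smoothed-dyad-density variant
is available behind `occupancy_profile(method = "dyad_density")` for
robustness checks.

## Region annotation

Open chromatin is the ±1000 bp window around each DNase peak center (summit
when present, else the interval midpoint), merged. Nucleosome-depleted
regions (NDRs) are the open-chromatin bases *not* covered by any
mono-nucleosome (120–180 bp) fragment; we return the uncovered
sub-intervals (`mode = "subtract"`) rather than requiring whole peaks to be
untouched (`mode = "strict"`), because in realistically covered data the
strict reading leaves almost no NDR bases. Active enhancers are open regions
overlapping both an H3K27ac and an H3K4me1 peak.

Comparing two cell lines, a region is *conserved open* when strictly more
than 80% of its bases are shared with the open set of at least one other
line, and *differentially open* when strictly less than 20% are shared —
both thresholds exposed as parameters. The comparisons are directional: the
set passed as the focal line defines which condition is "open".

## Motif scanning with exact p-values

JASPAR count matrices become log-odds PWMs,
$\mathrm{PWM}_{b,j} = \log_2\frac{(c_{b,j} + \pi\,q_b)/(N_j + \pi)}{q_b}$,
with uniform background $q$ and total pseudocount $\pi = 0.1$. The null
distribution of the window score is computed exactly by convolving the four
per-column score distributions over an integer grid: matrix entries are
rounded to a granularity of $10^{-3}$ bits, so for motif length $L \le 20$
the cumulative rounding shift is below 0.01 bits and p-values near the
$10^{-4}$ emission threshold are accurate to well under 1% relative error.
Scores and p-value lookups share the same rounded grid, which is what lets
the test suite check the dynamic program against exhaustive enumeration of
all $4^L$ words to $10^{-9}$.

Both strands are scanned (the minus strand via the reverse-complemented
matrix, reported on forward coordinates); windows containing N are skipped;
overlapping peaks are unioned before scanning so shared bases are scanned
once; overlapping hits of one TF are all retained, and downstream base-pair
counting deduplicates per base.

## The enrichment score

For one TF, with $a$/$c$ the motif-covered bases on NRs/NDRs and $b$/$d$ the
remaining NR/NDR bases, the pioneer propensity score is the odds ratio

$$\mathrm{score} = \frac{a/c}{b/d} = \frac{ad}{bc}.$$

Scores above 1 mean the TF's motifs cover nucleosomal DNA more densely than
nucleosome-free DNA. Significance comes from Fisher's exact test on the raw
integer table (two-sided by default, since both nucleosome-enriched and
nucleosome-depleted TFs are of interest; one-sided available), with
Benjamini–Hochberg correction across TFs. Zero cells trigger the
Haldane–Anscombe +0.5 correction *for the score only* — the exact test keeps
raw counts. Candidates are then filtered to expressed TFs (RPKM ≥ 10) and
FDR `q < 0.05`, and ranked by score; excluded records are flagged
(`low_expression`, `q_value`, `no_rpkm`) rather than dropped.

The Fisher p-value is computed directly from the hypergeometric distribution
(probability-based two-sided definition, tallying all tables with the same
margins whose probability does not exceed the observed one); this form
vectorizes over the hundreds of thousands of tables the exhaustive test
sweeps, and is cross-checked against `stats::fisher.test` in the suite.

Two analysis modes mirror the two biological questions: `all_open` compares
all NRs against NDRs in open chromatin; `differential` restricts NRs to
differentially open chromatin and NDRs to conserved open chromatin, asking
which TFs sit on nucleosomes precisely where accessibility differs between
cell states.

## Binding-motif profiles and interaction modes

Each motif hit is assigned to the dyad closest to its midpoint (ties to the
lower coordinate — the midpoint is the unique strand-invariant anchor), and
every hit base within ±1000 bp increments the profile at its dyad offset.
Strands are counted in genomic orientation; the nucleosome's two-fold
symmetry is exploited later by averaging the two halves rather than by
flipping minus-strand hits.

Three summaries characterize each TF:

* **Occupancy correlation**: Pearson correlation between the profile and the
  occupancy profile over ±400 bp, with a t-distribution p-value
  (2·400−1 df). TFs with `pcc >= 0.2` and `p < 0.05` are flagged as
  positive-correlation nucleosome binders.
* **End/dyad ratio** $R_{\mathrm{end/dyad}}$: motif bases in the DNA-end
  windows (SHL ±5.5 to ±7) over those near the dyad (SHL 0 to ±1.5). SHLs
  convert to bp as $\mathrm{round}(\mathrm{SHL} \times 73/7)$ with halves
  rounded away from zero, so SHL 7 maps exactly to the ±73 bp DNA end; the
  end window spans 34 offsets and the dyad window 33. The conversion factor
  is a package choice (73 bp per 7 turns); alternatives near 10 bp/turn
  shift window edges by at most 1–2 bp.
* **Symmetry PCC**: correlation between counts at offsets +1..+73 and the
  mirrored −1..−73, used as a QC filter (full nucleosomal halves; the
  clustering input itself is trimmed to ±60 bp).

Profiles are counted in base pairs (not motif instances), so a TF's profile
mass equals its motif-base total within range — an invariant the tests
assert.

## Clustering binding modes

Profiles surviving QC (≥ 500 motif bases on NRs; symmetry PCC ≥ 0.4) are
folded into half-profiles, $\mathrm{half}(i) = (X(+i) + X(-i))/2$ for
$i = 1..60$ with $\mathrm{half}(0) = X(0)$ — the entry/exit region beyond
±60 bp is excluded because MNase's A/T cleavage preference biases profile
shape near fragment ends — then min–max normalized so shape, not amplitude,
drives clustering. Combination by mean versus sum is immaterial after
normalization. The half-profiles are embedded in 2-D by exact t-SNE
(theta = 0; perplexity 30, auto-reduced below `(n-1)/3`; fixed seed) and
partitioned by PAM k-medoids with k = 6 by default; members with silhouette
width ≤ 0.25 are relabelled outliers, with silhouettes computed once before
removal. Clustering on the embedding follows the reference procedure;
`embed = FALSE` clusters the 61-dimensional half-profiles directly as a
robustness check.

## The synthetic-data generator

`simulate_bundle()` builds a complete study whose ground truth is known:

* a uniform-random genome (default 1 Mb) tiled with nucleosome slots at
  spacing 200 ± 20 bp (gaps floored at 160 bp);
* chromatin blocks of 2 kb labelled conserved-open (35%), differentially
  open — open only in the first, embryonic-like cell line (25%) — or closed;
* per cell line, each open-block nucleosome is absent with probability 0.5,
  leaving nucleosome-free holes that become NDRs; open-chromatin nucleosomes
  also receive 30 bp of extra positional dispersion (`open_fuzz_sd`),
  emulating the fuzzier positioning of accessible-region nucleosomes
  relative to closed-chromatin arrays;
* 30 fragments per retained nucleosome (Poisson), midpoints jittered by
  10 bp, lengths 147 ± 5 bp truncated to 100–200;
* 40 TFs (25% pioneers), each with a high-information 8-mer PFM whose
  consensus is physically written into the genome 200 times: into NRs with
  probability 0.7 (pioneers) or 0.1 (canonical), otherwise uniformly into
  NDR holes, with a ~200 bp ChIP-like peak around each instance — so the
  scanner must rediscover the planted sites;
* an RPKM table with a forced low-expression subset, and histone-mark proxy
  peaks over open blocks.

Two geometry choices deserve explanation. First, the block probabilities and
hole rate set the genome-wide NR:NDR base ratio near 1.7:1; with the 0.7 vs
0.1 placement biases this maps pioneers to density odds ratios above 1 and
canonical TFs far below 1, which is the contrast the enrichment statistic is
built to detect. Second, pioneer in-NR placements use nucleosomes in
differentially open blocks, so restricting the analysis to differential
chromatin concentrates their signal — the synthetic analogue of the
differential-mode improvement the pipeline reports.

What the generator does *not* emulate: MNase sequence bias, TF co-binding,
replicate structure beyond pooled Poisson sampling, GC heterogeneity, and
realistic motif degeneracy (planted instances are exact consensus copies).
Passing tests therefore demonstrate the correctness of the machinery and the
detectability of planted contrasts, not performance on real chromatin.

Dinucleotide QC uses a dedicated configuration: WW dinucleotides are planted
every 10 bp inside nucleosomes *with probability 0.5 per comb position*
(rotational preferences are statistical, not deterministic), on a
high-coverage landscape (60 fragments per nucleosome, 4 bp jitter) because
resolving 10 bp features needs 1–2 bp dyad accuracy. A single 146-point
profile has a noise floor of ~0.15–0.25 on the maximal autocorrelation, so
the shuffled-dyad null is assessed on the autocorrelation curve averaged
over ten shuffle replicates — the standard permutation treatment — rather
than on one noisy maximum.

With the default biases (canonical TFs still place 10% of instances on
nucleosomes), per-TF occupancy correlations of canonical TFs hover near
zero; the anti-correlation expected of purely nucleosome-avoiding binding is
asserted on panels generated with `canonical_nr_bias = 0`, where all
canonical TFs show negative correlations.

## Numerical choices and degenerate inputs

* Fragment/hit midpoints use `start + floor(len/2)`; all coordinates are
  0-based half-open (BED convention), converted at I/O boundaries.
* Local-maximum plateaus resolve to the lowest coordinate; min-separation is
  enforced greedily by descending height — both choices exist purely for
  determinism.
* Constant profiles min–max normalize to all zeros; constant inputs to
  correlations raise errors rather than returning NA silently.
* A zero dyad-window count makes the end/dyad ratio undefined; the default
  errors, `inf_on_zero = TRUE` returns `Inf` (used by the pipeline so such
  TFs sort as extreme end-binders rather than crashing the run).
* `p(-Inf) = 1` and scores above the attainable maximum give `p = 0` in the
  PWM p-value lookup.
* Every stochastic step (simulation, t-SNE) consumes an explicit seed and
  restores the caller's RNG state; PAM is deterministic.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data:
a 1 Mb default study (~3,400 nucleosomes, ~150k fragments per cell line,
40 TFs × 200 planted sites), 0.3–0.5 Mb panels for binding-mode and QC
analyses, and 60 template half-profiles for clustering recovery. These sizes
were chosen so the full chain exercises every code path in minutes on one
core while leaving planted contrasts statistically unambiguous.

## Known limitations

* NDR definition ("subtract") and Fisher sidedness ("two-sided") are
  documented package choices where the field uses both conventions; both are
  switchable.
* The enrichment score inherits the odds ratio's sensitivity to very small
  $c$ cells; the Haldane–Anscombe correction bounds but does not remove it.
* t-SNE coordinates are seed-reproducible but not stable across Rtsne
  versions; cluster *memberships* on well-separated data are.
* The SHL↔bp conversion is fixed at 73/7 bp per turn; sequences with
  stretched or compressed wraps are not modelled.
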