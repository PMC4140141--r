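---
title: "Methods: windowed differential methylation around the TSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed differential methylation around the TSS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscan)
```

## The model and its assumptions

methscan compares per-probe methylation fractions (beta values, in [0, 1])
between a disease and a healthy group of samples, and asks where along the
gene — on a signed axis with the transcription start site at 0, gene body
positive, promoter negative — the two groups differ, separately for classes
of genes (e.g. immune-inflammatory vs cell-cycle vs stably expressed).

The per-probe unit of analysis is deliberately minimal:

- a two-sided Mann–Whitney rank-sum p-value for disease vs healthy betas;
- a Storey (or Benjamini–Hochberg) q-value across all probes;
- the *methyl score*, mean(disease) − mean(healthy), whose sign classifies
  the probe as *negative* (hypomethylated in disease) or *positive*.

The rank test assumes independent samples within and between groups and
exchangeability under the null; it makes no distributional assumption on
the betas. Because rank tests are invariant to monotone transforms, testing
betas rather than M-values changes nothing about the p-values; it does
change the methyl score, which we keep on the beta scale so that a score of
−0.30 reads directly as a 30-percentage-point methylation loss. Probes are
treated as independent in the FDR step, which is the standard (if
optimistic) practice for array-scale screens; spatial correlation between
neighbouring probes is instead *exploited* descriptively by the window
statistics.

All downstream statistics consume only the *significant* probes — q ≤ 0.05
(inclusive) and TSS offset within [−2,000, +2,000] (inclusive). The
threshold q = 0.05 is kept inclusive and boundary probes are kept on both
window edges; with integer offsets, half-open windows would silently shift
counts by one probe at each boundary, so every interval in the package is
closed and documented as such.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `q_max` | 0.05 | — | conventional FDR budget; inclusive |
| `scope` | [−2000, +2000] | bp | CpG island/shore/shelf influence extends ~2 kb on either flank of the TSS |
| window width / step | 140 / 1 | bp | nucleosome-scale resolution; step 1 gives maximal positional detail |
| `min_probes` (140-bp tracks) | 3 per group | probes | a rank test on < 3 vs 3 observations cannot reach conventional significance and freq-neg from 1–2 probes is noise |
| promoter interval | [−1700, 0] | bp | the proximal-promoter span used for cluster calls; includes 0 |
| cluster `min_probes` | 3 | probes | "more than two" significant signed probes per gene |
| cluster scan | 800 / 50, [+750, −1500], ≥ 4 probes | bp | coarse positional map of sign homogeneity; "more than three" probes per gene per window |
| `min_genes` (correlation) | 10 | genes | Spearman rho on fewer than ~10 points is dominated by rank noise |
| FDR method | `storey` | — | estimates π₀ instead of fixing it at 1; `bh` offered for users who want the more conservative, assumption-free step-up |

The per-window test in `difference_track(mode = "freq_neg")` is a
Mann–Whitney test on −1/+1 sign indicators. The choice of test statistic
for windowed sign comparisons is genuinely open — a two-proportion
chi-squared is the natural alternative and is available via
`test = "proportion"` — but the rank test on indicators keeps one testing
machinery across all modes, and on 2-level data it is equivalent to a
tie-corrected rank comparison of the two sign distributions. No
multiple-testing correction is applied across windows: the tracks are
descriptive localisation devices, neighbouring windows overlap in 139 of
140 positions and are therefore maximally dependent, and the reported
per-window significance bands must be read as raw.

Two further open choices were resolved as follows. Dispersion comparisons
(`score_dispersion`) default to pairwise F tests of the reference group
against each other group, with a pooled mode available — pairwise keeps the
two-group F distribution exact. The expression split operates on per-gene
summaries (one observation per gene), not per-probe values, so that genes
with many probes do not dominate the rank test; per-probe pooling would
pseudo-replicate within-gene correlation.

## The synthetic study generator

`simulate_methylation()` emulates the design the package targets:

- 12 disease and 11 healthy samples;
- three gene classes of 1,284 (immune), 1,038 (cell cycle) and 575
  (stable) genes;
- per gene, a Poisson(6) number of probes placed uniformly on
  [−2,500, gene end], with gene end fixed at +5,000 bp — probe density
  comparable to 450K promoter coverage;
- per-probe baseline means drawn from Beta(mean 0.5, precision 4) — a
  broad, U-leaning law mimicking the wide baseline spread of array
  methylation — and per-sample betas from Beta(probe mean, precision 50),
  i.e. a per-probe sampling s.d. of about 0.07;
- a planted mean shift of −0.30 on the disease side for immune-class
  probes between −1,500 and +900 bp of the TSS (shifted means are clipped
  into (0, 1) and the clip count reported);
- per-gene differential expression `expr_slope × (mean planted shift of
  the gene's probes in the effect window) + N(0, expr_noise_sd)`, with
  slope −10 and noise s.d. 1, so expression moves opposite to methylation.

All draws come from a single seeded generator in a fixed order (probe
counts, positions, baseline means, healthy betas, disease betas,
expression noise), so a configuration is bit-reproducible from its seed.

What the generator does *not* emulate: Infinium I/II chemistry and probe
bias, cross-reactive probes, cell-type composition shifts between inflamed
and healthy tissue, spatially autocorrelated methylation along a gene,
bimodal CpG-island/open-sea baseline structure, and realistic
heteroscedastic expression noise. Passing tests on synthetic data
therefore demonstrate that the statistics recover what they define —
planted sign structure, its genomic localisation and its coupling to
expression — not that real gingival arrays would reproduce any published
effect size. One visible consequence of the clean design: classes without
a planted effect yield only the handful of false-positive probes that the
FDR budget admits, so their windowed tracks are sparse and mostly masked,
whereas real tissue comparisons produce thousands of significant probes in
every class.

## Numerical choices

- **Mann–Whitney**: exact enumeration only when both groups have ≤ 10
  observations and the pooled data are tie-free; otherwise the
  tie-corrected normal approximation with continuity correction. With the
  default 12 + 11 design the approximation path is always taken; the null
  distribution is discrete, so null p-values are sub-uniform and FDR
  control is conservative (the test suite checks this). Identical
  constant inputs return p = 1 rather than NaN.
- **Storey π₀**: `mean(p > λ)/(1 − λ)` on λ = 0.05…0.95,
  `smooth.spline(df = 3)` evaluated at λ = 0.95, clamped into (0, 1]; a
  non-positive estimate falls back to 1/m with a warning. q-values are
  `cummin` from the largest p downward, capped at 1.
- **Windows**: closed integer intervals aggregated by sorted-offset
  cumulative sums (`findInterval`), so profiling is O(n log n + W) and is
  tested against a naive recount.
- **Spearman**: rho is Pearson on mid-ranks (ties supported); p exact via
  the permutation null for n < 10 tie-free pairs, t-approximation
  otherwise; |rho| = 1 reports p = 0.
- **Degenerate inputs**: probes need ≥ 2 non-missing values per condition
  (otherwise dropped and counted); empty survivor sets warn and downstream
  stages no-op; zero-variance dispersion tests and empty cluster-call sets
  are hard errors; zero-score probes carry no sign and are excluded from
  freq-neg denominators and from cluster-homogeneity decisions — a gene
  whose promoter probes are {−, −, 0} is still an all-negative cluster.
- **Ties in betas**: midranks with the variance tie-correction; the exact
  enumeration path refuses ties and falls back to the approximation.

One TSS per gene is assumed throughout; with multiple annotated TSSs the
annotation must pre-select one. Coordinate conversion happens once
(`tss_offset`, strand-aware, 1-based inputs); all downstream code sees only
signed offsets.

## Problem sizes used by the test suite

Unit tests run on reduced simulations (40/30/20 genes per class, ~500
probes) where behaviour, not power, is under test. Calibration and
recovery checks use the sizes the questions demand: π₀ under a uniform
null at m = 10,000 over 10 seeds; null calibration at ~2,000 probes × 10
replicates; parameter recovery on the full default design (≈ 17,000
probes) over 10 seeds. These sizes keep the whole suite in the low minutes
on one core while leaving the stochastic criteria enough replicates to be
meaningful.

## Known limitations

- The pipeline consumes normalised beta values; raw IDAT processing,
  normalisation, detection-p QC and cell-composition correction are out of
  scope.
- Expression integration joins on gene symbol and treats the expression
  table as given; platform probe→symbol mapping is the caller's problem.
- Windowed tracks are descriptive; their per-window p-values are not
  corrected and should not be read as genome-wide inference.
- The cluster scan reports all windows and takes no position on where
  homogeneous-positive windows peak; with sparse probes per gene the
  ≥ 4-probe rule discards most genes per window by design.
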