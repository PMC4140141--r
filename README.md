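# methscan

Differential DNA-methylation analysis around transcription start sites, for
two-condition Infinium 450K-style beta-value data organised into gene
classes.

The package is built for the kind of question raised by inflammatory
disease epigenomics — for example, comparing gingival tissue from chronic
periodontitis patients against healthy controls: are immune-inflammatory
genes demethylated in disease relative to cell-cycle or stably expressed
genes, where along the gene does that happen, and does it track mRNA
expression? Its users are analysts who already have normalised beta values,
a probe-to-gene annotation with TSS-relative positions, gene-class lists
and a per-gene differential-expression table.

## What it computes

For each probe *p* with beta values in a disease group *D* and a healthy
group *H*:

- **Mann–Whitney test**: a two-sided rank-sum p-value comparing the two
  groups' beta values (exact null when both groups have ≤ 10 tie-free
  observations, tie-corrected normal approximation with continuity
  correction otherwise).
- **q-value**: Storey FDR by default — π₀ estimated on the λ-grid
  0.05…0.95 with a cubic smoothing spline evaluated at λ = 0.95, then
  `q = cummin(π₀ · m · p / rank)` capped at 1 — or plain
  Benjamini–Hochberg.
- **methyl score**: `m_p = mean(beta_D) − mean(beta_H)`. Probes with
  `m_p < 0` are *negative* (less methylated in disease), `m_p > 0`
  *positive*.

Probes with `q ≤ 0.05` inside ±2,000 bp of the TSS feed the downstream
stages:

- **Group comparison**: Pearson chi-squared on the group × {negative,
  positive} table; two-sided F tests of methyl-score dispersion; type-7
  quartile summaries.
- **Window scan**: 140-bp windows shifted 1 bp from +2,000 down to
  −2,000 (window *w* covers `[w − 140, w]`, labelled by its 5′ offset);
  per window, *freq-neg* = n_neg / (n_neg + n_pos) and the mean methyl
  score; between-group differences tested per window by Mann–Whitney.
- **Cluster analysis**: genes with ≥ 3 significant signed probes in the
  promoter (0 to −1,700 bp) are called `neg` / `pos` / `negpos` by sign
  homogeneity; the *cluster frequency* is (neg + pos)/total; an 800-bp,
  50-bp-shift scan from +750 to −1,500 maps where all-negative and
  all-positive genes concentrate (genes need ≥ 4 probes in a window to
  qualify).
- **Expression link**: genes split by the sign of differential mRNA
  expression and compared on methyl score and freq-neg (Mann–Whitney);
  windowed Spearman correlation of a per-gene summary — freq-neg, mean
  methyl score, or their product (the *interaction* parameter) — against
  differential expression.

A synthetic-data generator (`simulate_methylation()`) emulates the study
design end to end: 12 disease vs 11 healthy samples, immune / cell-cycle /
stable gene classes of 1,284 / 1,038 / 575 genes, Beta-distributed probe
values, a planted hypomethylation shift in the immune class between −1,500
and +900 bp, and per-gene expression changes anti-correlated with the
planted methylation change. `null_calibration()` checks the testing stack
on effect-free data.

## Worked example

```r
library(methscan)

sim <- simulate_methylation(sim_config(seed = 42))
fit <- meth_diff(sim$beta, sim$annotation)
fit
#> methdiff: 17271 probes, 12 disease vs 11 healthy samples
#>   FDR: storey (pi0 = 1.000); 2462 probe(s) with q <= 0.05

sig <- filter_significant(fit)
#> significant probes per group: cellcycle=12, immune=2394, stable=8

sign_contingency_test(sig)
#> probe-sign contingency (Pearson chi-squared, no continuity correction)
#>             negative positive
#>   cellcycle        7        5
#>   immune        2391        3
#>   stable           2        6
#> chi2 = 1128, df = 2, p = 9.607e-246

calls <- classify_promoter_clusters(sig)
cluster_frequency(calls[calls$group == "immune", ])$fraction
#> [1] 1

split_by_expression_sign(sig[sig$group == "immune", ], sim$expression)
#> expression_split: 1070 up- vs 13 down-regulated genes
#>   mean methyl score, up vs down: Mann-Whitney p = 2.49e-07
#>   freq-neg,          up vs down: Mann-Whitney p = 3.05e-07

peak_correlation(windowed_correlation(sig[sig$group == "immune", ],
                                      sim$expression))
#>      window_id        rho      p_value n_genes
#> 3184     -1183 -0.3693089 3.307483e-06     150
```

Reading the output: almost every significant probe in the immune class is
negative (hypomethylated in disease) while the other classes stay balanced,
so the sign contingency is overwhelmingly significant; every classified
immune promoter is an all-negative cluster; up-regulated genes have lower
methyl scores than down-regulated ones; and the interaction parameter is
significantly negatively rank-correlated with expression, strongest in the
window whose 5′ edge is 1,183 bp upstream of the TSS (150 genes) — i.e.
the pipeline recovers the planted promoter-proximal hypomethylation and its
coupling to transcription.

`run_pipeline()` chains all stages and `write_report()` emits the TSV /
YAML / markdown bundle.

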