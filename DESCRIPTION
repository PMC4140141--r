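Package: methscan
Title: Sliding-Window Analysis of Differential DNA Methylation Around
    Transcription Start Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential methylation analysis for two-condition Infinium
    450K-style beta-value matrices, organised around gene classes. Per-probe
    Mann-Whitney testing with Storey or Benjamini-Hochberg false discovery
    rate control and methyl-score sign classification; TSS-relative
    sliding-window profiles of negative-probe frequency and methyl score
    with per-window between-group testing; promoter probe-sign homogeneity
    ("cluster phenomenon") classification and positional cluster scans;
    and integration with differential mRNA expression through windowed
    Spearman correlation of methylation summaries and their interaction.
    Includes a synthetic-data generator that emulates a two-group gingival
    tissue study design with a plantable position-dependent hypomethylation
    effect, so the whole pipeline can be exercised and calibrated without
    external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
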