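# Small fixtures built in code.

small_config <- function(seed = 1, ...) {
  sim_config(genes_per_group = c(immune = 40, cellcycle = 30, stable = 20),
             seed = seed, ...)
}

# hand-assembled significant-probe table
fake_stats <- function(tss_offset, sign,
                       gene_id = paste0("g", seq_along(tss_offset)),
                       group = "immune",
                       methyl_score = ifelse(sign == "negative", -0.1,
                                             ifelse(sign == "positive", 0.1, 0)),
                       q_value = 0.01) {
  data.frame(probe_id = paste0("cg", seq_along(tss_offset)),
             gene_id = gene_id, group = group, tss_offset = tss_offset,
             p_value = q_value, q_value = q_value,
             methyl_score = methyl_score, sign = sign,
             stringsAsFactors = FALSE)
}

random_stats <- function(n, groups = c("immune", "cellcycle"),
                         range = c(-2000, 2000), n_genes = max(2, n %/% 4)) {
  sign <- sample(c("negative", "positive"), n, replace = TRUE)
  fake_stats(tss_offset = sample(seq(range[1], range[2]), n, replace = TRUE),
             sign = sign,
             gene_id = paste0("g", sample.int(n_genes, n, replace = TRUE)),
             group = sample(groups, n, replace = TRUE),
             methyl_score = ifelse(sign == "negative", -1, 1) * runif(n, 0.01, 0.4))
}
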