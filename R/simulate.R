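#' Configuration for the synthetic two-condition methylation study
#'
#' Parameters describe a two-group gingival-tissue design: 12 disease and 11
#' healthy samples; three gene classes (immune-inflammatory, cell cycle,
#' stably expressed) of 1,284 / 1,038 / 575 genes; probes scattered from
#' 2,500 bp upstream of the TSS through the gene end; and a planted
#' hypomethylation effect in one class restricted to a TSS-relative window,
#' with per-gene mRNA changes linearly coupled (negatively, by default) to
#' the planted methylation change.
#'
#' Beta values are drawn from Beta distributions parameterised by mean and
#' precision (`shape1 = mean * precision`, `shape2 = (1 - mean) * precision`):
#' per-probe baseline means come from
#' `Beta(baseline_mean, baseline_precision)` and per-sample values from
#' `Beta(probe mean, sample_precision)`. Affected probes (probes of
#' `effect_group` genes inside `effect_window`) have their disease-group mean
#' shifted by `effect_delta`, clipped into (0, 1) if needed.
#'
#' @param n_disease,n_healthy Samples per condition.
#' @param genes_per_group Named integer vector of genes per class.
#' @param probes_per_gene Mean of the Poisson probe count per gene.
#' @param gene_end Gene end offset in bp downstream of the TSS; probes are
#'   placed uniformly on `[-2500, gene_end]`.
#' @param baseline_mean,baseline_precision Law of per-probe baseline means.
#' @param sample_precision Precision of per-sample beta draws around the
#'   probe mean (larger = less sampling noise).
#' @param effect_window `c(lo, hi)` TSS-relative window (bp) carrying the
#'   planted effect.
#' @param effect_delta Signed beta-scale mean shift applied to disease
#'   samples of affected probes; `|effect_delta| < 1`.
#' @param effect_group Which gene class carries the effect.
#' @param expr_slope Slope mapping a gene's mean planted methylation shift
#'   to its differential mRNA expression (negative = anti-correlated).
#' @param expr_noise_sd Gaussian noise added to differential expression.
#' @param seed Integer seed; all draws come from one generator in a fixed
#'   order, so outputs are reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_methylation()]
#' @export
sim_config <- function(n_disease = 12L, n_healthy = 11L,
                       genes_per_group = c(immune = 1284L, cellcycle = 1038L,
                                           stable = 575L),
                       probes_per_gene = 6,
                       gene_end = 5000L,
                       baseline_mean = 0.5, baseline_precision = 4,
                       sample_precision = 50,
                       effect_window = c(-1500L, 900L),
                       effect_delta = -0.3,
                       effect_group = "immune",
                       expr_slope = -10,
                       expr_noise_sd = 1,
                       seed = 1L) {
  cfg <- list(n_disease = as.integer(n_disease),
              n_healthy = as.integer(n_healthy),
              genes_per_group = genes_per_group,
              probes_per_gene = probes_per_gene,
              gene_end = as.integer(gene_end),
              baseline_mean = baseline_mean,
              baseline_precision = baseline_precision,
              sample_precision = sample_precision,
              effect_window = as.integer(effect_window),
              effect_delta = effect_delta,
              effect_group = effect_group,
              expr_slope = expr_slope,
              expr_noise_sd = expr_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_disease < 2 || cfg$n_healthy < 2)
    stop("need at least 2 samples per condition")
  if (is.null(names(cfg$genes_per_group)) || any(cfg$genes_per_group <= 0))
    stop("genes_per_group must be a named vector of positive counts")
  if (cfg$probes_per_gene <= 0) stop("probes_per_gene must be positive")
  if (cfg$gene_end <= -2500) stop("gene_end must exceed -2500")
  if (cfg$baseline_mean <= 0 || cfg$baseline_mean >= 1)
    stop("baseline_mean must lie in (0, 1)")
  if (cfg$baseline_precision <= 0 || cfg$sample_precision <= 0)
    stop("precisions must be positive")
  if (length(cfg$effect_window) != 2 ||
      cfg$effect_window[1] > cfg$effect_window[2])
    stop("effect_window must be c(lo, hi) with lo <= hi")
  if (abs(cfg$effect_delta) >= 1) stop("|effect_delta| must be < 1")
  if (!cfg$effect_group %in% names(cfg$genes_per_group))
    stop("effect_group must name one of the gene groups")
  if (cfg$expr_noise_sd < 0) stop("expr_noise_sd must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_disease, "disease vs", x$n_healthy, "healthy;",
      sum(x$genes_per_group), "genes in", length(x$genes_per_group),
      "groups\n")
  cat(sprintf("  effect: delta %+0.2f on '%s' in [%d, %d] bp; expr slope %g (noise sd %g); seed %d\n",
              x$effect_delta, x$effect_group, x$effect_window[1],
              x$effect_window[2], x$expr_slope, x$expr_noise_sd, x$seed))
  invisible(x)
}

rbeta_mu <- function(n, mu, precision) {
  stats::rbeta(n, shape1 = mu * precision, shape2 = (1 - mu) * precision)
}

#' Simulate a two-condition methylation study with a planted effect
#'
#' Generates a full synthetic dataset — beta matrix, probe annotation, gene
#' sets, differential-expression table — plus the ground truth of the
#' planted effect. Draw order is fixed (probe counts, positions, baseline
#' means, healthy betas, disease betas, expression noise), so results are
#' bit-reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `meth_sim` with elements `beta` (a
#'   [beta_matrix()]), `annotation`, `gene_sets`, `expression`, `truth`
#'   (list with `probes` and `genes` data frames) and `config`.
#' @examples
#' sim <- simulate_methylation(sim_config(
#'   genes_per_group = c(immune = 20, cellcycle = 15, stable = 10)))
#' head(sim$annotation)
#' @export
simulate_methylation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  groups <- names(config$genes_per_group)
  gene_group <- rep(groups, config$genes_per_group)
  n_genes <- length(gene_group)
  gene_id <- sprintf("%s_g%04d", gene_group,
                     unlist(lapply(config$genes_per_group, seq_len)))

  n_probes_gene <- stats::rpois(n_genes, config$probes_per_gene)
  n_probes <- sum(n_probes_gene)
  if (n_probes == 0) stop("no probes drawn; increase probes_per_gene")
  probe_gene <- rep.int(seq_len(n_genes), n_probes_gene)
  pos <- as.integer(floor(stats::runif(n_probes, -2500, config$gene_end + 1)))
  pos <- pmin(pos, config$gene_end)

  mu0 <- rbeta_mu(n_probes, config$baseline_mean, config$baseline_precision)
  mu0 <- pmin(pmax(mu0, 0.02), 0.98)

  affected <- gene_group[probe_gene] == config$effect_group &
    pos >= config$effect_window[1] & pos <= config$effect_window[2]
  mu_dis <- mu0
  mu_dis[affected] <- mu_dis[affected] + config$effect_delta
  clipped <- mu_dis < 0.001 | mu_dis > 0.999
  if (any(clipped)) {
    message(sum(clipped), " shifted probe mean(s) clipped into (0, 1)")
    mu_dis <- pmin(pmax(mu_dis, 0.001), 0.999)
  }
  true_shift <- mu_dis - mu0

  probe_id <- sprintf("cg%08d", seq_len(n_probes))
  healthy <- matrix(rbeta_mu(n_probes * config$n_healthy, rep(mu0, config$n_healthy),
                             config$sample_precision),
                    nrow = n_probes)
  disease <- matrix(rbeta_mu(n_probes * config$n_disease, rep(mu_dis, config$n_disease),
                             config$sample_precision),
                    nrow = n_probes)
  values <- cbind(disease, healthy)
  rownames(values) <- probe_id
  colnames(values) <- c(sprintf("dis%02d", seq_len(config$n_disease)),
                        sprintf("hea%02d", seq_len(config$n_healthy)))
  beta <- beta_matrix(values, rep(c("disease", "healthy"),
                                  c(config$n_disease, config$n_healthy)))

  annotation <- data.frame(probe_id = probe_id,
                           gene_id = gene_id[probe_gene],
                           group = gene_group[probe_gene],
                           tss_offset = pos,
                           gene_end_offset = config$gene_end,
                           stringsAsFactors = FALSE)

  gene_sets <- split(gene_id, gene_group)[groups]

  # gene-level planted shift: mean shift of the gene's probes inside the window
  in_win <- pos >= config$effect_window[1] & pos <= config$effect_window[2]
  shift_sum <- rep(0, n_genes); shift_n <- rep(0L, n_genes)
  if (any(in_win)) {
    s <- tapply(true_shift[in_win], probe_gene[in_win], sum)
    n <- tapply(in_win[in_win], probe_gene[in_win], length)
    idx <- as.integer(names(s))
    shift_sum[idx] <- s; shift_n[idx] <- n
  }
  gene_shift <- ifelse(shift_n > 0, shift_sum / pmax(shift_n, 1L), 0)
  delta_clean <- config$expr_slope * gene_shift
  delta_mrna <- delta_clean + stats::rnorm(n_genes, 0, config$expr_noise_sd)

  truth <- list(
    probes = data.frame(probe_id = probe_id, affected = affected,
                        true_shift = true_shift, stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_id, group = gene_group,
                       true_window_shift = gene_shift,
                       true_delta_mrna = delta_clean,
                       stringsAsFactors = FALSE))

  structure(list(beta = beta,
                 annotation = annotation,
                 gene_sets = gene_sets,
                 expression = data.frame(gene_id = gene_id,
                                         delta_mrna = delta_mrna,
                                         stringsAsFactors = FALSE),
                 truth = truth,
                 config = config),
            class = "meth_sim")
}

#' @export
print.meth_sim <- function(x, ...) {
  cat(sprintf("meth_sim: %d probes, %d genes, %d + %d samples (seed %d)\n",
              nrow(x$beta$values), nrow(x$truth$genes),
              x$config$n_disease, x$config$n_healthy, x$config$seed))
  cat(sprintf("  planted: %d affected probe(s), delta %+0.2f in [%d, %d] on '%s'\n",
              sum(x$truth$probes$affected), x$config$effect_delta,
              x$config$effect_window[1], x$config$effect_window[2],
              x$config$effect_group))
  invisible(x)
}

#' Write a simulated dataset as a bundle of plain-text tables
#'
#' @param sim A `meth_sim` from [simulate_methylation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "meth_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             samples = file.path(dir, "samples.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth_probes = file.path(dir, "truth_probes.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             config = file.path(dir, "config.yaml"))
  write_beta_matrix(sim$beta, paths["beta"], paths["samples"])
  write_annotation(sim$annotation, paths["annotation"])
  write_expression(sim$expression, paths["expression"])
  .write_tsv(sim$truth$probes, paths["truth_probes"])
  .write_tsv(sim$truth$genes, paths["truth_genes"])
  for (g in names(sim$gene_sets)) {
    p <- file.path(dir, paste0("genes_", g, ".txt"))
    write_gene_set(sim$gene_sets[[g]], p)
    paths[paste0("genes_", g)] <- p
  }
  yaml::write_yaml(unclass(sim$config), paths["config"])
  invisible(paths)
}

#' Null calibration of the per-probe testing stack
#'
#' Repeatedly simulates data with no planted effect (`effect_delta = 0`),
#' runs the per-probe Mann-Whitney test and q-value computation, and
#' summarises how close the p-value distribution is to uniform and how many
#' probes are called at `q <= 0.05`. With 12 + 11 samples the rank test is
#' discrete, so the null p-value distribution is sub-uniform (stochastically
#' larger than uniform) — the KS distance is reported against the uniform
#' reference, and the q <= 0.05 call rate should be near zero.
#'
#' @param config A [sim_config()]; `effect_delta` is forced to 0 and
#'   `expr_slope` to 0. Replicate r uses seed `config$seed + r - 1`.
#' @param n_reps Number of replicates.
#' @param fdr_method Passed to [compute_qvalues()].
#' @return A list of class `null_calibration` with a per-replicate data
#'   frame (`ks_stat`, `frac_q05`, `n_probes`) and the means across
#'   replicates.
#' @export
null_calibration <- function(config = sim_config(), n_reps = 10,
                             fdr_method = "storey") {
  stopifnot(inherits(config, "sim_config"))
  config$effect_delta <- 0
  config$expr_slope <- 0
  reps <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_methylation(cfg)
    fit <- meth_diff(sim$beta, sim$annotation, fdr_method = fdr_method)
    p <- fit$stats$p_value
    ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
    data.frame(rep = r, ks_stat = unname(ks),
               frac_q05 = mean(fit$stats$q_value <= 0.05),
               n_probes = length(p))
  })
  reps <- do.call(rbind, reps)
  structure(list(replicates = reps,
                 mean_ks = mean(reps$ks_stat),
                 mean_frac_q05 = mean(reps$frac_q05)),
            class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf("null_calibration: %d replicate(s), %d probes each\n",
              nrow(x$replicates), x$replicates$n_probes[1]))
  cat(sprintf("  mean KS distance from uniform: %.4f\n", x$mean_ks))
  cat(sprintf("  mean fraction q <= 0.05:       %.5f\n", x$mean_frac_q05))
  invisible(x)
}
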