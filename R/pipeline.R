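#' Run the full methylation-profiling pipeline
#'
#' Orchestrates every stage on one dataset: per-probe differential testing
#' and FDR filtering, cross-group sign and dispersion comparisons, the
#' 140-bp sliding-window difference tracks, promoter cluster
#' classification with the 800-bp positional scan, and (when an expression
#' table is available) the expression-sign split and windowed Spearman
#' correlation. Inputs are either a simulated dataset (`sim`) or the four
#' tables read from files.
#'
#' @param sim A `meth_sim` from [simulate_methylation()]; overrides the
#'   individual tables.
#' @param beta,annotation,expression The input tables (see
#'   [read_beta_matrix()], [read_annotation()], [read_expression()]);
#'   `expression` may be NULL, in which case the expression stage is
#'   skipped with a warning.
#' @param q_max,scope FDR threshold and TSS-relative scope for
#'   [filter_significant()].
#' @param fdr_method Passed to [meth_diff()].
#' @param promoter,cluster_min_probes Passed to
#'   [classify_promoter_clusters()].
#' @param scan_range,scan_width,scan_step,scan_min_probes Passed to
#'   [scan_cluster_windows()] (run on `focus_group`).
#' @param window_width,window_step,min_probes Sliding-window parameters
#'   for [difference_track()].
#' @param min_genes Passed to [windowed_correlation()].
#' @param focus_group Group used for the cluster scan and correlation
#'   tracks (default the first group in the data).
#' @param parameter Correlation parameter (default `"interaction"`).
#' @return A list of class `meth_report` with elements `fit`,
#'   `significant`, `contingency`, `dispersion`, `score_summary`,
#'   `difference` (per group pair, freq-neg and score tracks), `clusters`
#'   (calls, per-group frequencies, enrichment test, scan), `expression`
#'   (split + correlation track) and `params`.
#' @seealso [write_report()]
#' @export
run_pipeline <- function(sim = NULL, beta = NULL, annotation = NULL,
                         expression = NULL,
                         q_max = 0.05, scope = c(-2000, 2000),
                         fdr_method = "storey",
                         promoter = c(-1700, 0), cluster_min_probes = 3,
                         scan_range = c(750, -1500), scan_width = 800,
                         scan_step = 50, scan_min_probes = 4,
                         window_width = 140, window_step = 1, min_probes = 3,
                         min_genes = 10, focus_group = NULL,
                         parameter = "interaction") {
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "meth_sim"))
    beta <- sim$beta; annotation <- sim$annotation
    expression <- sim$expression
  }
  if (is.null(beta) || is.null(annotation))
    stop("need either `sim` or both `beta` and `annotation`")

  params <- list(q_max = q_max, scope = scope, fdr_method = fdr_method,
                 promoter = promoter, cluster_min_probes = cluster_min_probes,
                 scan_range = scan_range, scan_width = scan_width,
                 scan_step = scan_step, scan_min_probes = scan_min_probes,
                 window_width = window_width, window_step = window_step,
                 min_probes = min_probes, min_genes = min_genes,
                 parameter = parameter)

  message("stage probe_stats: testing ", nrow(beta$values), " probes")
  fit <- meth_diff(beta, annotation, fdr_method = fdr_method)
  sig <- filter_significant(fit, q_max = q_max, window = scope)
  groups <- unique(annotation$group)
  if (is.null(focus_group)) focus_group <- groups[1]
  params$focus_group <- focus_group

  degenerate <- nrow(sig) == 0
  contingency <- dispersion <- scoresum <- NULL
  tracks <- list()
  clusters <- list()
  expr_res <- NULL

  if (!degenerate) {
    message("stage group_comparison")
    contingency <- tryCatch(sign_contingency_test(sig),
                            error = function(e) { warning(conditionMessage(e)); NULL })
    dispersion <- tryCatch(score_dispersion(sig, reference = focus_group),
                           error = function(e) { warning(conditionMessage(e)); NULL })
    scoresum <- score_summary(sig)

    message("stage window_scan")
    windows <- make_windows(start = scope[2], end = scope[1],
                            width = window_width, step = window_step)
    profiles <- lapply(groups, function(g)
      profile_group(sig[sig$group == g, , drop = FALSE], windows))
    names(profiles) <- groups
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) {
      key <- paste(pr[1], pr[2], sep = "-")
      tracks[[key]] <- list(
        freq_neg = difference_track(profiles[[pr[1]]], profiles[[pr[2]]],
                                    mode = "freq_neg", min_probes = min_probes),
        mean_score = difference_track(profiles[[pr[1]]], profiles[[pr[2]]],
                                      mode = "mean_score",
                                      min_probes = min_probes))
    }

    message("stage cluster_analysis")
    calls <- classify_promoter_clusters(sig, promoter = promoter,
                                        min_probes = cluster_min_probes)
    freqs <- lapply(split(calls, calls$group), cluster_frequency)
    enrich <- if (length(unique(calls$group)) >= 2)
      tryCatch(neg_enrichment_test(calls),
               error = function(e) { warning(conditionMessage(e)); NULL })
    scan <- scan_cluster_windows(sig[sig$group == focus_group, , drop = FALSE],
                                 range = scan_range, width = scan_width,
                                 step = scan_step,
                                 min_probes = scan_min_probes)
    clusters <- list(calls = calls, frequencies = freqs,
                     enrichment = enrich, scan = scan)

    if (is.null(expression)) {
      warning("no expression table; expression stage skipped")
    } else {
      message("stage expression_link")
      sig_focus <- sig[sig$group == focus_group, , drop = FALSE]
      expr_res <- list(
        split = tryCatch(split_by_expression_sign(sig_focus, expression,
                                                  scope = scope),
                         error = function(e) { warning(conditionMessage(e)); NULL }),
        correlation = windowed_correlation(sig_focus, expression,
                                           windows = windows,
                                           parameter = parameter,
                                           min_genes = min_genes))
    }
  } else {
    warning("empty survivor set: all downstream stages degenerate")
  }

  structure(list(fit = fit, significant = sig, degenerate = degenerate,
                 contingency = contingency, dispersion = dispersion,
                 score_summary = scoresum, difference = tracks,
                 clusters = clusters, expression = expr_res,
                 params = params),
            class = "meth_report")
}

#' @export
print.meth_report <- function(x, ...) {
  cat(sprintf("meth_report: %d probes tested, %d significant (q <= %g, %+d..%+d)\n",
              nrow(x$fit$stats), nrow(x$significant), x$params$q_max,
              x$params$scope[1], x$params$scope[2]))
  if (x$degenerate) {
    cat("  degenerate: no significant probes; downstream stages skipped\n")
    return(invisible(x))
  }
  if (!is.null(x$contingency))
    cat(sprintf("  sign contingency: chi2 = %.3g, p = %.3g\n",
                x$contingency$chi2, x$contingency$p_value))
  if (length(x$clusters$frequencies)) {
    fr <- vapply(x$clusters$frequencies, `[[`, numeric(1), "fraction")
    cat("  cluster phenomenon: ",
        paste(sprintf("%s %.1f%%", names(fr), 100 * fr), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$expression) && !is.null(x$expression$correlation)) {
    pk <- tryCatch(peak_correlation(x$expression$correlation),
                   error = function(e) NULL)
    if (!is.null(pk))
      cat(sprintf("  peak correlation (%s, %s): rho = %.3f at window %+d (%d genes)\n",
                  x$params$focus_group, x$params$parameter, pk$rho,
                  pk$window_id, pk$n_genes))
  }
  invisible(x)
}

#' Write a pipeline report bundle
#'
#' Emits every stage's table as TSV, the fully resolved parameters as
#' YAML, and a markdown summary (contingency table, cluster frequencies,
#' peak-correlation window). Every number in the markdown is re-derivable
#' from the emitted TSVs.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "meth_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(probe_stats = file.path(dir, "probe_stats.tsv"),
             significant = file.path(dir, "significant.tsv"),
             params = file.path(dir, "params.yaml"),
             summary = file.path(dir, "report.md"))
  .write_tsv(report$fit$stats, paths["probe_stats"])
  .write_tsv(as.data.frame(report$significant), paths["significant"])
  yaml::write_yaml(report$params, paths["params"])

  lines <- c("# Methylation profiling report", "")
  lines <- c(lines, sprintf("- probes tested: %d", nrow(report$fit$stats)),
             sprintf("- significant (q <= %g, %+d..%+d bp): %d",
                     report$params$q_max, report$params$scope[1],
                     report$params$scope[2], nrow(report$significant)))
  if (!report$degenerate) {
    if (!is.null(report$contingency)) {
      tab <- report$contingency$table
      lines <- c(lines, "", "## Probe-sign contingency", "",
                 "| group | negative | positive |", "|---|---|---|",
                 sprintf("| %s | %d | %d |", rownames(tab), tab[, 1], tab[, 2]),
                 "",
                 sprintf("chi2 = %.6g, df = %d, p = %.6g",
                         report$contingency$chi2, report$contingency$dof,
                         report$contingency$p_value))
    }
    if (length(report$clusters$frequencies)) {
      lines <- c(lines, "", "## Cluster phenomenon", "",
                 "| group | neg | pos | negpos | frequency |", "|---|---|---|---|---|")
      for (g in names(report$clusters$frequencies)) {
        fr <- report$clusters$frequencies[[g]]
        lines <- c(lines, sprintf("| %s | %d | %d | %d | %.4f |", g,
                                  fr$counts[["neg"]], fr$counts[["pos"]],
                                  fr$counts[["negpos"]], fr$fraction))
      }
      .write_tsv(as.data.frame(report$clusters$calls),
                 file.path(dir, "cluster_calls.tsv"))
      .write_tsv(as.data.frame(report$clusters$scan),
                 file.path(dir, "cluster_scan.tsv"))
      paths["cluster_calls"] <- file.path(dir, "cluster_calls.tsv")
      paths["cluster_scan"] <- file.path(dir, "cluster_scan.tsv")
    }
    for (key in names(report$difference)) {
      for (mode in names(report$difference[[key]])) {
        f <- file.path(dir, sprintf("difference_%s_%s.tsv", key, mode))
        .write_tsv(as.data.frame(report$difference[[key]][[mode]]), f)
        paths[paste0("difference_", key, "_", mode)] <- f
      }
    }
    if (!is.null(report$expression)) {
      if (!is.null(report$expression$correlation)) {
        f <- file.path(dir, "correlation_track.tsv")
        .write_tsv(as.data.frame(report$expression$correlation), f)
        paths["correlation_track"] <- f
        pk <- tryCatch(peak_correlation(report$expression$correlation),
                       error = function(e) NULL)
        if (!is.null(pk))
          lines <- c(lines, "", "## Peak methylation-expression correlation", "",
                     sprintf("rho = %.6f (p = %.6g) at window %+d..%+d, %d genes",
                             pk$rho, pk$p_value, pk$window_id -
                               report$params$window_width, pk$window_id,
                             pk$n_genes))
      }
      if (!is.null(report$expression$split)) {
        sp <- report$expression$split
        lines <- c(lines, "",
                   sprintf("expression split (%d up, %d down): methyl score p = %.6g; freq-neg p = %.6g",
                           sp$n_up, sp$n_down, sp$p_methyl_score, sp$p_freq_neg))
      }
    }
  } else {
    lines <- c(lines, "", "All downstream stages degenerate: no significant probes.")
  }
  writeLines(lines, paths["summary"])
  invisible(paths)
}
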