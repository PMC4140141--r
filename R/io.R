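#' Construct a beta-value matrix with condition labels
#'
#' A `beta_matrix` holds per-probe methylation fractions (beta values) for a
#' two-condition study: rows are array probes, columns are samples, and each
#' sample carries a condition label, `"disease"` or `"healthy"`.
#'
#' @param values Numeric matrix of beta values in `[0, 1]` (NA allowed),
#'   probes in rows and samples in columns; both dimnames required.
#' @param condition Character or factor of length `ncol(values)` with values
#'   in `{"disease", "healthy"}`; at least two samples per condition.
#' @return An object of class `beta_matrix`: a list with elements `values`
#'   (the matrix) and `condition` (a factor aligned with the columns).
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("cg", 1:3), paste0("s", 1:4)))
#' b <- beta_matrix(m, c("disease", "disease", "healthy", "healthy"))
#' dim(b$values)
#' @export
beta_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("probe ids (rownames) must be unique")
  condition <- as.character(condition)
  if (length(condition) != ncol(values))
    stop("`condition` must have one label per sample column")
  bad <- setdiff(unique(condition), c("disease", "healthy"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  out <- range(values, na.rm = TRUE)
  if (out[1] < 0 || out[2] > 1) {
    idx <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s'",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  tab <- table(factor(condition, levels = c("disease", "healthy")))
  if (any(tab < 2))
    stop("need at least 2 samples per condition; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  structure(list(values = values,
                 condition = factor(condition, levels = c("disease", "healthy"))),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("beta_matrix: %d probes x %d samples (%d disease, %d healthy)\n",
              nrow(x$values), ncol(x$values), tab[["disease"]], tab[["healthy"]]))
  invisible(x)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    na.strings = c("", ".", "NA"), check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

.write_tsv <- function(x, path, row.names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = row.names, col.names = TRUE)
}

#' Read a beta-value matrix and its sample sheet
#'
#' The matrix file is a TSV whose first column is the probe id and whose
#' remaining columns are samples; the sample sheet is a TSV with columns
#' `sample_id` and `condition`. Missing values are written/read as `.` or
#' an empty field. Probes with no observed value in any sample are dropped
#' with a message.
#'
#' @param path Path to the beta-value TSV.
#' @param sample_sheet Path to the sample-sheet TSV.
#' @return A [beta_matrix()].
#' @seealso [write_beta_matrix()]
#' @export
read_beta_matrix <- function(path, sample_sheet) {
  tab <- .read_tsv(path)
  if (ncol(tab) < 2) stop("beta matrix file needs a probe column plus samples")
  probe_ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probe_ids
  sheet <- .read_tsv(sample_sheet)
  if (!all(c("sample_id", "condition") %in% names(sheet)))
    stop("sample sheet must have columns 'sample_id' and 'condition'")
  miss <- setdiff(colnames(values), sheet$sample_id)
  if (length(miss))
    stop("samples absent from sample sheet: ", paste(miss, collapse = ", "))
  cond <- sheet$condition[match(colnames(values), sheet$sample_id)]
  all_na <- rowSums(!is.na(values)) == 0
  if (any(all_na)) {
    message(sum(all_na), " probe(s) with all values missing dropped")
    values <- values[!all_na, , drop = FALSE]
  }
  beta_matrix(values, cond)
}

#' Write a beta-value matrix and its sample sheet
#'
#' @param x A [beta_matrix()].
#' @param path Output path for the beta-value TSV.
#' @param sample_sheet Output path for the sample-sheet TSV.
#' @return Invisibly, `x`.
#' @export
write_beta_matrix <- function(x, path, sample_sheet) {
  stopifnot(inherits(x, "beta_matrix"))
  tab <- data.frame(probe_id = rownames(x$values), x$values,
                    check.names = FALSE)
  .write_tsv(tab, path)
  .write_tsv(data.frame(sample_id = colnames(x$values),
                        condition = as.character(x$condition)), sample_sheet)
  invisible(x)
}

#' TSS-relative, strand-aware probe offset
#'
#' Converts genomic positions to a signed offset relative to the gene's
#' transcription start site: positive offsets lie downstream of the TSS in
#' the direction of transcription (gene body), negative offsets upstream
#' (promoter). All arguments are vectorised.
#'
#' @param probe_pos 1-based genomic position of the probe.
#' @param tss_pos 1-based genomic position of the TSS (same chromosome).
#' @param strand `"+"` or `"-"` per gene.
#' @return Integer offsets in base pairs.
#' @examples
#' tss_offset(1100, 1000, "+")  # +100, gene body
#' tss_offset(900, 1000, "-")   # +100, gene body on the minus strand
#' @export
tss_offset <- function(probe_pos, tss_pos, strand) {
  if (any(is.na(strand))) stop("missing strand")
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ifelse(strand == "+", probe_pos - tss_pos, tss_pos - probe_pos)
}

#' Read a probe annotation table
#'
#' A TSV with columns `probe_id`, `gene_id`, `group`, `tss_offset` and
#' optionally `gene_end_offset`. Offsets are signed base pairs relative to
#' the TSS (see [tss_offset()]); the initial probe selection spans
#' -2,500 bp upstream of the TSS through the end of the gene.
#'
#' @param path Path to the annotation TSV.
#' @return A data frame with one row per probe-gene assignment.
#' @export
read_annotation <- function(path) {
  ann <- .read_tsv(path)
  need <- c("probe_id", "gene_id", "group", "tss_offset")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  ann$tss_offset <- as.integer(ann$tss_offset)
  ann
}

#' @rdname read_annotation
#' @param x Annotation data frame.
#' @export
write_annotation <- function(x, path) {
  .write_tsv(x, path)
  invisible(x)
}

#' Read gene sets from one-symbol-per-line files
#'
#' Each file defines one gene set; duplicate symbols within a file are
#' dropped with a warning, and a symbol present in several files stays a
#' member of every set (analyses run per set).
#'
#' @param paths Character vector of file paths, one per set.
#' @param names Set names; defaults to the file base names without extension.
#' @return A named list of character vectors.
#' @export
read_gene_sets <- function(paths, names = NULL) {
  if (is.null(names))
    names <- sub("\\.[^.]*$", "", basename(paths))
  stopifnot(length(names) == length(paths))
  if (anyDuplicated(names)) stop("gene set names must be unique")
  sets <- lapply(seq_along(paths), function(i) {
    lines <- readLines(paths[i])
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty gene set file: ", paths[i])
    if (anyDuplicated(lines)) {
      warning(sum(duplicated(lines)), " duplicate symbol(s) in ", paths[i],
              " dropped")
      lines <- unique(lines)
    }
    lines
  })
  names(sets) <- names
  overlap <- unlist(sets)
  overlap <- unique(overlap[duplicated(overlap)])
  if (length(overlap))
    message(length(overlap), " gene(s) belong to more than one set; ",
            "memberships kept in all sets")
  sets
}

#' @rdname read_gene_sets
#' @param set Character vector of gene symbols.
#' @param path Output path.
#' @export
write_gene_set <- function(set, path) {
  writeLines(set, path)
  invisible(set)
}

#' Read a per-gene differential-expression table
#'
#' Accepts either two columns (`gene_id`, `delta_mrna`) or three
#' (`gene_id`, `array_probe_id`, `delta_mrna`); with three, the per-gene
#' mean over array probes is taken. Genes whose resulting differential
#' expression is exactly zero are excluded (their sign is undefined) and
#' counted in a message.
#'
#' @param path Path to the expression TSV.
#' @return A data frame with columns `gene_id` and `delta_mrna`
#'   (disease minus healthy, platform units), one row per gene, no zeros.
#' @export
read_expression <- function(path) {
  tab <- .read_tsv(path)
  if (!"gene_id" %in% names(tab) || !"delta_mrna" %in% names(tab))
    stop("expression table must have columns 'gene_id' and 'delta_mrna'")
  if (!is.numeric(tab$delta_mrna))
    stop("non-numeric delta_mrna values in ", path)
  agg <- stats::aggregate(delta_mrna ~ gene_id, data = tab, FUN = mean)
  zero <- agg$delta_mrna == 0
  if (any(zero))
    message(sum(zero), " gene(s) with differential expression exactly 0 excluded")
  out <- agg[!zero, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_expression
#' @param x Expression data frame.
#' @export
write_expression <- function(x, path) {
  .write_tsv(x, path)
  invisible(x)
}
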