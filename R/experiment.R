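#' Construct an ExpressionExperiment
#'
#' The universal input container of the pipeline: a non-negative gene x
#' sample expression matrix together with a sample sheet recording, for
#' every sample, the tissue, the circadian time (CT, hours in `[0, 24)`),
#' the replicate number and the condition label. The sample sheet is the
#' single source of metadata truth; matrix column order carries no
#' meaning beyond its alignment with the sheet.
#'
#' @param values numeric matrix, genes x samples, non-negative, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param samples data.frame with columns `sample_id`, `tissue`, `ct`,
#'   `replicate`, `condition`; one row per matrix column.
#' @param unit `"counts"` or `"TPM"`.
#' @return object of class `ExpressionExperiment` (list with elements
#'   `values`, `samples`, `unit`).
#' @export
expression_experiment <- function(values, samples, unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("matrix must have unique gene ids as rownames")
  if (is.null(colnames(values))) stop("matrix must have sample ids as colnames")
  if (any(values < 0)) stop("expression matrix has negative entries")
  req <- c("sample_id", "tissue", "ct", "replicate", "condition")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  extra_m <- setdiff(colnames(values), samples$sample_id)
  extra_s <- setdiff(samples$sample_id, colnames(values))
  if (length(extra_m) || length(extra_s))
    stop("sample ids disagree between matrix and sheet; ",
         "matrix-only: [", paste(extra_m, collapse = ", "),
         "] sheet-only: [", paste(extra_s, collapse = ", "), "]")
  samples <- samples[match(colnames(values), samples$sample_id), req]
  rownames(samples) <- NULL
  if (any(is.na(samples$ct)) || any(samples$ct < 0) || any(samples$ct >= 24))
    stop("circadian time must lie in [0, 24)")
  if (any(samples$replicate < 1)) stop("replicate must be a positive integer")
  structure(list(values = values, samples = samples, unit = unit),
            class = "ExpressionExperiment")
}

#' @export
print.ExpressionExperiment <- function(x, ...) {
  cat(sprintf("ExpressionExperiment: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("  tissues:    ", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  cat("  conditions: ", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("  CT grid:    ", paste(sort(unique(x$samples$ct)), collapse = ", "),
      "h\n")
  invisible(x)
}

#' @export
dim.ExpressionExperiment <- function(x) dim(x$values)

#' Subset an experiment by sample metadata and/or genes
#'
#' @param exp an `ExpressionExperiment`.
#' @param tissue,condition optional labels; samples are kept whose
#'   metadata matches all given values.
#' @param genes optional character vector of gene ids to retain.
#' @return the subsetted `ExpressionExperiment`.
#' @export
subset_experiment <- function(exp, tissue = NULL, condition = NULL,
                              genes = NULL) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  keep <- rep(TRUE, ncol(exp$values))
  if (!is.null(tissue)) keep <- keep & exp$samples$tissue %in% tissue
  if (!is.null(condition)) keep <- keep & exp$samples$condition %in% condition
  if (!any(keep)) stop("no samples left after subsetting")
  v <- exp$values[, keep, drop = FALSE]
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss)) stop("unknown genes: ", paste(utils::head(miss, 5),
                                                    collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  expression_experiment(v, exp$samples[keep, , drop = FALSE], exp$unit)
}

#' Convert raw counts to TPM
#'
#' Per sample, `tpm_g = 1e6 * (c_g / L_g) / sum_j (c_j / L_j)` where `L`
#' is the per-gene effective length in bp. Column sums of the result are
#' 1e6 by construction.
#'
#' @param exp an `ExpressionExperiment` in counts.
#' @param lengths numeric vector of positive per-gene effective lengths,
#'   either unnamed in gene order or named by gene id.
#' @return an `ExpressionExperiment` with `unit = "TPM"`.
#' @export
counts_to_tpm <- function(exp, lengths) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  if (exp$unit != "counts") stop("input must be in counts")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(exp$values)]
  if (length(lengths) != nrow(exp$values) || any(is.na(lengths)) ||
      any(lengths <= 0))
    stop("lengths must be positive and cover every gene")
  rate <- exp$values / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample(s) with zero total rate: ",
                          paste(colnames(exp$values)[tot == 0], collapse = ", "))
  expression_experiment(sweep(rate, 2, tot, "/") * 1e6, exp$samples, "TPM")
}

#' Restrict to genes expressed in all samples
#'
#' Retains exactly the genes with expression strictly above `cutoff`
#' (default 0, i.e. TPM > 0) in every sample. The retained set defines
#' the analysis universe and the enrichment background. Idempotent.
#'
#' @param exp an `ExpressionExperiment` in TPM.
#' @param cutoff expression threshold; a gene is kept if it exceeds this
#'   in every sample (strict inequality).
#' @return the filtered `ExpressionExperiment`.
#' @export
filter_expressed <- function(exp, cutoff = 0) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  if (exp$unit != "TPM") stop("expressed-gene filter is defined on TPM")
  keep <- apply(exp$values > cutoff, 1, all)
  if (!any(keep)) stop("no gene is expressed in all samples")
  expression_experiment(exp$values[keep, , drop = FALSE], exp$samples, "TPM")
}
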