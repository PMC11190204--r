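#' Read an experiment from a matrix TSV and a sample sheet TSV
#'
#' The matrix file has gene ids in the first column and one named column
#' per sample; the sample sheet has columns `sample_id`, `tissue`, `ct`,
#' `replicate`, `condition`. Matrix columns are aligned to sheet rows by
#' sample id; a mismatch in either direction is fatal, listing the
#' offending ids.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param samples_path path to the sample sheet TSV.
#' @param unit unit of the stored values, `"counts"` or `"TPM"`.
#' @return an [expression_experiment()].
#' @export
read_experiment <- function(matrix_path, samples_path,
                            unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num)) {
    bad <- which(!num)[1]
    cell <- which(is.na(suppressWarnings(as.numeric(vals[[bad]]))))[1]
    stop("non-numeric cell in matrix at row ", cell, ", column '",
         names(vals)[bad], "'")
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  sheet <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  expression_experiment(m, sheet, unit)
}

#' Write an experiment as matrix + sample sheet TSVs
#'
#' Inverse of [read_experiment()]: `read_experiment(write_experiment(e))`
#' returns a value-identical experiment.
#'
#' @param exp an `ExpressionExperiment`.
#' @param matrix_path,samples_path output paths.
#' @return invisibly, the two paths.
#' @export
write_experiment <- function(exp, matrix_path, samples_path) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  out <- data.frame(gene_id = rownames(exp$values), exp$values,
                    check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(exp$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, samples_path))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT semantics: one set per line, tab-separated
#' `name description member1 member2 ...`. Duplicate members are removed;
#' empty member lists are fatal.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `description` attribute
#'   (named character vector of per-set descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("GMT set(s) with no members: ",
                     paste(vapply(parts[bad], `[`, "", 1), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "description") <- stats::setNames(vapply(parts, `[`, "", 2),
                                               names(sets))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set descriptions (recycled `"."`).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep(".", length(sets))
  lines <- mapply(function(nm, ds, mem)
    paste(c(nm, ds, unique(mem)), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6+1 gene annotation
#'
#' BED6 columns (chrom, start, end, name, score, strand; 0-based
#' half-open coordinates) plus a seventh biotype column from the closed
#' vocabulary `coding`, `lncRNA`, `antisense`, `bidirectional`.
#'
#' @param path BED6+1 file path (no header).
#' @return data.frame with columns `gene_id`, `biotype`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 7L) stop("annotation must be BED6 + biotype (7 columns)")
  ann <- data.frame(gene_id = tab[[4]], biotype = tab[[7]], chrom = tab[[1]],
                    start = tab[[2]], end = tab[[3]], strand = tab[[6]],
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' Write a BED6+1 gene annotation
#'
#' @param ann annotation data.frame as returned by [read_annotation()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  ann <- validate_annotation(ann)
  bed <- data.frame(ann$chrom, ann$start, ann$end, ann$gene_id, 0L,
                    ann$strand, ann$biotype)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

biotype_vocabulary <- c("coding", "lncRNA", "antisense", "bidirectional")

validate_annotation <- function(ann) {
  stopifnot(all(c("gene_id", "biotype", "chrom", "start", "end",
                  "strand") %in% names(ann)))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids in annotation")
  if (any(ann$start >= ann$end)) stop("annotation with start >= end")
  bad <- setdiff(unique(ann$biotype), biotype_vocabulary)
  if (length(bad)) stop("unknown biotype(s): ", paste(bad, collapse = ", "))
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be + or -")
  ann
}

#' Write a JSON run manifest
#'
#' Records parameters, seed and package version for a pipeline run.
#' Plain JSON writer (scalars, vectors, named lists) with no external
#' dependency.
#'
#' @param manifest named list of parameters.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  manifest$chronospec_version <-
    as.character(utils::packageVersion("chronospec"))
  writeLines(to_json(manifest), path)
  invisible(path)
}

to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  atom <- function(v) {
    if (is.character(v)) paste0('"', esc(v), '"')
    else if (is.logical(v)) ifelse(v, "true", "false")
    else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }
  if (is.list(x)) {
    if (is.null(names(x)))
      paste0("[", paste(vapply(x, to_json, ""), collapse = ", "), "]")
    else
      paste0("{", paste(sprintf('"%s": %s', esc(names(x)),
                                vapply(x, to_json, "")), collapse = ", "),
             "}")
  } else if (length(x) == 1L) {
    atom(x)
  } else {
    paste0("[", paste(atom(x), collapse = ", "), "]")
  }
}
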