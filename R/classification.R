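#' Partition DEGs into circadian-affected, constitutive and temporal
#'
#' The central trichotomy: a differential gene is `circadian_affected`
#' if it is rhythmic (BH q < 0.05 from the per-tissue rhythm scan) in
#' either tissue OR is a member of any core-clock TF target set;
#' otherwise `constitutive` if it is differential at every timepoint;
#' otherwise `temporal`. Non-differential genes are `non_deg`. The
#' three DEG classes are pairwise disjoint and exactly cover the DEG
#' set; the assignment is a pure function of the per-gene evidence.
#'
#' @param de a `DEResult` from [de_per_timepoint()].
#' @param rhythm_a,rhythm_b `RhythmResult` tables for the two tissues
#'   (same gene universe as `de`).
#' @param tf_targets named list of core-clock TF target gene sets (the
#'   union defines target membership), or `NULL` for none.
#' @return data.frame of class `DEGClassification`: `gene_id`, `class`,
#'   and the evidence columns `rhythmic_in_a`, `rhythmic_in_b`,
#'   `is_tf_target`, `n_de_timepoints`, `de_all_timepoints`.
#' @export
classify_degs <- function(de, rhythm_a, rhythm_b, tf_targets = NULL) {
  stopifnot(inherits(de, "DEResult"))
  genes <- de$summary$gene_id
  for (nm in c("rhythm_a", "rhythm_b")) {
    rr <- get(nm)
    miss <- setdiff(genes, rr$gene_id)
    if (length(miss))
      stop("gene universe mismatch: ", length(miss), " DE gene(s) absent ",
           "from ", nm, " (e.g. ", paste(utils::head(miss, 3),
                                         collapse = ", "), ")")
  }
  ra <- rhythm_a$is_rhythmic[match(genes, rhythm_a$gene_id)]
  rb <- rhythm_b$is_rhythmic[match(genes, rhythm_b$gene_id)]
  targets <- unique(unlist(tf_targets))
  tf <- genes %in% targets
  ev <- de$summary
  circ <- ra | rb | tf
  class <- ifelse(!ev$is_deg, "non_deg",
           ifelse(circ, "circadian_affected",
           ifelse(ev$de_all_timepoints, "constitutive", "temporal")))
  out <- data.frame(gene_id = genes, class = class, rhythmic_in_a = ra,
                    rhythmic_in_b = rb, is_tf_target = tf,
                    n_de_timepoints = ev$n_de_timepoints,
                    de_all_timepoints = ev$de_all_timepoints,
                    stringsAsFactors = FALSE)
  # partition property, asserted on every run
  deg <- out$class != "non_deg"
  stopifnot(all(xor(deg, !out$n_de_timepoints > 0L) |
                  (deg == (out$n_de_timepoints > 0L))),
            all(out$class %in% c("circadian_affected", "constitutive",
                                 "temporal", "non_deg")))
  class(out) <- c("DEGClassification", "data.frame")
  out
}

#' Per-class counts, proportions and expression comparison
#'
#' Summarises a DEG classification: counts and proportions over the
#' three DEG classes, the per-class median expression (median over
#' genes of the per-gene median TPM across samples), and pairwise
#' two-sided Wilcoxon rank-sum p-values between the classes' per-gene
#' expression levels.
#'
#' @param cls a `DEGClassification`.
#' @param exp an `ExpressionExperiment` in TPM covering the classified
#'   genes.
#' @return list with `counts`, `proportions` (over the three DEG
#'   classes), `median_tpm` (per class), and `wilcoxon` (data.frame of
#'   pairwise comparisons; a class with fewer than 2 genes is skipped
#'   with a warning).
#' @export
class_summary <- function(cls, exp) {
  stopifnot(inherits(cls, "DEGClassification"),
            inherits(exp, "ExpressionExperiment"))
  if (exp$unit != "TPM") stop("expression comparison is defined on TPM")
  deg_classes <- c("circadian_affected", "constitutive", "temporal")
  counts <- table(factor(cls$class, levels = c(deg_classes, "non_deg")))
  proportions <- counts[deg_classes] / sum(counts[deg_classes])
  med <- apply(exp$values[match(cls$gene_id, rownames(exp$values)), ,
                          drop = FALSE], 1, stats::median)
  by_class <- split(med, cls$class)
  median_tpm <- vapply(deg_classes, function(k) {
    v <- by_class[[k]]
    if (is.null(v)) NA_real_ else stats::median(v)
  }, numeric(1))
  pairs <- utils::combn(deg_classes, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- by_class[[pr[1]]]; b <- by_class[[pr[2]]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("class with < 2 genes: skipping ", pr[1], " vs ", pr[2])
      return(data.frame(class_a = pr[1], class_b = pr[2], p = NA_real_))
    }
    data.frame(class_a = pr[1], class_b = pr[2],
               p = stats::wilcox.test(a, b)$p.value)
  })
  list(counts = counts, proportions = proportions, median_tpm = median_tpm,
       wilcoxon = do.call(rbind, rows))
}
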