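#' Genome-wide rhythm scan for one tissue and condition
#'
#' Runs [jtk_test()] on every gene of an experiment restricted to a
#' single tissue and condition, applies Benjamini-Hochberg adjustment
#' across the genes of the scan, and attaches the cosinor amplitude,
#' peak lag and mesor on the input (TPM) scale. Results depend only on
#' the sample metadata, never on column order.
#'
#' @param exp an `ExpressionExperiment` in TPM.
#' @param tissue,condition labels selecting the samples to scan.
#' @param period,lag_step,exact_limit passed to [jtk_test()].
#' @param q_cutoff BH q-value below which a gene is flagged rhythmic.
#' @return data.frame of class `RhythmResult`: `gene_id`, `p`, `q`,
#'   `period`, `lag` (JTK best lag, hours), `amp`, `cosinor_lag`,
#'   `mesor`, `tau`, `is_rhythmic`.
#' @export
rhythm_scan <- function(exp, tissue = NULL, condition = NULL, period = 24,
                        lag_step = NULL, exact_limit = 50, q_cutoff = 0.05) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  if (!is.null(tissue) || !is.null(condition))
    exp <- subset_experiment(exp, tissue = tissue, condition = condition)
  if (length(unique(exp$samples$tissue)) > 1L ||
      length(unique(exp$samples$condition)) > 1L)
    stop("rhythm_scan expects a single tissue and condition")
  times <- exp$samples$ct
  if (length(unique(times)) < 4L)
    stop("fewer than 4 distinct timepoints: design too sparse for a scan")
  design <- jtk_design(times, period, lag_step, exact_limit)
  sc <- jtk_score_matrix(exp$values, design)
  cs <- cosinor_amp_phase(exp$values, times, period)
  q <- stats::p.adjust(sc$p, method = "BH")
  out <- data.frame(gene_id = rownames(exp$values), p = sc$p, q = q,
                    period = period, lag = sc$best_lag, amp = cs$amplitude,
                    cosinor_lag = cs$lag, mesor = cs$mesor,
                    tau = sc$tau_best, is_rhythmic = q < q_cutoff,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("RhythmResult", "data.frame")
  out
}

# circular difference in hours, in [0, 12]
circ_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Phase concordance between rhythmic lncRNAs and nearby coding genes
#'
#' Groups rhythmic lncRNAs into genomic clusters (transcripts whose
#' spans lie within `cluster_gap` of each other), pairs each cluster
#' with the rhythmic protein-coding genes whose span lies within
#' `window` bp of the cluster span, and summarises phase concordance.
#' Per cluster, each lncRNA transcript is paired with its nearest
#' rhythmic coding neighbour; reported are the median circular phase
#' difference over all lncRNA-neighbour pairs and (when at least 3
#' nearest pairs exist) the Pearson correlation over nearest pairs.
#' Globally, the Pearson correlation between the cluster lncRNA phase
#' (median over its transcripts) and the median neighbour coding phase
#' is returned with its test p-value.
#'
#' @param rhythms_lnc,rhythms_coding `RhythmResult` tables for the
#'   noncoding and coding genes; only rows with `is_rhythmic` are used.
#' @param annot annotation data.frame (see [read_annotation()]) covering
#'   the rhythmic genes.
#' @param window neighbourhood size in bp (default 50000).
#' @param cluster_gap maximal span gap grouping lncRNAs into one
#'   cluster.
#' @param phase which phase estimate to use, `"cosinor_lag"` or `"lag"`.
#' @return list with `clusters` (per-cluster table; clusters without a
#'   rhythmic coding neighbour are dropped and counted in
#'   `n_dropped`), `global_r`, `global_p` (Pearson across clusters),
#'   and `n_dropped`.
#' @export
neighbor_phase_correlation <- function(rhythms_lnc, rhythms_coding, annot,
                                       window = 50000, cluster_gap = 10000,
                                       phase = c("cosinor_lag", "lag")) {
  phase <- match.arg(phase)
  lnc <- rhythms_lnc[rhythms_lnc$is_rhythmic, , drop = FALSE]
  cod <- rhythms_coding[rhythms_coding$is_rhythmic, , drop = FALSE]
  if (!nrow(lnc) || !nrow(cod))
    return(list(clusters = NULL, global_r = NA_real_, global_p = NA_real_,
                n_dropped = 0L))
  ann <- annot[match(c(lnc$gene_id, cod$gene_id), annot$gene_id), ]
  if (any(is.na(ann$gene_id))) stop("annotation missing rhythmic genes")
  la <- annot[match(lnc$gene_id, annot$gene_id), ]
  ca <- annot[match(cod$gene_id, annot$gene_id), ]

  # cluster rhythmic lncRNAs: same chrom, span gap <= cluster_gap
  o <- order(la$chrom, la$start)
  la <- la[o, ]; lnc <- lnc[o, ]
  new_cluster <- c(TRUE, la$chrom[-1] != la$chrom[-nrow(la)] |
                     la$start[-1] - cummax_by(la$end, la$chrom)[-nrow(la)] >
                       cluster_gap)
  cl <- cumsum(new_cluster)

  rows <- list(); dropped <- 0L
  for (k in unique(cl)) {
    sel <- cl == k
    c_chrom <- la$chrom[sel][1]
    c_start <- min(la$start[sel]); c_end <- max(la$end[sel])
    nb <- which(ca$chrom == c_chrom & ca$start <= c_end + window &
                  ca$end >= c_start - window)
    if (!length(nb)) { dropped <- dropped + 1L; next }
    lph <- lnc[[phase]][sel]
    cph <- cod[[phase]][nb]
    # nearest rhythmic coding neighbour per lncRNA transcript
    nearest <- vapply(which(sel), function(i) {
      d <- pmax(0, pmax(ca$start[nb] - la$end[i], la$start[i] - ca$end[nb]))
      nb[which.min(d)]
    }, integer(1))
    near_ph <- cod[[phase]][nearest]
    pairs_diff <- as.vector(outer(lph, cph,
                                  function(a, b) circ_diff(a, b)))
    r_near <- if (length(lph) >= 3L && stats::sd(lph) > 0 &&
                  stats::sd(near_ph) > 0)
      stats::cor(lph, near_ph) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = k, chrom = c_chrom, start = c_start, end = c_end,
      n_lnc = sum(sel), n_neighbors = length(nb),
      lnc_phase = stats::median(lph),
      median_neighbor_phase = stats::median(cph),
      median_phase_diff = stats::median(pairs_diff),
      nearest_pair_r = r_near, stringsAsFactors = FALSE)
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else NULL
  global_r <- NA_real_; global_p <- NA_real_
  if (!is.null(clusters) && nrow(clusters) >= 3L &&
      stats::sd(clusters$lnc_phase) > 0 &&
      stats::sd(clusters$median_neighbor_phase) > 0) {
    ct <- stats::cor.test(clusters$lnc_phase,
                          clusters$median_neighbor_phase)
    global_r <- unname(ct$estimate); global_p <- ct$p.value
  }
  list(clusters = clusters, global_r = global_r, global_p = global_p,
       n_dropped = dropped)
}

# running max of `end` within chromosome runs (helper for clustering)
cummax_by <- function(x, by) {
  out <- numeric(length(x))
  for (b in unique(by)) {
    i <- which(by == b)
    out[i] <- cummax(x[i])
  }
  out
}
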