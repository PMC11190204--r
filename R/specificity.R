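#' Tissue-specificity index Tau
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`: 0 for uniform expression
#' across tissues, 1 for expression confined to a single tissue.
#'
#' @param x non-negative per-tissue expression vector (one gene), or a
#'   genes x tissues matrix.
#' @return tau in `[0, 1]`; `NA` for an all-zero profile.
#' @examples
#' compute_tau(c(8, 4, 2, 2))  # 0.6667
#' @export
compute_tau <- function(x) {
  f <- function(v) {
    m <- max(v)
    if (m == 0) return(NA_real_)
    sum(1 - v / m) / (length(v) - 1)
  }
  if (is.null(dim(x))) f(x) else apply(x, 1, f)
}

#' Tissue-specificity measure SPM
#'
#' `spm_i = x_i^2 / sum(x^2)`: the squared share of a gene's expression
#' in each tissue; rows sum to 1.
#'
#' @param x non-negative per-tissue expression vector or genes x tissues
#'   matrix.
#' @return vector (or matrix) of per-tissue SPM values; `NA` for an
#'   all-zero profile.
#' @examples
#' compute_spm(c(3, 4))  # 0.36 0.64
#' @export
compute_spm <- function(x) {
  if (is.null(dim(x))) {
    ss <- sum(x^2)
    if (ss == 0) return(rep(NA_real_, length(x)))
    return(x^2 / ss)
  }
  ss <- rowSums(x^2)
  out <- x^2 / ss
  out[ss == 0, ] <- NA_real_
  out
}

#' Expression enrichment EE
#'
#' `ee_i = (sum_j s_j / s_i) * (x_i / sum_j x_j)` where `s_i` is the
#' summed expression of all genes in tissue `i`: the ratio of the gene's
#' expression share in a tissue to that tissue's share of total output.
#' 1 in every tissue means no enrichment.
#'
#' @param x non-negative per-tissue expression vector or genes x tissues
#'   matrix.
#' @param s per-tissue total expression of all genes (positive).
#' @return vector (or matrix) of per-tissue EE values; `NA` for an
#'   all-zero profile.
#' @examples
#' compute_ee(c(9, 1), s = c(100, 100))  # 1.8 0.2
#' @export
compute_ee <- function(x, s) {
  if (any(s <= 0)) stop("per-tissue totals must be positive")
  w <- (sum(s) / s)
  if (is.null(dim(x))) {
    tot <- sum(x)
    if (tot == 0) return(rep(NA_real_, length(x)))
    return(w * x / tot)
  }
  stopifnot(ncol(x) == length(s))
  tot <- rowSums(x)
  out <- sweep(x / tot, 2, w, "*")
  out[tot == 0, ] <- NA_real_
  out
}

# per-tissue mean expression of an experiment, optionally at one timepoint
tissue_means <- function(exp, ct = NULL) {
  sel <- if (is.null(ct)) rep(TRUE, ncol(exp$values)) else exp$samples$ct == ct
  tis <- exp$samples$tissue[sel]
  v <- exp$values[, sel, drop = FALSE]
  m <- sapply(unique(tis), function(ti)
    rowMeans(v[, tis == ti, drop = FALSE]))
  m[, sort(colnames(m)), drop = FALSE]
}

#' Static tissue-specificity profile of an experiment
#'
#' Computes Tau, per-tissue SPM and per-tissue EE from the per-tissue
#' mean expression across all timepoints (the input to the indices is
#' always the per-tissue mean TPM). All-zero profiles yield `NA` and
#' their count is reported via the `n_undefined` attribute.
#'
#' @param exp an `ExpressionExperiment` in TPM covering >= 2 tissues.
#' @param log_transform if `TRUE`, indices are computed on
#'   `log2(1 + mean TPM)`.
#' @return data.frame of class `SpecificityProfile`: `gene_id`, `tau`,
#'   `spm_<tissue>` and `ee_<tissue>` columns, plus attributes
#'   `n_tissues` and `n_undefined`.
#' @export
specificity_profile <- function(exp, log_transform = FALSE) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  m <- tissue_means(exp)
  if (ncol(m) < 2L) stop("specificity needs >= 2 tissues")
  if (log_transform) m <- log2(1 + m)
  s <- colSums(m)
  spm <- compute_spm(m)
  ee <- compute_ee(m, s)
  out <- data.frame(gene_id = rownames(m), tau = compute_tau(m),
                    stringsAsFactors = FALSE)
  for (ti in colnames(m)) out[[paste0("spm_", ti)]] <- spm[, ti]
  for (ti in colnames(m)) out[[paste0("ee_", ti)]] <- ee[, ti]
  rownames(out) <- NULL
  attr(out, "n_tissues") <- ncol(m)
  attr(out, "n_undefined") <- sum(is.na(out$tau))
  class(out) <- c("SpecificityProfile", "data.frame")
  out
}

#' Call tissue-specific genes from a specificity profile
#'
#' Two modes mirroring common practice: `spm_top_decile` ranks genes by
#' their maximum per-tissue SPM and keeps the top 10%; `cutoff` keeps
#' genes whose maximum index exceeds `cutoff` (strict `>`). Each called
#' gene is assigned to its argmax tissue. Ties at the decile boundary
#' are broken by gene id (lexicographic), and the number of boundary
#' ties is recorded in the `n_boundary_ties` attribute.
#'
#' @param profile a `SpecificityProfile`.
#' @param method `"spm_top_decile"` or `"cutoff"`.
#' @param cutoff threshold for `cutoff` mode (default 0.8).
#' @param index index family for `cutoff` mode: `"spm"` (per-tissue
#'   columns) or `"tau"` (tissue assignment still by max SPM).
#' @param top_fraction kept fraction for the decile mode.
#' @return data.frame `gene_id`, `tissue`, `score` of the called genes.
#' @export
call_specific_genes <- function(profile, method = c("spm_top_decile",
                                                    "cutoff"),
                                cutoff = 0.8, index = c("spm", "tau"),
                                top_fraction = 0.10) {
  method <- match.arg(method); index <- match.arg(index)
  spm_cols <- grep("^spm_", names(profile), value = TRUE)
  spm <- as.matrix(profile[, spm_cols])
  colnames(spm) <- sub("^spm_", "", spm_cols)
  max_spm <- apply(spm, 1, max)
  arg_tissue <- colnames(spm)[max.col(spm, ties.method = "first")]
  score <- if (method == "cutoff" && index == "tau") profile$tau else max_spm
  ok <- !is.na(score)
  if (method == "spm_top_decile") {
    n_keep <- floor(sum(ok) * top_fraction)
    ord <- order(-score, profile$gene_id)
    ord <- ord[ok[ord]]
    keep <- ord[seq_len(n_keep)]
    boundary <- score[ord[n_keep]]
    n_ties <- sum(score[ok] == boundary) - sum(score[keep] == boundary)
  } else {
    keep <- which(ok & score > cutoff)
    n_ties <- 0L
  }
  out <- data.frame(gene_id = profile$gene_id[keep],
                    tissue = arg_tissue[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "n_boundary_ties") <- n_ties
  out
}

#' Per-timepoint specificity indices and their oscillation test
#'
#' At every timepoint, replicate values are averaged per tissue and the
#' chosen index is computed from the per-tissue means; the resulting
#' per-gene index time series is then tested for 24 h oscillation with
#' [jtk_test()] and BH-adjusted across genes ("circadian Tau genes" for
#' `index = "tau"`). Tau and SPM series are invariant to a global
#' per-timepoint rescaling of all tissues; EE additionally requires the
#' totals to rescale identically.
#'
#' @param exp an `ExpressionExperiment` in TPM; every tissue must be
#'   sampled at every timepoint.
#' @param index `"tau"`, `"spm"` or `"ee"`; for `spm`/`ee` the series is
#'   the gene's maximum per-tissue value at each timepoint.
#' @param period,lag_step,exact_limit passed to [jtk_test()].
#' @param q_cutoff BH threshold for the oscillation flag.
#' @return list with `series` (genes x timepoints matrix of the index)
#'   and `test` (data.frame `gene_id`, `p`, `q`, `lag`,
#'   `is_oscillating`).
#' @export
specificity_timecourse <- function(exp, index = c("tau", "spm", "ee"),
                                   period = 24, lag_step = NULL,
                                   exact_limit = 50, q_cutoff = 0.05) {
  index <- match.arg(index)
  stopifnot(inherits(exp, "ExpressionExperiment"))
  tps <- sort(unique(exp$samples$ct))
  tab <- table(exp$samples$tissue, exp$samples$ct)
  if (any(tab == 0)) stop("missing tissue x timepoint cell(s)")
  series <- sapply(tps, function(ct) {
    m <- tissue_means(exp, ct)
    switch(index,
           tau = compute_tau(m),
           spm = apply(compute_spm(m), 1, max),
           ee = apply(compute_ee(m, colSums(m)), 1, max))
  })
  colnames(series) <- paste0("CT", tps)
  rownames(series) <- rownames(exp$values)
  x <- series
  x[is.na(x)] <- 0
  design <- jtk_design(tps, period, lag_step, exact_limit)
  sc <- jtk_score_matrix(x, design)
  q <- stats::p.adjust(sc$p, method = "BH")
  test <- data.frame(gene_id = rownames(series), p = sc$p, q = q,
                     lag = sc$best_lag, is_oscillating = q < q_cutoff,
                     stringsAsFactors = FALSE)
  rownames(test) <- NULL
  list(series = series, test = test)
}
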