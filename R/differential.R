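#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: each sample's factor is the median across
#' genes of its ratio to the per-gene geometric mean, using only genes
#' with positive counts in all samples.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of size factors (one per sample).
#' @export
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene with positive counts in all samples")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - ref)))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

rowVars_ <- function(m) {
  n <- ncol(m)
  (rowSums(m^2) - rowSums(m)^2 / n) / (n - 1)
}

#' Negative-binomial Wald test between two replicate groups
#'
#' Self-contained two-group NB engine: counts are normalised by
#' median-of-ratios size factors, the per-gene dispersion is estimated
#' by method of moments pooled across both groups (floored at `1e-8`),
#' and a Wald test is performed on the log fold-change between the NB
#' group means, with the statistic referred to a t distribution on
#' `nA + nB - 2` degrees of freedom to account for the plug-in
#' dispersion. Genes with zero counts in both groups return
#' `log2_fc = 0, p = 1`; a gene with zero counts in one group only is
#' moderated with a half-count so its fold-change stays finite.
#'
#' @param counts_A,counts_B genes x replicates count matrices (same
#'   genes, >= 2 replicates each).
#' @param size_factors named or positional size factors for the columns
#'   of `cbind(counts_A, counts_B)`; estimated from the two groups if
#'   missing.
#' @return data.frame `log2_fc` (A over B), `p` (two-sided),
#'   `dispersion`.
#' @export
nb_de_test <- function(counts_A, counts_B, size_factors = NULL) {
  counts_A <- as.matrix(counts_A); counts_B <- as.matrix(counts_B)
  stopifnot(nrow(counts_A) == nrow(counts_B))
  nA <- ncol(counts_A); nB <- ncol(counts_B)
  if (nA < 2L || nB < 2L) stop("need >= 2 replicates per group")
  if (is.null(size_factors))
    size_factors <- estimate_size_factors(cbind(counts_A, counts_B))
  sA <- size_factors[seq_len(nA)]; sB <- size_factors[nA + seq_len(nB)]
  kA <- sweep(counts_A, 2, sA, "/"); kB <- sweep(counts_B, 2, sB, "/")
  qA <- rowMeans(kA); qB <- rowMeans(kB)

  # method-of-moments dispersion, pooled over groups:
  # Var(k_j) = q * mean(1/s_j) + alpha * q^2
  mom <- function(k, q, s) {
    v <- rowVars_(k)
    (v - q * mean(1 / s)) / q^2
  }
  aA <- mom(kA, qA, sA); aB <- mom(kB, qB, sB)
  wA <- nA - 1; wB <- nB - 1
  alpha <- (ifelse(is.finite(aA), aA, 0) * wA +
              ifelse(is.finite(aB), aB, 0) * wB) / (wA + wB)
  alpha <- pmax(alpha, 1e-8)

  both_zero <- qA == 0 & qB == 0
  one_zero <- (qA == 0) != (qB == 0)
  qA2 <- ifelse(one_zero, (rowSums(kA) + 0.5) / nA, qA)
  qB2 <- ifelse(one_zero, (rowSums(kB) + 0.5) / nB, qB)

  # Var(log qhat) by delta method from Var(qhat)
  vlog <- function(q, s, n, alpha) {
    vq <- (q * sum(1 / s) + alpha * q^2 * n) / n^2
    vq / q^2
  }
  vl <- vlog(qA2, sA, nA, alpha) + vlog(qB2, sB, nB, alpha)
  W <- (log(qA2) - log(qB2)) / sqrt(vl)
  p <- 2 * stats::pt(-abs(W), df = nA + nB - 2)
  p[both_zero | !is.finite(W)] <- 1
  lfc <- log2(qA2 / qB2)
  lfc[both_zero] <- 0
  data.frame(log2_fc = lfc, p = p, dispersion = alpha,
             row.names = rownames(counts_A))
}

#' Negative-binomial likelihood-ratio test (second engine)
#'
#' Score-style companion to [nb_de_test()] for the optional two-engine
#' consensus: likelihood ratio between separate and common NB means at
#' the gene's pooled method-of-moments dispersion, referred to
#' chi-squared with 1 df.
#'
#' @inheritParams nb_de_test
#' @param dispersion per-gene dispersion (e.g. from [nb_de_test()]);
#'   recomputed if missing.
#' @return data.frame `log2_fc`, `p`.
#' @export
nb_lrt_test <- function(counts_A, counts_B, size_factors = NULL,
                        dispersion = NULL) {
  counts_A <- as.matrix(counts_A); counts_B <- as.matrix(counts_B)
  nA <- ncol(counts_A); nB <- ncol(counts_B)
  if (is.null(size_factors))
    size_factors <- estimate_size_factors(cbind(counts_A, counts_B))
  sA <- size_factors[seq_len(nA)]; sB <- size_factors[nA + seq_len(nB)]
  if (is.null(dispersion))
    dispersion <- nb_de_test(counts_A, counts_B, size_factors)$dispersion
  kA <- sweep(counts_A, 2, sA, "/"); kB <- sweep(counts_B, 2, sB, "/")
  qA <- rowMeans(kA); qB <- rowMeans(kB)
  q0 <- (rowSums(kA) + rowSums(kB)) / (nA + nB)
  ll <- function(counts, s, q, alpha) {
    out <- 0
    for (j in seq_along(s)) {
      mu <- pmax(q * s[j], 1e-12)
      out <- out + stats::dnbinom(counts[, j], mu = mu, size = 1 / alpha,
                                  log = TRUE)
    }
    out
  }
  l1 <- ll(counts_A, sA, pmax(qA, 1e-12), dispersion) +
    ll(counts_B, sB, pmax(qB, 1e-12), dispersion)
  l0 <- ll(counts_A, sA, pmax(q0, 1e-12), dispersion) +
    ll(counts_B, sB, pmax(q0, 1e-12), dispersion)
  stat <- pmax(0, 2 * (l1 - l0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[qA == 0 & qB == 0] <- 1
  data.frame(log2_fc = log2(pmax(qA, 1e-12) / pmax(qB, 1e-12)), p = p,
             row.names = rownames(counts_A))
}

#' Per-timepoint differential expression between two tissues
#'
#' Runs the NB engine at every circadian timepoint between the
#' replicates of two tissues, BH-adjusts within each timepoint, and
#' flags differential genes with `q < alpha` AND `|log2_fc| >= lfc`
#' (the "greater than 2-fold" gate at the default `lfc = 1`). Optional
#' consensus mode additionally requires BH significance under the NB
#' likelihood-ratio engine, mirroring a two-engine intersection rule.
#' Size factors are estimated once across all samples of both tissues.
#'
#' @param exp an `ExpressionExperiment` in counts containing both
#'   tissues at every timepoint, with replicates.
#' @param tissue_a,tissue_b tissue labels; fold-changes are
#'   `tissue_a` over `tissue_b`.
#' @param alpha BH q-value cutoff.
#' @param lfc absolute log2 fold-change gate.
#' @param consensus if `TRUE`, apply the two-engine intersection rule.
#' @param condition optional condition restriction.
#' @return object of class `DEResult`: list with `table` (long per
#'   gene x timepoint data.frame: `gene_id`, `ct`, `log2_fc`, `p`, `q`,
#'   `is_de`), `summary` (per gene: `de_timepoint_set`,
#'   `n_de_timepoints`, `is_deg`, `de_all_timepoints`), `timepoints`,
#'   `tissue_a`, `tissue_b`.
#' @export
de_per_timepoint <- function(exp, tissue_a, tissue_b, alpha = 0.05,
                             lfc = 1, consensus = FALSE, condition = NULL) {
  stopifnot(inherits(exp, "ExpressionExperiment"))
  if (exp$unit != "counts") stop("differential testing runs on raw counts")
  exp <- subset_experiment(exp, tissue = c(tissue_a, tissue_b),
                           condition = condition)
  sm <- exp$samples
  tps <- sort(unique(sm$ct))
  for (ti in c(tissue_a, tissue_b)) {
    have <- unique(sm$ct[sm$tissue == ti])
    if (!setequal(have, tps))
      stop("tissue ", ti, " missing timepoint(s): ",
           paste(setdiff(tps, have), collapse = ", "))
  }
  sf <- estimate_size_factors(exp$values)
  rows <- vector("list", length(tps))
  for (k in seq_along(tps)) {
    iA <- which(sm$tissue == tissue_a & sm$ct == tps[k])
    iB <- which(sm$tissue == tissue_b & sm$ct == tps[k])
    res <- nb_de_test(exp$values[, iA, drop = FALSE],
                      exp$values[, iB, drop = FALSE],
                      size_factors = sf[c(iA, iB)])
    q <- stats::p.adjust(res$p, method = "BH")
    is_de <- q < alpha & abs(res$log2_fc) >= lfc
    if (consensus) {
      res2 <- nb_lrt_test(exp$values[, iA, drop = FALSE],
                          exp$values[, iB, drop = FALSE],
                          size_factors = sf[c(iA, iB)],
                          dispersion = res$dispersion)
      is_de <- is_de & stats::p.adjust(res2$p, method = "BH") < alpha
    }
    rows[[k]] <- data.frame(gene_id = rownames(exp$values), ct = tps[k],
                            log2_fc = res$log2_fc, p = res$p, q = q,
                            is_de = is_de, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  de_result(tab, tps, tissue_a, tissue_b)
}

#' Assemble a `DEResult` from a long per-timepoint table
#'
#' Also the import path for externally computed per-timepoint results
#' (any engine satisfying the `gene_id, ct, log2_fc, p, q, is_de`
#' contract).
#'
#' @param tab long data.frame with columns `gene_id`, `ct`, `log2_fc`,
#'   `p`, `q`, `is_de`.
#' @param timepoints,tissue_a,tissue_b design metadata (derived from
#'   `tab` if omitted).
#' @return a `DEResult`.
#' @export
de_result <- function(tab, timepoints = sort(unique(tab$ct)),
                      tissue_a = NA_character_, tissue_b = NA_character_) {
  stopifnot(all(c("gene_id", "ct", "log2_fc", "p", "q", "is_de") %in%
                  names(tab)))
  genes <- unique(tab$gene_id)
  de_sets <- lapply(split(tab$ct[tab$is_de], tab$gene_id[tab$is_de]), sort)
  n_de <- integer(length(genes)); names(n_de) <- genes
  n_de[names(de_sets)] <- lengths(de_sets)
  summary <- data.frame(
    gene_id = genes,
    de_timepoint_set = vapply(genes, function(g) {
      s <- de_sets[[g]]
      if (is.null(s)) "" else paste0("CT", s, collapse = ",")
    }, "", USE.NAMES = FALSE),
    n_de_timepoints = unname(n_de[genes]),
    stringsAsFactors = FALSE)
  summary$is_deg <- summary$n_de_timepoints > 0L
  summary$de_all_timepoints <- summary$n_de_timepoints == length(timepoints)
  out <- list(table = tab, summary = summary, timepoints = timepoints,
              tissue_a = tissue_a, tissue_b = tissue_b)
  class(out) <- "DEResult"
  out
}

#' @export
print.DEResult <- function(x, ...) {
  cat(sprintf("DEResult: %s vs %s, %d genes, %d timepoints\n",
              x$tissue_a, x$tissue_b, nrow(x$summary),
              length(x$timepoints)))
  cat(sprintf("  DEGs: %d (%d at all timepoints)\n",
              sum(x$summary$is_deg), sum(x$summary$de_all_timepoints)))
  invisible(x)
}

#' Permutation baseline for the all-timepoint DEG fraction
#'
#' Observed statistic: among genes differential at >= 1 timepoint, the
#' fraction differential at every timepoint. The null is built by
#' permuting the timepoint labels of the samples (by default within
#' each tissue, preserving the replicate structure; alternatively
#' across all samples of both tissues), rerunning the per-timepoint
#' analysis, and recomputing the fraction.
#'
#' @inheritParams de_per_timepoint
#' @param n_perm number of permutations (a warning below 10).
#' @param seed RNG seed (null distribution is reproducible).
#' @param scheme `"within_tissue"` or `"all_samples"` label shuffle.
#' @return list with `observed_fraction`, `null_fractions`, `p`
#'   (empirical two-sided), `scheme`, and the observed `DEResult` as
#'   `de`.
#' @export
permutation_all_timepoint_fraction <- function(exp, tissue_a, tissue_b,
                                               n_perm = 50, seed = 1,
                                               scheme = c("within_tissue",
                                                          "all_samples"),
                                               alpha = 0.05, lfc = 1,
                                               condition = NULL) {
  scheme <- match.arg(scheme)
  if (n_perm < 10) warning("n_perm < 10: the null will be very coarse")
  exp <- subset_experiment(exp, tissue = c(tissue_a, tissue_b),
                           condition = condition)
  frac <- function(de) {
    n_deg <- sum(de$summary$is_deg)
    if (n_deg == 0) return(NA_real_)
    sum(de$summary$de_all_timepoints) / n_deg
  }
  de_obs <- de_per_timepoint(exp, tissue_a, tissue_b, alpha, lfc)
  observed <- frac(de_obs)
  set.seed(seed)
  null_fractions <- vapply(seq_len(n_perm), function(i) {
    ep <- exp
    if (scheme == "within_tissue") {
      for (ti in unique(ep$samples$tissue)) {
        idx <- which(ep$samples$tissue == ti)
        ep$samples$ct[idx] <- sample(ep$samples$ct[idx])
      }
    } else {
      ep$samples$ct <- sample(ep$samples$ct)
    }
    frac(de_per_timepoint(ep, tissue_a, tissue_b, alpha, lfc))
  }, numeric(1))
  ok <- !is.na(null_fractions)
  p <- if (is.na(observed) || !any(ok)) NA_real_ else {
    lo <- (1 + sum(null_fractions[ok] <= observed)) / (1 + sum(ok))
    hi <- (1 + sum(null_fractions[ok] >= observed)) / (1 + sum(ok))
    min(1, 2 * min(lo, hi))
  }
  list(observed_fraction = observed, null_fractions = null_fractions,
       p = p, scheme = scheme, de = de_obs)
}
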