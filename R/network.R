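#' Variance-stabilising transform for counts
#'
#' `log2(1 + c / sizefactor)` per sample with median-of-ratios size
#' factors: the pipeline's documented stand-in for a regularised log
#' transform ahead of co-expression analysis. Zero counts map to 0 and
#' the transform is monotone in counts within each sample.
#'
#' @param exp an `ExpressionExperiment` in counts, or a count matrix.
#' @return genes x samples numeric matrix.
#' @export
vst <- function(exp) {
  counts <- if (inherits(exp, "ExpressionExperiment")) exp$values else exp
  sf <- estimate_size_factors(counts)
  log2(1 + sweep(counts, 2, sf, "/"))
}

#' Filter rows by median absolute deviation
#'
#' Keeps rows whose raw MAD (consistency constant 1, i.e. the plain
#' median of absolute deviations from the median) is strictly above
#' `threshold`; constant rows are always dropped.
#'
#' @param m numeric matrix.
#' @param threshold MAD cutoff (default 0.1).
#' @param scaled if `TRUE`, use the 1.4826-scaled MAD instead.
#' @return the filtered matrix.
#' @export
mad_filter <- function(m, threshold = 0.1, scaled = FALSE) {
  const <- if (scaled) 1.4826 else 1
  mads <- apply(m, 1, stats::mad, constant = const)
  keep <- mads > threshold
  if (!any(keep)) stop("MAD filter removed every gene")
  m[keep, , drop = FALSE]
}

#' Biweight midcorrelation
#'
#' Outlier-robust correlation: observations are weighted by
#' `(1 - u^2)^2` with `u = (x - median(x)) / (9 * mad(x))` (raw MAD)
#' and weights zeroed beyond 9 MADs. When an input has zero MAD the
#' coefficient falls back to Pearson for that pair and the result
#' carries a `fallback` attribute.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need >= 3 observations")
  wgt <- function(v) {
    md <- stats::median(v)
    s <- stats::mad(v, constant = 1)
    if (s == 0) return(NULL)
    u <- (v - md) / (9 * s)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - md) * w
  }
  a <- wgt(x); b <- wgt(y)
  if (is.null(a) || is.null(b)) {
    out <- stats::cor(x, y)
    if (is.na(out)) out <- 0
    attr(out, "fallback") <- "pearson"
    return(out)
  }
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# all-pairs bicor of matrix rows (genes x samples)
bicor_matrix <- function(m) {
  md <- apply(m, 1, stats::median)
  s <- apply(m, 1, stats::mad, constant = 1)
  centred <- m - md
  bad <- s == 0
  u <- centred / (9 * s)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  z <- centred * w
  if (any(bad)) {           # Pearson fallback rows
    mu <- rowMeans(m[bad, , drop = FALSE])
    z[bad, ] <- m[bad, , drop = FALSE] - mu
  }
  z <- z / sqrt(rowSums(z^2))
  out <- tcrossprod(z)
  out[out > 1] <- 1; out[out < -1] <- -1
  attr(out, "n_fallback") <- sum(bad)
  out
}

# unsigned topological overlap from an adjacency matrix
tom_similarity <- function(adj) {
  diag(adj) <- 0
  L <- adj %*% adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- (L + adj) / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules (simplified WGCNA-style)
#'
#' Adjacency is `|bicor|^softpower` (unsigned network, or
#' `((1 + bicor)/2)^softpower` signed), turned into the topological
#' overlap similarity, clustered by average-linkage on TOM
#' dissimilarity, and cut statically at `cut_height`. Clusters smaller
#' than `min_module_size` are merged into the `"unassigned"` bucket.
#' Each module's eigengene is the first principal-component score
#' series over samples of the standardised module submatrix, scaled to
#' unit norm and sign-oriented to correlate positively with the module
#' mean profile.
#'
#' @param m filtered genes x samples matrix (e.g. [vst()] +
#'   [mad_filter()] output).
#' @param softpower soft-thresholding exponent (default 14).
#' @param min_module_size minimal module size (default 30).
#' @param cut_height static tree-cut height on TOM dissimilarity;
#'   `NULL` (default) picks the midpoint between the median and the
#'   maximal merge height of the tree, a scale-adaptive static cut
#'   (TOM dissimilarities within even perfectly correlated modules sit
#'   well above 0, so a fixed small cut height would shatter every
#'   module).
#' @param signed use a signed network.
#' @return object of class `ModuleAssignment`: list with `modules`
#'   (named character vector gene -> module label `"M1"`, ... or
#'   `"unassigned"`), `eigengenes` (samples x modules matrix),
#'   `mean_expression` (samples x modules), `sizes`, and `tom_range`.
#' @export
detect_modules <- function(m, softpower = 14, min_module_size = 30,
                           cut_height = NULL, signed = FALSE) {
  if (softpower < 1) stop("softpower must be >= 1")
  if (nrow(m) < 3L) stop("too few genes for module detection")
  bc <- bicor_matrix(m)
  adj <- if (signed) ((1 + bc) / 2)^softpower else abs(bc)^softpower
  tom <- tom_similarity(adj)
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  if (is.null(cut_height))
    cut_height <- (stats::median(tree$height) + max(tree$height)) / 2
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # stable labels: modules ordered by decreasing size
  keep <- keep[order(-sizes[keep])]
  lab <- rep("unassigned", nrow(m))
  for (i in seq_along(keep)) lab[cl == as.integer(keep[i])] <- paste0("M", i)
  names(lab) <- rownames(m)
  mods <- setdiff(unique(lab), "unassigned")
  eig <- sapply(mods, function(mod) {
    sub <- m[lab == mod, , drop = FALSE]
    sub <- t(scale(t(sub)))
    sub[!is.finite(sub)] <- 0
    sv <- svd(sub, nu = 0, nv = 1)
    e <- sv$v[, 1]
    mean_prof <- colMeans(m[lab == mod, , drop = FALSE])
    if (stats::cor(e, mean_prof) < 0) e <- -e
    e / sqrt(sum(e^2))
  })
  me <- sapply(mods, function(mod) colMeans(m[lab == mod, , drop = FALSE]))
  if (length(mods)) {
    rownames(eig) <- colnames(m); rownames(me) <- colnames(m)
  }
  out <- list(modules = lab, eigengenes = eig, mean_expression = me,
              sizes = table(lab), tom_range = range(tom))
  class(out) <- "ModuleAssignment"
  out
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat("ModuleAssignment:\n")
  print(x$sizes)
  invisible(x)
}

#' Test modules for 24 h cycling
#'
#' Runs [jtk_test()] on every module's eigengene score series and on
#' its mean-expression series (per-sample series, times taken from the
#' sample sheet), BH-adjusts each across modules, and calls a module
#' cycling when either series reaches `q < alpha`.
#'
#' @param assignment a `ModuleAssignment`.
#' @param times observation times in hours, one per sample column.
#' @param period,lag_step,exact_limit passed to [jtk_test()].
#' @param alpha BH cutoff.
#' @return data.frame: `module`, `p_eigengene`, `q_eigengene`,
#'   `p_mean`, `q_mean`, `lag_eigengene`, `is_cycling`.
#' @export
cycling_modules <- function(assignment, times, period = 24,
                            lag_step = NULL, exact_limit = 50,
                            alpha = 0.05) {
  stopifnot(inherits(assignment, "ModuleAssignment"))
  mods <- colnames(assignment$eigengenes)
  if (!length(mods))
    return(data.frame(module = character(), p_eigengene = numeric(),
                      q_eigengene = numeric(), p_mean = numeric(),
                      q_mean = numeric(), lag_eigengene = numeric(),
                      is_cycling = logical()))
  design <- jtk_design(times, period, lag_step, exact_limit)
  sc_e <- jtk_score_matrix(t(assignment$eigengenes), design)
  sc_m <- jtk_score_matrix(t(assignment$mean_expression), design)
  q_e <- stats::p.adjust(sc_e$p, method = "BH")
  q_m <- stats::p.adjust(sc_m$p, method = "BH")
  data.frame(module = mods, p_eigengene = sc_e$p, q_eigengene = q_e,
             p_mean = sc_m$p, q_mean = q_m, lag_eigengene = sc_e$best_lag,
             is_cycling = q_e < alpha | q_m < alpha,
             stringsAsFactors = FALSE)
}
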