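#' Exact null distribution of Kendall's S against a tied reference
#'
#' Computes the exact permutation null of Kendall's S statistic between a
#' tie-free data vector and a fixed reference whose values contain ties
#' (groups of equal reference values arise from replicated timepoints and
#' from symmetries of the cosine reference). Under a random permutation of
#' the data ranks, the number of concordant cross-group pairs decomposes
#' into independent Mann-Whitney counts, so the pmf is obtained by
#' convolving exact Wilcoxon distributions.
#'
#' @param tie_pattern integer vector of reference group sizes (ties in the
#'   reference); must sum to `n`.
#' @param n number of observations.
#' @param exact_limit designs with `n` above this fall back to a normal
#'   approximation with continuity correction (flagged in the result).
#' @return object of class `jtk_null` with elements `n`, `tie_pattern`,
#'   `M` (maximal |S|), `exact` (logical), and for exact nulls `S`
#'   (support, step 2) and `pmf`; for approximate nulls `sd`. Use
#'   [jtk_null_p_upper()] for one-sided upper tail probabilities.
#' @examples
#' nd <- kendall_S_exact_null(c(1, 1, 1), 3)
#' rbind(S = nd$S, p = nd$pmf)  # {-3,-1,1,3} with mass {1,2,2,1}/6
#' @export
kendall_S_exact_null <- function(tie_pattern, n, exact_limit = 50) {
  tie_pattern <- as.integer(tie_pattern)
  if (any(tie_pattern < 1L)) stop("tie_pattern entries must be positive")
  if (sum(tie_pattern) != n) stop("tie_pattern must sum to n")
  M <- (n^2 - sum(tie_pattern^2)) / 2  # number of cross-group pairs
  if (n > exact_limit) {
    # Jonckheere-Terpstra variance; S = 2*JT - M so Var(S) = 4*Var(JT)
    v <- (n^2 * (2 * n + 3) - sum(tie_pattern^2 * (2 * tie_pattern + 3))) / 72
    out <- list(n = n, tie_pattern = tie_pattern, M = M, exact = FALSE,
                sd = 2 * sqrt(v))
    class(out) <- "jtk_null"
    return(out)
  }
  # pmf of C = number of concordant cross-group pairs, as a convolution of
  # independent Mann-Whitney U distributions (group t vs all earlier groups)
  pmf <- 1
  cum <- 0L
  for (ct in tie_pattern) {
    if (cum > 0L) {
      u <- stats::dwilcox(0:(cum * ct), m = cum, n = ct)
      new <- numeric(length(pmf) + length(u) - 1L)
      for (k in seq_along(u)) {
        if (u[k] > 0) {
          idx <- k:(k + length(pmf) - 1L)
          new[idx] <- new[idx] + pmf * u[k]
        }
      }
      pmf <- new
    }
    cum <- cum + ct
  }
  out <- list(n = n, tie_pattern = tie_pattern, M = M, exact = TRUE,
              S = 2 * (seq_along(pmf) - 1L) - M, pmf = pmf)
  class(out) <- "jtk_null"
  out
}

#' One-sided upper tail probability of a `jtk_null`
#'
#' @param null object from [kendall_S_exact_null()].
#' @param s observed Kendall S value(s); ties in the data may place `s`
#'   off the tie-free support, in which case the tail is taken over all
#'   null values `>= s` (a conservative convention).
#' @return `P(S >= s)` under the null, one value per element of `s`.
#' @export
jtk_null_p_upper <- function(null, s) {
  if (null$exact) {
    tail <- rev(cumsum(rev(null$pmf)))        # tail[k] = P(S >= S[k])
    idx <- findInterval(s - 1e-9, null$S) + 1L # first support value >= s
    p <- ifelse(idx > length(null$S), 0, tail[pmin(idx, length(null$S))])
    pmin(1, p)
  } else {
    pmin(1, stats::pnorm(s - 1, mean = 0, sd = null$sd, lower.tail = FALSE))
  }
}

# Reference values, tie pattern and pair-sign vector for one lag.
# Returns list(r, groups, sr) where sr is sign(r_i - r_j) over pairs i<j.
jtk_reference <- function(times, lag, period) {
  # rounding makes analytically tied cosine values (symmetric timepoints)
  # exactly equal, so the tie pattern and the pair signs agree
  r <- round(cos(2 * pi * (times - lag) / period), 9)
  if (length(unique(r)) < 2L)
    stop("degenerate reference: all reference values equal for lag ", lag)
  list(r = r, groups = as.integer(table(r)))
}

# Precompute, for a design (times, period, lag grid), everything needed to
# score many series: per lag the pair signs of the reference and the exact
# (or approximate) null.
jtk_design <- function(times, period = 24, lag_step = NULL, exact_limit = 50) {
  n <- length(times)
  ut <- sort(unique(times))
  if (length(ut) < 2L) stop("need at least 2 distinct observation times")
  if (is.null(lag_step)) lag_step <- min(diff(ut)) / 2
  lags <- seq(0, period - lag_step, by = lag_step)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # i < j
  refs <- vector("list", length(lags))
  cache <- list()
  for (k in seq_along(lags)) {
    ref <- jtk_reference(times, lags[k], period)
    key <- paste(sort(ref$groups), collapse = ",")
    if (is.null(cache[[key]]))
      cache[[key]] <- kendall_S_exact_null(ref$groups, n, exact_limit)
    refs[[k]] <- list(lag = lags[k],
                      sr = sign(ref$r[pairs[, 1]] - ref$r[pairs[, 2]]),
                      null = cache[[key]])
  }
  list(n = n, times = times, period = period, lags = lags,
       pairs = pairs, refs = refs)
}

# Score a genes x samples matrix against a jtk_design.
# Returns list(p, best_lag, S_best, tau_best) with one entry per row.
jtk_score_matrix <- function(X, design) {
  pr <- design$pairs
  SD <- sign(X[, pr[, 1], drop = FALSE] - X[, pr[, 2], drop = FALSE])
  nlag <- length(design$refs)
  P <- matrix(NA_real_, nrow(X), nlag)
  Smat <- matrix(NA_real_, nrow(X), nlag)
  for (k in seq_len(nlag)) {
    ref <- design$refs[[k]]
    S <- as.vector(SD %*% ref$sr)
    Smat[, k] <- S
    P[, k] <- jtk_null_p_upper(ref$null, S)
  }
  best <- max.col(-P, ties.method = "first")
  minp <- P[cbind(seq_len(nrow(P)), best)]
  p <- pmin(1, nlag * minp)
  # tie-corrected Kendall tau-b at the best lag
  n_t <- vapply(seq_len(nrow(X)), function(g) {
    sd_g <- SD[g, ]
    sr <- design$refs[[best[g]]]$sr
    d0 <- sum(sd_g != 0); r0 <- sum(sr != 0)
    if (d0 == 0 || r0 == 0) return(0)
    Smat[g, best[g]] / sqrt(d0 * r0)
  }, numeric(1))
  list(p = p, best_lag = design$lags[best],
       S_best = Smat[cbind(seq_len(nrow(P)), best)], tau_best = n_t)
}

#' Jonckheere-Terpstra-Kendall test for 24 h rhythmicity
#'
#' Rank-based test of concordance between a time series and a family of
#' phase-shifted cosine references. For each candidate lag the Kendall S
#' between the series and the reference is referred to its exact
#' permutation null (ties in the reference handled exactly; ties in the
#' data via the conservative tail convention); the minimum one-sided p
#' over lags is Bonferroni-multiplied by the number of lags and capped at
#' 1. A constant series carries no concordance signal and yields p = 1.
#'
#' @param x numeric series (one value per observation; replicates allowed).
#' @param times observation times in hours, same length as `x`.
#' @param period test period in hours (default 24).
#' @param lag_step spacing of the candidate lag grid in hours; defaults to
#'   half the smallest sampling interval.
#' @param exact_limit see [kendall_S_exact_null()].
#' @return list with `p` (Bonferroni-over-lags p-value), `best_lag`
#'   (candidate lag minimising the per-lag p, hours), `tau` (tie-corrected
#'   Kendall tau at the best lag), `S` (Kendall S at the best lag), and
#'   `n_lags`.
#' @examples
#' t <- rep(seq(0, 20, 4), each = 4)
#' jtk_test(cos(2 * pi * (t - 8) / 24), t)$best_lag
#' @export
jtk_test <- function(x, times, period = 24, lag_step = NULL,
                     exact_limit = 50) {
  stopifnot(length(x) == length(times))
  design <- jtk_design(times, period, lag_step, exact_limit)
  res <- jtk_score_matrix(matrix(x, nrow = 1), design)
  list(p = res$p, best_lag = res$best_lag, tau = res$tau_best,
       S = res$S_best, n_lags = length(design$lags))
}

#' Cosinor amplitude, peak phase and mesor
#'
#' Least-squares fit of `x ~ m + a*cos(2*pi*t/period) + b*sin(2*pi*t/period)`.
#' Amplitude is `sqrt(a^2 + b^2)` (half peak-to-trough on the input scale),
#' the lag is the peak time of the fitted waveform in `[0, period)`, and
#' the mesor is the fitted midline `m`.
#'
#' @param x numeric series, or a genes x samples matrix for a vectorised
#'   fit of many series sharing the same times.
#' @param times observation times in hours.
#' @param period period in hours (default 24).
#' @return for a vector input, named vector `c(amplitude, lag, mesor)`;
#'   for a matrix, a data.frame with one row per input row.
#' @examples
#' t <- seq(0, 20, 4)
#' cosinor_amp_phase(5 + 2 * cos(2 * pi * (t - 4) / 24), t)
#' @export
cosinor_amp_phase <- function(x, times, period = 24) {
  if (length(unique(times)) < 3L)
    stop("cosinor fit needs at least 3 distinct observation times")
  w <- 2 * pi / period
  D <- cbind(1, cos(w * times), sin(w * times))
  if (qr(D)$rank < 3L) stop("rank-deficient cosinor design")
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else x
  stopifnot(ncol(X) == length(times))
  coefs <- t(solve(crossprod(D), crossprod(D, t(X))))  # genes x 3
  a <- coefs[, 2]; b <- coefs[, 3]
  amplitude <- sqrt(a^2 + b^2)
  lag <- (atan2(b, a) / w) %% period
  lag[amplitude < 1e-12] <- 0
  if (single)
    c(amplitude = amplitude[1], lag = lag[1], mesor = coefs[1, 1])
  else
    data.frame(amplitude = amplitude, lag = lag, mesor = coefs[, 1],
               row.names = rownames(X))
}
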