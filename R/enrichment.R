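#' Two-sided Fisher exact enrichment of one set against another
#'
#' Builds the 2x2 table `a = |query & target|`, `b = |query \ target|`,
#' `c = |target \ query|`, `d = rest of background`, computes the
#' two-sided exact hypergeometric p (sum over all tables with the given
#' margins whose probability does not exceed the observed one, with the
#' customary `1 + 1e-7` relative tolerance for probability ties), and
#' the odds ratio `a*d / (b*c)` with a Haldane 0.5 correction applied
#' (and flagged) only when a zero cell occurs. Both sets are
#' intersected with the background first.
#'
#' @param query,target character vectors of gene ids.
#' @param background character vector: the gene universe (the expressed
#'   genes of the experiment).
#' @return one-row data.frame of class `EnrichmentResult`: `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p`, `haldane` (logical flag).
#' @export
fisher_enrich <- function(query, target, background) {
  if (!length(background)) stop("empty background universe")
  background <- unique(background)
  query <- intersect(unique(query), background)
  target <- intersect(unique(target), background)
  a <- length(intersect(query, target))
  b <- length(query) - a
  cc <- length(target) - a
  d <- length(background) - a - b - cc
  p <- fisher_p_two_sided(a, b, cc, d)
  haldane <- any(c(a, b, cc, d) == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  out <- data.frame(a = a, b = b, c = cc, d = d, odds_ratio = or, p = p,
                    haldane = haldane)
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

# two-sided exact p for a 2x2 table with fixed margins, from the
# hypergeometric pmf: sum of P(k) over k with P(k) <= P(a) * (1 + 1e-7)
fisher_p_two_sided <- function(a, b, cc, d) {
  m <- a + b          # query size
  n <- cc + d         # non-query size
  k <- a + cc         # target size
  lo <- max(0L, k - n); hi <- min(k, m)
  supp <- lo:hi
  pk <- stats::dhyper(supp, m, n, k)
  p_obs <- pk[supp == a]
  min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

#' Enrichment of every query set against every target set
#'
#' All query x target pairs are tested with [fisher_enrich()] against
#' the shared background; BH adjustment is applied within each query
#' across its targets. Direction is `enriched` if `OR > 1` and
#' `q < alpha`, `depleted` if `OR < 1` and `q < alpha`, otherwise `ns`.
#'
#' @param queries,targets named lists of gene-id vectors.
#' @param background the gene universe.
#' @param alpha BH q-value cutoff for the direction call.
#' @return data.frame with one row per pair: `query`, `target`, the
#'   2x2 cells, `odds_ratio`, `p`, `q`, `direction`.
#' @export
enrich_matrix <- function(queries, targets, background, alpha = 0.05) {
  stopifnot(length(names(queries)) == length(queries),
            length(names(targets)) == length(targets))
  rows <- list()
  for (qn in names(queries)) {
    block <- do.call(rbind, lapply(names(targets), function(tn)
      cbind(data.frame(query = qn, target = tn, stringsAsFactors = FALSE),
            fisher_enrich(queries[[qn]], targets[[tn]], background))))
    block$q <- stats::p.adjust(block$p, method = "BH")
    rows[[qn]] <- block
  }
  out <- do.call(rbind, rows)
  out$direction <- ifelse(out$q >= alpha, "ns",
                          ifelse(out$odds_ratio > 1, "enriched", "depleted"))
  rownames(out) <- NULL
  out
}
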