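#' Per-gene amplitude change between control and disrupted conditions
#'
#' Joins two rhythm scans of the same tissue (control vs disrupted) and
#' reports, per gene, the cosinor amplitudes of both conditions, their
#' difference `delta = amp_control - amp_disrupted` and `abs_delta`.
#' Optionally amplitudes are expressed relative to the mesor
#' (`amp / mesor`) for a scale-free comparison.
#'
#' @param rhythm_ctrl,rhythm_dis `RhythmResult` tables over the same
#'   gene universe.
#' @param relative if `TRUE`, use `amp / mesor` on both sides.
#' @param rhythmic_only if `TRUE`, keep only genes rhythmic (q < 0.05)
#'   in at least one condition.
#' @return data.frame of class `AmplitudeChange`: `gene_id`,
#'   `amp_control`, `amp_disrupted`, `delta`, `abs_delta`.
#' @export
amplitude_change <- function(rhythm_ctrl, rhythm_dis, relative = FALSE,
                             rhythmic_only = FALSE) {
  if (!setequal(rhythm_ctrl$gene_id, rhythm_dis$gene_id))
    stop("gene universe mismatch between conditions")
  rd <- rhythm_dis[match(rhythm_ctrl$gene_id, rhythm_dis$gene_id), ]
  a_c <- rhythm_ctrl$amp; a_d <- rd$amp
  if (relative) {
    a_c <- a_c / rhythm_ctrl$mesor
    a_d <- a_d / rd$mesor
  }
  out <- data.frame(gene_id = rhythm_ctrl$gene_id, amp_control = a_c,
                    amp_disrupted = a_d, delta = a_c - a_d,
                    abs_delta = abs(a_c - a_d), stringsAsFactors = FALSE)
  if (rhythmic_only)
    out <- out[rhythm_ctrl$is_rhythmic | rd$is_rhythmic, , drop = FALSE]
  out <- out[is.finite(out$abs_delta), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("AmplitudeChange", "data.frame")
  out
}

#' Compare amplitude-change effect sizes across gene sets
#'
#' For every gene set: the median and mean `abs_delta` of the set and
#' of its complement, and a two-sided Wilcoxon rank-sum test of the
#' set's `abs_delta` against the complement's. With `downsample`, the
#' larger of the two groups is randomly subsampled (seeded) to the
#' smaller's size and the test repeated over `rounds` rounds, reporting
#' the median p.
#'
#' @param ac an `AmplitudeChange` table.
#' @param sets named list of gene-id vectors (subsets of the table's
#'   universe; a set smaller than 5 is skipped with a warning).
#' @param downsample equalise group sizes by subsampling.
#' @param rounds downsampling rounds.
#' @param seed RNG seed for the subsampling.
#' @return data.frame: `set`, `n_set`, `n_complement`, `median_set`,
#'   `median_complement`, `mean_set`, `mean_complement`, `p`.
#' @export
compare_sets <- function(ac, sets, downsample = FALSE, rounds = 20,
                         seed = 1) {
  stopifnot(inherits(ac, "AmplitudeChange"))
  unknown <- setdiff(unlist(sets), ac$gene_id)
  if (length(unknown))
    stop("set gene(s) outside the amplitude universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  set.seed(seed)
  rows <- lapply(names(sets), function(nm) {
    in_set <- ac$gene_id %in% sets[[nm]]
    a <- ac$abs_delta[in_set]; b <- ac$abs_delta[!in_set]
    if (length(a) < 5L) {
      warning("set ", nm, " has fewer than 5 genes: skipped")
      return(NULL)
    }
    p <- if (!downsample) stats::wilcox.test(a, b)$p.value else {
      k <- min(length(a), length(b))
      stats::median(vapply(seq_len(rounds), function(i)
        stats::wilcox.test(sample(a, k), sample(b, k))$p.value,
        numeric(1)))
    }
    data.frame(set = nm, n_set = length(a), n_complement = length(b),
               median_set = stats::median(a),
               median_complement = stats::median(b),
               mean_set = mean(a), mean_complement = mean(b), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
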