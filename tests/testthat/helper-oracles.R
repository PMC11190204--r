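# shared helpers: permutation enumeration and small builders

# all permutations of 1..n as an n! x n matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Kendall S between every permutation row of P and reference r
perm_S_values <- function(P, r) {
  n <- ncol(P)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sr <- sign(r[pr[, 1]] - r[pr[, 2]])
  SD <- sign(P[, pr[, 1], drop = FALSE] - P[, pr[, 2], drop = FALSE])
  as.vector(SD %*% sr)
}

# minimal rhythm-result table for classifier tests
fake_rhythm <- function(gene_id, rhythmic) {
  data.frame(gene_id = gene_id, p = ifelse(rhythmic, 1e-6, 0.9),
             q = ifelse(rhythmic, 1e-5, 0.95), period = 24, lag = 0,
             amp = 1, cosinor_lag = 0, mesor = 10, tau = 0.5,
             is_rhythmic = rhythmic, stringsAsFactors = FALSE)
}

# long DE table from a per-gene list of DE timepoints
fake_de <- function(gene_id, de_sets, timepoints = seq(0, 20, 4)) {
  tab <- expand.grid(gene_id = gene_id, ct = timepoints,
                     stringsAsFactors = FALSE)
  tab$log2_fc <- 0; tab$p <- 0.9; tab$q <- 0.95; tab$is_de <- FALSE
  for (g in names(de_sets)) {
    sel <- tab$gene_id == g & tab$ct %in% de_sets[[g]]
    tab$log2_fc[sel] <- 3; tab$p[sel] <- 1e-8; tab$q[sel] <- 1e-7
    tab$is_de[sel] <- TRUE
  }
  de_result(tab, timepoints, "liver", "kidney")
}
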