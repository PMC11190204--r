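test_that("identical groups give zero fold-change and p = 1", {
  set.seed(30)
  X <- matrix(rnbinom(50 * 4, mu = 100, size = 10), 50,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  res <- nb_de_test(X, X, size_factors = rep(1, 8))
  expect_true(all(res$log2_fc == 0))
  expect_true(all(res$p == 1))
  zero <- nb_de_test(matrix(0, 2, 3), matrix(0, 2, 3),
                     size_factors = rep(1, 6))
  expect_equal(zero$p, c(1, 1))
  expect_equal(zero$log2_fc, c(0, 0))
})

test_that("swapping the groups negates fold-changes, p unchanged", {
  set.seed(31)
  A <- matrix(rnbinom(200 * 4, mu = 150, size = 10), 200)
  B <- matrix(rnbinom(200 * 4, mu = 80, size = 10), 200)
  r1 <- nb_de_test(A, B, size_factors = rep(1, 8))
  r2 <- nb_de_test(B, A, size_factors = rep(1, 8))
  expect_equal(r1$log2_fc, -r2$log2_fc, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("the NB Wald test is calibrated under the null and powered", {
  set.seed(32)
  X <- matrix(rnbinom(2000 * 8, mu = 100, size = 10), 2000)
  null <- nb_de_test(X[, 1:4], X[, 5:8], size_factors = rep(1, 8))
  frac <- mean(null$p < 0.05)
  ci <- 0.05 + c(-1, 1) * 3 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
  # planted 4-fold change, mean 100, alpha = 0.05 dispersion, 4 vs 4
  A <- matrix(rnbinom(1000 * 4, mu = 400, size = 20), 1000)
  B <- matrix(rnbinom(1000 * 4, mu = 100, size = 20), 1000)
  pow <- nb_de_test(A, B, size_factors = rep(1, 8))
  expect_gte(mean(stats::p.adjust(pow$p, "BH") < 0.05), 0.9)
  expect_equal(median(pow$log2_fc), 2, tolerance = 0.1)
})

test_that("the NB engine agrees with an established NB engine", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  n <- 300
  A <- matrix(rnbinom(n * 4, mu = 100, size = 10), n)
  B <- matrix(rnbinom(n * 4, mu = c(rep(400, 50), rep(100, n - 50)),
                      size = 10), n)
  rownames(A) <- rownames(B) <- sprintf("g%03d", 1:n)
  mine <- nb_de_test(A, B)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cbind(A, B), S4Vectors::DataFrame(group = factor(rep(c("A", "B"),
                                                         each = 4))),
    ~group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds, contrast = c("group", "A", "B"))
  expect_gt(cor(mine$log2_fc, ref$log2FoldChange, use = "complete.obs"),
            0.99)
  mine_sig <- stats::p.adjust(mine$p, "BH") < 0.05
  ref_sig <- !is.na(ref$padj) & ref$padj < 0.05
  # the unshrunk engine is somewhat more conservative than the
  # shrinkage engine: its calls are (almost) nested in the reference's
  expect_gte(mean(mine_sig[1:50]), 0.8)
  expect_gte(mean(ref_sig[mine_sig]), 0.9)
  expect_lt(mean(mine_sig[51:n]), 0.05)
  expect_lt(mean(ref_sig[51:n]), 0.05)
})

test_that("per-timepoint DE recovers planted constitutive and temporal genes", {
  cfg <- sim_config(n_genes = 600, nb_dispersion = 0.01, seed = 34)
  sim <- simulate_experiment(cfg)
  de <- de_per_timepoint(sim$experiment, "liver", "kidney")
  tr <- sim$truth[match(de$summary$gene_id, sim$truth$gene_id), ]
  spec <- !is.na(tr$specific_tissue)
  expect_gt(mean(de$summary$de_all_timepoints[spec]), 0.95)
  tmp <- !is.na(tr$temporal_tissue)
  called_sets <- strsplit(de$summary$de_timepoint_set[tmp], ",")
  truth_sets <- strsplit(tr$temporal_timepoints[tmp], ",")
  match_frac <- mean(mapply(function(a, b)
    setequal(a, paste0("CT", b)), called_sets, truth_sets))
  expect_gt(match_frac, 0.9)
  # fold-change sign: liver-specific genes are up in liver
  up_liver <- spec & tr$specific_tissue == "liver"
  lfc0 <- de$table$log2_fc[de$table$ct == 0]
  expect_true(all(lfc0[up_liver] > 0))
  # is_deg equals the union of per-timepoint DE sets
  union_set <- unique(de$table$gene_id[de$table$is_de])
  expect_setequal(de$summary$gene_id[de$summary$is_deg], union_set)
  # BH q monotone in p within each timepoint
  for (ct in unique(de$table$ct)) {
    sl <- de$table[de$table$ct == ct, ]
    o <- order(sl$p)
    expect_true(all(diff(sl$q[o]) >= -1e-12))
  }
})

test_that("the 2-fold gate vetoes significant sub-threshold fold-changes", {
  set.seed(35)
  # 20 of 400 genes carry a 1.7-fold shift, measured with 16 replicates:
  # tiny p but |lfc| < 1, so the fold gate must veto the call
  samples <- expand.grid(replicate = 1:16, ct = seq(0, 20, 4),
                         tissue = c("liver", "kidney"),
                         stringsAsFactors = FALSE)
  samples$condition <- "control"
  samples$sample_id <- sprintf("%s_%02d_%d", samples$tissue, samples$ct,
                               samples$replicate)
  n <- 400
  shifted <- 1:20
  mu <- matrix(100, n, nrow(samples))
  mu[shifted, samples$tissue == "liver"] <- 170
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 100), n,
                dimnames = list(sprintf("g%03d", 1:n), samples$sample_id))
  de <- de_per_timepoint(expression_experiment(cnt, samples, "counts"),
                         "liver", "kidney")
  sl <- de$table[de$table$gene_id %in% sprintf("g%03d", shifted), ]
  expect_lt(median(sl$q), 0.01)           # overwhelmingly significant
  expect_true(all(abs(sl$log2_fc) < 1))   # but below the fold gate
  expect_false(any(sl$is_de))
})

test_that("consensus mode only removes calls", {
  sim <- simulate_experiment(sim_config(n_genes = 300, seed = 36))
  d1 <- de_per_timepoint(sim$experiment, "liver", "kidney")
  d2 <- de_per_timepoint(sim$experiment, "liver", "kidney",
                         consensus = TRUE)
  expect_true(all(d2$table$is_de <= d1$table$is_de))
  expect_gt(sum(d2$summary$is_deg), 0)
})

test_that("permutation baselines behave as constructed", {
  # all planted DEGs time-uniform: observed fraction sits inside the null
  cfg <- sim_config(n_genes = 400, frac_tissue_specific = 0.15,
                    frac_temporal = 0, frac_rhythmic = 0,
                    nb_dispersion = 0.05, seed = 37)
  sim <- simulate_experiment(cfg)
  pf <- permutation_all_timepoint_fraction(sim$experiment, "liver",
                                           "kidney", n_perm = 20, seed = 2)
  qs <- quantile(pf$null_fractions, c(0.025, 0.975), na.rm = TRUE)
  expect_gte(pf$observed_fraction, qs[1])
  expect_lte(pf$observed_fraction, qs[2])
  # determinism
  pf2 <- permutation_all_timepoint_fraction(sim$experiment, "liver",
                                            "kidney", n_perm = 20, seed = 2)
  expect_identical(pf$null_fractions, pf2$null_fractions)
  expect_warning(permutation_all_timepoint_fraction(
    sim$experiment, "liver", "kidney", n_perm = 5, seed = 1), "coarse")
})
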