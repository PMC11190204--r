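test_that("the three indices match hand-evaluated formulas exactly", {
  expect_equal(compute_tau(c(1, 0, 0, 0)), 1, tolerance = 1e-12)
  expect_equal(compute_tau(c(3, 3, 3, 3)), 0, tolerance = 1e-12)
  expect_equal(compute_tau(c(8, 4, 2, 2)), (0 + 0.5 + 0.75 + 0.75) / 3,
               tolerance = 1e-12)
  expect_equal(compute_spm(c(1, 0, 0, 0)), c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(compute_spm(c(2, 2, 2, 2)), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(compute_spm(c(3, 4)), c(9 / 25, 16 / 25), tolerance = 1e-12)
  expect_equal(compute_ee(c(5, 5), c(70, 70)), c(1, 1), tolerance = 1e-12)
  expect_equal(compute_ee(c(9, 1), c(100, 100)), c(1.8, 0.2),
               tolerance = 1e-12)
  # doubling one tissue's total halves its EE with x fixed
  e1 <- compute_ee(c(9, 1), c(100, 100))
  e2 <- compute_ee(c(9, 1), c(200, 100))
  expect_equal(e2[1] / e1[1], (300 / 200) / (200 / 100), tolerance = 1e-12)
})

test_that("index invariants hold on random profiles", {
  set.seed(20)
  X <- matrix(rlnorm(200 * 5), 200, 5)
  spm <- compute_spm(X)
  expect_equal(unname(rowSums(spm)), rep(1, 200), tolerance = 1e-9)
  tau <- compute_tau(X)
  expect_true(all(tau >= 0 & tau <= 1))
  # positive rescaling leaves tau and spm unchanged
  expect_equal(compute_tau(X * 7.3), tau, tolerance = 1e-12)
  expect_equal(compute_spm(X * 7.3), spm, tolerance = 1e-12)
  # EE invariant when totals rescale identically
  s <- colSums(X)
  expect_equal(compute_ee(X * 3, s * 3), compute_ee(X, s),
               tolerance = 1e-12)
  # all-zero profile undefined
  X0 <- rbind(X, 0)
  expect_true(is.na(compute_tau(X0)[201]))
  expect_true(all(is.na(compute_spm(X0)[201, ])))
})

test_that("the three indices rank genes concordantly", {
  set.seed(21)
  X <- matrix(rlnorm(500 * 6, sdlog = 1.5), 500, 6)
  tau <- compute_tau(X)
  spm_max <- apply(compute_spm(X), 1, max)
  ee_max <- apply(compute_ee(X, colSums(X)), 1, max)
  expect_gt(cor(tau, spm_max, method = "spearman"), 0.8)
  expect_gt(cor(tau, ee_max, method = "spearman"), 0.8)
  expect_gt(cor(spm_max, ee_max, method = "spearman"), 0.8)
})

make_profile <- function(spm_scores) {
  # one gene per score: expression (x, 1) across 2 tissues chosen so the
  # max SPM equals the requested score (x^2 / (x^2 + 1) = score)
  x1 <- sqrt(spm_scores / (1 - spm_scores))
  vals <- cbind(x1, 1)
  dimnames(vals) <- list(sprintf("g%02d", seq_along(spm_scores)),
                         c("a1", "b1"))
  samples <- data.frame(sample_id = c("a1", "b1"), tissue = c("A", "B"),
                        ct = 0, replicate = 1, condition = "control")
  specificity_profile(expression_experiment(vals, samples, "TPM"))
}

test_that("specific-gene calling respects decile and strict-cutoff rules", {
  scores <- c(0.99, rep(0.6, 9))
  prof <- make_profile(scores)
  top <- call_specific_genes(prof, "spm_top_decile")
  expect_equal(nrow(top), 1)
  expect_equal(top$score, 0.99, tolerance = 1e-9)
  prof2 <- make_profile(c(0.9, 0.8, 0.5))
  kept <- call_specific_genes(prof2, "cutoff", cutoff = 0.8)
  expect_equal(nrow(kept), 1)  # strict >
  expect_equal(kept$score, 0.9, tolerance = 1e-9)
})

test_that("planted tissue-specific genes are recovered (Jaccard >= 0.9)", {
  cfg <- sim_config(n_genes = 1000, frac_tissue_specific = 0.1,
                    frac_temporal = 0, frac_rhythmic = 0,
                    nb_dispersion = 0.01, de_fold = 8, seed = 22)
  sim <- simulate_experiment(cfg)
  tpm <- filter_expressed(counts_to_tpm(sim$experiment, sim$lengths))
  prof <- specificity_profile(tpm)
  called <- call_specific_genes(prof, "spm_top_decile")
  truth_set <- sim$truth$gene_id[!is.na(sim$truth$specific_tissue)]
  truth_set <- intersect(truth_set, prof$gene_id)
  jac <- length(intersect(called$gene_id, truth_set)) /
    length(union(called$gene_id, truth_set))
  expect_gte(jac, 0.9)
  # assigned tissue matches the planted one
  tr <- sim$truth[match(called$gene_id, sim$truth$gene_id), ]
  hit <- !is.na(tr$specific_tissue)
  expect_true(all(called$tissue[hit] == tr$specific_tissue[hit]))
})

test_that("uniform genes have a flat tau series with p = 1", {
  set.seed(23)
  samples <- expand.grid(replicate = 1:2, ct = seq(0, 20, 4),
                         tissue = c("A", "B"), stringsAsFactors = FALSE)
  samples$condition <- "control"
  samples$sample_id <- sprintf("%s_%02d_%d", samples$tissue, samples$ct,
                               samples$replicate)
  m <- matrix(100, 5, nrow(samples),
              dimnames = list(paste0("g", 1:5), samples$sample_id))
  st <- specificity_timecourse(expression_experiment(m, samples, "TPM"))
  expect_true(all(st$series == 0))
  expect_true(all(st$test$p == 1))
})

test_that("tau/spm timepoint series ignore global per-timepoint rescaling", {
  sim <- simulate_experiment(sim_config(n_genes = 80, seed = 24))
  tpm <- counts_to_tpm(sim$experiment, sim$lengths)
  st <- specificity_timecourse(tpm, "tau")
  scaled <- tpm
  set.seed(24)
  fac <- stats::setNames(runif(6, 0.5, 2), sort(unique(tpm$samples$ct)))
  scaled$values <- sweep(scaled$values, 2,
                         fac[as.character(scaled$samples$ct)], "*")
  st2 <- specificity_timecourse(scaled, "tau")
  expect_equal(st2$series, st$series, tolerance = 1e-9)
  sp1 <- specificity_timecourse(tpm, "spm")
  sp2 <- specificity_timecourse(scaled, "spm")
  expect_equal(sp2$series, sp1$series, tolerance = 1e-9)
})

test_that("oscillating specificity of rhythmic tissue-shifted genes is detected", {
  # genes 8x higher and rhythmic in liver: tau tracks the rhythm at 24 h
  set.seed(25)
  tps <- seq(0, 22, 2)
  n <- 120
  phi <- runif(n / 2, 0, 24)
  samples <- expand.grid(replicate = 1:2, ct = tps,
                         tissue = c("liver", "kidney"),
                         stringsAsFactors = FALSE)
  samples$condition <- "control"
  samples$sample_id <- sprintf("%s_%02d_%d", samples$tissue, samples$ct,
                               samples$replicate)
  mu <- matrix(100, n, nrow(samples))
  liver <- samples$tissue == "liver"
  mu[1:(n / 2), liver] <- 800 *
    (1 + 0.5 * cos(2 * pi * outer(phi, samples$ct[liver], "-") / 24))
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 50), n,
                dimnames = list(sprintf("g%03d", 1:n), samples$sample_id))
  ex <- filter_expressed(counts_to_tpm(
    expression_experiment(cnt, samples, "counts"), rep(1000, n)))
  st <- specificity_timecourse(ex, "tau")
  planted <- st$test$gene_id %in% sprintf("g%03d", 1:(n / 2))
  expect_gt(mean(st$test$is_oscillating[planted]), 0.7)
  expect_lt(mean(st$test$is_oscillating[!planted]), 0.2)
  err <- abs(st$test$lag[planted] - phi[match(st$test$gene_id[planted],
                                              sprintf("g%03d", 1:(n / 2)))])
  expect_lt(median(pmin(err, 24 - err)), 2)
})
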