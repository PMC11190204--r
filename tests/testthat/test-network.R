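test_that("vst maps zeros to zero, is monotone, and absorbs depth scaling", {
  set.seed(60)
  m <- matrix(rnbinom(100 * 6, mu = 100, size = 5), 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  m[1, ] <- 0
  v <- vst(m)
  expect_true(all(v[1, ] == 0))
  expect_true(all(v >= 0))
  # monotone within a sample
  o <- order(m[, 2])
  expect_true(all(diff(v[o, 2]) >= 0))
  # doubling every count of one sample is absorbed by its size factor:
  # with the per-gene geometric-mean reference over n samples, that
  # sample's factor rises by exactly 2^(1 - 1/n) and the others fall by
  # 2^(1/n)
  m2 <- m; m2[, 3] <- m2[, 3] * 2
  sf1 <- estimate_size_factors(m); sf2 <- estimate_size_factors(m2)
  expect_equal(unname(sf2[3] / sf1[3]), 2^(1 - 1 / 6), tolerance = 1e-9)
  expect_equal(unname(sf2[-3] / sf1[-3]), rep(2^(-1 / 6), 5),
               tolerance = 1e-9)
  # so the transformed values of the doubled sample shift by far less
  # than the raw doubling (one log2 unit)
  shift <- vst(m2)[-1, 3] - v[-1, 3]
  expect_lt(max(abs(shift)), 0.35)
})

test_that("mad_filter implements the raw-MAD rule", {
  m <- rbind(const = rep(5, 8), alt = rep(c(0, 1), 4),
             wide = c(0, 9, 1, 8, 2, 7, 3, 6))
  colnames(m) <- paste0("s", 1:8)
  kept <- mad_filter(m, threshold = 0.1)
  expect_setequal(rownames(kept), c("alt", "wide"))     # constant dropped
  expect_equal(stats::mad(m["alt", ], constant = 1), 0.5)
  expect_true("alt" %in% rownames(mad_filter(m, 0.4)))  # MAD 0.5 > 0.4
  expect_false("alt" %in% rownames(mad_filter(m, 0.5))) # strict >
  expect_setequal(rownames(mad_filter(m, 0)), c("alt", "wide"))
  expect_error(mad_filter(m["const", , drop = FALSE]), "every gene")
})

test_that("bicor is a correlation with robustness to outliers", {
  set.seed(61)
  x <- rnorm(100)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  # close to Pearson on clean bivariate Gaussian data
  for (i in 1:5) {
    z <- rnorm(500)
    a <- z + rnorm(500); b <- 0.6 * z + rnorm(500, 0, sqrt(1 - 0.36))
    expect_lt(abs(bicor(a, b) - cor(a, b)), 0.05)
  }
  # one gross outlier barely moves bicor, unlike Pearson
  xo <- c(rnorm(50), 100); yo <- c(rnorm(50), 100)
  expect_lt(abs(bicor(xo, yo)), 0.4)
  expect_gt(cor(xo, yo), 0.9)
  # zero-MAD input falls back to Pearson, flagged
  cst <- c(rep(1, 49), 2)
  out <- bicor(cst, rnorm(50))
  expect_identical(attr(out, "fallback"), "pearson")
  expect_error(bicor(1:4, 1:5), "length mismatch")
})

test_that("matrix bicor agrees with the pairwise scalar version", {
  set.seed(62)
  m <- matrix(rnorm(8 * 30), 8, dimnames = list(paste0("g", 1:8), NULL))
  bm <- bicor_matrix_ref <- chronospec:::bicor_matrix(m)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(bm[i, j], as.numeric(bicor(m[i, ], m[j, ])),
                 tolerance = 1e-12)
})

test_that("TOM is a symmetric similarity with unit diagonal in [0,1]", {
  set.seed(63)
  bl <- simulate_coexpression_blocks(c(25, 25), c(0, 12), seed = 4)
  adj <- abs(chronospec:::bicor_matrix(bl$values))^6
  tom <- chronospec:::tom_similarity(adj)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, nrow(tom)))
  expect_equal(tom, t(tom), tolerance = 1e-12)
})

test_that("planted blocks are recovered and labelled order-independently", {
  skip_if_not_installed("mclust")
  bl <- simulate_coexpression_blocks(c(60, 60, 60), c(2, 10, NA), seed = 5)
  ma <- detect_modules(bl$values, softpower = 14, min_module_size = 30)
  expect_gte(mclust::adjustedRandIndex(bl$block, ma$modules), 0.9)
  # permuting gene order changes labels at most
  set.seed(64)
  perm <- sample(nrow(bl$values))
  ma2 <- detect_modules(bl$values[perm, ], softpower = 14,
                        min_module_size = 30)
  expect_gte(mclust::adjustedRandIndex(ma$modules[rownames(bl$values)[perm]],
                                       ma2$modules), 0.999)
  expect_error(detect_modules(bl$values, softpower = 0), "softpower")
})

test_that("the eigengene of a rank-1 block matches the shared profile", {
  set.seed(65)
  prof <- cos(2 * pi * (rep(seq(0, 20, 4), each = 4) - 8) / 24)
  m <- outer(runif(40, 0.5, 2), prof)
  m <- m + matrix(rnorm(length(m), 0, 1e-6), nrow(m))
  dimnames(m) <- list(paste0("g", 1:40), paste0("s", seq_along(prof)))
  ma <- detect_modules(m, softpower = 6, min_module_size = 10,
                       cut_height = 0.9)
  expect_equal(ncol(ma$eigengenes), 1)
  e <- ma$eigengenes[, 1]
  expect_gt(abs(cor(e, prof)), 0.999)
  expect_equal(sum(e^2), 1, tolerance = 1e-9)      # unit norm
  expect_gt(cor(e, ma$mean_expression[, 1]), 0)    # sign orientation
})

test_that("cycling calls separate rhythmic from arrhythmic modules", {
  bl <- simulate_coexpression_blocks(c(60, 60, 60), c(2, 10, NA), seed = 5)
  ma <- detect_modules(bl$values, softpower = 14, min_module_size = 30)
  cyc <- cycling_modules(ma, bl$samples$ct)
  # map modules back to planted blocks via majority labels
  block_of <- vapply(cyc$module, function(mod) {
    as.integer(names(sort(-table(bl$block[ma$modules == mod])))[1])
  }, integer(1))
  expect_true(all(cyc$is_cycling[block_of %in% c(1, 2)]))
  expect_false(any(cyc$is_cycling[block_of == 3]))
  # recovered eigengene phases match the planted block phases
  for (b in 1:2) {
    lag <- cyc$lag_eigengene[block_of == b]
    expect_lte(min(abs(lag - bl$block_phases[b]),
                   24 - abs(lag - bl$block_phases[b])), 2)
  }
})

test_that("cycling modules concentrate planted rhythmic genes (enrichment)", {
  bl <- simulate_coexpression_blocks(c(60, 60, 60), c(2, 10, NA), seed = 6)
  ma <- detect_modules(bl$values, softpower = 14, min_module_size = 30)
  cyc <- cycling_modules(ma, bl$samples$ct)
  planted_rhythmic <- rownames(bl$values)[bl$block != 3]
  modules <- split(names(ma$modules), ma$modules)
  em <- enrich_matrix(modules[cyc$module[cyc$is_cycling]],
                      list(rhythmic = planted_rhythmic),
                      rownames(bl$values))
  expect_true(all(em$odds_ratio > 1))
  expect_true(all(em$q < 0.05))
})
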