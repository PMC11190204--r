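#' Configuration for the multi-tissue circadian count simulator
#'
#' Defines the study design the generator emulates: two tissues sampled
#' every 4 h over one circadian cycle in constant darkness with 4
#' replicates, negative-binomial counts, a rhythmic fraction with 24 h
#' period, tissue-specific baseline shifts, temporal (some-timepoint)
#' fold changes, coding/noncoding biotypes with genomic positions, and
#' clock-TF target labels correlated with rhythmicity.
#'
#' @param n_genes number of genes.
#' @param tissues tissue labels.
#' @param timepoints circadian times in hours, strictly increasing in
#'   `[0, 24)`.
#' @param n_replicates replicates per tissue x timepoint.
#' @param frac_rhythmic fraction of rhythmic genes per tissue (scalar or
#'   one value per tissue); per-tissue rhythmic sets are nested so that
#'   shared rhythmic genes share phase and amplitude.
#' @param frac_tissue_specific fraction of genes with a baseline fold
#'   shift in one tissue (differential at every timepoint).
#' @param frac_temporal fraction of genes with a fold shift in one tissue
#'   at a strict subset of timepoints only.
#' @param de_fold fold factor used for both tissue-specific and temporal
#'   shifts.
#' @param rel_amplitude relative amplitude of rhythmic genes (fraction of
#'   baseline mean, must be `< 1`).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean.
#' @param nb_dispersion negative-binomial dispersion `alpha` in
#'   `var = mu + alpha * mu^2`; 0 gives Poisson counts.
#' @param frac_tf_target_given_rhythmic,frac_tf_target_given_nonrhythmic
#'   probability of carrying a core-clock TF target label given the
#'   gene's rhythmicity (in any tissue).
#' @param lncRNA_fraction fraction of noncoding genes (split among the
#'   lncRNA / antisense / bidirectional biotypes).
#' @param lnc_near_coding_fraction fraction of lncRNAs placed within the
#'   50 kb neighbourhood of a coding partner gene; when both members of
#'   such a pair are rhythmic the lncRNA phase is coupled to the
#'   partner's phase with jitter `phase_coupling_sd`.
#' @param phase_coupling_sd phase jitter (hours) for coupled lncRNAs.
#' @param genome_length,cluster_spacing coordinate placement: gene starts
#'   are spaced `cluster_spacing` bp apart along one chromosome, so
#'   unpaired genes never fall in each other's 50 kb window.
#' @param gene_length gene length in bp (fixed; 1 kb by default so counts
#'   are proportional to TPM up to a per-sample scaling).
#' @param condition condition label for the generated samples.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       tissues = c("liver", "kidney"),
                       timepoints = seq(0, 20, by = 4),
                       n_replicates = 4,
                       frac_rhythmic = 0.2,
                       frac_tissue_specific = 0.1,
                       frac_temporal = 0.1,
                       de_fold = 8,
                       rel_amplitude = 0.5,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       nb_dispersion = 0.1,
                       frac_tf_target_given_rhythmic = 0.5,
                       frac_tf_target_given_nonrhythmic = 0.05,
                       lncRNA_fraction = 0.15,
                       lnc_near_coding_fraction = 0.6,
                       phase_coupling_sd = 1,
                       genome_length = 5e8,
                       cluster_spacing = 2e5,
                       gene_length = 1000,
                       condition = "control",
                       seed = 1) {
  frac_rhythmic <- rep_len(frac_rhythmic, length(tissues))
  names(frac_rhythmic) <- tissues
  fr <- c(frac_rhythmic, frac_tissue_specific, frac_temporal,
          frac_tf_target_given_rhythmic, frac_tf_target_given_nonrhythmic,
          lncRNA_fraction, lnc_near_coding_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (rel_amplitude >= 1) stop("rel_amplitude must be < 1 (mean stays positive)")
  if (rel_amplitude < 0) stop("rel_amplitude must be non-negative")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (is.unsorted(timepoints, strictly = TRUE) || any(timepoints < 0) ||
      any(timepoints >= 24))
    stop("timepoints must be strictly increasing within [0, 24)")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Draw the structural truth (flags, phases, baselines, coordinates) for a
# config. Separated from count sampling so that a control/disrupted pair
# can share everything except amplitudes and noise.
sim_structure <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  tissues <- cfg$tissues

  # nested rhythmic sets across tissues: one random gene order, each
  # tissue takes its leading fraction
  ord <- sample.int(n)
  rhythmic <- sapply(tissues, function(ti)
    seq_len(n) %in% ord[seq_len(round(cfg$frac_rhythmic[ti] * n))])
  rhythmic <- matrix(rhythmic, nrow = n,
                     dimnames = list(gene_id, tissues))
  any_rhythmic <- rowSums(rhythmic) > 0
  phase <- stats::runif(n, 0, 24)
  amp <- ifelse(any_rhythmic, cfg$rel_amplitude, 0)

  # tissue-specific (all-timepoint) and temporal (subset) fold shifts,
  # on disjoint gene sets
  n_spec <- round(cfg$frac_tissue_specific * n)
  n_temp <- round(cfg$frac_temporal * n)
  de_pool <- sample.int(n, n_spec + n_temp)
  spec_idx <- de_pool[seq_len(n_spec)]
  temp_idx <- de_pool[n_spec + seq_len(n_temp)]
  specific_tissue <- rep(NA_character_, n)
  specific_tissue[spec_idx] <- sample(tissues, n_spec, replace = TRUE)
  temporal_tissue <- rep(NA_character_, n)
  temporal_tissue[temp_idx] <- sample(tissues, n_temp, replace = TRUE)
  # temporal fold patterns must not masquerade as 24 h rhythms: when the
  # grid contains antiphase pairs (t, t+12) the subset is a union of such
  # pairs, which has zero first-harmonic content; otherwise fall back to
  # random strict subsets
  ntp <- length(cfg$timepoints)
  pair_lo <- cfg$timepoints[(cfg$timepoints + 12) %in% cfg$timepoints &
                              cfg$timepoints < 12]
  temporal_tps <- vector("list", n)
  for (g in temp_idx) {
    if (length(pair_lo) >= 2L) {
      k <- sample(seq_len(length(pair_lo) - 1L), 1L)
      lo <- sample(pair_lo, k)
      temporal_tps[[g]] <- sort(c(lo, lo + 12))
    } else {
      k <- sample(seq_len(ntp - 1L), 1L)
      temporal_tps[[g]] <- sort(sample(cfg$timepoints, k))
    }
  }

  # TF-target labels correlated with rhythmicity
  p_tf <- ifelse(any_rhythmic, cfg$frac_tf_target_given_rhythmic,
                 cfg$frac_tf_target_given_nonrhythmic)
  is_tf_target <- stats::runif(n) < p_tf

  # biotypes and coordinates; a fraction of lncRNAs sit within 50 kb of a
  # coding partner, with coupled phases when both are rhythmic
  n_nc <- round(cfg$lncRNA_fraction * n)
  biotype <- rep("coding", n)
  nc_idx <- sample.int(n, n_nc)
  biotype[nc_idx] <- sample(c("lncRNA", "antisense", "bidirectional"), n_nc,
                            replace = TRUE, prob = c(0.7, 0.2, 0.1))
  start <- (seq_len(n) - 1L) * cfg$cluster_spacing %% cfg$genome_length
  lnc_idx <- which(biotype == "lncRNA")
  coding_idx <- which(biotype == "coding")
  paired <- sample(lnc_idx, round(cfg$lnc_near_coding_fraction *
                                    length(lnc_idx)))
  partner <- rep(NA_integer_, n)
  if (length(paired)) {
    partner[paired] <- sample(coding_idx, length(paired), replace = TRUE)
    off <- sample(c(-1, 1), length(paired), TRUE) *
      stats::runif(length(paired), 2000, 40000)
    start[paired] <- pmax(0, start[partner[paired]] + round(off))
    couple <- paired[any_rhythmic[paired] & any_rhythmic[partner[paired]]]
    phase[couple] <- (phase[partner[couple]] +
                        stats::rnorm(length(couple), 0,
                                     cfg$phase_coupling_sd)) %% 24
  }

  baseline <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  B <- matrix(baseline, n, length(tissues), dimnames = list(gene_id, tissues))
  for (ti in tissues) {
    sel <- !is.na(specific_tissue) & specific_tissue == ti
    B[sel, ti] <- B[sel, ti] * cfg$de_fold
  }

  list(gene_id = gene_id, rhythmic = rhythmic, phase = phase, amp = amp,
       specific_tissue = specific_tissue, temporal_tissue = temporal_tissue,
       temporal_tps = temporal_tps, is_tf_target = is_tf_target,
       biotype = biotype, start = start, partner = partner, B = B)
}

# Expected count mean for every gene x sample under a structure.
sim_means <- function(cfg, str, samples, amp = NULL) {
  if (is.null(amp)) amp <- str$amp
  n <- cfg$n_genes
  mu <- matrix(0, n, nrow(samples))
  for (s in seq_len(nrow(samples))) {
    ti <- samples$tissue[s]
    ct <- samples$ct[s]
    rhy <- str$rhythmic[, ti]
    m <- str$B[, ti] * (1 + ifelse(rhy, amp, 0) *
                          cos(2 * pi * (ct - str$phase) / 24))
    tmp <- !is.na(str$temporal_tissue) & str$temporal_tissue == ti &
      vapply(str$temporal_tps, function(v) ct %in% v, logical(1))
    m[tmp] <- m[tmp] * cfg$de_fold
    mu[, s] <- m
  }
  dimnames(mu) <- list(str$gene_id, samples$sample_id)
  mu
}

sim_sample_sheet <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      ct = cfg$timepoints, tissue = cfg$tissues,
                      stringsAsFactors = FALSE)
  grid$condition <- cfg$condition
  grid$sample_id <- sprintf("%s_ct%02d_r%d", grid$tissue, grid$ct,
                            grid$replicate)
  grid[, c("sample_id", "tissue", "ct", "replicate", "condition")]
}

sim_draw_counts <- function(cfg, mu, seed) {
  set.seed(seed)
  cnt <- if (cfg$nb_dispersion == 0)
    stats::rpois(length(mu), mu)
  else
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  matrix(cnt, nrow(mu), ncol(mu), dimnames = dimnames(mu))
}

sim_truth_table <- function(cfg, str) {
  any_rhy <- rowSums(str$rhythmic) > 0
  is_deg <- !is.na(str$specific_tissue) | !is.na(str$temporal_tissue)
  cls <- ifelse(!is_deg, "non_deg",
         ifelse(any_rhy | str$is_tf_target, "circadian_affected",
         ifelse(!is.na(str$specific_tissue), "constitutive", "temporal")))
  out <- data.frame(gene_id = str$gene_id, biotype = str$biotype,
                    chrom = "chr1", start = str$start,
                    end = str$start + cfg$gene_length, strand = "+",
                    true_phase = ifelse(any_rhy, str$phase, NA_real_),
                    true_rel_amplitude = str$amp,
                    specific_tissue = str$specific_tissue,
                    temporal_tissue = str$temporal_tissue,
                    temporal_timepoints = vapply(str$temporal_tps,
                      function(v) paste(v, collapse = ","), ""),
                    is_tf_target = str$is_tf_target,
                    partner_gene = ifelse(is.na(str$partner), NA_character_,
                                          str$gene_id[str$partner]),
                    true_class = cls, stringsAsFactors = FALSE)
  for (ti in cfg$tissues)
    out[[paste0("is_rhythmic_", ti)]] <- str$rhythmic[, ti]
  out
}

sim_tf_sets <- function(str) {
  targets <- str$gene_id[str$is_tf_target]
  tfs <- c("BMAL1_targets", "CLOCK_targets", "PER_targets", "CRY_targets")
  assign <- sample(tfs, length(targets), replace = TRUE)
  sets <- split(targets, factor(assign, levels = tfs))
  sets[lengths(sets) > 0]
}

#' Simulate a ground-truthed multi-tissue circadian count experiment
#'
#' Counts are drawn as `NB(mu, alpha)` with
#' `mu = B_(g,tissue) * (1 + A_g * cos(2*pi*(ct - phi_g)/24))`, times a
#' fold factor in the gene's specific tissue (all timepoints) or at a
#' planted subset of timepoints (temporal genes). Deterministic given
#' the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list of class `chronospec_sim` with elements `experiment`
#'   (counts [expression_experiment()]), `truth` (per-gene truth table,
#'   including the planted `true_class`), `annotation` (BED-style
#'   data.frame), `tf_sets` (clock-TF target gene sets), `lengths`
#'   (per-gene lengths) and `config`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  str <- sim_structure(cfg)
  samples <- sim_sample_sheet(cfg)
  mu <- sim_means(cfg, str, samples)
  counts <- sim_draw_counts(cfg, mu, seed = cfg$seed + 1L)
  truth <- sim_truth_table(cfg, str)
  out <- list(experiment = expression_experiment(counts, samples, "counts"),
              truth = truth,
              annotation = truth[, c("gene_id", "biotype", "chrom", "start",
                                     "end", "strand")],
              tf_sets = sim_tf_sets(str),
              lengths = stats::setNames(rep(cfg$gene_length, cfg$n_genes),
                                        str$gene_id),
              config = cfg)
  class(out) <- "chronospec_sim"
  out
}

#' Simulate a control/disrupted experiment pair with scaled amplitudes
#'
#' Both arms share the structural truth (baselines, phases, flags,
#' coordinates); the disrupted arm has the relative amplitude of every
#' gene in a named set multiplied by that set's factor, with phases
#' preserved. Count noise uses one RNG stream per arm keyed by
#' `(seed, arm)`, so the pairing is reproducible.
#'
#' @param cfg a [sim_config()].
#' @param amplitude_factors named numeric vector: amplitude multiplier
#'   per gene set (factors must be `>= 0`; a factor of 1 leaves the arm
#'   differing from control only by sampling noise).
#' @param sets named list of gene-id vectors matching
#'   `names(amplitude_factors)`; if `NULL`, disjoint random sets of
#'   `set_size` genes are planted.
#' @param set_size size of planted sets when `sets` is `NULL`.
#' @param set_pool pool for planted sets: `"rhythmic"` (genes rhythmic in
#'   at least one tissue, the natural choice when the factor should bite;
#'   falls back to all genes if too few) or `"all"` (uniform draw, the
#'   exchangeable construction appropriate for factor-1 null checks).
#' @return list of class `chronospec_sim_pair` with elements `control`,
#'   `disrupted` (both count [expression_experiment()]s with matching
#'   condition labels), `truth`, `sets`, `amplitude_factors`, `lengths`
#'   and `config`.
#' @export
simulate_disruption_pair <- function(cfg, amplitude_factors, sets = NULL,
                                     set_size = 200,
                                     set_pool = c("rhythmic", "all")) {
  set_pool <- match.arg(set_pool)
  stopifnot(inherits(cfg, "sim_config"))
  if (any(amplitude_factors < 0)) stop("amplitude factors must be >= 0")
  if (is.null(names(amplitude_factors)) || anyDuplicated(names(amplitude_factors)))
    stop("amplitude_factors must have unique names")
  str <- sim_structure(cfg)
  if (is.null(sets)) {
    pool <- if (set_pool == "all") str$gene_id else
      str$gene_id[rowSums(str$rhythmic) > 0]
    need <- set_size * length(amplitude_factors)
    if (length(pool) < need) pool <- str$gene_id
    picked <- sample(pool, need)
    sets <- split(picked, rep(names(amplitude_factors), each = set_size))
    sets <- sets[names(amplitude_factors)]
  } else {
    if (!setequal(names(sets), names(amplitude_factors)))
      stop("sets and amplitude_factors must share names")
    unknown <- setdiff(unlist(sets), str$gene_id)
    if (length(unknown)) stop("unknown gene(s) in set map: ",
                              paste(utils::head(unknown, 5), collapse = ", "))
    if (any(table(unlist(sets)) > 1L))
      stop("sets with amplitude factors must be disjoint")
  }
  amp_dis <- str$amp
  for (nm in names(sets)) {
    idx <- match(sets[[nm]], str$gene_id)
    amp_dis[idx] <- amp_dis[idx] * amplitude_factors[[nm]]
  }

  build_arm <- function(amp, arm, label) {
    cfg_arm <- cfg
    cfg_arm$condition <- label
    samples <- sim_sample_sheet(cfg_arm)
    samples$sample_id <- paste0(samples$sample_id, "_", label)
    mu <- sim_means(cfg, str, samples, amp = amp)
    counts <- sim_draw_counts(cfg, mu, seed = cfg$seed + arm)
    expression_experiment(counts, samples, "counts")
  }
  out <- list(control = build_arm(str$amp, 1L, "control"),
              disrupted = build_arm(amp_dis, 2L, "disrupted"),
              truth = sim_truth_table(cfg, str),
              sets = sets, amplitude_factors = amplitude_factors,
              lengths = stats::setNames(rep(cfg$gene_length, cfg$n_genes),
                                        str$gene_id),
              config = cfg)
  class(out) <- "chronospec_sim_pair"
  out
}

#' Simulate a matrix with planted co-expression blocks
#'
#' Each block shares a latent per-sample profile: a 24 h cosine with the
#' block's phase, or (phase `NA`) an arrhythmic shared Gaussian profile.
#' Gene `g` in block `b` is `sqrt(rho) * z_b + sqrt(1 - rho) * noise`,
#' giving within-block correlation `rho` and zero between-block
#' correlation in expectation.
#'
#' @param block_sizes integer vector, genes per block.
#' @param block_phases numeric vector (hours) or `NA` for an arrhythmic
#'   block; one per block.
#' @param timepoints,n_replicates sampling design.
#' @param rho within-block correlation.
#' @param seed RNG seed.
#' @return list with `values` (genes x samples matrix), `block`
#'   (integer label per gene), `samples` (sample sheet) and
#'   `block_phases`.
#' @export
simulate_coexpression_blocks <- function(block_sizes, block_phases,
                                         timepoints = seq(0, 20, 4),
                                         n_replicates = 4, rho = 0.9,
                                         seed = 1) {
  stopifnot(length(block_sizes) == length(block_phases), rho >= 0, rho <= 1)
  set.seed(seed)
  samples <- expand.grid(replicate = seq_len(n_replicates), ct = timepoints,
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("s_ct%02d_r%d", samples$ct, samples$replicate)
  samples$tissue <- "liver"; samples$condition <- "control"
  ns <- nrow(samples)
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  Z <- sapply(block_phases, function(ph) {
    if (is.na(ph)) stats::rnorm(ns)
    else sqrt(2) * cos(2 * pi * (samples$ct - ph) / 24) +
      stats::rnorm(ns, 0, 0.1)
  })
  Z <- scale(Z)  # unit-variance latent profiles
  X <- sqrt(rho) * t(Z[, block, drop = FALSE]) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * ns), n, ns)
  dimnames(X) <- list(sprintf("b%d_g%03d", block, seq_len(n)),
                      samples$sample_id)
  list(values = X, block = block,
       samples = samples[, c("sample_id", "tissue", "ct", "replicate",
                             "condition")],
       block_phases = block_phases)
}

#' Write a simulated experiment to a directory
#'
#' Writes the matrix TSV, sample sheet, truth table, BED6+1 annotation
#' and the planted clock-TF target GMT.
#'
#' @param sim a `chronospec_sim` from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "chronospec_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_experiment(sim$experiment, file.path(dir, "matrix.tsv"),
                   file.path(dir, "samples.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_annotation(sim$annotation, file.path(dir, "annotation.bed"))
  write_gmt(sim$tf_sets, file.path(dir, "tf_targets.gmt"))
  invisible(dir)
}
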