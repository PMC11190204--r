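---
title: "Methods: rhythm detection, tissue specificity, and the DEG trichotomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm detection, tissue specificity, and the DEG trichotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronospec)
```

# Scope and data model

`chronospec` analyses multi-tissue circadian RNA-seq: a gene × sample
matrix (counts or TPM) with a sample sheet giving each sample's tissue,
circadian time (CT, hours in [0, 24)), replicate and condition. The
sheet is the single source of metadata truth; column order never
carries meaning. Counts are converted to TPM with user-supplied
effective lengths, and the analysis universe is the set of genes with
TPM > 0 in every sample (`filter_expressed`); that universe is also the
background of every enrichment test. The strict TPM > 0 rule is the
default; the `cutoff` argument allows stricter definitions, which in
our experience changes the universe size but not the qualitative
behaviour of downstream stages.

# Rhythm detection

## The exact Jonckheere–Terpstra–Kendall null

`jtk_test` scores the concordance (Kendall's S) between a series and a
cosine reference at each candidate peak lag. The reference values at
the sampled CTs contain ties: replicates share a timepoint, and the
cosine takes equal values at symmetric timepoints. Under the
permutation null, the count of concordant cross-group pairs decomposes
into independent Mann–Whitney counts (group *t* against all earlier
groups), so `kendall_S_exact_null` convolves exact Wilcoxon pmfs
(`stats::dwilcox`) to obtain the exact distribution of S. For designs
with more than `exact_limit = 50` observations a normal approximation
with continuity correction is used and flagged; the standard 6 × 4
design (24 observations) is always exact.

Numerical note: reference values are rounded to 9 decimals before tie
grouping *and* pair-sign computation, so analytically tied cosine
values (e.g. cos(±60°)) are treated identically in the statistic and in
its null. Ties in the *data* contribute zero to S and are referred to
the tie-free null — the conventional, slightly conservative choice; the
reported tie-corrected tau-b uses the standard denominator.

## Lags, multiplicity and amplitude

The period is fixed at 24 h; the lag grid steps by half the sampling
interval (2 h on a 4 h grid), giving 12 one-sided tests per gene whose
minimum p is Bonferroni-multiplied by the lag count and capped at 1
(the classic convention for this test family). Because lags 12 h apart
use negated references, this is equivalent to a two-sided scan of six
waveforms. BH adjustment across genes then defines rhythmic genes at
q < 0.05. Two consequences are worth knowing:

- p-values are *discrete and super-uniform*: under a null simulation
  the fraction of raw p < 0.05 sits near 0.02–0.03, not 0.05, because
  the 12 lag statistics are strongly correlated and the Bonferroni
  factor is conservative. The test suite asserts non-anti-conservative
  calibration with a one-sided KS test.
- the minimum attainable p is design-limited. On a 6-point
  single-replicate series the floor is 12 × 1/180 ≈ 0.067, so no
  6-point series can ever reach q < 0.05. Wherever the pipeline tests
  derived series (module eigengenes, specificity timecourses) it
  therefore keeps per-sample resolution when replicates exist: the
  eigengene is tested on its 24 sample scores (replicates enter the
  exact null as reference ties), not on 6 within-timepoint means.

Since the rank statistic carries no scale, amplitude (AMP), peak lag
and mesor are estimated by a least-squares cosinor fit on the input TPM
scale; AMP is half the peak-to-trough of the fitted 24 h component.
JTK p-values are invariant to monotone transforms of the data, so
log-transforming TPM before `rhythm_scan` changes AMP but not the
rhythmic gene set.

# Tissue specificity

Three indices are computed from per-tissue mean TPM (per timepoint for
the timecourse, across all timepoints otherwise): Tau, SPM and EE. Tau
is implemented in its canonical form Σ(1 − x̂ᵢ)/(n − 1). (Printed
versions of this index sometimes carry a Σxᵢ² denominator; that form is
dimensionally inconsistent with a [0, 1] specificity score and is not
what the cited index defines, so the canonical form is used and the
discrepancy is documented here rather than silently matched.) Tau and
SPM are invariant to positive rescaling of a gene's profile; EE is
invariant only when tissue totals rescale identically — the test suite
asserts exactly these invariances.

Tissue-specific genes are called either as the top 10% by max-tissue
SPM (decile ties broken lexicographically by gene id and counted) or by
a strict `> 0.8` cutoff; each call is assigned to the argmax tissue.

`specificity_timecourse` recomputes an index per timepoint and feeds
the per-gene series to the JTK test ("circadian specificity" genes at
BH q < 0.05). One construction detail: a gene rhythmic in one tissue
with *equal* baselines produces a frequency-doubled (12 h) Tau series —
specificity rises whenever the tissues diverge in either direction — and
is invisible to a 24 h test. The biologically meaningful signal, a
tissue-specific gene whose specificity oscillates, corresponds to a
baseline shift plus rhythm in the same tissue, and that is what the
tests plant. Note the design floor above: on a 6-timepoint grid the
index series (one value per timepoint) cannot reach q < 0.05, so this
analysis is informative on denser grids (the tests use a 2 h grid).

# Differential expression and the permutation baseline

The per-timepoint engine is a deliberately simple, fully documented
negative-binomial Wald test: median-of-ratios size factors estimated
once across all samples of both tissues; per-gene dispersion by method
of moments pooled across the two groups and floored at 1e-8; Wald
statistic on the log ratio of group means, referred to a t distribution
on n_A + n_B − 2 degrees of freedom (the t reference compensates for
plug-in dispersion noise; on 4-vs-4 null simulations the raw p < 0.05
fraction sits within the binomial band around 0.05, which the
acceptance suite checks). A gene with zero counts in exactly one group
is moderated with a half-count so its fold-change stays finite; all-zero
genes return p = 1. There is no fold-change shrinkage: the engine
trades a little power for calibration, and the test suite cross-checks
it against an established shrinkage engine, asserting near-identical
fold-changes and (almost) nested significance calls.

Differential calls require BH q < 0.05 within the timepoint *and*
|log2 FC| ≥ 1 ("greater than 2-fold"). An optional consensus mode also
requires BH significance under a companion NB likelihood-ratio engine,
mirroring two-engine intersection designs; and `de_result()` can
assemble a `DEResult` from any external engine's per-timepoint table.

`permutation_all_timepoint_fraction` contrasts the observed fraction of
DEGs significant at all timepoints with a null built by shuffling
timepoint labels. The permutation unit is a genuine design choice: the
default shuffles CT labels within each tissue (preserving the
tissue contrast, destroying time structure); a full-sample shuffle is
available via `scheme = "all_samples"`. The manifest records the choice.

# The DEG trichotomy

`classify_degs` is a pure function of the evidence: circadian-affected
if rhythmic (per-tissue BH q < 0.05, control condition) in either
tissue OR in the union of the supplied clock-TF target sets; else
constitutive if differential at all timepoints; else temporal; non-DEGs
are labelled `non_deg`. The partition property (three disjoint classes
exactly covering the DEG set) is asserted on every run, and removing
the TF collection can only move genes out of the circadian class — a
monotonicity the tests exercise. Class proportions are data outcomes,
not tuned targets: they depend on the planted fractions, the rhythm
test's power and the fold gate.

# Enrichment

`fisher_enrich` computes the two-sided exact hypergeometric p (sum of
all tables with probability ≤ the observed, with the customary 1 + 1e-7
relative tolerance for probability ties) directly from `dhyper`; the
suite verifies equality with `stats::fisher.test` to 1e-12 over
exhaustive margin sweeps. The odds ratio is a·d/(b·c), with a Haldane
0.5 correction applied (and flagged) only when a zero cell occurs. Both
sets are intersected with the expressed-gene background first; BH runs
within each query across its targets.

# Co-expression modules

Counts are transformed by `log2(1 + c/sf)` with median-of-ratios size
factors — the package's variance-stabilising stand-in ahead of network
construction — then filtered at raw MAD > 0.1 (consistency constant 1;
the 1.4826-scaled MAD is available but off by default). Similarity is
the biweight midcorrelation (9-MAD outlier weighting, Pearson fallback
for zero-MAD rows, flagged); adjacency is |bicor|^softpower (unsigned
default, signed available; softpower 14 by default), turned into
topological overlap and clustered by average linkage on TOM
dissimilarity.

The tree is cut *statically* — a deliberate simplification of dynamic
tree cutting that keeps the procedure deterministic — but the cut
height defaults to a scale-adaptive value: the midpoint between the
median and the maximum merge height. A fixed small cut height cannot
work on TOM dissimilarities, because even a block of 0.9-correlated
genes has within-module TOM dissimilarity near 0.8 (TOM similarity is
bounded well below 1 by the network's finite connectivity), so any
fixed cut in the 0.25 range shatters every module. The adaptive default
recovers planted block structure with adjusted Rand ≥ 0.9 in the
acceptance suite; `cut_height` remains settable for users who want a
fixed cut. Clusters below `min_module_size = 30` go to `unassigned`.

Eigengenes are first principal-component score series over samples of
the standardised module submatrix, unit-norm and sign-oriented to
correlate positively with the module mean. Cycling is called when
either the eigengene or the mean-expression series reaches BH q < 0.05
across modules (both reported), tested per sample as explained above.

# Disruption

`amplitude_change` joins two rhythm scans of the same tissue and
reports per-gene Δ = AMP_control − AMP_disrupted and |Δ|; by default all
genes with both amplitudes defined enter (a `rhythmic_only` flag
restricts to q < 0.05 genes, since whether such violin-style contrasts
should include arrhythmic genes is a genuine open choice). Amplitudes
are compared on the TPM scale; `relative = TRUE` uses AMP/mesor.
`compare_sets` runs two-sided Wilcoxon rank-sum tests of |Δ| for each
set against its complement, reporting both median and mean |Δ| per
group (which aggregate is "the" effect size is another open choice, so
both ship); `downsample` equalises group sizes over seeded rounds and
reports the median p.

# The simulator: what it emulates, and what it does not

`simulate_experiment` draws counts c ~ NB(μ, α) with
μ = B_(g,tissue) · (1 + A·cos(2π(ct − φ)/24)), emulating the study
design the pipeline targets: 2 tissues × 6 CTs (every 4 h, constant
darkness) × 4 replicates (2 in the disruption arm of the real design;
`n_replicates` is a config field). Defaults: 20% rhythmic genes per
tissue (nested across tissues, shared phase φ ~ U[0, 24)), relative
amplitude 0.5, log-normal baselines (meanlog = log 100, sdlog = 1 — a
typical expressed-gene TPM spread), NB dispersion 0.1, 10%
tissue-specific genes (8-fold baseline shift in one tissue), 10%
temporal genes (8-fold shift at a strict subset of timepoints), TF
target probability 0.5 given rhythmic vs 0.05 otherwise, 15% noncoding
genes with a fraction of lncRNAs placed within 50 kb of a coding
partner and phase-coupled (sd 1 h) when both are rhythmic. Gene lengths
are fixed at 1 kb so counts are TPM-proportional per sample; the
raised-cosine waveform matches the reference family of the detector
(which, being rank-based, is waveform-agnostic).

Two construction details keep the planted truth internally consistent:

- *Temporal* fold patterns are unions of antiphase timepoint pairs
  (t, t + 12), which carry no 24 h first harmonic. Arbitrary subsets
  (e.g. a contiguous half-cycle bump) are genuinely 24 h-concordant,
  would be correctly called rhythmic, and would make the "temporal"
  truth label contradict its own definition.
- Rhythmic sets are nested across tissues, so by default no gene is
  rhythmic in exactly one tissue with equal baselines — a configuration
  that sits exactly on the 2-fold DE boundary at its trough and makes
  truth labels ambiguous.

`simulate_disruption_pair` shares all structure between arms and scales
only the amplitudes of named sets, with one RNG stream per arm keyed by
(seed, arm). Planted sets default to the rhythmic pool (`set_pool =
"rhythmic"`), where an amplitude factor can bite; for factor-1 *null*
checks the exchangeable construction (`set_pool = "all"`) is the right
one, because amplitude-estimate noise differs between rhythmic and
arrhythmic genes and a rhythmic-only set is not exchangeable with its
complement even when nothing is disrupted.

What the simulator does **not** emulate: batch and library-preparation
effects, gene–gene correlation outside planted blocks, cell-type
mixtures, non-sinusoidal waveforms, phase dispersion between
replicates, length biases (lengths are constant), or read-level noise.
Passing tests therefore demonstrate correctness of the statistics under
a clean NB world, not robustness to every artefact of real RNA-seq.

# Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to estimate each property
stably while staying lightweight: 2,000-gene null simulations for
type-I fractions; 10,000 genes for rhythm sensitivity/FDR (the
sensitivity estimator's Monte-Carlo error is then ~0.008); 1,500 genes
at dispersion 0.01 for classification recovery; 60-gene blocks for
module recovery; 200-gene sets for disruption power, with 100 repeats
of 250-gene simulations for null uniformity; 60 permutations for the
all-timepoint baseline. Exact-null verification enumerates all
permutations for designs up to n = 8 and the tied (2,2,2) design.

Other numerics: BH everywhere via `p.adjust`; dispersion floor 1e-8;
half-count moderation only for one-group-zero genes; cosinor fits via
the normal equations (the 3-column design is tiny and well-conditioned
after the rank check); reference rounding at 9 decimals; lag ties in
`jtk_test` resolved toward the smallest lag index.

# Known limitations

- The JTK p-value is conservative by construction (Bonferroni over
  correlated lags); its null p < 0.05 fraction is ~0.025, not 0.05.
  Power comparisons against likelihood-based rhythm detectors are out
  of scope.
- Single fixed period (24 h); no multi-period scan or detrending.
- The static tree cut has no analogue of dynamic-cut's branch
  sensitivity; very unequal module sizes may merge at the adaptive cut.
- The per-cluster lncRNA–neighbour "correlation between two unpaired
  phase sets" is underdetermined as usually stated; the package reports
  both a nearest-gene pairing correlation and the all-pairs median
  circular phase difference per cluster, plus the across-cluster global
  correlation, and labels them as such rather than presenting any one
  as canonical.
- The NB engine fits a two-group contrast only; multi-factor designs
  and fold-change shrinkage are out of scope (external engines can be
  imported via `de_result`).
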