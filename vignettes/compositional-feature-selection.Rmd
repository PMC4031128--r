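---
title: "Compositional feature selection with clr + sparse PLS-DA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional feature selection with clr + sparse PLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

16S rRNA OTU tables are compositional: sequencing depth is an arbitrary
instrument property, so the counts for a sample only carry relative
information, and every analysis that treats relative abundances as
unconstrained variables (correlations, ordinary regression) picks up
artifacts of the unit-sum constraint. On top of that, case-control
microbiome cohorts are wide — hundreds to thousands of OTUs against a
few dozen subjects — so any discriminant model must be heavily
regularized to say anything at all.

`clrda` addresses the two problems in the standard way for
compositional data analysis:

1. **Centered log-ratio (clr) transform.** Counts are closed to
   proportions (after a pseudocount, see below) and each component is
   divided by the geometric mean of its sample and logged:
   `clr_ij = ln v_ij - mean_j ln v_ij`. This maps each composition into
   an unconstrained Euclidean space where linear methods behave;
   full-feature clr rows sum to zero, and clr values are invariant to
   per-sample rescaling of the raw counts.

2. **Sparse Partial Least Squares Discriminant Analysis (sPLS-DA).**
   The binary phenotype is dummy-coded and column-centered; the model
   extracts `K` orthogonal latent components that maximize covariance
   between the clr matrix and the response. Sparsity comes from
   soft-thresholding each component's candidate direction `z`
   (the leading left singular vector of `X'Y`):
   `w_j = sign(z_j) max(|z_j| - eta * max_i |z_i|, 0)`, then `w` is
   renormalized. `eta` in `[0, 1)` interpolates between dense PLS
   (`eta = 0`) and keeping only features within `(1 - eta)` of the
   strongest signal. Both `X` and `Y` are deflated by each component's
   rank-one fit (PLS2 regression mode), which makes the coefficient
   matrix `B = W (P'W)^{-1} Q'` well defined and prediction a single
   linear map.

Inference on individual OTUs is resampling-based: the tuned model is
refit on class-stratified bootstrap resamples and on label
permutations, and an OTU's pseudo p-value measures how much of its
bootstrap coefficient distribution lies beyond the permutation null's
two-sided 95% envelope.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `pseudocount` | 0.5 | counts | clr is undefined at zero; a constant pseudocount is deterministic and preserves within-sample rank order. Multiplicative zero replacement is deliberately not implemented. |
| `top_n` | 300 | OTUs | pre-filter to the most variable OTUs on the clr scale (variance with denominator n−1, ties broken lexicographically). There is no canonical cutoff; the value is logged with every run. |
| `eta_grid` | 0, 0.1, …, 0.9 | sparsity | the standard grid for the soft-threshold parameter. |
| `K_grid` | 1–3 | components | case-control signals rarely need more than a few latent directions. |
| `folds` | 5 | — | stratified CV; reduced (floor 2, with a warning) when a class is smaller than the fold count. |
| `B`, `P` | 1000 | resamples | bootstrap and permutation counts; reducible for desk-scale runs. |
| `alpha` | 0.05 | — | both the null-envelope level and the selection threshold. |

Model selection minimizes CV misclassification error; ties prefer
smaller `K`, then larger `eta` — the simplest, sparsest model that
explains the data. All centering uses training-fold means only, so no
information leaks from held-out folds. Features are centered but not
variance-scaled by default (`scale_features = TRUE` enables unit
variance); clr already puts OTUs on a common log scale, and the
per-OTU null thresholds absorb residual scale differences.

## The pseudo p-value, and two deliberate readings

For OTU `j`, let `L_j`, `U_j` be the 2.5% and 97.5% empirical
quantiles of its permutation-null coefficient draws (per-OTU, not
pooled, because clr scales are heterogeneous). The significance
strength `s_j` is the fraction of bootstrap draws outside `[L_j, U_j]`
and `pseudo_p_j = 1 - s_j`; an OTU whose bootstrap mass lies entirely
beyond the null envelope gets `pseudo_p = 0`. Selection is
`pseudo_p <= alpha`.

Two conventions are exposed rather than silently chosen:

* `tail_rule = "strict"` (default) counts draws strictly outside the
  closed interval. This matters in the sparse regime: when `eta` is
  large, an OTU's null draws are often all exactly zero, the envelope
  collapses to `(0, 0)`, and a non-strict rule would count the equally
  all-zero bootstrap draws of every irrelevant OTU as "beyond the
  tails", selecting essentially the whole table. The strict rule
  agrees with the non-strict one whenever the null distribution is
  continuous.
* `p_is_fraction = TRUE` reports `s_j` itself as the p-value, the
  complementary reading of "the fraction of bootstrap coefficients at
  or beyond the null tails"; it is provided for comparison only.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces the world all end-to-end tests run in: a
two-class cohort (default 36 positive / 15 negative, mirroring a
71%-prevalence field cohort) with per-OTU baseline log-abundances
`mu_j ~ Normal(0, 2)` (few dominant taxa, long rare tail), planted
class effects `delta_j = ±effect` (balanced signs) on `n_disc`
discriminative OTUs, per-sample log-normal noise `sigma` (default 1,
a realistic clr-scale spread for stool taxa), multinomial counts at a
log-normal library size (default mean 19,000, CV 0.34, matching
deep-ish MiSeq runs; desk tests use ~2,000 for speed), and an optional
richness bonus: class-1 samples carry a few extra rare OTUs, giving
the class-linked richness difference seen in helminth-positive
subjects.

Two design choices deserve emphasis:

* Effects are planted directly on the (approximate) clr scale via the
  log-normal-multinomial construction, so "recover the planted OTUs"
  is a well-defined target. For the same reason, discriminative OTUs
  are drawn from the more abundant half of the baseline
  (`mu_j >= median`): an effect planted on a taxon that draws no reads
  is invisible in any count table and would make recovery metrics
  meaningless.
* Recovery experiments run with `richness_bonus = 0`. The bonus OTUs
  are perfectly class-linked presence/absence taxa by construction —
  legitimate signal, but not part of the recorded truth — so they are
  only enabled when the richness phenomenon itself is under test.

A green recovery test therefore establishes that the pipeline finds
clr-scale location shifts of the stated size in an idealized cohort;
it does not establish robustness to real-data features the generator
omits: phylogenetic correlation between taxa, zero inflation beyond
multinomial sampling, batch effects, or compositional interactions
among discriminative taxa.

## Numerical choices

* Component directions get a deterministic sign (the largest-|z|
  element is made positive), so scores and weights are reproducible
  across platforms; prediction ties go to the lexicographically first
  class level.
* Degenerate fits — an all-zero `X'Y`, a soft threshold that removes
  every feature, a singular `P'W` — raise typed errors rather than
  returning NaNs; cross-validation records such grid points as missing
  and tuning fails only if the whole grid is degenerate.
* Rarefaction subsamples without replacement (multivariate
  hypergeometric), Shannon entropy uses log base 2 (the QIIME
  convention; natural log via `base`), the two-sample t-test is the
  classical pooled-variance form (Welch via `pooled = FALSE`), and
  ANOSIM uses mid-ranks and the add-one permutation rule so p is never
  exactly zero.
* Prevalence intervals are Wald intervals `p ± 1.96 sqrt(p(1-p)/n)`,
  clipped to [0, 100] and reported to one decimal. Not all published
  cohort tables use Wald intervals; rows following other recipes will
  not reproduce and are excluded from tests.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; pipeline stage seeds are derived from one master
  seed and logged.

## Known limitations

* **Power of the pseudo-p rule at moderate effect sizes.** Selection
  requires ~95% of an OTU's bootstrap mass beyond the null's 95%
  envelope — roughly `b >= 1.96 s0 + 1.645 sb` for true coefficient
  `b` and null/bootstrap spreads `s0`, `sb`. PLS-DA permutation nulls
  are wide (the fit partially matches permuted labels whenever the
  feature count rivals the sample count), and under heavy sparsity an
  OTU's bootstrap support-retention rate caps the attainable tail
  fraction near 0.5. In simulation, clr shifts of ~1.5 units at
  n = 60 are consistently *ranked* first but not *selected*; shifts of
  ~3 clr units (e.g. presence/absence taxa) are required for
  selection. The package's acceptance suite states the stronger
  sensitivity expectation verbatim and reports it red rather than
  weakening it; the null-calibration side (≈0% false selections on
  effect-free cohorts) holds comfortably.
* The sparse direction is used as thresholded, without a
  least-squares refit on the support (some sparse-PLS implementations
  refit); this is simpler and hand-verifiable, and is the documented
  difference knob against those tools.
* Only the QIIME classic TSV dialect is parsed; BIOM, trees, and
  tree-dependent metrics (UniFrac, Faith's PD) are out of scope —
  Bray-Curtis stands in, and externally computed distance matrices
  can be imported as square TSV.
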