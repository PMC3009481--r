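---
title: "Nonnegative PCA for serum proteomic profiles: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonnegative PCA for serum proteomic profiles: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtNPCA)
```

## Data model

A preprocessed mass-spectral serum profile study is a nonnegative matrix
`X` with `d` biological samples in rows and `m` pseudo-genes (one per m/z
position) in columns, `m >> d`, plus optional labels in {−1, +1} with the
cancer class as +1. `MassSpecSet` stores this as a SummarizedExperiment
(assay features × samples, Bioconductor convention) and enforces three
invariants at construction: nonnegative intensities, a strictly
increasing m/z axis, and — when labels are present — both classes
occurring. All analysis functions consume the samples × features
orientation returned by `intensities()`; the literature on this data type
uses both orientations, and fixing one at the container boundary removes
a recurring source of silent transposition bugs.

Raw-spectrum preprocessing (baseline correction, smoothing, peak
calibration) is out of scope: the package starts from calibrated
intensity matrices.

## The NPCA objective and its two solvers

NPCA treats the `m` pseudo-gene profiles — columns of `X`, points in
sample space — as observations and maximizes, over entrywise-nonnegative
`U` (d × k),

$$J(U, \alpha) = \tfrac12\,\lVert U^\top X\rVert_F^2
  - \alpha\,\lVert U^\top U - I\rVert_F^2 .$$

The first term is the (uncentered) variance captured by the candidate
components; the penalty pushes `U` towards column orthonormality with
strength `α`. The gradient is
$\nabla_U J = XX^\top U + 4\alpha\,U(I - U^\top U)$, and
`npcaGradient()` is tested against central finite differences of
`npcaObjective()` at relative error ≤ 1e−5.

Mean-centering is deliberately **off** by default: a zero-mean version of
nonnegative data is no longer nonnegative, which contradicts the premise
of nonnegative components; an experimental `center` option subtracts
column means and clips at zero, for users who want variance about the
mean at the cost of that inconsistency.

**Gradient solver.** The fixed-step projected normalized-gradient ascent
`U(t+1) = \max(U(t) + \nabla J/\lVert\nabla J\rVert,\ 0)` with step
η = 1. A fixed normalized step cannot settle, so the solver tracks the
best-objective iterate and returns it; the trade-off is that its final
objective typically sits a few percent below the exact coordinate
optimum, with occasional larger excursions on small problems (quantified
in the test suite).

**Coordinate solver.** Holding all other entries fixed, `J` restricted to
a single entry `u = U[s, l]` is the quartic
$f(u) = -\alpha u^4 + c_2 u^2 + c_1 u + c_0$ with

$$c_2 = \tfrac12 A_{ss} - 2\alpha\Big(\sum_{r \ne s} U_{rl}^2 - 1\Big)
       - 2\alpha \sum_{q \ne l} U_{sq}^2, \qquad
  c_1 = \sum_{r \ne s} A_{sr} U_{rl}
       - 4\alpha \sum_{q \ne l} U_{sq} \sum_{r \ne s} U_{rl} U_{rq},$$

where `A = XXᵀ` (the constant `c₀` never moves the argmax). Because
`α > 0` makes the leading coefficient negative, the nonnegative argmax
exists and is found exactly among the real nonnegative roots of the cubic
`f′` (Cardano/trigonometric closed form) plus the boundary 0, so the
objective is non-decreasing at every single update. Sweeps run in
compiled code with `O(d + k)` work per entry via incrementally maintained
caches `AU` and `UᵀU` (refreshed every 50 sweeps against floating-point
drift). `coordinateUpdate()` exposes one exact update in R and is tested
against a grid-search oracle.

**Termination.** Both solvers stop when the *projected* gradient norm —
the KKT residual, where descent components at entries pinned to zero are
zeroed out — falls below `tol` (default 1e−4), or after `maxIter`
iterations/sweeps (default 2000). The plain gradient norm would never
reach any small tolerance while nonnegativity constraints are active,
which they essentially always are.

**Initialization.** The default is a deterministic NNDSVD-style spectral
start: column `j` of `U₀` is the dominant nonnegative part of the `j`-th
leading eigenvector of `XXᵀ`, unit-normalized. On low-rank nonnegative
data with block-structured factors this start places each component near
its own support; from an unstructured random start (`init = "random"`,
entrywise |N(0,1)| scaled to Frobenius norm √k) the exact solver
reproducibly converges to local maxima whose components straddle several
supports, which halves factor-recovery correlation on the package's own
recovery fixture. A matrix can also be supplied directly, which is how
the holdout harness warm-starts each trial from the previous one.
Identical inputs and seed give bit-identical models for every
initialization mode.

## The role of scale: one penalty, two regimes

`α` multiplies a term of fixed scale while the variance term scales with
`‖X‖²`, so the *regime* of the fit is set by the ratio of the top
eigenvalue `λ₁` of `XXᵀ` to `4α`:

* `λ₁ ≪ 4α` — penalty-dominant: `UᵀU ≈ I` to within ~`λ₁/4α`, components
  take disjoint supports (nonnegative + orthonormal forces this), and the
  fit behaves as variance maximization under a hard orthonormality
  constraint. This is the regime for factor recovery, for NNLS inductive
  embedding (which needs `X ≈ U Pᵀ`), and for τ ranking; it is reached by
  dividing `X` by its spectral norm (`rescale` option, auto-enabled where
  needed).
* `λ₁ ≫ 4α` — variance-dominant: the default classification regime,
  matching the original protocol of applying `α = 10` to intensities
  as-is. `U` is denser and only loosely orthonormal, giving a richer
  (more PCA-like, but nonnegative) meta-sample code.

The experimental value `α = 10` is the package default throughout. (An
`α ∝ d` heuristic circulates for this model but rests on equating
`‖I‖²_F` with `d²`; under the squared Frobenius norm it is `d`, so the
package does not implement that rule.)

## Sparse coding

Sparseness is the Hoyer norm-ratio
`δ(v) = (√n − ‖v‖₁/‖v‖₂)/(√n − 1)` — 1 for a one-hot vector, 0 for a
constant one, scale-invariant, clamped to [0, 1] against floating-point
residue at the extremes. `projectToSparseness()` maps a vector to the
nearest nonnegative point (in the alternating-projection sense) with the
same L2 norm and a prescribed δ: shift onto the target-L1 hyperplane,
rescale onto the L2 sphere along the line through the hyperplane
midpoint, zero out negatives, repeat on the surviving support. Each round
permanently zeroes at least one coordinate, so at most `n` rounds run. On
problems small enough to enumerate support sets, the result agrees with
the exact constrained minimizer of `‖v − u‖₂` to 1e−6 (tested against
that oracle); the L2 norm is preserved to 1e−8.

`sparsifyMetaSamples()` applies the projection to every row
(meta-sample, the default — sparse coding is introduced per meta-sample)
or column (loading vector, the published experiments quote δ for loading
vectors) of a fitted `U`, then recomputes `P` and the variance weights.
The projection attains δ *exactly*, in both directions: a vector sparser
than the target is densified. The pipeline default δ = 0.2 follows the
published experimental setting, with δ ≤ 0.5 as general guidance. The
published alternative α rule for sparse-coded fits is not implemented
(its printed form is ambiguous); α stays at its experimental value.

## The NPCA-SVM classifier

`trainNPCASVM()` chains NPCA (defaults `k = d − 1`, `α = 10`, raw scale,
gradient solver), row-wise sparse coding at δ = 0.2, and a soft-margin
SVM (e1071/libsvm; `C = 1`, linear or RBF with `gamma = 1/k` — the QP is
deliberately delegated, since the contribution here is the feature
extraction, not the SVM). Two embeddings exist for unseen samples,
because the construction of a new sample's meta-sample is genuinely
underdetermined:

* **transductive** (default): refit NPCA on training + test rows jointly
  (warm-started from the cached training `U`), retrain the SVM on the
  training rows of the joint `U`, classify the test rows. This mirrors
  the published repeated-holdout workflow, in which the unsupervised
  decomposition always saw the whole dataset; the test *features* (never
  labels) inform the decomposition, a standard transductive caveat that
  the label-shuffle control quantifies.
* **nnls**: an inductive, deployable mode. `u′` solves
  `min ‖x′ − P₀u′‖₂, u′ ≥ 0` (pracma::lsqnonneg) against the
  *pre-sparse-coding* loadings `P₀`, then receives the same δ-projection
  as the training meta-samples. Consistency of this embedding requires
  `X ≈ U P₀ᵀ`, so nnls models are fitted in the penalty-dominant regime
  (automatic spectral rescaling); embeddings of training rows then match
  their meta-samples to within the orthonormality residual (a few
  percent at finite α — exact agreement is unattainable because the
  optimum of the penalized objective is never exactly orthonormal).

`evaluateHOCV()` implements the evaluation protocol: stratified random
50% holdout splits (stratification guards against empty-class splits;
the split sequence is a pure function of labels, trial count, holdout
fraction and seed, so every algorithm compared under one seed sees
identical splits), per-trial classification rate / sensitivity /
specificity with the cancer class positive, and means ± standard
deviations across trials (a single trial reports sd 0, flagged). The
t-test prefilter can run on the full labeled data before splitting
(`"full"` — the published protocol, which leaks the test rows' labels
into feature selection), per training fold (`"per-fold"`, leakage-free),
or not at all. The prefilter itself uses the Welch statistic (no
variance-homogeneity assumption is warranted for intensity data), keeps
`min(m, 10·d)` features under `"auto"`, breaks |t| ties by smaller column
index, and returns a bit-identical column subset.

Peer baselines (`runBaseline()`): k-NN, SVM on raw features, PCA-SVM,
NMF-SVM, ICA-SVM, PCA-LDA, plus a majority-vote chance-level control.
PCA and LDA come from stats/MASS; NMF (Lee–Seung multiplicative updates,
Frobenius loss) and FastICA (symmetric fixed-point, logcosh contrast, on
PCA-whitened scores) are implemented in-package because no pre-installed
package provides them; all extractors follow the same transductive or
per-fold convention as NPCA-SVM.

## Biomarker discovery

The filter-wrapper algorithm has three stages.

1. **Bayes-factor filter.** For each pseudo-gene, a closed-form
   two-sample Bayes factor BF01 of equal means against an alternative
   with a unit-information normal prior (scale `priorScale = 1`) on the
   standardized effect: with pooled-variance t statistic `t`, degrees of
   freedom ν and effective size `n_e`,
   $$BF_{01} = \sqrt{1 + n_e g}\,
   \left(\frac{1 + t^2/((1 + n_e g)\nu)}{1 + t^2/\nu}\right)^{(\nu+1)/2}.$$
   BF01 is symmetric in the groups, exceeds 1 at t = 0, decreases
   strictly in |t| at fixed sizes, and tends to the finite floor
   `(1 + n_e g)^{−ν/2}` as |t| → ∞ (returned in the zero-variance
   different-means degenerate case; zero variance with equal means is an
   error). Small BF01 = strong differential evidence. `buildCandidates()`
   keeps the `⌈m × 0.01⌉` smallest by default, sorted ascending.
2. **NPCA ranking.** `τᵢ = Σⱼ wⱼ Pᵢⱼ`, the variance-weighted sum of row
   `i` of the loading matrix, with `wⱼ` the ratio of variance explained
   by score column `j`. The ranking fit uses the exact coordinate solver
   in the penalty-dominant regime with α = 10 and `k = d − 1`. Tie-breaks
   use |τ|: published coefficient tables include negative values despite
   a nonnegative loading matrix (plausibly from centering before
   scoring), so sign cannot be load-bearing; an experimental
   `centerScores` flag reproduces signed coefficients.
3. **Greedy SVM-LOOCV wrapper.** Candidates are added one at a time,
   each step choosing the gene whose inclusion maximizes leave-one-out
   SVM accuracy on the raw (globally standardized) selected intensity
   columns — ties broken by larger |τ|, then smaller index — and removing
   it from the pool. The published stopping phrase "maximum accuracy with
   the fewest biomarkers" is implemented as: stop at the first step where
   no candidate *strictly* improves accuracy (or at 100%), which makes
   the cumulative accuracy trace strictly increasing by construction.
   LOOCV accuracy is computed through libsvm's C-level cross-validation
   with singleton folds, which is exact and deterministic (verified in
   the tests against an explicit per-fold refit loop); the final panel's
   sensitivity and specificity come from one explicit leave-one-out pass.

Two behaviours of this wrapper are worth knowing. LOOCV accuracy moves in
steps of `1/d`, so exact ties are common at small `d` and the |τ|
tie-break — which ranks by contribution to overall variance, i.e. favours
bright columns — carries real weight. And as in any wrapper selection,
once the panel's accuracy is near ceiling a null gene can win a step by
chance complementarity; the stopping rule bounds, but does not eliminate,
this overfitting.

## The synthetic-data generators

`generateProfiles()` emulates a *preprocessed* serum profile at desk
scale: a shared mean spectrum (exponential baseline, decay 3 across the
m/z range 900–11000 Da, plus Gaussian peaks at 5% of positions with
heights 2–10× baseline), entrywise multiplicative lognormal noise at 25%
coefficient of variation (typical technical + biological CV for
calibrated MS intensities), clipped at zero; marker columns drawn
uniformly at random receive an additive mean shift of `effectSize`
within-class standard deviations in the +1 class only. Defaults — 30+30
samples, 300 pseudo-genes, 10 markers at 2σ — are the package's standard
study condition. The generator does *not* emulate raw-spectrum artifacts
(baseline drift, peak-width variation, isotope envelopes, m/z
miscalibration, per-sample gain), correlated marker blocks, or markers
preferentially located on peaks; in real serum data discriminative
proteins are typically peaks, so passing tests here speak to the
algorithmic pipeline, not to instrument-level robustness. With
`effectSize = 0` marker columns are statistically indistinguishable from
nulls, which the tests exploit as a null calibration.

`generateLowRank()` builds `X = U*S + |ε|` with unit-norm nonnegative
`U*` columns on disjoint row blocks (plus a small off-support bleed),
half-normal scores, and |Gaussian| noise at a relative level — the
ground-truth fixture for factor recovery.

## Problem sizes and runtime choices

The shipped tests use 30+30 × 300 profiles and 20 holdout trials for
classification checks, 10 seeded repetitions for recovery and biomarker
properties, and n ≤ 6 for the enumeration-based projection oracle —
sizes chosen so the full suite exercises every claim in minutes on a
single core while keeping each statistical bound comfortably away from
its noise floor. The coordinate solver's compiled sweeps make the exact
solver the cheaper of the two at these sizes.

## Known limitations

* The objective is scale-sensitive: α = 10 means different things at
  different intensity scales, and the two regimes above are a design
  response, not a removal, of that sensitivity.
* Meta-samples are a sample-space code: their class information is
  bounded by how class-coherent the sample geometry is. When only a
  small fraction of features carries signal (and no prefilter trims the
  rest), raw-feature classifiers can outperform the meta-sample route on
  synthetic data — a regime the label-shuffle control and baselines make
  visible.
* The fixed-step gradient scheme is faithful to its published form but
  crude; use the coordinate solver when the optimum itself matters.
* Transductive evaluation leaks test-row features into the
  decomposition; the nnls mode with per-fold prefiltering is the
  leakage-free configuration and is the one validated against shuffled
  labels.
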