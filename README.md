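# ProtNPCA

Nonnegative principal component analysis (NPCA) with sparse coding for
mass-spectral serum proteomic profiles: an NPCA-SVM pattern classifier, a
repeated-holdout benchmarking harness against six standard peer
algorithms, and an NPCA-based filter-wrapper biomarker capturing
algorithm.

## The problem

SELDI/MALDI-TOF serum profiling produces, after preprocessing, a
nonnegative intensity matrix `X` (d biological samples × m "pseudo-genes",
one per m/z position, with m ≫ d) and binary diagnostic labels
(−1 control, +1 cancer). Classical PCA reduces such data with a holistic,
signed basis: positive and negative loadings partially cancel, so local
features — exactly the ones that distinguish cancer from control spectra —
are diluted. NPCA restores a purely additive representation by demanding
nonnegative components.

## The model

NPCA treats each pseudo-gene profile (a column of `X`, a point in sample
space ℝᵈ) as an observation and seeks k nonnegative, near-orthonormal
directions `U ∈ ℝ^{d×k}`, `U ≥ 0`, maximizing the penalized variance
objective

    J(U, α) = ½‖UᵀX‖²_F − α‖UᵀU − I‖²_F,      ∇J = XXᵀU + 4αU(I − UᵀU),

where `α ≥ 0` controls the degree of orthonormality. Two solvers are
provided: the fixed-step projected normalized-gradient scheme
`U ← max(U + ∇J/‖∇J‖, 0)` (η = 1, best-objective iterate returned), and an
exact cyclic coordinate solver that maximizes the per-entry quartic
`f(u) = −αu⁴ + c₂u² + c₁u + c₀` in closed form and is monotone by
construction. Convergence is declared when the projected-gradient (KKT)
norm falls below 10⁻⁴.

The decomposition `Xᵀ ≈ P Uᵀ` (with loadings/scores `P = XᵀU`) yields one
**meta-sample** per biological sample — the corresponding row of `U` — which
is sparse-coded to a target Hoyer sparseness
`δ(v) = (√n − ‖v‖₁/‖v‖₂)/(√n − 1)` by the hyperplane–hypersphere
projection, and classified with a soft-margin SVM (linear or RBF kernel).
Biomarker discovery filters candidates by a closed-form two-sample Bayes
factor (BF01, small = differential), ranks pseudo-genes by the
variance-weighted loading coefficient `τᵢ = Σⱼ wⱼ Pᵢⱼ`, and greedily
forward-selects genes under SVM leave-one-out cross-validation with
|τ| tie-breaks.

## Worked example

```r
library(ProtNPCA)

sim <- generateProfiles(syntheticSpec(seed = 42))   # 30+30 samples, 300 pseudo-genes
sim$data
#> MassSpecSet: 60 samples x 300 pseudo-genes
#>   m/z range: [947.8679, 11000]
#>   labels: 30 control (-1), 30 cancer (+1)

report <- evaluateHOCV(sim$data, "npca-svm", nTrials = 20, seed = 42)
report
#> CVReport: npca-svm, 20 trials at 50% holdout (seed 42)
#>   rate          89.67% +/-  4.31
#>   sensitivity   89.33% +/-  8.21
#>   specificity   90.00% +/-  8.52
```

The report aggregates 20 stratified 50% holdout trials: the NPCA-SVM
classifier recovers the planted class structure at ~90% accuracy, with
sensitivity (cancer detection rate) and specificity (control detection
rate) quoted separately. A peer baseline on the identical splits:

```r
cvSummary(runBaseline("knn", sim$data, nTrials = 20, seed = 42))
#>                 mean       sd
#> rate        85.16667 4.520907
#> sensitivity 91.66667 6.069770
#> specificity 78.66667 7.366750
```

Biomarker capture on the same data (the generator planted 10 markers):

```r
cand <- buildCandidates(sim$data, size = 20)   # smallest Bayes factors
bio  <- greedyForwardSelect(sim$data, cand, seed = 42)
bio
#> BiomarkerResult: 3 biomarkers from 20 candidates (linear kernel)
#>  index   mz bayesFactor     tau svmRatio cumAccuracy
#>     11 1317   4.638e-10 0.02180   0.9000       90.00
#>    133 5564   4.463e-09 0.05904   0.8833       96.67
#>    100 4366   5.236e-01 0.02441   0.5500       98.33
#>   final LOOCV accuracy 98.33% (sensitivity 100.00%, specificity 96.67%)
```

The first two captured genes are planted markers; each row reports the
gene's Bayes factor, NPCA ranking coefficient τ, standalone SVM-LOOCV
ratio, and the cumulative panel accuracy after adding it.

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/npca-protpat simulate --out X.csv --seed 7
Rscript inst/scripts/npca-protpat classify --input X.csv --trials 20 \
    --seed 7 --out report.json
Rscript inst/scripts/npca-protpat biomarkers --input X.csv --candidates 20 \
    --seed 7 --out biomarkers.json
```

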