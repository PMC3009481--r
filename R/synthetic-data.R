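#' Specification for synthetic serum-profile generation
#'
#' Bundles the parameters of [generateProfiles()].  The defaults emulate a
#' desk-scale preprocessed SELDI/MALDI-like serum profile study: two
#' balanced groups of 30 samples over 300 pseudo-genes, an exponentially
#' decaying baseline with Gaussian-shaped peaks, multiplicative lognormal
#' intensity noise at 25% coefficient of variation, and 10 planted marker
#' pseudo-genes whose class means differ by 2 within-class standard
#' deviations.
#'
#' @param nPerClass integer pair, samples in the control (-1) and cancer
#'   (+1) class.
#' @param nFeatures number of pseudo-genes (m/z positions).
#' @param nMarkers number of planted class-discriminative pseudo-genes.
#' @param effectSize mean shift of marker columns in the +1 class, in
#'   units of the within-class standard deviation.
#' @param peakDensity fraction of pseudo-genes carrying a spectral peak.
#' @param noiseCv coefficient of variation of the multiplicative lognormal
#'   intensity noise.
#' @param baselineDecay decay rate of the exponential baseline across the
#'   m/z range.
#' @param mzRange numeric pair, the simulated m/z interval in Daltons.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return a `syntheticSpec` list.
#' @export
syntheticSpec <- function(nPerClass = c(30, 30), nFeatures = 300,
                          nMarkers = 10, effectSize = 2,
                          peakDensity = 0.05, noiseCv = 0.25,
                          baselineDecay = 3, mzRange = c(900, 11000),
                          seed = 1) {
  spec <- list(nPerClass = as.integer(nPerClass),
               nFeatures = as.integer(nFeatures),
               nMarkers = as.integer(nMarkers),
               effectSize = effectSize, peakDensity = peakDensity,
               noiseCv = noiseCv, baselineDecay = baselineDecay,
               mzRange = mzRange, seed = as.integer(seed))
  if (length(spec$nPerClass) != 2 || any(spec$nPerClass < 1)) {
    stopValidation("nPerClass must be two positive integers")
  }
  if (spec$nMarkers > spec$nFeatures) {
    stopValidation("nMarkers (", spec$nMarkers,
                   ") cannot exceed nFeatures (", spec$nFeatures, ")")
  }
  if (spec$effectSize < 0) stopValidation("effectSize must be >= 0")
  if (spec$noiseCv < 0) stopValidation("noiseCv must be >= 0")
  class(spec) <- "syntheticSpec"
  spec
}

#' Generate labeled serum-profile-like intensity matrices
#'
#' Simulates a preprocessed mass-spectral serum profile study: every
#' sample shares a mean spectrum made of an exponentially decaying
#' baseline plus Gaussian-shaped peaks at random m/z positions; each
#' intensity is then multiplied by lognormal noise (sd on the log scale
#' chosen so the linear-scale coefficient of variation is `noiseCv`) and
#' clipped at zero.  Marker columns receive an additive
#' `effectSize * sd` shift in the +1 (cancer) class, where `sd` is the
#' empirical within-class standard deviation of the column, so planted
#' markers differ in mean only.
#'
#' @param spec a [syntheticSpec()].
#' @return a list with elements `data` (a labeled [MassSpecSet]) and
#'   `markers` (the ground-truth marker column indices).
#' @examples
#' sim <- generateProfiles(syntheticSpec(nPerClass = c(5, 5),
#'                                       nFeatures = 40, nMarkers = 2,
#'                                       seed = 7))
#' sim$markers
#' @export
generateProfiles <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "syntheticSpec"))
  d <- sum(spec$nPerClass)
  m <- spec$nFeatures
  labels <- rep(c(-1L, 1L), spec$nPerClass)
  withSeed(spec$seed, {
    gaps <- runif(m, 0.5, 1.5)
    mzv <- spec$mzRange[1] +
      cumsum(gaps) / sum(gaps) * diff(spec$mzRange)
    pos <- (mzv - spec$mzRange[1]) / diff(spec$mzRange)
    base <- 10 * exp(-spec$baselineDecay * pos)
    nPeaks <- max(1L, round(spec$peakDensity * m))
    centers <- runif(nPeaks)
    widths <- runif(nPeaks, 0.005, 0.03)
    heights <- runif(nPeaks, 20, 100)
    profile <- base
    for (p in seq_len(nPeaks)) {
      profile <- profile +
        heights[p] * exp(-(pos - centers[p])^2 / (2 * widths[p]^2))
    }
    sdlog <- sqrt(log(1 + spec$noiseCv^2))
    noise <- matrix(exp(rnorm(d * m, -sdlog^2 / 2, sdlog)), d, m)
    values <- sweep(noise, 2, profile, `*`)
    markers <- sort(sample.int(m, spec$nMarkers))
    for (j in markers) {
      shift <- spec$effectSize * sd(values[, j])
      values[labels == 1L, j] <- values[labels == 1L, j] + shift
    }
    values <- pmax(values, 0)
    list(data = MassSpecSet(values, mz = mzv, labels = labels),
         markers = markers)
  })
}

#' Generate low-rank nonnegative matrices with known factors
#'
#' Builds `X = U_true %*% S_true + |E|` where the columns of the d x k
#' matrix `U_true` are unit-norm, nonnegative and have disjoint dominant
#' supports (contiguous blocks of rows, plus a small off-support bleed),
#' `S_true` is a k x m nonnegative score matrix, and `E` is Gaussian noise
#' scaled to `noise` times the mean entry of the noiseless product.  Used
#' as the parameter-recovery fixture for [npcaFit()].
#'
#' @param d rows (meta-sample dimension).
#' @param m columns (pseudo-genes).
#' @param k rank, at most `min(d, m)`.
#' @param noise relative noise level (0 for an exactly rank-k matrix).
#' @param seed RNG seed.
#' @return a list with elements `X`, `U_true` and `S_true`.
#' @export
generateLowRank <- function(d, m, k, noise = 0.05, seed = 1) {
  if (k > min(d, m)) {
    stopValidation("k (", k, ") cannot exceed min(d, m) = ", min(d, m))
  }
  withSeed(seed, {
    blocks <- split(seq_len(d), sort(rep_len(seq_len(k), d)))
    U <- matrix(runif(d * k, 0, 0.02), d, k)
    for (j in seq_len(k)) {
      U[blocks[[j]], j] <- abs(rnorm(length(blocks[[j]]), 1, 0.2))
    }
    U <- sweep(U, 2, sqrt(colSums(U^2)), `/`)
    S <- matrix(abs(rnorm(k * m)), k, m)
    X0 <- U %*% S
    X <- X0 + abs(matrix(rnorm(d * m, 0, noise * mean(X0)), d, m))
    list(X = X, U_true = U, S_true = S)
  })
}
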