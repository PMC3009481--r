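#' Closed-form two-sample Bayes factor for equal means
#'
#' Evidence ratio BF01 of the null hypothesis of equal group means against
#' an alternative in which the standardized mean difference has a
#' unit-information normal prior (scale `priorScale`).  In terms of the
#' pooled two-sample t statistic `t` with `nu = n1 + n2 - 2` degrees of
#' freedom and effective sample size `ne = 1 / (1/n1 + 1/n2)`:
#' \deqn{BF_{01} = \sqrt{1 + n_e g}\,
#'   \left(\frac{1 + t^2 / ((1 + n_e g)\,\nu)}{1 + t^2/\nu}
#'   \right)^{(\nu+1)/2}, \quad g = \text{priorScale}^2.}
#' BF01 is symmetric in the two groups, strictly decreasing in |t| at
#' fixed group sizes, and exceeds 1 at t = 0; small values indicate strong
#' evidence for differential expression.
#'
#' @param groupA,groupB numeric vectors of intensities, each with at least
#'   2 observations.
#' @param priorScale prior standard deviation of the standardized effect
#'   (default 1, a unit-information prior).
#' @return the Bayes factor BF01 (> 0), with the pooled t statistic
#'   attached as attribute `"t"`.
#' @examples
#' set.seed(1)
#' bayesFactor(rnorm(20), rnorm(20))        # > 1: favors the null
#' bayesFactor(rnorm(20), rnorm(20, 3))     # << 1: differential
#' @export
bayesFactor <- function(groupA, groupB, priorScale = 1) {
  n1 <- length(groupA)
  n2 <- length(groupB)
  if (n1 < 2 || n2 < 2) {
    stopValidation("each group needs at least 2 observations (got ",
                   n1, " and ", n2, ")")
  }
  nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(groupA) + (n2 - 1) * var(groupB)) / nu
  diff <- mean(groupA) - mean(groupB)
  if (sp2 == 0) {
    if (diff == 0) {
      stopValidation("zero pooled variance with equal means: ",
                     "Bayes factor is degenerate")
    }
    t <- Inf
  } else {
    t <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  ne <- 1 / (1 / n1 + 1 / n2)
  g <- priorScale^2
  shrink <- 1 + ne * g
  bf <- if (is.infinite(t)) {
    shrink^(-nu / 2)            # limit of the closed form as |t| -> Inf
  } else {
    sqrt(shrink) * ((1 + t^2 / (shrink * nu)) / (1 + t^2 / nu))^((nu + 1) / 2)
  }
  structure(bf, t = t)
}

#' Filter candidate biomarkers by Bayes factor
#'
#' Computes the two-sample Bayes factor BF01 of every pseudo-gene between
#' the cancer (+1) and control (-1) classes and returns the `size`
#' candidates with the smallest BF01 (strongest differential evidence),
#' sorted by ascending BF01.  The default `"auto"` keeps the top 1%,
#' `ceiling(m * 0.01)`.
#'
#' @param x a labeled [MassSpecSet].
#' @param size number of candidates, or `"auto"`.
#' @param priorScale passed to [bayesFactor()].
#' @return a data.frame with one row per candidate: `index` (column index
#'   into `x`), `mz`, `bayesFactor` and `tStatistic`.
#' @export
buildCandidates <- function(x, size = "auto", priorScale = 1) {
  stopifnot(is(x, "MassSpecSet"))
  vals <- intensities(x)
  m <- ncol(vals)
  labels <- .checkLabels(classLabels(x), nrow(vals))
  if (identical(size, "auto")) size <- ceiling(m * 0.01)
  size <- as.integer(size)
  if (size < 1 || size > m) {
    stopValidation("size must be between 1 and m = ", m)
  }
  a <- vals[labels == 1, , drop = FALSE]
  b <- vals[labels == -1, , drop = FALSE]
  res <- vapply(seq_len(m), function(j) {
    bf <- bayesFactor(a[, j], b[, j], priorScale)
    c(bf, attr(bf, "t"))
  }, numeric(2))
  ord <- order(res[1, ], seq_len(m))[seq_len(size)]
  data.frame(index = ord, mz = mz(x)[ord], bayesFactor = res[1, ord],
             tStatistic = res[2, ord], row.names = NULL)
}

#' NPCA ranking coefficients for pseudo-genes
#'
#' Ranks the contribution of each pseudo-gene to the nonnegative PCs: for
#' the decomposition `t(X) ~ P t(U)`, the coefficient of pseudo-gene `i`
#' is the variance-weighted sum of the i-th row of the loading/score
#' matrix, \eqn{\tau_i = \sum_j w_j P_{ij}}, with `w_j` the ratio of
#' variance explained by the j-th PC.
#'
#' @param x the [MassSpecSet] (or matrix) the model was fitted on.
#' @param model a fitted [NPCAModel-class].
#' @param centerScores experimental: compute the scores from the
#'   column-centered matrix before weighting (can produce negative
#'   coefficients).
#' @return numeric vector of m ranking coefficients.
#' @export
npcaRank <- function(x, model, centerScores = FALSE) {
  stopifnot(is(model, "NPCAModel"))
  Xm <- .asIntensity(x)
  if (!all(dim(Xm) == dim(model@X))) {
    stopValidation("x has dimensions ", nrow(Xm), " x ", ncol(Xm),
                   " but the model was fitted on ", nrow(model@X), " x ",
                   ncol(model@X))
  }
  P <- if (centerScores) {
    crossprod(scale(Xm, center = TRUE, scale = FALSE), model@U)
  } else {
    crossprod(Xm, model@U)
  }
  as.vector(P %*% model@w)
}

#' BiomarkerResult: biomarkers captured by the filter-wrapper algorithm
#'
#' @slot selected data.frame, one row per captured biomarker in selection
#'   order: `index`, `mz`, `bayesFactor`, `tau`, `svmRatio` (standalone
#'   LOOCV accuracy fraction) and `cumAccuracy` (cumulative LOOCV accuracy
#'   %, strictly increasing).
#' @slot finalAccuracy,finalSensitivity,finalSpecificity final LOOCV
#'   performance (%) of the selected panel.
#' @slot kernel SVM kernel used inside the wrapper.
#' @slot candidateSetSize size of the initial candidate set.
#' @export
setClass("BiomarkerResult",
  representation(selected = "data.frame", finalAccuracy = "numeric",
                 finalSensitivity = "numeric", finalSpecificity = "numeric",
                 kernel = "character", candidateSetSize = "integer"))

setValidity("BiomarkerResult", function(object) {
  sel <- object@selected
  if (anyDuplicated(sel$index)) return("selected indices must be distinct")
  if (nrow(sel) > 1 && any(diff(sel$cumAccuracy) <= 0)) {
    return("cumulative accuracy must be strictly increasing")
  }
  if (nrow(sel) > 0 &&
      abs(sel$cumAccuracy[nrow(sel)] - object@finalAccuracy) > 1e-9) {
    return("final accuracy must equal the last cumulative accuracy")
  }
  TRUE
})

setMethod("show", "BiomarkerResult", function(object) {
  cat(sprintf("BiomarkerResult: %d biomarkers from %d candidates (%s kernel)\n",
              nrow(object@selected), object@candidateSetSize,
              object@kernel))
  if (nrow(object@selected)) {
    print(format(object@selected, digits = 4), row.names = FALSE)
  }
  cat(sprintf("  final LOOCV accuracy %.2f%% (sensitivity %.2f%%, specificity %.2f%%)\n",
              object@finalAccuracy, object@finalSensitivity,
              object@finalSpecificity))
})

#' Leave-one-out cross-validated SVM accuracy
#'
#' Accuracy (% of correct leave-one-out predictions) of a soft-margin SVM
#' on the given feature columns.  Columns are standardized once before
#' evaluation; the LOOCV loop itself is exact and deterministic.
#'
#' @param X numeric matrix (samples x selected features) or vector.
#' @param y -1/+1 labels, at least 2 samples per class.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C soft-margin cost.
#' @param gamma RBF width, default `1 / ncol(X)`.
#' @param standardize center and scale columns before fitting.
#' @return LOOCV accuracy in percent.
#' @export
loocvAccuracy <- function(X, y, kernel = "linear", C = 1, gamma = NULL,
                          standardize = TRUE) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  kernel <- .checkKernel(kernel)
  y <- .checkLabels(y, nrow(X))
  if (min(table(y)) < 2) {
    stopValidation("each class needs at least 2 samples for LOOCV")
  }
  if (standardize) X <- .scaleCols(X, seq_len(nrow(X)))
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  fit <- e1071::svm(X, factor(y, levels = c(-1, 1)),
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    cost = C, gamma = gamma, scale = FALSE,
                    cross = nrow(X))
  fit$tot.accuracy
}

# Explicit LOOCV predictions (needed for sensitivity/specificity of the
# final panel, where the fold-accuracy ordering of the fast path is
# uninformative).
.loocvPredictions <- function(X, y, kernel, C, gamma) {
  vapply(seq_len(nrow(X)), function(i) {
    fit <- .fitSVM(X[-i, , drop = FALSE], y[-i], kernel, C, gamma)
    as.integer(as.character(predict(fit, X[i, , drop = FALSE])))
  }, integer(1))
}

#' Greedy forward biomarker selection under SVM-LOOCV
#'
#' The wrapper stage of the NPCA-based filter-wrapper algorithm.  Starting
#' from the Bayes-factor candidate set, it repeatedly adds the candidate
#' pseudo-gene whose inclusion gives the highest SVM leave-one-out
#' accuracy on the raw selected intensity columns, removing it from the
#' candidate set; ties at equal accuracy are broken by the larger
#' absolute NPCA ranking coefficient |tau|, then by the smaller column
#' index.  Selection stops when no remaining candidate strictly improves
#' the accuracy, or when accuracy reaches 100%, so the cumulative accuracy
#' trace is strictly increasing.
#'
#' @param x a labeled [MassSpecSet].
#' @param candidates a data.frame from [buildCandidates()], or an integer
#'   vector of candidate column indices.
#' @param tau NPCA ranking coefficients (length m) from [npcaRank()]; if
#'   `NULL`, an NPCA model is fitted on the candidate columns with
#'   `alpha = 10` and its ranks are used.
#' @param kernel,C,gamma SVM parameters inside the wrapper.
#' @param maxBiomarkers optional cap on the panel size.
#' @param seed seed for the internal NPCA fit when `tau` is `NULL`.
#' @return a [BiomarkerResult-class].
#' @examples
#' sim <- generateProfiles(syntheticSpec(nPerClass = c(10, 10),
#'                                       nFeatures = 60, nMarkers = 3,
#'                                       effectSize = 3, seed = 5))
#' cand <- buildCandidates(sim$data, size = 10)
#' res <- greedyForwardSelect(sim$data, cand)
#' res@selected$index
#' @export
greedyForwardSelect <- function(x, candidates, tau = NULL,
                                kernel = "linear", C = 1, gamma = NULL,
                                maxBiomarkers = Inf, seed = 1) {
  stopifnot(is(x, "MassSpecSet"))
  kernel <- .checkKernel(kernel)
  vals <- intensities(x)
  y <- .checkLabels(classLabels(x), nrow(vals))
  if (is.data.frame(candidates)) {
    cand <- as.integer(candidates$index)
    bfLookup <- stats::setNames(candidates$bayesFactor, candidates$index)
  } else {
    cand <- as.integer(candidates)
    bfLookup <- NULL
  }
  if (length(cand) == 0) stopValidation("the candidate set is empty")
  if (any(cand < 1 | cand > ncol(vals))) {
    stopValidation("candidate indices out of range")
  }

  if (is.null(tau)) {
    Xc <- vals[, cand, drop = FALSE]
    sf <- .spectralNorm(Xc)
    model <- npcaFit(Xc / sf, k = nrow(Xc) - 1L, alpha = 10,
                     solver = "coordinate", seed = seed)
    tau <- rep(0, ncol(vals))
    tau[cand] <- npcaRank(Xc / sf, model)
  }
  if (length(tau) != ncol(vals)) {
    stopValidation("tau must have one coefficient per pseudo-gene")
  }

  Z <- .scaleCols(vals, seq_len(nrow(vals)))
  selected <- integer(0)
  accTrace <- numeric(0)
  standalone <- numeric(0)
  bestAcc <- -Inf
  remaining <- cand
  while (length(remaining) > 0 && length(selected) < maxBiomarkers &&
         bestAcc < 100) {
    accs <- vapply(remaining, function(j) {
      loocvAccuracy(Z[, c(selected, j), drop = FALSE], y, kernel, C,
                    gamma, standardize = FALSE)
    }, numeric(1))
    top <- max(accs)
    if (top <= bestAcc) break
    tied <- remaining[accs == top]
    pick <- tied[order(-abs(tau[tied]), tied)][1]
    if (length(selected) == 0) {
      standalone <- stats::setNames(accs, remaining)
    }
    selected <- c(selected, pick)
    accTrace <- c(accTrace, top)
    bestAcc <- top
    remaining <- setdiff(remaining, pick)
  }

  gamma2 <- if (is.null(gamma)) 1 / length(selected) else gamma
  finalPred <- .loocvPredictions(Z[, selected, drop = FALSE], y, kernel,
                                 C, gamma2)
  met <- suppressWarnings(confusionMetrics(y, finalPred))

  selDf <- data.frame(
    index = selected,
    mz = mz(x)[selected],
    bayesFactor = if (is.null(bfLookup)) NA_real_ else
      unname(bfLookup[as.character(selected)]),
    tau = tau[selected],
    svmRatio = vapply(selected, function(j) {
      sa <- standalone[as.character(j)]
      if (length(sa) == 0 || is.na(sa)) {
        sa <- loocvAccuracy(Z[, j, drop = FALSE], y, kernel, C, gamma,
                            standardize = FALSE)
      }
      unname(sa) / 100
    }, numeric(1)),
    cumAccuracy = accTrace)
  new("BiomarkerResult", selected = selDf,
      finalAccuracy = unname(met["rate"]),
      finalSensitivity = unname(met["sensitivity"]),
      finalSpecificity = unname(met["specificity"]),
      kernel = kernel, candidateSetSize = length(cand))
}
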