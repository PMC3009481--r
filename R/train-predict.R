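#' Train an NPCA-SVM proteomic pattern classifier
#'
#' The classification pipeline: (1) fit [npcaFit()] on the raw training
#' intensities, treating pseudo-gene profiles as observations, giving the
#' meta-sample matrix `U` (d x k); (2) sparse-code each meta-sample to
#' sparseness `delta`; (3) train a soft-margin SVM on the meta-samples
#' with the -1/+1 labels.  The orthonormality penalty `alpha = 10` is
#' applied to the intensities as-is, so with typical intensity scales the
#' PC matrix is only weakly pushed towards orthonormality (`rescale`
#' divides the intensities by their spectral norm first, which makes the
#' penalty dominant and the PC matrix near-orthonormal).
#'
#' Defaults follow the serum-profile experiments: `k = d - 1` (since the
#' number of pseudo-genes vastly exceeds the number of samples),
#' `alpha = 10` and `delta = 0.2`.
#'
#' @param x a labeled [MassSpecSet], or a nonnegative samples x features
#'   matrix combined with `labels`.
#' @param labels -1/+1 labels when `x` is a plain matrix.
#' @param k number of NPCA components, or `"auto"` for `d - 1`.
#' @param alpha NPCA orthonormality penalty.
#' @param delta meta-sample sparseness target in \[0, 1\].
#' @param kernel SVM kernel, `"linear"` or `"rbf"`.
#' @param C SVM soft-margin cost.
#' @param gamma RBF kernel width; default `1 / k`.
#' @param seed RNG seed for the NPCA initialization.
#' @param solver NPCA solver passed to [npcaFit()]: the fixed-step
#'   `"gradient"` scheme (default) or the exact `"coordinate"` solver.
#' @param rescale divide intensities by their spectral norm before the
#'   NPCA fit.  Defaults to `FALSE` for transductive models and to `TRUE`
#'   for `"nnls"` models: the inductive embedding solves
#'   `min || x' - P u' ||` against the trained loadings, which is only
#'   consistent with the training meta-samples when `X ~ U t(P)`, i.e.
#'   when the PC matrix is near-orthonormal (penalty-dominant regime).
#' @param projectionMode how unseen samples are embedded at prediction
#'   time: `"transductive"` (joint NPCA refit, mirrors the repeated-
#'   holdout workflow) or `"nnls"` (inductive nonnegative least squares
#'   against the trained loadings; no test data enters the fit).
#' @param npcaInit optional warm-start matrix for the NPCA fit.
#' @return a fitted [SVMPatternModel-class].
#' @examples
#' sim <- generateProfiles(syntheticSpec(nPerClass = c(8, 8),
#'                                       nFeatures = 60, seed = 3))
#' fit <- trainNPCASVM(sim$data, seed = 3)
#' fit
#' @export
trainNPCASVM <- function(x, labels = NULL, k = "auto", alpha = 10,
                         delta = 0.2, kernel = c("linear", "rbf"),
                         C = 1, gamma = NULL, seed = 1,
                         solver = c("gradient", "coordinate"),
                         projectionMode = c("transductive", "nnls"),
                         npcaInit = NULL, rescale = NULL) {
  kernel <- .checkKernel(kernel)
  solver <- match.arg(solver)
  projectionMode <- match.arg(projectionMode)
  Xm <- .asIntensity(x)
  if (is.null(labels)) labels <- .labelsOf(x)
  labels <- .checkLabels(labels, nrow(Xm))
  d <- nrow(Xm)
  if (identical(k, "auto")) k <- d - 1L
  k <- as.integer(k)
  if (k > d) stopValidation("k (", k, ") cannot exceed d = ", d)
  if (is.null(gamma)) gamma <- 1 / k

  if (is.null(rescale)) rescale <- projectionMode == "nnls"
  sf <- if (rescale) .spectralNorm(Xm) else 1
  if (sf <= 0) stopValidation("training intensities are all zero")
  Xs <- Xm / sf
  npca <- npcaFit(Xs, k = k, alpha = alpha, solver = solver,
                  init = if (is.null(npcaInit)) "nndsvd" else npcaInit,
                  seed = seed)
  P0 <- npca@P
  if (delta > 0 && k >= 2) {
    npca <- sparsifyMetaSamples(npca, delta, axis = "rows")
  }
  svmFit <- .fitSVM(npca@U, labels, kernel, C, gamma)
  new("SVMPatternModel", svmFit = svmFit, kernel = kernel, cost = C,
      gamma = gamma, npca = npca, P0 = P0, delta = delta,
      projectionMode = projectionMode, scaleFactor = sf,
      trainLabels = labels, trainX = Xs, seed = as.integer(seed))
}

.checkKernel <- function(kernel) {
  kernel <- kernel[1]
  if (!kernel %in% c("linear", "rbf")) {
    stopValidation("unsupported kernel '", kernel,
                   "'; supported kernels: linear, rbf")
  }
  kernel
}

.fitSVM <- function(features, labels, kernel, C, gamma) {
  e1071::svm(features, factor(labels, levels = c(-1, 1)),
             kernel = if (kernel == "rbf") "radial" else "linear",
             cost = C, gamma = gamma, scale = FALSE)
}

#' Predict class labels for unseen mass-spectral samples
#'
#' Embeds each unseen sample as a meta-sample and applies the trained SVM
#' decision rule.  In `"nnls"` mode the embedding `u'` solves
#' `min || x' - P u' ||_2` subject to `u' >= 0` against the trained
#' loading matrix, then receives the same sparseness coding as the
#' training meta-samples.  In `"transductive"` mode the NPCA decomposition
#' is refit on the training and test rows jointly (warm-started from the
#' cached training `U`), the SVM is retrained on the training rows of the
#' joint `U`, and the test rows are classified.
#'
#' @param object a fitted [SVMPatternModel-class].
#' @param newdata a [MassSpecSet] or samples x features matrix with the
#'   same pseudo-gene columns as the training data.
#' @param mode optionally override the model's projection mode.
#' @return integer vector of -1/+1 labels, one per row of `newdata`.
#' @export
setMethod("predict", "SVMPatternModel", function(object, newdata,
                                                 mode = NULL) {
  Xnew <- .asIntensity(newdata)
  if (nrow(Xnew) == 0) return(integer(0))
  if (ncol(Xnew) != ncol(object@trainX)) {
    stopValidation("newdata has ", ncol(Xnew), " pseudo-gene columns; the ",
                   "model was trained on ", ncol(object@trainX))
  }
  mode <- if (is.null(mode)) object@projectionMode else mode
  Xs <- Xnew / object@scaleFactor
  if (mode == "nnls") {
    P <- object@P0
    Unew <- t(apply(Xs, 1, function(xi) pracma::lsqnonneg(P, xi)$x))
    if (object@delta > 0 && ncol(Unew) >= 2) {
      Unew <- t(apply(Unew, 1, function(u) {
        if (sum(u^2) == 0) u else projectToSparseness(u, object@delta)
      }))
    }
    pred <- predict(object@svmFit, Unew)
  } else {
    d <- nrow(object@trainX)
    k <- object@npca@k
    Xall <- rbind(object@trainX, Xs)
    init <- rbind(object@npca@U,
                  matrix(sqrt(1 / k), nrow(Xs), k))
    joint <- npcaFit(Xall, k = k, alpha = object@npca@alpha,
                     solver = object@npca@solver, init = init,
                     seed = object@seed)
    if (object@delta > 0 && k >= 2) {
      joint <- sparsifyMetaSamples(joint, object@delta, axis = "rows")
    }
    svmFit <- .fitSVM(joint@U[seq_len(d), , drop = FALSE],
                      object@trainLabels, object@kernel, object@cost,
                      object@gamma)
    pred <- predict(svmFit, joint@U[d + seq_len(nrow(Xs)), , drop = FALSE])
  }
  as.integer(as.character(pred))
})

#' Classification rate, sensitivity and specificity
#'
#' Standard confusion-matrix summaries with the cancer class (+1) as
#' positive: rate = 100 (TP + TN) / total, sensitivity = 100 TP / (TP +
#' FN), specificity = 100 TN / (TN + FP).  When a class is absent from
#' `yTrue` the corresponding conditional rate is `NaN` (with a warning).
#'
#' @param yTrue,yPred equal-length vectors of -1/+1 labels.
#' @return named numeric vector `c(rate, sensitivity, specificity)`, in
#'   percent.
#' @examples
#' confusionMetrics(c(1, 1, -1, -1), c(1, -1, -1, -1))
#' @export
confusionMetrics <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) {
    stopValidation("yTrue and yPred have different lengths (",
                   length(yTrue), " vs ", length(yPred), ")")
  }
  if (!all(c(yTrue, yPred) %in% c(-1, 1))) {
    stopValidation("labels must be -1 or +1")
  }
  tp <- sum(yTrue == 1 & yPred == 1)
  fn <- sum(yTrue == 1 & yPred == -1)
  tn <- sum(yTrue == -1 & yPred == -1)
  fp <- sum(yTrue == -1 & yPred == 1)
  if (tp + fn == 0) warning("no positive samples; sensitivity undefined")
  if (tn + fp == 0) warning("no negative samples; specificity undefined")
  c(rate = 100 * (tp + tn) / length(yTrue),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NaN)
}
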