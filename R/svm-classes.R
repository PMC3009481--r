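#' SVMPatternModel: an NPCA-SVM proteomic pattern classifier
#'
#' Couples a fitted, sparse-coded [NPCAModel-class] with a soft-margin SVM
#' trained on its meta-samples (the rows of `U`).  Unseen samples are
#' embedded either transductively (NPCA refit on train + test rows,
#' warm-started from the cached training `U`) or inductively by
#' nonnegative least squares against the trained loading matrix `P`.
#'
#' @slot svmFit the underlying [e1071::svm] fit over meta-samples.
#' @slot kernel `"linear"` or `"rbf"`.
#' @slot cost soft-margin cost (the SVM C parameter).
#' @slot gamma RBF kernel width (ignored for the linear kernel).
#' @slot npca the fitted (sparse-coded) [NPCAModel-class].
#' @slot P0 the loading matrix of the fit before sparse coding; inductive
#'   nnls embeddings are computed against it and then sparse-coded, which
#'   keeps them consistent with the training meta-samples.
#' @slot delta sparseness target applied to the meta-samples.
#' @slot projectionMode `"transductive"` or `"nnls"`.
#' @slot scaleFactor the scalar the training intensities were divided by
#'   before NPCA (the spectral norm of the training matrix).
#' @slot trainLabels the -1/+1 training labels.
#' @slot trainX the scaled training intensity matrix (d x m).
#' @slot seed seed used for the NPCA initialization.
#' @export
setClass("SVMPatternModel",
  representation(svmFit = "ANY", kernel = "character", cost = "numeric",
                 gamma = "numeric", npca = "NPCAModel", P0 = "matrix",
                 delta = "numeric",
                 projectionMode = "character", scaleFactor = "numeric",
                 trainLabels = "integer", trainX = "matrix",
                 seed = "integer"))

setValidity("SVMPatternModel", function(object) {
  if (!object@kernel %in% c("linear", "rbf")) {
    return("kernel must be 'linear' or 'rbf'")
  }
  if (!object@projectionMode %in% c("transductive", "nnls")) {
    return("projectionMode must be 'transductive' or 'nnls'")
  }
  if (!is.null(object@svmFit$coefs) && any(abs(object@svmFit$coefs) < 0)) {
    return("dual coefficients must be finite")
  }
  TRUE
})

setMethod("show", "SVMPatternModel", function(object) {
  cat("SVMPatternModel (NPCA-SVM)\n")
  cat(sprintf("  kernel: %s (C = %g%s), projection: %s\n", object@kernel,
              object@cost,
              if (object@kernel == "rbf")
                sprintf(", gamma = %g", object@gamma) else "",
              object@projectionMode))
  cat(sprintf("  NPCA: k = %d, alpha = %g, sparseness delta = %g\n",
              object@npca@k, object@npca@alpha, object@delta))
  cat(sprintf("  trained on %d samples x %d pseudo-genes\n",
              nrow(object@trainX), ncol(object@trainX)))
})

#' CVReport: repeated-holdout classification performance
#'
#' Per-trial classification rate, sensitivity and specificity (all in
#' percent, positive class = cancer = +1) of one algorithm under repeated
#' stratified holdout cross-validation, together with their means and
#' standard deviations.
#'
#' @slot algorithm algorithm name.
#' @slot perTrial data.frame with columns `rate`, `sensitivity`,
#'   `specificity`, one row per trial.
#' @slot nTrials number of holdout trials.
#' @slot holdoutFraction fraction of samples held out per trial.
#' @slot seed the split-generator seed.
#' @export
setClass("CVReport",
  representation(algorithm = "character", perTrial = "data.frame",
                 nTrials = "integer", holdoutFraction = "numeric",
                 seed = "integer"))

setValidity("CVReport", function(object) {
  pt <- object@perTrial
  if (!all(c("rate", "sensitivity", "specificity") %in% names(pt))) {
    return("perTrial must have rate/sensitivity/specificity columns")
  }
  vals <- unlist(pt[c("rate", "sensitivity", "specificity")])
  vals <- vals[!is.na(vals)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 100)) {
    return("all rates must lie in [0, 100]")
  }
  TRUE
})

#' @describeIn CVReport-class mean and standard deviation of each metric,
#'   recomputed from the per-trial values (sd is 0 by convention for a
#'   single trial).
#' @param object,x a `CVReport`.
#' @export
cvSummary <- function(object) {
  stopifnot(is(object, "CVReport"))
  pt <- object@perTrial
  one <- function(v) {
    c(mean = mean(v, na.rm = TRUE),
      sd = if (length(v) > 1) sd(v, na.rm = TRUE) else 0)
  }
  out <- rbind(rate = one(pt$rate), sensitivity = one(pt$sensitivity),
               specificity = one(pt$specificity))
  as.data.frame(out)
}

setMethod("show", "CVReport", function(object) {
  s <- cvSummary(object)
  cat(sprintf("CVReport: %s, %d trials at %.0f%% holdout (seed %d)\n",
              object@algorithm, object@nTrials,
              100 * object@holdoutFraction, object@seed))
  for (metric in rownames(s)) {
    cat(sprintf("  %-12s %6.2f%% +/- %5.2f\n", metric,
                s[metric, "mean"], s[metric, "sd"]))
  }
  if (object@nTrials == 1) {
    cat("  (single trial: standard deviations are 0 by convention)\n")
  }
})
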