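#' Two-sample t-test prefilter for pseudo-genes
#'
#' Ranks every pseudo-gene by the absolute Welch (unequal-variance)
#' two-sample t statistic between the two classes and keeps the `nKeep`
#' most significant columns.  This is the basic feature-selection step
#' applied to high-dimensional serum profiles before classification; the
#' `"auto"` rule keeps approximately ten features per biological sample,
#' i.e. `min(m, 10 * d)`.
#'
#' Ties in |t| are broken deterministically by the smaller column index.
#' The selected columns keep their original relative order, and the
#' returned indices refer to columns of the input matrix, so the output is
#' a bit-identical column subset of the input.
#'
#' @param x a labeled [MassSpecSet].
#' @param nKeep number of pseudo-genes to keep, or `"auto"` for
#'   `min(m, 10 * d)`.
#' @return a list with elements `data` (the filtered [MassSpecSet]) and
#'   `indices` (integer column indices into the input).
#' @examples
#' sim <- generateProfiles(syntheticSpec(nPerClass = c(10, 10),
#'                                       nFeatures = 50, seed = 1))
#' sel <- ttestPrefilter(sim$data, nKeep = 5)
#' sel$indices
#' @export
ttestPrefilter <- function(x, nKeep = "auto") {
  stopifnot(is(x, "MassSpecSet"))
  vals <- intensities(x)
  d <- nrow(vals)
  m <- ncol(vals)
  labels <- .checkLabels(classLabels(x), d)
  if (identical(nKeep, "auto")) {
    nKeep <- min(m, 10L * d)
  }
  nKeep <- as.integer(nKeep)
  if (nKeep < 1 || nKeep > m) {
    stopValidation("nKeep must be between 1 and the number of pseudo-genes (",
                   m, ")")
  }
  tstat <- welchStatistics(vals, labels)
  ord <- order(-abs(tstat), seq_len(m))
  idx <- sort(ord[seq_len(nKeep)])
  list(data = x[idx, ], indices = idx)
}

# Vectorized Welch t statistics for every column of a samples x features
# matrix; requires >= 2 samples per class.
welchStatistics <- function(vals, labels) {
  a <- vals[labels == 1, , drop = FALSE]
  b <- vals[labels == -1, , drop = FALSE]
  na <- nrow(a)
  nb <- nrow(b)
  if (na < 2 || nb < 2) {
    stopValidation("each class needs at least 2 samples for the t-test ",
                   "(got ", na, " and ", nb, ")")
  }
  ma <- colMeans(a)
  mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  se <- sqrt(va / na + vb / nb)
  t <- (ma - mb) / se
  # a constant feature in both classes carries no class signal
  t[se == 0] <- 0
  t
}
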