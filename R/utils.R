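# Internal helpers shared across the package.

# Validation failures that a command-line front end maps to exit code 2.
stopValidation <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("protnpca_validation", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

.assertMatrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stopValidation(name, " must be a numeric matrix")
  }
  if (any(!is.finite(x))) {
    stopValidation(name, " contains non-finite entries")
  }
  invisible(x)
}

.assertNonnegative <- function(x, name = deparse(substitute(x))) {
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = is.matrix(x))
    if (is.matrix(bad)) {
      stopValidation(name, " has a negative entry at row ", bad[1, 1],
                     ", column ", bad[1, 2])
    }
    stopValidation(name, " has a negative entry at position ", bad[1])
  }
  invisible(x)
}

# Largest singular value of X, used to put intensity matrices on the scale
# where the default orthonormality penalty (alpha = 10) dominates the
# variance term of the NPCA objective.
.spectralNorm <- function(x) {
  if (length(x) == 0) return(0)
  sqrt(max(eigen(tcrossprod(x), symmetric = TRUE, only.values = TRUE)$values, 0))
}

# Extract the samples x features intensity matrix from either a MassSpecSet
# or a plain matrix.
.asIntensity <- function(x) {
  if (is(x, "MassSpecSet")) return(intensities(x))
  .assertMatrix(x, "x")
  x
}

.labelsOf <- function(x) {
  if (is(x, "MassSpecSet")) return(classLabels(x))
  NULL
}

.checkLabels <- function(labels, n) {
  if (is.null(labels)) stopValidation("class labels are required")
  if (length(labels) != n) {
    stopValidation("expected ", n, " labels but got ", length(labels))
  }
  if (!all(labels %in% c(-1, 1))) {
    stopValidation("labels must take values -1 or +1")
  }
  if (length(unique(labels)) < 2) {
    stopValidation("both classes (-1 and +1) must be present")
  }
  as.integer(labels)
}
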