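#' MassSpecSet: labeled nonnegative mass-spectral intensity matrices
#'
#' `MassSpecSet` is a thin extension of
#' [SummarizedExperiment::SummarizedExperiment] holding a preprocessed
#' mass-spectral serum profile: a nonnegative intensity matrix over
#' "pseudo-genes" (one per m/z position) with optional binary class labels
#' (\code{-1} = control, \code{+1} = cancer).  Following Bioconductor
#' convention the assay is stored features x samples; the user-facing
#' accessor [intensities()] returns the transposed samples x features
#' matrix, which is the orientation used by all analysis functions in this
#' package.
#'
#' Validity requires all intensities to be nonnegative, the m/z axis to be
#' strictly increasing, and -- when labels are present -- both classes to
#' occur at least once.
#'
#' @param values numeric matrix, samples in rows and pseudo-genes in
#'   columns; all entries must be nonnegative.
#' @param mz numeric vector of strictly increasing positive m/z values, one
#'   per column of `values`.
#' @param labels optional integer/numeric vector of class labels in
#'   \{-1, +1\}, one per sample.
#' @param featureIds optional character identifiers per pseudo-gene;
#'   defaults to `"mz_<value>"`.
#' @param object a `MassSpecSet`.
#'
#' @return `MassSpecSet()` returns a validated `MassSpecSet`.
#'   `intensities()` returns the samples x features matrix, `mz()` the m/z
#'   axis, `classLabels()` the label vector (or `NULL`), and `featureIds()`
#'   the per-column identifiers.
#'
#' @examples
#' x <- MassSpecSet(matrix(abs(rnorm(12)), 3, 4),
#'                  mz = c(900, 950, 1000, 1100),
#'                  labels = c(-1, 1, 1))
#' dim(intensities(x))
#' mz(x)
#' @aliases MassSpecSet intensities mz classLabels featureIds
#' @export
MassSpecSet <- function(values, mz, labels = NULL, featureIds = NULL) {
  .assertMatrix(values, "values")
  if (length(mz) != ncol(values)) {
    stopValidation("length of mz (", length(mz), ") must equal the number ",
                   "of pseudo-gene columns (", ncol(values), ")")
  }
  if (is.null(featureIds)) {
    featureIds <- paste0("mz_", format(mz, trim = TRUE, digits = 10))
  }
  rowdat <- S4Vectors::DataFrame(mz = as.numeric(mz),
                                 feature_id = as.character(featureIds))
  coldat <- if (is.null(labels)) {
    S4Vectors::make_zero_col_DFrame(nrow(values))
  } else {
    S4Vectors::DataFrame(label = as.integer(labels))
  }
  assay <- t(values)
  dimnames(assay) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = assay), rowData = rowdat, colData = coldat)
  new("MassSpecSet", se)
}

#' @export
setClass("MassSpecSet", contains = "SummarizedExperiment")

setValidity("MassSpecSet", function(object) {
  a <- SummarizedExperiment::assay(object, "intensity")
  if (!is.numeric(a)) return("intensity assay must be numeric")
  if (any(!is.finite(a))) return("intensity assay contains non-finite values")
  if (any(a < 0)) {
    bad <- which(a < 0, arr.ind = TRUE)[1, ]
    # assay is features x samples; report in the user's samples x features
    # orientation
    return(sprintf("negative intensity at sample %d, pseudo-gene %d",
                   bad[2], bad[1]))
  }
  m <- SummarizedExperiment::rowData(object)$mz
  if (is.null(m)) return("rowData must contain an 'mz' column")
  if (any(m <= 0)) return("m/z values must be positive")
  if (length(m) > 1 && any(diff(m) <= 0)) {
    return(sprintf("m/z axis must be strictly increasing (violated at index %d)",
                   which(diff(m) <= 0)[1] + 1L))
  }
  lab <- SummarizedExperiment::colData(object)$label
  if (!is.null(lab)) {
    if (!all(lab %in% c(-1L, 1L))) return("labels must be -1 or +1")
    if (length(unique(lab)) < 2) return("both classes must occur at least once")
  }
  TRUE
})

#' @rdname MassSpecSet
#' @export
setMethod("intensities", "MassSpecSet", function(object) {
  t(SummarizedExperiment::assay(object, "intensity"))
})

#' @rdname MassSpecSet
#' @export
setMethod("mz", "MassSpecSet", function(object) {
  as.numeric(SummarizedExperiment::rowData(object)$mz)
})

#' @rdname MassSpecSet
#' @export
setMethod("classLabels", "MassSpecSet", function(object) {
  lab <- SummarizedExperiment::colData(object)$label
  if (is.null(lab)) NULL else as.integer(lab)
})

#' @rdname MassSpecSet
#' @export
setMethod("featureIds", "MassSpecSet", function(object) {
  as.character(SummarizedExperiment::rowData(object)$feature_id)
})

setMethod("show", "MassSpecSet", function(object) {
  lab <- classLabels(object)
  cat("MassSpecSet:", ncol(object), "samples x", nrow(object),
      "pseudo-genes\n")
  cat("  m/z range: [", min(mz(object)), ", ", max(mz(object)), "]\n",
      sep = "")
  if (is.null(lab)) {
    cat("  unlabeled\n")
  } else {
    cat("  labels: ", sum(lab == -1), " control (-1), ", sum(lab == 1),
        " cancer (+1)\n", sep = "")
  }
})
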