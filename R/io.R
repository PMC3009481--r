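#' Read and write labeled intensity matrices as delimited text
#'
#' The on-disk format is one header row of m/z values followed by one row
#' per biological sample.  Class labels may be supplied either as a
#' reserved first column named `label` (values -1/+1) or as a separate
#' single-column file passed through `labelsPath`.  Files are UTF-8 with
#' '.' as the decimal separator.
#'
#' @param path path to the delimited intensity file.
#' @param delimiter field separator, default `","` (use `"\t"` for TSV).
#' @param labelsPath optional path to a single-column file of -1/+1 labels,
#'   one per sample, overriding any `label` column in `path`.
#' @return a validated [MassSpecSet].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' x <- MassSpecSet(matrix(1:6 / 2, 2, 3), mz = c(900.1, 950.2, 1000.3),
#'                  labels = c(-1, 1))
#' writeIntensityMatrix(x, f)
#' y <- readIntensityMatrix(f)
#' all.equal(intensities(x), intensities(y), check.attributes = FALSE)
#' @export
readIntensityMatrix <- function(path, delimiter = ",", labelsPath = NULL) {
  if (!file.exists(path)) stopValidation("file not found: ", path)
  df <- tryCatch(
    read.table(path, sep = delimiter, header = TRUE, check.names = FALSE,
               colClasses = "numeric", fill = FALSE),
    error = function(e) stopValidation("parse error in ", path, ": ",
                                       conditionMessage(e)))
  labels <- NULL
  if (names(df)[1] == "label") {
    labels <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  if (!is.null(labelsPath)) {
    if (!file.exists(labelsPath)) {
      stopValidation("labels file not found: ", labelsPath)
    }
    labels <- scan(labelsPath, what = numeric(), quiet = TRUE)
  }
  mzvals <- suppressWarnings(as.numeric(names(df)))
  if (any(is.na(mzvals))) {
    stopValidation("header row must contain numeric m/z values; offending ",
                   "entry: '", names(df)[which(is.na(mzvals))[1]], "'")
  }
  values <- as.matrix(df)
  dimnames(values) <- NULL
  if (!is.null(labels) && length(labels) != nrow(values)) {
    stopValidation("labels length (", length(labels),
                   ") does not match the number of samples (",
                   nrow(values), ")")
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stopValidation("negative intensity at sample ", neg[1, 1],
                   ", pseudo-gene ", neg[1, 2], " in ", path)
  }
  tryCatch(MassSpecSet(values, mz = mzvals, labels = labels),
           error = function(e) stopValidation(conditionMessage(e)))
}

#' @param x a [MassSpecSet] to write.
#' @param writeLabels if `TRUE` (default) and `x` carries labels, a leading
#'   `label` column is written.
#' @rdname readIntensityMatrix
#' @export
writeIntensityMatrix <- function(x, path, delimiter = ",",
                                 writeLabels = TRUE) {
  stopifnot(is(x, "MassSpecSet"))
  vals <- intensities(x)
  df <- as.data.frame(vals)
  names(df) <- format(mz(x), trim = TRUE, digits = 10)
  lab <- classLabels(x)
  if (writeLabels && !is.null(lab)) {
    df <- cbind(label = lab, df)
  }
  write.table(df, path, sep = delimiter, row.names = FALSE, quote = FALSE)
  invisible(path)
}
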