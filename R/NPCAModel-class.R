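#' NPCAModel: a fitted nonnegative principal component decomposition
#'
#' Holds the result of [npcaFit()]: the nonnegative PC matrix `U` (d x k,
#' rows are meta-samples, columns are nonnegative PCs), the per-pseudo-gene
#' loading/score matrix `P = t(X) %*% U` (m x k), the orthonormality
#' penalty `alpha`, convergence diagnostics, and the variance-explained
#' weights `w` (one per component, summing to 1).
#'
#' @slot U d x k nonnegative PC matrix.
#' @slot P m x k loading/score matrix.
#' @slot X the d x m training matrix the model was fitted on.
#' @slot alpha nonnegative orthonormality penalty.
#' @slot k number of components.
#' @slot solver `"gradient"` or `"coordinate"`.
#' @slot converged `TRUE` if the gradient-norm threshold was reached.
#' @slot n_iter iterations (gradient steps or coordinate sweeps) performed.
#' @slot objective_trace objective value at the initial point and after
#'   each iteration (length `n_iter + 1`).
#' @slot grad_norm_final Frobenius norm of the objective gradient at the
#'   returned `U`.
#' @slot w variance-explained ratios of the k score columns.
#' @slot seed the RNG seed used for initialization.
#'
#' @param object an `NPCAModel`.
#' @return `metaSamples()` returns `U`, `loadings()` returns `P`, and
#'   `varianceWeights()` returns `w`.
#' @aliases metaSamples loadings varianceWeights
#' @export
setClass("NPCAModel",
  representation(U = "matrix", P = "matrix", X = "matrix",
                 alpha = "numeric", k = "integer", solver = "character",
                 converged = "logical", n_iter = "integer",
                 objective_trace = "numeric", grad_norm_final = "numeric",
                 w = "numeric", seed = "integer"))

setValidity("NPCAModel", function(object) {
  if (any(object@U < 0)) return("U must be entrywise nonnegative")
  if (ncol(object@P) != object@k) return("P must have exactly k columns")
  if (nrow(object@P) != ncol(object@X)) {
    return("P must have one row per pseudo-gene")
  }
  if (length(object@w)) {
    if (any(object@w < 0)) return("variance weights must be nonnegative")
    if (abs(sum(object@w) - 1) > 1e-9) {
      return("variance weights must sum to 1")
    }
  }
  if (length(object@objective_trace) != object@n_iter + 1L) {
    return("objective_trace must have length n_iter + 1")
  }
  TRUE
})

#' @rdname NPCAModel-class
#' @export
setMethod("metaSamples", "NPCAModel", function(object) object@U)

#' @rdname NPCAModel-class
#' @export
setMethod("loadings", "NPCAModel", function(object) object@P)

#' @rdname NPCAModel-class
#' @export
setMethod("varianceWeights", "NPCAModel", function(object) object@w)

setMethod("show", "NPCAModel", function(object) {
  cat("NPCAModel: k =", object@k, "components over",
      nrow(object@U), "meta-samples x", nrow(object@P), "pseudo-genes\n")
  cat(sprintf("  solver: %s, alpha = %g, %s after %d iterations (|grad| = %.3g)\n",
              object@solver, object@alpha,
              if (object@converged) "converged" else "best iterate returned",
              object@n_iter, object@grad_norm_final))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@w), collapse = ", "), "\n")
})

#' Serialize or restore a fitted NPCA model
#'
#' Models are written as a single versioned JSON document containing `U`,
#' `P`, `X`, penalty, seed and the convergence metadata, so that fitted
#' decompositions can be archived and reloaded without rerunning the
#' optimizer.
#'
#' @param model an [NPCAModel-class] object.
#' @param path output (or input) file path.
#' @return `readNPCAModel()` returns the restored [NPCAModel-class].
#' @export
saveNPCAModel <- function(model, path) {
  stopifnot(is(model, "NPCAModel"))
  payload <- list(
    format = "ProtNPCA/NPCAModel", version = 1L,
    d = nrow(model@U), m = nrow(model@P), k = model@k,
    alpha = model@alpha, solver = model@solver, seed = model@seed,
    converged = model@converged, n_iter = model@n_iter,
    grad_norm_final = model@grad_norm_final, w = model@w,
    objective_trace = model@objective_trace,
    U = as.vector(model@U), P = as.vector(model@P), X = as.vector(model@X))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveNPCAModel
#' @export
readNPCAModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ProtNPCA/NPCAModel")) {
    stopValidation(path, " is not a serialized NPCA model")
  }
  new("NPCAModel",
      U = matrix(p$U, p$d, p$k), P = matrix(p$P, p$m, p$k),
      X = matrix(p$X, p$d, p$m), alpha = p$alpha, k = as.integer(p$k),
      solver = p$solver, converged = p$converged,
      n_iter = as.integer(p$n_iter), objective_trace = p$objective_trace,
      grad_norm_final = p$grad_norm_final, w = p$w,
      seed = as.integer(p$seed))
}
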