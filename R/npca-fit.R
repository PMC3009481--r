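#' Penalized variance objective of nonnegative PCA
#'
#' The NPCA objective treats the columns of `X` (one per pseudo-gene, each
#' a point in sample space) as observations and seeks nonnegative,
#' near-orthonormal directions `U` of maximal variance:
#' \deqn{J(U, \alpha) = \tfrac12 \|U^T X\|_F^2 - \alpha \|U^T U - I\|_F^2.}
#' The penalty `alpha >= 0` controls how strictly the PC matrix is pushed
#' towards orthonormality (`t(U) %*% U ~ I`).
#'
#' @param U d x k nonnegative matrix (columns are candidate PCs).
#' @param X d x m data matrix.
#' @param alpha nonnegative orthonormality penalty.
#' @return the scalar objective value.
#' @seealso [npcaGradient()], [npcaFit()]
#' @export
npcaObjective <- function(U, X, alpha) {
  .assertMatrix(U, "U")
  .assertMatrix(X, "X")
  if (nrow(U) != nrow(X)) {
    stopValidation("U and X must have the same number of rows (got ",
                   nrow(U), " and ", nrow(X), ")")
  }
  if (length(alpha) != 1 || !is.finite(alpha) || alpha < 0) {
    stopValidation("alpha must be a single nonnegative number")
  }
  G <- crossprod(U)
  0.5 * sum(crossprod(U, X)^2) - alpha * sum((G - diag(ncol(U)))^2)
}

#' Analytic gradient of the NPCA objective
#'
#' Returns the gradient of [npcaObjective()] with respect to `U`, in `U`'s
#' d x k layout:
#' \deqn{\nabla_U J = X X^T U + 4\alpha\, U (I - U^T U).}
#'
#' @inheritParams npcaObjective
#' @return a d x k matrix, the gradient at `U`.
#' @export
npcaGradient <- function(U, X, alpha) {
  .assertMatrix(U, "U")
  .assertMatrix(X, "X")
  if (nrow(U) != nrow(X)) {
    stopValidation("U and X must have the same number of rows (got ",
                   nrow(U), " and ", nrow(X), ")")
  }
  X %*% crossprod(X, U) + 4 * alpha * U %*% (diag(ncol(U)) - crossprod(U))
}

# Objective/gradient in terms of the cached d x d Gram matrix A = X X'.
.objectiveFromGram <- function(U, A, alpha) {
  G <- crossprod(U)
  0.5 * sum(U * (A %*% U)) - alpha * sum((G - diag(ncol(U)))^2)
}

.gradientFromGram <- function(U, A, alpha) {
  A %*% U + 4 * alpha * U %*% (diag(ncol(U)) - crossprod(U))
}

# Spectral (NNDSVD-style) initialization: column j starts from the
# dominant nonnegative part of the j-th leading eigenvector of the Gram
# matrix, normalized to unit length.  Deterministic.
.nndsvdInit <- function(A, k) {
  e <- eigen(A, symmetric = TRUE)
  U0 <- matrix(0, nrow(A), k)
  for (j in seq_len(k)) {
    v <- e$vectors[, j]
    vp <- pmax(v, 0)
    vn <- pmax(-v, 0)
    u <- if (sum(vp^2) >= sum(vn^2)) vp else vn
    nu <- sqrt(sum(u^2))
    U0[, j] <- if (nu > 0) u / nu else 1 / sqrt(nrow(A))
  }
  U0
}

# KKT residual under U >= 0: at entries sitting on the boundary, a
# negative (descent) gradient component is feasible and does not count.
.projGradNorm <- function(U, A, alpha) {
  G <- .gradientFromGram(U, A, alpha)
  G[U == 0 & G < 0] <- 0
  sqrt(sum(G^2))
}

#' Fit a nonnegative principal component decomposition
#'
#' Maximizes the penalized variance objective [npcaObjective()] under the
#' entrywise constraint `U >= 0`, using one of two solvers:
#'
#' * `"gradient"`: projected normalized-gradient ascent with the fixed
#'   step \eqn{\eta(t) = 1},
#'   `U(t+1) = max(U(t) + grad / ||grad||, 0)`, stopping when the norm of
#'   the projected gradient (the KKT residual under `U >= 0`: descent
#'   components at entries clipped to zero do not count) drops to `tol`.
#'   A fixed normalized step is not monotone, so the returned `U` is the
#'   best-objective iterate seen, not necessarily the last.
#' * `"coordinate"`: cyclic exact coordinate maximization.  For each entry
#'   `u[s, l]` the objective restricted to that entry is the quartic
#'   \eqn{f(u) = -\alpha u^4 + c_2 u^2 + c_1 u + c_0} whose nonnegative
#'   argmax is found exactly from the roots of its cubic derivative; the
#'   objective is therefore non-decreasing at every single update.  This
#'   requires `alpha > 0` (otherwise the per-entry problem is unbounded).
#'
#' @param X a [MassSpecSet] or a nonnegative d x m matrix (rows = samples).
#' @param k number of components, `1 <= k <= d`.
#' @param alpha nonnegative orthonormality penalty (default 10, the value
#'   used throughout the classification experiments).
#' @param solver `"gradient"` (default) or `"coordinate"`.
#' @param init initialization: `"nndsvd"` (default) seeds each column
#'   with the dominant nonnegative part of the corresponding leading
#'   eigenvector of `X %*% t(X)` (deterministic, and in practice far less
#'   prone to local maxima with mixed supports); `"random"` draws entries
#'   as |N(0,1)| scaled so that `norm(U0, "F") == sqrt(k)`; or a d x k
#'   nonnegative matrix (e.g. a cached `U` from a previous fit used as a
#'   warm start).
#' @param maxIter maximum gradient steps / coordinate sweeps (default 2000).
#' @param tol termination threshold on the gradient Frobenius norm
#'   (default `1e-4`).
#' @param seed RNG seed for the initialization; identical inputs and seed
#'   give a bit-identical model.
#' @param center experimental: subtract column means and clip at zero
#'   before fitting.  Off by default because centering conflicts with the
#'   nonnegativity of both the data and the PCs.
#' @return an [NPCAModel-class] object.
#' @examples
#' lr <- generateLowRank(d = 8, m = 20, k = 2, noise = 0.02, seed = 1)
#' fit <- npcaFit(lr$X / max(svd(lr$X)$d), k = 2, alpha = 10,
#'                solver = "coordinate", seed = 1)
#' varianceWeights(fit)
#' @export
npcaFit <- function(X, k, alpha = 10,
                    solver = c("gradient", "coordinate"),
                    init = "nndsvd", maxIter = 2000, tol = 1e-4, seed = 1,
                    center = FALSE) {
  solver <- match.arg(solver)
  Xm <- .asIntensity(X)
  if (center) {
    Xm <- pmax(scale(Xm, center = TRUE, scale = FALSE), 0)
    attr(Xm, "scaled:center") <- NULL
  }
  .assertNonnegative(Xm, "X")
  d <- nrow(Xm)
  k <- as.integer(k)
  if (k < 1 || k > d) {
    stopValidation("k must satisfy 1 <= k <= d = ", d)
  }
  if (alpha < 0 || (solver == "coordinate" && alpha == 0)) {
    stopValidation("alpha must be ", if (solver == "coordinate")
      "strictly positive for the coordinate solver" else "nonnegative")
  }
  seed <- as.integer(seed)
  A <- tcrossprod(Xm)
  if (is.null(init)) init <- "nndsvd"
  if (is.character(init)) {
    U0 <- switch(match.arg(init, c("nndsvd", "random")),
      nndsvd = .nndsvdInit(A, k),
      random = {
        R <- withSeed(seed, matrix(abs(rnorm(d * k)), d, k))
        R * sqrt(k) / sqrt(sum(R^2))
      })
  } else {
    .assertMatrix(init, "init")
    if (!all(dim(init) == c(d, k))) {
      stopValidation("init must be a ", d, " x ", k, " matrix")
    }
    U0 <- pmax(init, 0)
  }

  if (solver == "gradient") {
    res <- .fitGradient(U0, A, alpha, maxIter, tol)
  } else {
    res <- .fitCoordinate(U0, A, alpha, maxIter, tol)
  }

  U <- res$U
  P <- crossprod(Xm, U)
  vars <- apply(P, 2, var)
  w <- if (sum(vars) > 0) vars / sum(vars) else rep(NA_real_, k)
  new("NPCAModel", U = U, P = P, X = Xm, alpha = alpha, k = k,
      solver = solver, converged = res$converged,
      n_iter = as.integer(res$n_iter),
      objective_trace = res$trace,
      grad_norm_final = .projGradNorm(U, A, alpha),
      w = w, seed = seed)
}

.fitGradient <- function(U, A, alpha, maxIter, tol) {
  obj <- .objectiveFromGram(U, A, alpha)
  trace <- numeric(maxIter + 1)
  trace[1] <- obj
  bestU <- U
  bestObj <- obj
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(maxIter)) {
    G <- .gradientFromGram(U, A, alpha)
    G[U == 0 & G < 0] <- 0
    gn <- sqrt(sum(G^2))
    if (gn <= tol) {
      converged <- TRUE
      break
    }
    U <- pmax(U + G / gn, 0)
    obj <- .objectiveFromGram(U, A, alpha)
    iter <- t
    trace[t + 1] <- obj
    if (obj > bestObj) {
      bestObj <- obj
      bestU <- U
    }
  }
  list(U = bestU, converged = converged, n_iter = iter,
       trace = trace[seq_len(iter + 1)])
}

.fitCoordinate <- function(U, A, alpha, maxIter, tol) {
  res <- coord_descent_cpp(U, A, alpha, as.integer(maxIter), tol)
  list(U = res$U, converged = res$converged, n_iter = res$n_sweeps,
       trace = as.numeric(res$trace))
}

#' Exact single-entry update of the coordinate NPCA solver
#'
#' With every other entry of `U` held fixed, the NPCA objective restricted
#' to the single entry `u = U[s, l]` is the quartic
#' \eqn{f(u) = -\alpha u^4 + c_2 u^2 + c_1 u + c_0} with
#' \deqn{c_2 = \tfrac12 A_{ss} - 2\alpha\big(\sum_{r \ne s} U_{rl}^2 - 1\big)
#'       - 2\alpha \sum_{q \ne l} U_{sq}^2,}
#' \deqn{c_1 = \sum_{r \ne s} A_{sr} U_{rl}
#'       - 4\alpha \sum_{q \ne l} U_{sq} \sum_{r \ne s} U_{rl} U_{rq},}
#' where \eqn{A = X X^T} (the constant \eqn{c_0} never affects the argmax).
#' The returned value is the exact maximizer of `f` over `u >= 0`, found
#' among the nonnegative real roots of the cubic `f'` and the boundary 0.
#' Substituting it can never decrease [npcaObjective()].
#'
#' @inheritParams npcaObjective
#' @param s row index of the entry to update.
#' @param l column index of the entry to update.
#' @return the new (nonnegative) value of `U[s, l]`.
#' @export
coordinateUpdate <- function(U, X, alpha, s, l) {
  .assertMatrix(U, "U")
  .assertMatrix(X, "X")
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    stopValidation("alpha must be strictly positive")
  }
  s <- as.integer(s); l <- as.integer(l)
  if (s < 1 || s > nrow(U) || l < 1 || l > ncol(U)) {
    stopValidation("entry index (", s, ", ", l, ") out of range")
  }
  A <- tcrossprod(X)
  u0 <- U[s, l]
  coll <- U[, l]
  c_ll <- sum(coll^2) - u0^2                 # sum_{r != s} U_rl^2
  rowq <- U[s, ]
  bq <- as.vector(crossprod(U, coll)) - u0 * rowq  # sum_{r != s} U_rl U_rq
  m1 <- sum(A[s, ] * coll) - A[s, s] * u0
  c2 <- A[s, s] / 2 - 2 * alpha * (c_ll - 1) -
    2 * alpha * (sum(rowq^2) - u0^2)
  c1 <- m1 - 4 * alpha * (sum(rowq * bq) - u0 * bq[l])
  .argmaxQuartic(alpha, c2, c1)
}

# argmax over u >= 0 of f(u) = -alpha u^4 + c2 u^2 + c1 u
.argmaxQuartic <- function(alpha, c2, c1) {
  f <- function(u) -alpha * u^4 + c2 * u^2 + c1 * u
  # f'(u) = -4 alpha u^3 + 2 c2 u + c1
  roots <- polyroot(c(c1, 2 * c2, 0, -4 * alpha))
  cand <- Re(roots)[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))]
  cand <- unique(c(0, cand[cand > 0]))
  cand[which.max(f(cand))]
}

#' Variance-explained ratios of the NPCA score columns
#'
#' Computes, for each component `j`, the ratio of the sample variance of
#' score column `j` (column `j` of `P = t(X) %*% U`) to the total variance
#' over all score columns.  These weights sum to 1 and are the weights of
#' the NPCA ranking coefficient used in biomarker discovery.
#'
#' @param model a fitted [NPCAModel-class].
#' @param X optionally, the matrix the model was fitted on (defaults to
#'   the stored training matrix).
#' @return numeric vector of k nonnegative ratios summing to 1.
#' @export
varianceExplained <- function(model, X = NULL) {
  stopifnot(is(model, "NPCAModel"))
  Xm <- if (is.null(X)) model@X else .asIntensity(X)
  if (nrow(Xm) != nrow(model@U)) {
    stopValidation("X has ", nrow(Xm), " rows but the model was fitted on ",
                   nrow(model@U))
  }
  P <- crossprod(Xm, model@U)
  vars <- apply(P, 2, var)
  if (sum(vars) <= 0) {
    stopValidation("all score columns are constant; variance ratios undefined")
  }
  vars / sum(vars)
}
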