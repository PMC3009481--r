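#' Hoyer sparseness of a nonnegative vector
#'
#' The sparseness of a nonnegative vector `v` of length `n >= 2` is the
#' norm-ratio measure
#' \deqn{\delta(v) = \frac{\sqrt{n} - \|v\|_1 / \|v\|_2}{\sqrt{n} - 1},}
#' a scale-invariant value in \[0, 1\]: 1 when exactly one entry is
#' positive, 0 when all entries are equal.
#'
#' @param v nonnegative, nonzero numeric vector of length at least 2.
#' @return the sparseness, a real number in \[0, 1\].
#' @examples
#' sparseness(c(0, 0, 7, 0))   # 1
#' sparseness(rep(2, 5))       # 0
#' sparseness(c(3, 4, 0, 0))   # 0.6
#' @export
sparseness <- function(v) {
  n <- length(v)
  if (n < 2) stopValidation("sparseness needs a vector of length >= 2")
  if (any(!is.finite(v))) stopValidation("v contains non-finite entries")
  .assertNonnegative(v, "v")
  l2 <- sqrt(sum(v^2))
  if (l2 == 0) stopValidation("sparseness is undefined for the zero vector")
  # clamp away floating-point residue at the exact extremes
  min(max((sqrt(n) - sum(v) / l2) / (sqrt(n) - 1), 0), 1)
}

#' L1 norm attaining a target sparseness at a given L2 norm
#'
#' Inverts the sparseness measure: a nonnegative vector of length `n` with
#' L2 norm `l2` has sparseness `delta` exactly when its L1 norm equals
#' `l2 * (sqrt(n) - delta * (sqrt(n) - 1))`.
#'
#' @param l2 positive L2 norm.
#' @param n vector length, at least 2.
#' @param delta target sparseness in \[0, 1\].
#' @return the corresponding L1 norm.
#' @export
targetL1 <- function(l2, n, delta) {
  if (l2 <= 0) stopValidation("l2 must be positive")
  if (n < 2) stopValidation("n must be at least 2")
  if (delta < 0 || delta > 1) stopValidation("delta must lie in [0, 1]")
  l2 * (sqrt(n) - delta * (sqrt(n) - 1))
}

#' Project a nonnegative vector to a target sparseness
#'
#' Finds a nonnegative vector with the same L2 norm as `u` whose
#' sparseness is exactly `delta`, i.e. the nonnegative intersection of the
#' L1 hyperplane `sum(v) = L1(delta)` with the L2 hypersphere
#' `||v|| = ||u||` closest to `u`.  Uses Hoyer's alternating projection:
#' shift onto the hyperplane, rescale onto the sphere along the line
#' through the hyperplane midpoint, zero out negative entries, and repeat
#' on the remaining support.  Each round fixes at least one entry at zero,
#' so the loop terminates in at most `length(u)` rounds.
#'
#' @param u nonnegative, nonzero numeric vector.
#' @param delta target sparseness in \[0, 1\].
#' @return a nonnegative vector `v` with `||v||_2 == ||u||_2` (to 1e-8)
#'   and `sparseness(v) == delta` (to 1e-6).
#' @examples
#' v <- projectToSparseness(c(1, 2, 3, 4), 0.5)
#' sparseness(v)
#' sqrt(sum(v^2)) - sqrt(sum(c(1, 2, 3, 4)^2))
#' @export
projectToSparseness <- function(u, delta) {
  n <- length(u)
  if (n < 2) stopValidation("u must have length >= 2")
  .assertNonnegative(u, "u")
  l2 <- sqrt(sum(u^2))
  if (l2 == 0) stopValidation("cannot project the zero vector")
  if (delta < 0 || delta > 1) stopValidation("delta must lie in [0, 1]")
  l1 <- targetL1(l2, n, delta)

  zero <- rep(FALSE, n)
  s <- u + (l1 - sum(u)) / n
  for (round in seq_len(n + 1)) {
    free <- !zero
    nf <- sum(free)
    if (nf == 1) {
      # single free coordinate: it must carry the whole mass
      s[free] <- l2
      break
    }
    mid <- ifelse(zero, 0, l1 / nf)
    w <- s - mid
    # largest a with || mid + a w ||_2 = l2
    aa <- sum(w^2)
    bb <- 2 * sum(mid * w)
    cc <- sum(mid^2) - l2^2
    disc <- bb^2 - 4 * aa * cc
    if (disc < 0) disc <- 0
    a <- if (aa > 0) (-bb + sqrt(disc)) / (2 * aa) else 0
    s <- mid + a * w
    if (all(s >= -1e-12)) {
      s[s < 0] <- 0
      break
    }
    if (round > n) {
      stopValidation("sparseness projection failed to converge after ", n,
                     " rounds (delta = ", delta, ", n = ", n, ")")
    }
    zero <- zero | (s < 0)
    s[zero] <- 0
    free <- !zero
    s[free] <- s[free] + (l1 - sum(s)) / sum(free)
  }
  s
}

#' Sparse-code the meta-samples or loading vectors of a fitted NPCA model
#'
#' Replaces every row (meta-sample) or column (loading vector / PC) of the
#' model's `U` matrix by its projection to sparseness `delta`, preserving
#' nonnegativity and each vector's L2 norm, and recomputes the score
#' matrix `P = t(X) %*% U` and the variance-explained weights.  Zero rows
#' or columns cannot be projected and are skipped with a warning.
#'
#' @param model a fitted [NPCAModel-class].
#' @param delta target sparseness in \[0, 1\] (the classification pipeline
#'   default is 0.20).
#' @param axis `"rows"` (meta-samples, the default) or `"columns"`
#'   (loading vectors).
#' @return a new [NPCAModel-class] with the sparse-coded `U`.
#' @export
sparsifyMetaSamples <- function(model, delta, axis = c("rows", "columns")) {
  stopifnot(is(model, "NPCAModel"))
  axis <- match.arg(axis)
  U <- model@U
  if (axis == "rows") {
    for (i in seq_len(nrow(U))) {
      if (sum(U[i, ]^2) == 0) {
        warning("meta-sample row ", i, " is zero; skipped")
        next
      }
      U[i, ] <- projectToSparseness(U[i, ], delta)
    }
  } else {
    for (j in seq_len(ncol(U))) {
      if (sum(U[, j]^2) == 0) {
        warning("loading column ", j, " is zero; skipped")
        next
      }
      U[, j] <- projectToSparseness(U[, j], delta)
    }
  }
  P <- crossprod(model@X, U)
  vars <- apply(P, 2, var)
  w <- if (sum(vars) > 0) vars / sum(vars) else model@w
  methods::initialize(model, U = U, P = P, w = w)
}
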