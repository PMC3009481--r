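# Independent oracles and small fixture builders shared across tests.

# Greedy matching of recovered factor columns to true columns by absolute
# correlation; returns the mean matched |correlation|.
matchedColumnCorrelation <- function(U, Utrue) {
  k <- ncol(Utrue)
  C <- abs(cor(U, Utrue))
  tot <- 0
  for (i in seq_len(k)) {
    w <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
    tot <- tot + C[w[1], w[2]]
    C[w[1], ] <- NA
    C[, w[2]] <- NA
  }
  tot / k
}

# Exact projection oracle: minimizer of ||v - u||_2 subject to
# sum(v) = L1(delta), ||v||_2 = ||u||_2, v >= 0, by enumerating support
# sets (KKT stationarity on a support gives v = a*u + b).  Exponential in
# length(u); intended for n <= 6.
oracleSparsenessProjection <- function(u, delta) {
  n <- length(u)
  L2 <- sqrt(sum(u^2))
  L1 <- targetL1(L2, n, delta)
  best <- NULL
  bestd <- Inf
  for (mask in 1:(2^n - 1)) {
    A <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    uA <- u[A]
    nA <- length(A)
    if (nA == 1) {
      if (abs(L1 - L2) < 1e-9) {
        v <- rep(0, n)
        v[A] <- L2
        d <- sum((v - u)^2)
        if (d < bestd) {
          bestd <- d
          best <- v
        }
      }
      next
    }
    Su <- sum(uA)
    lhs <- sum(uA^2) - Su^2 / nA
    rhs <- L2^2 - L1^2 / nA
    if (lhs <= 1e-14 || rhs < 0) next
    for (a in c(sqrt(rhs / lhs), -sqrt(rhs / lhs))) {
      b <- (L1 - a * Su) / nA
      vA <- a * uA + b
      if (all(vA >= -1e-10)) {
        v <- rep(0, n)
        v[A] <- pmax(vA, 0)
        d <- sum((v - u)^2)
        if (d < bestd) {
          bestd <- d
          best <- v
        }
      }
    }
  }
  best
}

# Central finite differences of the NPCA objective.
finiteDifferenceGradient <- function(U, X, alpha, h = 1e-6) {
  G <- matrix(0, nrow(U), ncol(U))
  for (i in seq_len(nrow(U))) {
    for (j in seq_len(ncol(U))) {
      Up <- U; Up[i, j] <- U[i, j] + h
      Um <- U; Um[i, j] <- U[i, j] - h
      G[i, j] <- (npcaObjective(Up, X, alpha) -
                    npcaObjective(Um, X, alpha)) / (2 * h)
    }
  }
  G
}

# Two well-separated classes embedded as planted peaks: both classes share
# a peaky base profile, the +1 class has `nShift` columns (half the
# features by default, so the class signal dominates the sample geometry)
# shifted by `sigma` within-class standard deviations.
makeSeparableProfiles <- function(d = 40, m = 200, nShift = round(m / 2),
                                  sigma = 4, seed = 1) {
  generateProfiles(syntheticSpec(nPerClass = c(d / 2, d / 2),
                                 nFeatures = m, nMarkers = nShift,
                                 effectSize = sigma, seed = seed))
}

# Exhaustive manual leave-one-out with an explicit per-fold SVM refit,
# the slow independent route against the pooled fast path.
explicitLoocvAccuracy <- function(X, y, kernel = "linear", C = 1) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  correct <- vapply(seq_len(nrow(X)), function(i) {
    fit <- e1071::svm(X[-i, , drop = FALSE],
                      factor(y[-i], levels = c(-1, 1)),
                      kernel = kernel, cost = C, scale = FALSE)
    pred <- as.integer(as.character(predict(fit, X[i, , drop = FALSE])))
    pred == y[i]
  }, logical(1))
  100 * mean(correct)
}
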