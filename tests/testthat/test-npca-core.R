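test_that("the objective matches hand computations", {
  # orthonormal U, UtX = (1, 0): J = 0.5, penalty exactly zero
  U <- matrix(c(1, 0), 2, 1)
  X <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(npcaObjective(U, X, 0), 0.5)
  expect_equal(npcaObjective(U, X, 7), 0.5)
  # zero U: only the -alpha * ||-I||^2 term survives
  expect_equal(npcaObjective(matrix(0, 3, 1), matrix(1:6 / 2, 3, 2), 10),
               -10)
  # independent direct evaluation of the two Frobenius terms
  set.seed(21)
  U <- matrix(abs(rnorm(6)), 3, 2)
  X <- matrix(abs(rnorm(12)), 3, 4)
  direct <- 0.5 * sum((t(U) %*% X)^2) -
    2 * sum((t(U) %*% U - diag(2))^2)
  expect_equal(npcaObjective(U, X, 2), direct)
  expect_error(npcaObjective(U, matrix(1, 4, 4), 2), "same number of rows")
})

test_that("the analytic gradient agrees with finite differences", {
  # degenerate cases first
  U <- diag(3)[, 1:2]
  expect_equal(npcaGradient(U, matrix(0, 3, 5), 4), matrix(0, 3, 2))
  set.seed(22)
  X <- matrix(abs(rnorm(30)), 6, 5)
  U <- matrix(abs(rnorm(18)), 6, 3)
  expect_equal(npcaGradient(U, X, 0), X %*% crossprod(X, U))
  for (alpha in c(0, 1, 10)) {
    G <- npcaGradient(U, X, alpha)
    Gfd <- finiteDifferenceGradient(U, X, alpha)
    expect_lt(max(abs(G - Gfd)) / max(abs(G)), 1e-5)
  }
})

test_that("npcaFit is deterministic and respects its contracts", {
  lr <- generateLowRank(8, 20, 2, 0.05, seed = 3)
  X <- lr$X / max(svd(lr$X)$d)
  for (solver in c("gradient", "coordinate")) {
    f1 <- npcaFit(X, 2, 10, solver, init = "random", seed = 7)
    f2 <- npcaFit(X, 2, 10, solver, init = "random", seed = 7)
    expect_identical(f1@U, f2@U)
    expect_true(all(f1@U >= 0))
    expect_length(f1@objective_trace, f1@n_iter + 1)
    expect_equal(f1@P, crossprod(X, f1@U))
    expect_equal(sum(f1@w), 1, tolerance = 1e-9)
  }
  expect_error(npcaFit(-X, 2, 10), "negative")
  expect_error(npcaFit(X, 9, 10), "1 <= k <= d")
  expect_error(npcaFit(X, 2, 0, "coordinate"), "strictly positive")
})

test_that("a rank-one nonnegative matrix yields its generating direction", {
  set.seed(31)
  a <- abs(rnorm(6)) + 0.1
  b <- abs(rnorm(10)) + 0.1
  X <- a %o% b
  X <- X / max(svd(X)$d)
  fit <- npcaFit(X, 1, 10, "coordinate", seed = 1)
  cosang <- abs(sum(fit@U[, 1] * a)) /
    sqrt(sum(fit@U[, 1]^2) * sum(a^2))
  expect_gte(cosang, 0.99)
})

test_that("a scaled identity input converges to a permutation-like U", {
  fit <- npcaFit(5 * diag(3), 3, 50, "coordinate", seed = 2)
  U <- fit@U
  # normalize columns and compare against the best column permutation
  Un <- sweep(U, 2, sqrt(colSums(U^2)), `/`)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  dists <- vapply(perms, function(p) {
    norm(Un - diag(3)[, p], "F")
  }, numeric(1))
  expect_lt(min(dists), 1e-2)
})

test_that("single coordinate updates are exact argmaxes and fixed points", {
  set.seed(33)
  U <- matrix(abs(rnorm(8)), 4, 2)
  X <- matrix(abs(rnorm(24)), 4, 6)
  alpha <- 5
  for (s in 1:4) {
    for (l in 1:2) {
      unew <- coordinateUpdate(U, X, alpha, s, l)
      expect_gte(unew, 0)
      # objective never decreases at a single update
      U2 <- U
      U2[s, l] <- unew
      expect_gte(npcaObjective(U2, X, alpha) - npcaObjective(U, X, alpha),
                 -1e-10)
      # updating an entry already at its argmax changes nothing
      expect_equal(coordinateUpdate(U2, X, alpha, s, l), unew,
                   tolerance = 1e-8)
      U <- U2
    }
  }
  expect_error(coordinateUpdate(U, X, 0, 1, 1), "strictly positive")
  expect_error(coordinateUpdate(U, X, 5, 9, 1), "out of range")
})

test_that("the coordinate solver is monotone over full sweeps", {
  lr <- generateLowRank(10, 30, 3, 0.1, seed = 5)
  X <- lr$X / max(svd(lr$X)$d)
  fit <- npcaFit(X, 3, 10, "coordinate", init = "random", seed = 5)
  expect_true(all(diff(fit@objective_trace) >= -1e-9))
})

test_that("stronger penalties give more orthonormal PC matrices", {
  lr <- generateLowRank(20, 100, 4, 0.1, seed = 77)
  X <- lr$X / max(svd(lr$X)$d) * 4
  devs <- vapply(1:10, function(s) {
    vapply(c(1, 100), function(a) {
      f <- npcaFit(X, 4, a, "coordinate", init = "random", seed = s)
      norm(crossprod(f@U) - diag(4), "F")
    }, numeric(1))
  }, numeric(2))
  expect_lte(mean(devs[2, ]), mean(devs[1, ]))
})

test_that("the fixed-step gradient solver tracks the exact solver", {
  # small instances, shared random starting point; the fixed normalized
  # step caps how closely the crude scheme can approach the exact
  # coordinate optimum, so the typical gap is a few percent with
  # occasional worse excursions
  set.seed(55)
  gaps <- vapply(1:8, function(r) {
    d <- sample(4:10, 1)
    m <- sample(8:20, 1)
    k <- sample(2:4, 1)
    X <- matrix(abs(rnorm(d * m)), d, m)
    U0 <- matrix(abs(rnorm(d * k)), d, k)
    U0 <- U0 * sqrt(k) / sqrt(sum(U0^2))
    og <- max(npcaFit(X, k, 10, "gradient", init = U0)@objective_trace)
    oc <- max(npcaFit(X, k, 10, "coordinate", init = U0)@objective_trace)
    abs(og - oc) / abs(oc)
  }, numeric(1))
  expect_lt(median(gaps), 0.05)
  expect_lt(max(gaps), 0.3)
})

test_that("variance-explained weights are normalized score variances", {
  lr <- generateLowRank(10, 30, 3, 0.1, seed = 6)
  X <- lr$X / max(svd(lr$X)$d)
  fit <- npcaFit(X, 3, 10, "coordinate", seed = 1)
  expect_equal(sum(varianceExplained(fit)), 1, tolerance = 1e-9)
  f1 <- npcaFit(X, 1, 10, "coordinate", seed = 1)
  expect_equal(varianceExplained(f1), 1)

  # hand-built example: orthonormal nonnegative U, score variances 9 : 1
  Xh <- rbind(c(6, 0, 6, 0), c(2, 0, 2, 0))
  model <- new("NPCAModel", U = diag(2), P = crossprod(Xh, diag(2)),
               X = Xh, alpha = 1, k = 2L, solver = "coordinate",
               converged = TRUE, n_iter = 0L, objective_trace = 0,
               grad_norm_final = 0, w = c(0.5, 0.5), seed = 1L)
  expect_equal(varianceExplained(model), c(0.9, 0.1))
  constant <- new("NPCAModel", U = diag(2),
                  P = crossprod(matrix(1, 2, 4), diag(2)),
                  X = matrix(1, 2, 4), alpha = 1, k = 2L,
                  solver = "coordinate", converged = TRUE, n_iter = 0L,
                  objective_trace = 0, grad_norm_final = 0,
                  w = c(0.5, 0.5), seed = 1L)
  expect_error(varianceExplained(constant), "constant")
})

test_that("fitted models survive JSON serialization", {
  lr <- generateLowRank(6, 15, 2, 0.05, seed = 8)
  fit <- npcaFit(lr$X / max(svd(lr$X)$d), 2, 10, "coordinate", seed = 3)
  f <- tempfile(fileext = ".json")
  saveNPCAModel(fit, f)
  back <- readNPCAModel(f)
  expect_equal(back@U, fit@U)
  expect_equal(back@P, fit@P)
  expect_equal(back@w, fit@w)
  expect_equal(back@n_iter, fit@n_iter)
  expect_error(readNPCAModel({
    p <- tempfile()
    jsonlite::write_json(list(a = 1), p)
    p
  }), "not a serialized")
})
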