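test_that("the Bayes factor favors the null at t = 0 and is symmetric", {
  a <- withr::with_seed(1, rnorm(20, 5, 1))
  bf0 <- bayesFactor(a, a)
  expect_gt(as.numeric(bf0), 1)
  expect_equal(attr(bf0, "t"), 0)
  b <- withr::with_seed(2, rnorm(15, 7, 1))
  expect_equal(as.numeric(bayesFactor(a, b)),
               as.numeric(bayesFactor(b, a)))
  expect_error(bayesFactor(a, 3), "at least 2 observations")
  expect_error(bayesFactor(rep(2, 5), rep(2, 5)), "degenerate")
  # zero variance with different means: maximal evidence, finite limit
  expect_gt(as.numeric(bayesFactor(rep(2, 5), rep(3, 5))), 0)
})

test_that("the Bayes factor decreases strictly with |t| at fixed sizes", {
  base <- withr::with_seed(3, rnorm(20, sd = 1))
  base <- (base - mean(base)) / sd(base)  # exactly mean 0, sd 1
  shifts <- c(0, 0.5, 1, 2, 4, 8)
  res <- vapply(shifts, function(h) {
    bf <- bayesFactor(base + h, base)
    c(as.numeric(bf), abs(attr(bf, "t")))
  }, numeric(2))
  expect_true(all(diff(res[2, ]) > 0))   # |t| really scans upwards
  expect_true(all(diff(res[1, ]) < 0))   # BF01 strictly decreasing
})

test_that("candidate filtering sizes follow the top-one-percent rule", {
  sim <- generateProfiles(syntheticSpec(nPerClass = c(5, 5),
                                        nFeatures = 300, seed = 4))
  cand <- buildCandidates(sim$data)
  expect_equal(nrow(cand), 3)
  expect_true(all(diff(cand$bayesFactor) >= 0))

  wide <- MassSpecSet(withr::with_seed(5, matrix(runif(4 * 16331), 4)),
                      mz = seq_len(16331) + 700,
                      labels = c(-1, -1, 1, 1))
  expect_equal(nrow(buildCandidates(wide)), 164)
  expect_error(buildCandidates(sim$data, size = 400), "between 1 and")
})

test_that("planted differential pseudo-genes dominate the candidate set", {
  hits <- vapply(1:10, function(s) {
    sim <- generateProfiles(syntheticSpec(nFeatures = 205, nMarkers = 5,
                                          effectSize = 3, seed = s))
    cand <- buildCandidates(sim$data, size = 5)
    length(intersect(cand$index, sim$markers))
  }, numeric(1))
  expect_gte(sum(hits >= 4), 9)
})

test_that("NPCA ranking coefficients are variance-weighted loading sums", {
  Xh <- rbind(c(2, 1, 3, 1), c(1, 2, 1, 3))
  P <- rbind(c(1, 2), c(3, 4))
  model <- new("NPCAModel", U = diag(2), P = crossprod(Xh, diag(2)),
               X = Xh, alpha = 1, k = 2L, solver = "coordinate",
               converged = TRUE, n_iter = 0L, objective_trace = 0,
               grad_norm_final = 0, w = c(0.75, 0.25), seed = 1L)
  # tau = P %*% w with the model's own loadings
  expect_equal(npcaRank(Xh, model), as.vector(crossprod(Xh, diag(2)) %*%
                                                c(0.75, 0.25)))
  # k = 1: tau equals the single loading column
  lr <- generateLowRank(8, 20, 2, 0.05, seed = 6)
  X <- lr$X / max(svd(lr$X)$d)
  f1 <- npcaFit(X, 1, 10, "coordinate", seed = 1)
  expect_equal(npcaRank(X, f1), as.vector(f1@P))
  # scaling X by c > 0 scales tau by c at fixed U
  expect_equal(npcaRank(3 * X, f1), 3 * npcaRank(X, f1))
  expect_error(npcaRank(X[, 1:10], f1), "dimensions")
})

test_that("LOOCV accuracy matches an explicit leave-one-out refit loop", {
  # hand-checkable 6-sample 1-D dataset
  x6 <- matrix(c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3), ncol = 1)
  y6 <- c(-1, -1, -1, 1, 1, 1)
  expect_equal(loocvAccuracy(x6, y6), 100)
  expect_equal(loocvAccuracy(x6, y6), explicitLoocvAccuracy(x6, y6))
  set.seed(7)
  for (rep in 1:3) {
    X <- matrix(rnorm(20 * 2, mean = 3), 20, 2)
    y <- rep(c(-1, 1), each = 10)
    X[y == 1, 1] <- X[y == 1, 1] + 1.5
    Z <- scale(X)
    expect_equal(loocvAccuracy(Z, y, standardize = FALSE),
                 explicitLoocvAccuracy(Z, y))
  }
  # an uninformative constant feature cannot beat chance by much
  const <- matrix(1, 20, 1)
  y <- rep(c(-1, 1), each = 10)
  expect_lte(loocvAccuracy(const, y), 50 + 100 / 20)
  expect_error(loocvAccuracy(x6, c(-1, 1, 1, 1, 1, 1)), "at least 2")
})

test_that("greedy selection stops at a perfect single separator", {
  sim <- generateProfiles(syntheticSpec(nPerClass = c(10, 10),
                                        nFeatures = 50, nMarkers = 0,
                                        seed = 8))
  vals <- intensities(sim$data)
  vals[, 25] <- 1 + 9 * (classLabels(sim$data) == 1)  # perfect separator
  x <- MassSpecSet(vals, mz = mz(sim$data), labels = classLabels(sim$data))
  res <- greedyForwardSelect(x, candidates = c(10, 25, 40),
                             tau = rep(1, 50))
  expect_equal(res@selected$index, 25)
  expect_equal(res@selected$cumAccuracy, 100)
  expect_equal(res@finalAccuracy, 100)
  expect_error(greedyForwardSelect(x, integer(0)), "empty")
})

test_that("accuracy ties are broken by the larger |tau| then the index", {
  sim <- generateProfiles(syntheticSpec(nPerClass = c(10, 10),
                                        nFeatures = 40, nMarkers = 0,
                                        seed = 9))
  vals <- intensities(sim$data)
  sep <- 1 + 9 * (classLabels(sim$data) == 1)
  vals[, 12] <- sep
  vals[, 30] <- sep    # identical separating columns: an exact tie
  x <- MassSpecSet(vals, mz = mz(sim$data), labels = classLabels(sim$data))
  tau <- rep(0.1, 40)
  tau[30] <- -5        # magnitude wins regardless of sign
  res <- greedyForwardSelect(x, candidates = c(12, 30), tau = tau)
  expect_equal(res@selected$index[1], 30)
  tau[30] <- 0.1       # full tie: smaller column index wins
  res2 <- greedyForwardSelect(x, candidates = c(12, 30), tau = tau)
  expect_equal(res2@selected$index[1], 12)
})

test_that("selected panels are distinct subsets with increasing accuracy", {
  sim <- generateProfiles(syntheticSpec(nFeatures = 120, nMarkers = 3,
                                        effectSize = 2.5, seed = 10))
  cand <- buildCandidates(sim$data, size = 30)
  res <- greedyForwardSelect(sim$data, cand, seed = 10)
  expect_true(all(res@selected$index %in% cand$index))
  expect_false(anyDuplicated(res@selected$index) > 0)
  if (nrow(res@selected) > 1) {
    expect_true(all(diff(res@selected$cumAccuracy) > 0))
  }
  expect_equal(res@finalAccuracy,
               res@selected$cumAccuracy[nrow(res@selected)])
})
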