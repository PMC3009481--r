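test_that("training on well-separated classes fits them perfectly", {
  sim <- makeSeparableProfiles(d = 40, m = 200, sigma = 4, seed = 1)
  model <- trainNPCASVM(sim$data, seed = 1)
  trainPred <- as.integer(as.character(
    predict(model@svmFit, metaSamples(model@npca))))
  expect_equal(mean(trainPred == classLabels(sim$data)), 1)

  # transductive re-prediction of the training samples themselves
  pred <- predict(model, sim$data)
  expect_gte(mean(pred == classLabels(sim$data)), 0.95)
})

test_that("training is deterministic and validates its inputs", {
  sim <- makeSeparableProfiles(d = 20, m = 80, sigma = 4, seed = 2)
  holdout <- makeSeparableProfiles(d = 10, m = 80, sigma = 4, seed = 3)
  m1 <- trainNPCASVM(sim$data, seed = 5)
  m2 <- trainNPCASVM(sim$data, seed = 5)
  expect_identical(predict(m1, holdout$data, mode = "nnls"),
                   predict(m2, holdout$data, mode = "nnls"))
  expect_error(trainNPCASVM(sim$data, kernel = "poly"),
               "supported kernels: linear, rbf")
  X <- intensities(sim$data)
  expect_error(trainNPCASVM(X, labels = rep(1, 20)), "both classes")
  expect_error(trainNPCASVM(sim$data, k = 25), "cannot exceed")
})

test_that("nnls embeddings recover meta-samples on noiseless low-rank data", {
  lr <- generateLowRank(12, 40, 3, 0, seed = 2)
  X <- lr$X / max(svd(lr$X)$d)
  fit <- npcaFit(X, 3, 10, "coordinate", seed = 1)
  relerr <- vapply(seq_len(nrow(X)), function(i) {
    u <- pracma::lsqnonneg(fit@P, X[i, ])$x
    sqrt(sum((u - fit@U[i, ])^2)) / sqrt(sum(fit@U[i, ]^2))
  }, numeric(1))
  # the PC matrix is near- (not exactly) orthonormal at finite alpha, so
  # the embedding matches to the reconstruction residual, not exactly
  expect_lt(max(relerr), 0.05)
  expect_lt(mean(relerr), 0.03)
})

test_that("prediction handles empty input and mismatched columns", {
  sim <- makeSeparableProfiles(d = 16, m = 50, sigma = 4, seed = 4)
  model <- trainNPCASVM(sim$data, seed = 1, projectionMode = "nnls")
  expect_identical(predict(model, matrix(0.5, 0, 50)), integer(0))
  expect_error(predict(model, matrix(0.5, 2, 49)), "49 pseudo-gene")
})

test_that("confusion metrics follow their standard definitions", {
  y <- c(1, 1, -1, -1)
  expect_equal(unname(confusionMetrics(y, y)), c(100, 100, 100))
  expect_equal(unname(confusionMetrics(y, rep(1, 4))), c(50, 100, 0))
  yTrue <- c(rep(1, 10), rep(-1, 10))
  yPred <- c(rep(1, 9), -1, rep(-1, 8), 1, 1)
  expect_equal(unname(confusionMetrics(yTrue, yPred)), c(85, 90, 80))
  expect_error(confusionMetrics(c(1, -1), c(1)), "different lengths")
  expect_warning(met <- confusionMetrics(c(-1, -1), c(-1, 1)),
                 "sensitivity undefined")
  expect_true(is.nan(met["sensitivity"]))
  # negating all labels swaps sensitivity and specificity
  m1 <- confusionMetrics(yTrue, yPred)
  m2 <- confusionMetrics(-yTrue, -yPred)
  expect_equal(m1[["rate"]], m2[["rate"]])
  expect_equal(m1[["sensitivity"]], m2[["specificity"]])
  expect_equal(m1[["specificity"]], m2[["sensitivity"]])
})

test_that("holdout splits are stratified, reproducible and seed-driven", {
  labels <- rep(c(-1, 1), c(14, 10))
  s1 <- hocvSplits(labels, 25, 0.5, seed = 9)
  s2 <- hocvSplits(labels, 25, 0.5, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1, hocvSplits(labels, 25, 0.5, seed = 10)))
  for (tr in s1) {
    expect_equal(sum(labels[tr] == -1), 7)
    expect_equal(sum(labels[tr] == 1), 5)
  }
  expect_error(hocvSplits(labels, 5, 1.2, 1), "strictly between")
})

test_that("cross-validation reports are internally consistent", {
  sim <- makeSeparableProfiles(d = 16, m = 60, sigma = 4, seed = 6)
  rep1 <- evaluateHOCV(sim$data, "knn", nTrials = 6, seed = 2)
  s <- cvSummary(rep1)
  expect_equal(s["rate", "mean"], mean(rep1@perTrial$rate))
  expect_equal(s["rate", "sd"], sd(rep1@perTrial$rate))
  expect_true(all(rep1@perTrial$rate >= 0 & rep1@perTrial$rate <= 100))
  # single-trial reports have zero standard deviations by convention
  rep2 <- evaluateHOCV(sim$data, "knn", nTrials = 1, seed = 2)
  expect_equal(cvSummary(rep2)["rate", "sd"], 0)
})

test_that("the majority baseline sits at chance on balanced data", {
  sim <- generateProfiles(syntheticSpec(nPerClass = c(15, 15),
                                        nFeatures = 40, nMarkers = 0,
                                        seed = 7))
  rep <- evaluateHOCV(sim$data, "majority", nTrials = 100, seed = 3)
  expect_lt(abs(cvSummary(rep)["rate", "mean"] - 50), 5)
})

test_that("peer baselines separate what is separable and share splits", {
  sim <- makeSeparableProfiles(d = 24, m = 80, sigma = 4, seed = 8)
  for (alg in c("pca-svm", "knn", "svm")) {
    rep <- evaluateHOCV(sim$data, alg, nTrials = 10, seed = 4)
    expect_gte(cvSummary(rep)["rate", "mean"], 95)
  }
  for (alg in c("nmf-svm", "ica-svm", "pca-lda")) {
    rep <- suppressWarnings(
      evaluateHOCV(sim$data, alg, nTrials = 5, seed = 4, k = 5))
    expect_gte(cvSummary(rep)["rate", "mean"], 80)
  }
  expect_error(runBaseline("boost", sim$data), "unknown baseline")
  expect_error(evaluateHOCV(sim$data, "boost"), "unknown algorithm")
})

test_that("npca-svm evaluation runs in both projection modes", {
  sim <- makeSeparableProfiles(d = 20, m = 60, sigma = 4, seed = 9)
  rt <- evaluateHOCV(sim$data, "npca-svm", nTrials = 4, seed = 5)
  expect_gte(cvSummary(rt)["rate", "mean"], 80)
  rn <- evaluateHOCV(sim$data, "npca-svm", nTrials = 4, seed = 5,
                     projectionMode = "nnls", prefilter = "per-fold")
  expect_gte(cvSummary(rn)["rate", "mean"], 80)
})
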