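test_that("the RBF kernel has the Gaussian closed form", {
  expect_equal(rbfKernel(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rbfKernel(c(0, 0), c(2, 2), sigma = 2), exp(-1))
  set.seed(21)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(rbfKernel(a, b), rbfKernel(b, a))
  expect_gt(rbfKernel(a, b), 0)
  expect_lte(rbfKernel(a, b), 1)
  expect_error(rbfKernel(1:3, 1:4), "equal length")
  expect_error(rbfKernel(1:3, 1:3, sigma = 0), "sigma")
})

test_that("the SVM separates well-separated classes and satisfies the KKT conditions", {
  set.seed(22)
  X <- matrix(c(rnorm(10, -3), rnorm(10, 3)), ncol = 1)
  y <- rep(c(-1, 1), each = 10)
  fit <- trainSvm(X, y, svmConfig(C = 1))
  expect_equal(sign(svmDecision(fit, X)), y)

  # dual feasibility and margin conditions on a 10-sample toy problem
  X2 <- matrix(rnorm(20), 10, 2)
  y2 <- rep(c(-1, 1), 5)
  C <- 0.5
  fit2 <- trainSvm(X2, y2, svmConfig(C = C))
  a <- fit2@alpha
  expect_true(all(a >= -1e-10 & a <= C + 1e-10))
  expect_equal(sum(a * y2), 0, tolerance = 1e-8)
  f <- svmDecision(fit2, X2)
  margin <- y2 * f
  expect_true(all(margin[a < 1e-8] >= 1 - 1e-6))          # alpha = 0
  free <- a > 1e-8 & a < C - 1e-8
  expect_true(all(abs(margin[free] - 1) <= 1e-6))          # 0 < alpha < C
  expect_true(all(margin[a > C - 1e-8] <= 1 + 1e-6))       # alpha = C

  expect_error(trainSvm(X, rep(1, 20), svmConfig()), "both classes")
})

test_that("duplicating every training sample leaves predictions unchanged", {
  # duplication halves each point's required alpha; when no alpha is at the
  # box bound (separable data, generous C) the decision function is
  # invariant. (With bounded alphas duplication is equivalent to doubling
  # C, so invariance cannot hold there.)
  set.seed(23)
  X <- rbind(matrix(rnorm(16, -2, 0.3), 8, 2),
             matrix(rnorm(16, 2, 0.3), 8, 2))
  y <- rep(c(-1, 1), each = 8)
  grid <- matrix(rnorm(40), 20, 2)
  f1 <- trainSvm(X, y, svmConfig(C = 10))
  expect_lt(max(f1@alpha), 10 - 1e-6)  # interior solution
  f2 <- trainSvm(rbind(X, X), c(y, y), svmConfig(C = 10))
  expect_equal(svmDecision(f1, grid), svmDecision(f2, grid),
               tolerance = 1e-5)
})

test_that("decision values agree with an independent libsvm solve", {
  skip_if_not_installed("e1071")
  set.seed(24)
  for (r in 1:20) {
    n <- sample(8:30, 1)
    p <- sample(1:8, 1)
    C <- sample(c(0.05, 0.5, 1, 5), 1)
    X <- matrix(rnorm(n * p), n)
    y <- rep(c(-1, 1), length.out = n)[sample(n)]
    newX <- matrix(rnorm(6 * p), 6)
    mine <- svmDecision(trainSvm(X, y, svmConfig(C = C)), newX)
    ref <- libsvmDecision(X, y, newX, sigma = 2, C = C)
    expect_equal(mine, ref, tolerance = 5e-3, ignore_attr = TRUE)
  }
})

test_that("classification metrics reproduce confusion-count arithmetic", {
  truth <- rep(c(1, -1), each = 25)
  pred <- c(rep(1, 19), rep(-1, 6), rep(-1, 17), rep(1, 8))
  m <- classificationMetrics(truth, pred)
  expect_equal(unname(m), c(0.72, 0.76, 0.68))
  # GR decomposition holds for arbitrary predictions
  set.seed(25)
  pr <- sample(c(-1, 1), 50, replace = TRUE)
  m2 <- classificationMetrics(truth, pr)
  expect_equal(m2[["gr"]],
               (m2[["sensitivity"]] * 25 + m2[["specificity"]] * 25) / 50)
})

test_that("LOOCV runs one fold per sample with leak-free nested selection", {
  study <- generateFeatureDataset(6, 25, informative_idx = 1:4,
                                  effect_size = 3, seed = 26)
  cfg <- svmConfig(C = 1, k = 5)
  cv <- loocv(study, cfg)
  expect_equal(nrow(cvFolds(cv)), 12)
  expect_length(foldSelections(cv), 12)
  m <- cvMetrics(cv)
  expect_true(all(m >= 0 & m <= 1))

  # each fold's selection equals a direct top-k ranking on the training
  # subset (validates the leave-one-out score decomposition)
  for (i in c(1, 5, 12)) {
    direct <- rankAndSelect(zMatrix(study)[-i, ], k = 5,
                            labels = studyLabels(study)[-i])$selected
    expect_identical(foldSelections(cv)[[i]], direct)
  }

  # mutating the held-out sample's features must not change that fold's
  # selection or the model trained for it
  z <- zMatrix(study)
  z[3, ] <- z[3, ] + 100
  mutated <- LabeledStudy(z, studyLabels(study), studySubjects(study))
  cv2 <- loocv(mutated, cfg)
  expect_identical(foldSelections(cv2)[[3]], foldSelections(cv)[[3]])

  expect_error(loocv(generateFeatureDataset(2, 5, seed = 1),
                     svmConfig(k = 2)),
               NA)  # 4 samples is the minimum
})

test_that("an extremely wide kernel degrades gracefully", {
  study <- generateFeatureDataset(5, 10, seed = 27)
  cv <- loocv(study, svmConfig(sigma = 1e6, C = 1, k = 5))
  expect_true(all(cvFolds(cv)$predicted %in% c(-1, 1)))
})

test_that("the hyperparameter sweep reduces to LOOCV and is deterministic", {
  study <- generateFeatureDataset(6, 20, informative_idx = 1:3,
                                  effect_size = 2.5, seed = 28)
  one <- sweepGr(study, kGrid = 5, cGrid = 1)
  cv <- loocv(study, svmConfig(C = 1, k = 5))
  expect_equal(one$gr[1, 1], unname(cvMetrics(cv)["gr"]))
  expect_equal(one$best$k, 5L)

  sw1 <- sweepGr(study, kGrid = c(3, 6), cGrid = c(0.1, 1))
  sw2 <- sweepGr(study, kGrid = c(3, 6), cGrid = c(0.1, 1))
  expect_identical(sw1, sw2)
  expect_equal(sw1$best$gr, max(sw1$gr))
  expect_error(sweepGr(study, kGrid = integer(0)), "non-empty")
})
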