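test_that("paired-study generation is reproducible and structurally valid", {
  eff <- plantedEffect(rbind(c(1, 2), c(2, 4)), deltaR = 0.3)
  a <- generatePairedStudy(n_subjects = 4, n_regions = 5, n_frames = 30,
                           effect = eff, seed = 7)
  b <- generatePairedStudy(n_subjects = 4, n_regions = 5, n_frames = 30,
                           effect = eff, seed = 7)
  expect_identical(a, b)
  expect_true(validObject(a))
  expect_identical(names(a@pre), names(a@post))
  expect_equal(nFrames(a@pre[[1]]), 30)
  expect_equal(nRegions(a@post[[3]]), 5)
  c <- generatePairedStudy(n_subjects = 4, n_regions = 5, n_frames = 30,
                           effect = eff, seed = 8)
  expect_false(identical(a@pre[[1]]@series, c@pre[[1]]@series))
})

test_that("a null effect leaves pre/post correlations unshifted", {
  st <- generatePairedStudy(n_subjects = 25, n_regions = 6, n_frames = 175,
                            seed = 11)
  edgeCor <- function(ts, i, j) cor(ts@series[, i], ts@series[, j])
  diffs <- sapply(st@subjects, function(s)
    edgeCor(st@post[[s]], 1, 2) - edgeCor(st@pre[[s]], 1, 2))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("a planted correlation shift is recovered on average", {
  # Monte Carlo over replicate studies: the mean pre-to-post shift of the
  # sample correlation on the planted edge should match delta_r = +0.3
  eff <- plantedEffect(rbind(c(1, 2)), deltaR = 0.3)
  reps <- 100
  shifts <- vapply(seq_len(reps), function(r) {
    st <- generatePairedStudy(n_subjects = 5, n_regions = 4,
                              n_frames = 175, effect = eff,
                              seed = 100 + r)
    mean(sapply(st@subjects, function(s)
      cor(st@post[[s]]@series[, 1], st@post[[s]]@series[, 2]) -
        cor(st@pre[[s]]@series[, 1], st@pre[[s]]@series[, 2])))
  }, numeric(1))
  se <- sd(shifts) / sqrt(reps)
  expect_lt(abs(mean(shifts) - 0.3), 3 * se)
})

test_that("invalid planted effects are rejected", {
  expect_error(plantedEffect(rbind(c(2, 1)), 0.3), "i < j")
  expect_error(plantedEffect(rbind(c(1, 2), c(1, 2)), 0.3), "distinct")
  expect_error(plantedEffect(rbind(c(1, 2)), 1.2), "deltaR")
  # base_corr + delta outside (-1, 1)
  expect_error(
    generatePairedStudy(n_subjects = 2, n_regions = 4, n_frames = 20,
                        base_corr = 0.8,
                        effect = plantedEffect(rbind(c(1, 3)), 0.5),
                        seed = 1),
    "\\(1, 3\\)")
  expect_error(
    generatePairedStudy(n_subjects = 2, n_regions = 4, n_frames = 20,
                        effect = plantedEffect(rbind(c(1, 9)), 0.1),
                        seed = 1),
    "region range")
})

test_that("motion traces have the stated spikes and are reproducible", {
  m0 <- generateMotionTrace(20, baseline_sd = 0, seed = 1)
  expect_true(all(motionParams(m0) == 0))
  expect_true(all(fdValues(framewiseDisplacement(m0)) == 0))

  m1 <- generateMotionTrace(50, spike_frames = 20, spike_translation_mm = 1,
                            baseline_sd = 0.01, seed = 3)
  fd <- fdValues(framewiseDisplacement(m1))
  expect_gte(fd[20], 1)

  expect_identical(generateMotionTrace(50, spike_frames = c(5, 9), seed = 2),
                   generateMotionTrace(50, spike_frames = c(5, 9), seed = 2))
  expect_error(generateMotionTrace(50, spike_frames = 1, seed = 1),
               "frame 1")
})

test_that("feature datasets are balanced, null-centred, and separable when planted", {
  st <- generateFeatureDataset(25, 100, seed = 5)
  expect_equal(as.vector(table(studyLabels(st))), c(25, 25))
  expect_identical(studySubjects(st)[1], studySubjects(st)[26])

  # null: mean tau across features is ~0
  tau <- tauValues(kendallTau(zMatrix(st), studyLabels(st)))
  se <- sd(tau) / sqrt(length(tau))
  expect_lt(abs(mean(tau)), 3 * se)

  # planted: strongly informative features always rank at the top
  hits <- vapply(seq_len(100), function(r) {
    s <- generateFeatureDataset(25, 100, informative_idx = 1:5,
                                effect_size = 3, seed = 500 + r)
    all(1:5 %in% rankAndSelect(s, k = 20)$selected)
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  expect_error(generateFeatureDataset(1, 10, seed = 1), "n_per_class")
  expect_error(generateFeatureDataset(5, 10, informative_idx = 11, seed = 1),
               "informative_idx")
})

test_that("null synthetic data show no optimistic LOOCV bias", {
  # Leak-free LOOCV on null data cannot beat chance. It can fall below it:
  # leave-one-out on balanced classes makes the held-out sample's class the
  # training minority, a known pessimistic bias. We therefore check the
  # one-sided no-optimism bound at the binomial 99% level plus a sanity
  # floor, rather than a two-sided band at exactly 0.5.
  reps <- 100
  cfg <- svmConfig(C = 1, k = 10)
  gr <- vapply(seq_len(reps), function(r) {
    st <- generateFeatureDataset(10, 30, seed = 900 + r)
    unname(cvMetrics(loocv(st, cfg))["gr"])
  }, numeric(1))
  half_width <- 2.326 * sqrt(0.25 / (reps * 20))
  expect_lt(mean(gr), 0.5 + half_width)
  expect_gt(mean(gr), 0.30)
})
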