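makeTs <- function(n_frames = 20, n_regions = 3, tr = 2, seed = 1) {
  set.seed(seed)
  RoiTimeSeries(matrix(rnorm(n_frames * n_regions), n_frames, n_regions),
                tr = tr)
}

test_that("initial-volume discard trims exactly k frames", {
  ts <- makeTs(180, 4)
  expect_equal(nFrames(discardInitial(ts)), 175)  # default k = 5
  expect_identical(discardInitial(ts, 0), ts)
  expect_equal(nFrames(discardInitial(ts, 179)), 1)
  expect_equal(seriesMatrix(discardInitial(ts, 5)),
               seriesMatrix(ts)[-(1:5), ])
  expect_error(discardInitial(ts, 180), "discard")
})

test_that("frame-wise displacement follows the arc-length conversion", {
  # single 1-degree rotation step -> 50 * pi / 180 mm
  p <- matrix(0, 10, 6)
  p[5:10, 4] <- 1
  fd <- fdValues(framewiseDisplacement(MotionTrace(p, unit = "degrees")))
  expect_equal(fd[5], 50 * pi / 180, tolerance = 1e-12)
  expect_equal(fd[-5], rep(0, 9))

  # 0.2 mm step on each translation axis -> 0.6 mm, flagged at 0.5
  q <- matrix(0, 6, 6)
  q[4:6, 1:3] <- 0.2
  fds <- framewiseDisplacement(MotionTrace(q))
  expect_equal(fdValues(fds)[4], 0.6)
  expect_identical(which(fdFlags(fds)), 4L)

  # zero motion and first-frame convention
  z <- framewiseDisplacement(MotionTrace(matrix(1.3, 8, 6)))
  expect_true(all(fdValues(z) == 0))

  # radians vs degrees must differ by the conversion factor
  fdr <- fdValues(framewiseDisplacement(MotionTrace(p, unit = "radians")))
  expect_equal(fdr[5], 50)
})

test_that("FD agrees with a brute-force oracle and ignores constant offsets", {
  set.seed(3)
  p <- matrix(rnorm(60, sd = 0.2), 10, 6)
  m <- MotionTrace(p, unit = "degrees")
  expect_equal(fdValues(framewiseDisplacement(m)),
               bruteFD(p, unit = "degrees"), tolerance = 1e-12)
  shifted <- MotionTrace(sweep(p, 2, rnorm(6), "+"), unit = "degrees")
  expect_equal(fdValues(framewiseDisplacement(shifted)),
               fdValues(framewiseDisplacement(m)), tolerance = 1e-10)
})

test_that("scrubbing interpolates flagged frames linearly", {
  ts <- RoiTimeSeries(cbind(a = c(1, 2, 9, 4, 5), b = c(10, 20, 0, 40, 50)),
                      tr = 2)
  flags <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  out <- scrubFrames(ts, flags)
  expect_equal(seriesMatrix(out$series)[3, ], c(a = 3, b = 30))
  expect_identical(out$mask, flags)

  # untouched when nothing is flagged
  none <- scrubFrames(ts, rep(FALSE, 5))
  expect_identical(none$series, ts)

  # flagged run at the start extends the first unflagged value
  startFlags <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  out2 <- scrubFrames(ts, startFlags)
  expect_equal(seriesMatrix(out2$series)[1:2, 1], c(9, 9))

  # idempotence
  again <- scrubFrames(out$series, flags)
  expect_equal(seriesMatrix(again$series), seriesMatrix(out$series))

  expect_error(scrubFrames(ts, rep(TRUE, 5)), "all frames")
  expect_error(scrubFrames(ts, rep(FALSE, 4)), "frame counts")
})

test_that("nuisance regression removes covariates exactly", {
  ts <- makeTs(30, 4, seed = 2)
  # intercept-only = demeaning
  dm <- regressNuisance(ts)
  expect_equal(colMeans(seriesMatrix(dm)), rep(0, 4), tolerance = 1e-12)
  expect_equal(seriesMatrix(dm),
               scale(seriesMatrix(ts), scale = FALSE),
               ignore_attr = TRUE)

  # a series equal to a covariate is annihilated
  cov <- matrix(rnorm(30 * 2), 30, 2)
  ts2 <- RoiTimeSeries(cbind(cov[, 1], seriesMatrix(ts)[, 2:4]), tr = 2)
  res <- regressNuisance(ts2, cov)
  expect_lt(max(abs(seriesMatrix(res)[, 1])), 1e-10)

  # residuals orthogonal to every covariate column
  ip <- crossprod(cov, seriesMatrix(res))
  norms <- outer(sqrt(colSums(cov^2)),
                 pmax(sqrt(colSums(seriesMatrix(res)^2)), 1))
  expect_lt(max(abs(ip) / norms), 1e-8)

  # adding a covariate orthogonal to the data leaves residuals unchanged
  ortho <- residuals(lm(rnorm(30) ~ seriesMatrix(res) + cov))
  res2 <- regressNuisance(ts2, cbind(cov, ortho))
  expect_equal(seriesMatrix(res2), seriesMatrix(res), tolerance = 1e-10,
               ignore_attr = TRUE)

  # collinear design is refused, naming the column
  bad <- cbind(c1 = cov[, 1], c2 = cov[, 1] * 2)
  expect_error(regressNuisance(ts, bad), "collinear.*c2")
})

test_that("band-pass keeps in-band and rejects out-of-band components", {
  tr <- 2
  t <- seq_len(600)
  inband <- sin(2 * pi * 0.04 * t * tr)
  outband <- sin(2 * pi * 0.2 * t * tr)
  ts <- RoiTimeSeries(cbind(inband, outband, 1), tr = tr)
  out <- seriesMatrix(bandpassFilter(ts))
  core <- 150:450  # trim filter transients
  ampIn <- max(abs(out[core, 1]))
  ampOut <- max(abs(out[core, 2]))
  expect_gt(ampIn, 0.9)
  expect_lt(ampIn, 1.1)
  expect_lt(ampOut, 0.1)
  expect_lt(max(abs(out[core, 3])), 0.02)  # DC removed (residual ripple)
  expect_error(bandpassFilter(ts, 0.01, 0.3), "Nyquist")
  expect_error(bandpassFilter(ts, 0.1, 0.05), "lowHz")
})

test_that("parcellation averages voxels by atlas label", {
  # one label covering everything = global mean
  vol <- array(rnorm(3 * 3 * 2 * 5), c(3, 3, 2, 5))
  atlas1 <- array(1L, c(3, 3, 2))
  ts1 <- parcellate(vol, atlas1, tr = 2)
  expect_equal(seriesMatrix(ts1)[, 1], apply(vol, 4, mean))

  # constructed fixture: label k's voxels carry value k * t at frame t
  atlas <- array(rep(1:3, each = 6), c(3, 3, 2))
  vol2 <- array(0, c(3, 3, 2, 4))
  for (t in 1:4) vol2[, , , t] <- array(atlas * t, c(3, 3, 2))
  ts2 <- parcellate(vol2, atlas, tr = 2)
  expect_equal(seriesMatrix(ts2), outer(1:4, 1:3), ignore_attr = TRUE)
  expect_identical(regionIds(ts2), 1:3)

  # 116 labels -> 116 regions
  atlas116 <- array(rep(1:116, length.out = 120), c(6, 5, 4))
  vol116 <- array(rnorm(120 * 3), c(6, 5, 4, 3))
  expect_equal(nRegions(parcellate(vol116, atlas116, tr = 2)), 116)

  expect_error(parcellate(vol2, atlas, tr = 2, regionIds = c(1, 7)),
               "absent.*7")
  expect_error(parcellate(vol2, array(1L, c(2, 2, 2)), tr = 2), "grids")
})

test_that("the preprocessing chain composes and logs its parameters", {
  set.seed(9)
  ts <- makeTs(60, 4, seed = 9)
  motion <- generateMotionTrace(55, spike_frames = 30, baseline_sd = 0.005,
                                seed = 4)
  out <- preprocessSeries(ts, discard = 5, covariates = motionParams(motion),
                          motion = motion, lowHz = 0.01, highHz = 0.08)
  expect_equal(nFrames(out$series), 55)
  expect_equal(out$log$order, c("discard", "regress", "bandpass", "scrub"))
  expect_equal(out$log$framesInterpolated, sum(out$scrubMask))
})
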