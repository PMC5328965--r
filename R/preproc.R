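#' Discard initial volumes
#'
#' Removes the first k frames of a regional time series (magnetic-saturation
#' volumes at the start of a scan; the conventional default discards 5, so a
#' 180-volume acquisition retains 175 frames).
#'
#' @param ts a [RoiTimeSeries-class].
#' @param k number of initial frames to drop (default 5); must be smaller
#'   than the frame count.
#' @return A [RoiTimeSeries-class] with `nFrames(ts) - k` frames.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(180 * 3), 180, 3), tr = 2)
#' nFrames(discardInitial(ts))  # 175
#' @export
discardInitial <- function(ts, k = 5) {
  stopifnot(is(ts, "RoiTimeSeries"))
  k <- as.integer(k)
  if (k < 0L) stop("k must be non-negative")
  if (k >= nrow(ts@series))
    stop("cannot discard ", k, " frames from a ", nrow(ts@series),
         "-frame series")
  if (k == 0L) return(ts)
  RoiTimeSeries(ts@series[-seq_len(k), , drop = FALSE], tr = ts@tr,
                regionIds = ts@regionIds)
}

#' Frame-wise displacement from realignment parameters
#'
#' Summarises head motion at each frame as the frame-wise displacement (FD):
#' the sum of absolute frame-to-frame changes of the six rigid-body
#' parameters, with each rotational change converted from angle to arc
#' length on the surface of a sphere (radius 50 mm by default; degrees are
#' converted to radians first). FD at the first frame is defined as 0.
#' Frames with FD above `thresholdMm` are flagged for scrubbing.
#'
#' @param m a [MotionTrace-class] with a declared rotation unit.
#' @param sphereRadiusMm radius for the rotation-to-mm conversion
#'   (default 50).
#' @param thresholdMm flagging threshold in mm (default 0.5).
#' @return An [FDSeries-class].
#' @details FD depends only on frame-to-frame differences, so it is
#'   invariant to adding a constant to any parameter.
#' @examples
#' p <- matrix(0, 10, 6); p[5, 4] <- pi / 180  # 1 degree rotation step
#' fdValues(framewiseDisplacement(MotionTrace(p)))[5]  # 50*pi/180
#' @export
framewiseDisplacement <- function(m, sphereRadiusMm = 50, thresholdMm = 0.5) {
  stopifnot(is(m, "MotionTrace"))
  p <- m@params
  rot <- p[, 4:6, drop = FALSE]
  if (m@unit == "degrees") rot <- rot * pi / 180
  d_trans <- abs(diff(p[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot)) * sphereRadiusMm
  fd <- c(0, rowSums(d_trans) + rowSums(d_rot))
  new("FDSeries", fd = fd, flags = fd > thresholdMm,
      thresholdMm = as.numeric(thresholdMm),
      sphereRadiusMm = as.numeric(sphereRadiusMm))
}

#' Scrub high-motion frames by linear interpolation
#'
#' Replaces every frame whose FD exceeds the threshold with, per region, the
#' linear interpolation between its nearest unflagged neighbours. Flagged
#' runs at the start or end of the series, which have only one unflagged
#' neighbour, take that neighbour's value. Scrubbing is idempotent: applying
#' it again with the same flags changes nothing.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param fd an [FDSeries-class] with matching frame count, or a logical
#'   flag vector.
#' @param thresholdMm threshold in mm used to re-derive flags when `fd` is
#'   an [FDSeries-class] (default 0.5).
#' @return list with `series` (the scrubbed [RoiTimeSeries-class]) and
#'   `mask` (logical, `TRUE` for replaced frames).
#' @examples
#' ts <- RoiTimeSeries(cbind(1:10, 101:110), tr = 2)
#' flags <- rep(FALSE, 10); flags[4] <- TRUE
#' scrubFrames(ts, flags)$series
#' @export
scrubFrames <- function(ts, fd, thresholdMm = 0.5) {
  stopifnot(is(ts, "RoiTimeSeries"))
  flags <- if (is(fd, "FDSeries")) fd@fd > thresholdMm else as.logical(fd)
  n <- nrow(ts@series)
  if (length(flags) != n)
    stop("FD series and time series frame counts differ (",
         length(flags), " vs ", n, ")")
  if (all(flags))
    stop("all frames are flagged; nothing left to interpolate from")
  if (!any(flags))
    return(list(series = ts, mask = flags))
  good <- which(!flags)
  x <- ts@series
  # rule = 2: boundary runs take the nearest unflagged value
  for (rgn in seq_len(ncol(x))) {
    x[flags, rgn] <- approx(good, x[good, rgn], xout = which(flags),
                            method = "linear", rule = 2)$y
  }
  list(series = RoiTimeSeries(x, tr = ts@tr, regionIds = ts@regionIds),
       mask = flags)
}

#' Regress nuisance covariates out of a regional time series
#'
#' Removes nuisance signal (head-motion parameters, global mean, white
#' matter, cerebrospinal fluid, ...) by ordinary least squares: each
#' region's series is replaced by its residual from a regression on the
#' covariates plus an intercept. With no covariates this demeans each
#' region. Residuals are orthogonal to every covariate column.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param covariates numeric matrix, frames x p, or `NULL` for
#'   intercept-only.
#' @return A [RoiTimeSeries-class] of residuals.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(60), 20, 3), tr = 2)
#' cov <- matrix(rnorm(40), 20, 2)
#' res <- regressNuisance(ts, cov)
#' max(abs(crossprod(cov, seriesMatrix(res))))  # ~ 0
#' @export
regressNuisance <- function(ts, covariates = NULL) {
  stopifnot(is(ts, "RoiTimeSeries"))
  n <- nrow(ts@series)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariate rows (", nrow(covariates),
           ") must match frames (", n, ")")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("nuisance design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  resid <- ts@series - X %*% qr.coef(qrX, ts@series)
  RoiTimeSeries(resid, tr = ts@tr, regionIds = ts@regionIds)
}

#' Chebyshev band-pass filter
#'
#' Zero-phase Chebyshev Type I band-pass filtering of each region's series,
#' retaining the low-frequency BOLD fluctuations of interest
#' (0.01-0.08 Hz by default). The filter (order 4, 0.5 dB passband ripple by
#' default) is applied forward and backward (`signal::filtfilt`) so the
#' output is zero-phase.
#'
#' @param ts a [RoiTimeSeries-class]; TR sets the sampling rate.
#' @param lowHz,highHz passband edges in Hz; must satisfy
#'   `0 < lowHz < highHz < 1/(2*TR)`.
#' @param order filter order (default 4).
#' @param rippleDb passband ripple in dB (default 0.5).
#' @return A filtered [RoiTimeSeries-class].
#' @examples
#' t <- seq_len(400)
#' ts <- RoiTimeSeries(cbind(sin(2 * pi * 0.04 * t * 2)), tr = 2)
#' out <- bandpassFilter(ts)  # in-band sinusoid passes
#' @export
bandpassFilter <- function(ts, lowHz = 0.01, highHz = 0.08, order = 4,
                           rippleDb = 0.5) {
  stopifnot(is(ts, "RoiTimeSeries"))
  nyquist <- 1 / (2 * ts@tr)
  if (lowHz <= 0 || lowHz >= highHz)
    stop("require 0 < lowHz < highHz")
  if (highHz >= nyquist)
    stop("highHz (", highHz, ") must be below the Nyquist frequency (",
         nyquist, " Hz)")
  flt <- signal::cheby1(order, rippleDb, W = c(lowHz, highHz) / nyquist,
                        type = "pass")
  x <- apply(ts@series, 2L, function(col) signal::filtfilt(flt, col))
  RoiTimeSeries(x, tr = ts@tr, regionIds = ts@regionIds)
}

#' Extract regional mean time series from a 4D volume
#'
#' Averages the signal of a 4D functional volume over the voxels of each
#' atlas label, yielding one column per region ordered by ascending label
#' ID. Label 0 is background. With the 116-label AAL-style atlas this
#' produces the 116-region series the connectivity analysis expects.
#'
#' @param volume4d 4D numeric array (x, y, z, frames).
#' @param atlas 3D integer array of region labels on the same grid.
#' @param tr repetition time in seconds.
#' @param regionIds optional integer vector of labels to extract; every
#'   requested label must be present in the atlas. Default: all non-zero
#'   labels in the atlas.
#' @return A [RoiTimeSeries-class].
#' @examples
#' vol <- array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10))
#' atlas <- array(rep(1:2, each = 16), c(4, 4, 2))
#' parcellate(vol, atlas, tr = 2)
#' @export
parcellate <- function(volume4d, atlas, tr, regionIds = NULL) {
  dv <- dim(volume4d)
  da <- dim(atlas)
  if (length(dv) != 4L)
    stop("volume must be 4-dimensional (x, y, z, frames)")
  if (!identical(as.integer(dv[1:3]), as.integer(da)))
    stop("volume and atlas grids differ: ",
         paste(dv[1:3], collapse = "x"), " vs ",
         paste(da, collapse = "x"))
  lab <- as.integer(atlas)
  if (any(lab < 0L))
    stop("atlas labels must be non-negative integers")
  present <- sort(unique(lab[lab > 0L]))
  if (is.null(regionIds)) {
    regionIds <- present
  } else {
    regionIds <- sort(as.integer(regionIds))
    missing <- setdiff(regionIds, present)
    if (length(missing))
      stop("label(s) absent from the atlas: ",
           paste(missing, collapse = ", "))
  }
  nvox <- prod(dv[1:3])
  mat <- matrix(as.numeric(volume4d), nrow = nvox, ncol = dv[4L])
  keep <- lab %in% regionIds
  sums <- rowsum(mat[keep, , drop = FALSE],
                 group = lab[keep], reorder = TRUE)
  counts <- as.numeric(table(lab[keep])[as.character(regionIds)])
  RoiTimeSeries(t(sums / counts), tr = tr, regionIds = regionIds)
}

#' Standard preprocessing chain for one regional time series
#'
#' Applies the default preparation order: initial-volume discard, nuisance
#' regression, band-pass filtering, then FD-based scrubbing. Every step is
#' optional and the order is fixed; the parameters used are returned
#' alongside the data so a run can be logged and reproduced.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param discard number of initial frames to drop (default 5; 0 disables).
#' @param covariates nuisance covariate matrix aligned to the *retained*
#'   frames, or `NULL` to skip regression.
#' @param motion optional [MotionTrace-class] aligned to the retained
#'   frames; enables scrubbing.
#' @param lowHz,highHz band-pass edges; `NULL` `lowHz` disables filtering.
#' @param fdThresholdMm scrubbing threshold (default 0.5 mm).
#' @return list with `series`, `scrubMask`, and `log` (parameters applied).
#' @export
preprocessSeries <- function(ts, discard = 5, covariates = NULL,
                             motion = NULL, lowHz = 0.01, highHz = 0.08,
                             fdThresholdMm = 0.5) {
  log <- list(order = c("discard", "regress", "bandpass", "scrub"),
              discard = discard, bandHz = c(lowHz, highHz),
              fdThresholdMm = fdThresholdMm,
              nuisanceColumns = NCOL(covariates))
  if (discard > 0) ts <- discardInitial(ts, discard)
  if (!is.null(covariates)) ts <- regressNuisance(ts, covariates)
  if (!is.null(lowHz)) ts <- bandpassFilter(ts, lowHz, highHz)
  mask <- rep(FALSE, nrow(ts@series))
  if (!is.null(motion)) {
    fd <- framewiseDisplacement(motion, thresholdMm = fdThresholdMm)
    sc <- scrubFrames(ts, fd, thresholdMm = fdThresholdMm)
    ts <- sc$series
    mask <- sc$mask
  }
  log$framesInterpolated <- sum(mask)
  list(series = ts, scrubMask = mask, log = log)
}
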