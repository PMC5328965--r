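#' Generate a paired pre/post study with planted connectivity effects
#'
#' Simulates a paired resting-state design: `n_subjects` subjects scanned
#' twice (pre and post), each session a zero-mean multivariate Gaussian
#' regional time series whose correlation matrix is a common base matrix
#' (off-diagonals `base_corr`) plus, in the post session, the planted
#' per-edge shifts of `effect`. Per-subject heterogeneity is introduced by
#' jittering the base correlations subject-wise (SD `jitter_sd`, shared by
#' both of a subject's sessions so that pre/post differences reflect only
#' the planted effect plus sampling noise). Defaults mirror a 25-subject,
#' 116-region, 175-retained-frame, TR = 2 s acquisition.
#'
#' Each target correlation matrix is repaired to positive definiteness by
#' clipping eigenvalues below 1e-6 and rescaling to unit diagonal, which
#' preserves the planted structure approximately while guaranteeing a valid
#' sampling covariance.
#'
#' @param n_subjects number of subjects (>= 2), default 25.
#' @param n_regions number of regions (>= 3), default 116.
#' @param n_frames frames per session, default 175.
#' @param tr repetition time in seconds, default 2.
#' @param base_corr common off-diagonal base correlation, default 0.1.
#' @param effect a [PlantedEffect-class]; default: no planted edges.
#' @param noise_sd SD of additive white measurement noise (default 0).
#' @param jitter_sd SD of the per-subject correlation jitter (default 0.02).
#' @param ar optional AR(1) coefficient for temporal autocorrelation
#'   (default 0, white series).
#' @param seed integer seed; identical arguments and seed reproduce the
#'   study bit-for-bit.
#' @return A [PairedStudy-class].
#' @examples
#' eff <- plantedEffect(rbind(c(1, 2)), deltaR = 0.3)
#' st <- generatePairedStudy(n_subjects = 4, n_regions = 6, n_frames = 50,
#'                           effect = eff, seed = 1)
#' st
#' @export
generatePairedStudy <- function(n_subjects = 25, n_regions = 116,
                                n_frames = 175, tr = 2, base_corr = 0.1,
                                effect = plantedEffect(), noise_sd = 0,
                                jitter_sd = 0.02, ar = 0, seed = 1) {
  stopifnot(is(effect, "PlantedEffect"))
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (n_regions < 3L) stop("n_regions must be >= 3")
  edges <- effect@edges
  if (nrow(edges) && any(edges[, 2L] > n_regions))
    stop("planted edge outside the region range")
  target <- base_corr + effect@deltaR
  bad <- which(abs(target) >= 1)
  if (length(bad))
    stop("target correlation out of (-1, 1) on planted edge (",
         edges[bad[1L], 1L], ", ", edges[bad[1L], 2L], ")")

  base <- matrix(base_corr, n_regions, n_regions)
  diag(base) <- 1
  delta <- matrix(0, n_regions, n_regions)
  if (nrow(edges)) {
    delta[edges] <- effect@deltaR
    delta[edges[, 2:1, drop = FALSE]] <- effect@deltaR
  }

  set.seed(as.integer(seed))
  subjects <- sprintf("sub%02d", seq_len(n_subjects))
  pre <- post <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    jit <- matrix(0, n_regions, n_regions)
    jit[upper.tri(jit)] <- rnorm(n_regions * (n_regions - 1L) / 2L,
                                 sd = jitter_sd)
    jit <- jit + t(jit)
    cPre <- .repairCorrelation(base + jit, edges)
    cPost <- .repairCorrelation(base + jit + delta, edges)
    pre[[s]] <- .sampleSeries(n_frames, cPre, tr, noise_sd, ar)
    post[[s]] <- .sampleSeries(n_frames, cPost, tr, noise_sd, ar)
  }
  names(pre) <- names(post) <- subjects
  new("PairedStudy", subjects = subjects, pre = pre, post = post,
      truth = effect, seed = as.integer(seed))
}

# Eigenvalue-clipping repair to a valid correlation matrix: eigenvalues
# below 1e-6 are raised to 1e-6 and the result rescaled to unit diagonal.
.repairCorrelation <- function(m, edges = NULL) {
  diag(m) <- 1
  eig <- eigen(m, symmetric = TRUE)
  if (min(eig$values) >= 1e-6) return(m)
  v <- pmax(eig$values, 1e-6)
  m2 <- eig$vectors %*% (v * t(eig$vectors))
  d <- diag(m2)
  if (any(d <= 0))
    stop("could not repair target covariance to positive definite",
         if (!is.null(edges) && nrow(edges))
           paste0(" (planted edge (", edges[1L, 1L], ", ", edges[1L, 2L],
                  "))") else "")
  m2 / sqrt(outer(d, d))
}

.sampleSeries <- function(n_frames, corr, tr, noise_sd, ar) {
  R <- nrow(corr)
  z <- matrix(rnorm(n_frames * R), n_frames, R)
  if (ar != 0) {
    z <- apply(z, 2L, function(col)
      as.numeric(stats::filter(col, ar, method = "recursive")))
    z <- z * sqrt(1 - ar^2)  # restore unit marginal variance
  }
  x <- z %*% chol(corr)
  if (noise_sd > 0) x <- x + rnorm(length(x), sd = noise_sd)
  RoiTimeSeries(x, tr = tr)
}

#' Generate a head-motion trace with optional spikes
#'
#' Simulates realignment parameters as a smooth low-amplitude Gaussian
#' random walk on all six rigid-body parameters, with additive single-frame
#' spikes at the stated frames: `spike_translation_mm` is added to the x
#' translation and `spike_rotation` (in `unit`) to the x rotation at each
#' spike frame. Spikes may not be placed at frame 1, where frame-wise
#' displacement is undefined.
#'
#' @param n_frames number of frames (>= 2).
#' @param spike_frames integer frames in `2:n_frames` receiving a spike.
#' @param spike_translation_mm translation spike amplitude in mm (default 1).
#' @param spike_rotation rotation spike amplitude (default 0).
#' @param baseline_sd SD of the per-frame random-walk increments
#'   (default 0.01).
#' @param seed integer seed.
#' @param unit rotation unit of the returned trace (default radians).
#' @return A [MotionTrace-class].
#' @examples
#' m <- generateMotionTrace(50, spike_frames = 20, seed = 1)
#' fdValues(framewiseDisplacement(m))[20] >= 1
#' @export
generateMotionTrace <- function(n_frames, spike_frames = integer(0),
                                spike_translation_mm = 1,
                                spike_rotation = 0, baseline_sd = 0.01,
                                seed = 1, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  n_frames <- as.integer(n_frames)
  spike_frames <- as.integer(spike_frames)
  if (any(spike_frames < 2L | spike_frames > n_frames))
    stop("spike frames must lie in 2..n_frames (FD is undefined at frame 1)")
  set.seed(as.integer(seed))
  p <- matrix(0, n_frames, 6L)
  if (baseline_sd > 0)
    p <- apply(matrix(rnorm(n_frames * 6L, sd = baseline_sd), n_frames, 6L),
               2L, cumsum)
  p[spike_frames, 1L] <- p[spike_frames, 1L] + spike_translation_mm
  p[spike_frames, 4L] <- p[spike_frames, 4L] + spike_rotation
  MotionTrace(p, unit = unit)
}

#' Generate a feature-level labelled dataset
#'
#' A shortcut generator for classifier and permutation unit tests: Gaussian
#' features for `n_per_class` paired samples per class, with the
#' informative features' class means separated by `effect_size` (+1 class
#' shifted up by half, -1 class down by half). Labels are exactly balanced
#' and sample i of each class shares subject ID i (the pairing).
#'
#' @param n_per_class samples per class (>= 2).
#' @param n_features number of features.
#' @param informative_idx indices of informative features (subset of
#'   `1:n_features`).
#' @param effect_size between-class mean shift of informative features, in
#'   SD units (features have unit variance).
#' @param seed integer seed.
#' @return A [LabeledStudy-class] with pre samples first.
#' @examples
#' study <- generateFeatureDataset(10, 50, informative_idx = 1:5,
#'                                 effect_size = 3, seed = 1)
#' table(studyLabels(study))
#' @export
generateFeatureDataset <- function(n_per_class, n_features,
                                   informative_idx = integer(0),
                                   effect_size = 0, seed = 1) {
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 2L) stop("n_per_class must be >= 2")
  informative_idx <- as.integer(informative_idx)
  if (length(informative_idx) &&
      any(informative_idx < 1L | informative_idx > n_features))
    stop("informative_idx must lie within 1..n_features")
  set.seed(as.integer(seed))
  n <- 2L * n_per_class
  x <- matrix(rnorm(n * n_features), n, n_features)
  labels <- rep(c(-1, 1), each = n_per_class)
  if (length(informative_idx))
    x[, informative_idx] <- x[, informative_idx] +
      outer(labels, rep(effect_size / 2, length(informative_idx)))
  subjects <- sprintf("sub%02d", rep(seq_len(n_per_class), 2L))
  LabeledStudy(x, labels = labels, subjects = subjects)
}

#' Connectivity features of a paired study
#'
#' Runs every session of a [PairedStudy-class] through
#' [correlationMatrix()] and [vectorizeUpper()] and assembles the
#' [LabeledStudy-class] the classifier consumes: one Fisher-z feature row
#' per session, label -1 for pre and +1 for post, subject IDs preserved.
#'
#' @param study a [PairedStudy-class].
#' @return A [LabeledStudy-class] with all pre samples followed by all post
#'   samples.
#' @examples
#' st <- generatePairedStudy(n_subjects = 3, n_regions = 5, n_frames = 40,
#'                           seed = 1)
#' dim(zMatrix(studyFeatures(st)))  # 6 x 10
#' @export
studyFeatures <- function(study) {
  stopifnot(is(study, "PairedStudy"))
  featRow <- function(ts) zValues(vectorizeUpper(correlationMatrix(ts)))
  zPre <- t(vapply(study@pre, featRow,
                   numeric(nRegions(study@pre[[1L]]) *
                           (nRegions(study@pre[[1L]]) - 1L) / 2L)))
  zPost <- t(vapply(study@post, featRow, numeric(ncol(zPre))))
  LabeledStudy(rbind(zPre, zPost),
               labels = rep(c(-1, 1), each = length(study@subjects)),
               subjects = rep(study@subjects, 2L))
}
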