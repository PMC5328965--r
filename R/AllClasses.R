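#' Regional BOLD time series
#'
#' A frames-by-regions matrix of regional mean BOLD signal together with the
#' repetition time (TR) and the 1-based atlas label IDs of the regions.
#' Columns are ordered by ascending region ID throughout the package.
#'
#' @slot series numeric matrix, frames x regions.
#' @slot tr repetition time in seconds.
#' @slot regionIds integer vector of 1-based atlas label IDs, one per column.
#'
#' @seealso [RoiTimeSeries()] for the constructor, [parcellate()],
#'   [discardInitial()], [bandpassFilter()].
#' @exportClass RoiTimeSeries
setClass("RoiTimeSeries",
  representation(series = "matrix", tr = "numeric", regionIds = "integer"))

setValidity("RoiTimeSeries", function(object) {
  msg <- NULL
  if (!is.numeric(object@series)) msg <- c(msg, "series must be numeric")
  if (anyNA(object@series)) msg <- c(msg, "series contains missing values")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  if (length(object@regionIds) != ncol(object@series))
    msg <- c(msg, "regionIds length must equal the number of regions")
  if (anyDuplicated(object@regionIds))
    msg <- c(msg, "regionIds must be unique")
  if (is.null(msg)) TRUE else msg
})

#' @param series numeric matrix, frames x regions.
#' @param tr repetition time in seconds.
#' @param regionIds integer region label IDs (default `1:ncol(series)`).
#' @return A `RoiTimeSeries` object.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(40), 10, 4), tr = 2)
#' nFrames(ts); nRegions(ts)
#' @rdname RoiTimeSeries-class
#' @export
RoiTimeSeries <- function(series, tr, regionIds = seq_len(ncol(series))) {
  series <- as.matrix(series)
  storage.mode(series) <- "double"
  new("RoiTimeSeries", series = series, tr = as.numeric(tr),
      regionIds = as.integer(regionIds))
}

#' Rigid-body head-motion trace
#'
#' Per-frame realignment parameters: three translations (mm) and three
#' rotations about the coordinate axes. The rotation unit must be declared
#' (`"radians"` or `"degrees"`); frame-wise displacement conversion depends
#' on it.
#'
#' @slot params numeric matrix, frames x 6 (tx, ty, tz, rx, ry, rz).
#' @slot unit rotation unit, `"radians"` or `"degrees"`.
#' @seealso [framewiseDisplacement()], [generateMotionTrace()].
#' @exportClass MotionTrace
setClass("MotionTrace",
  representation(params = "matrix", unit = "character"))

setValidity("MotionTrace", function(object) {
  msg <- NULL
  if (ncol(object@params) != 6L)
    msg <- c(msg, "params must have 6 columns (3 translations, 3 rotations)")
  if (nrow(object@params) < 2L)
    msg <- c(msg, "at least 2 frames are required")
  if (!object@unit %in% c("radians", "degrees"))
    msg <- c(msg, "unit must be 'radians' or 'degrees'")
  if (is.null(msg)) TRUE else msg
})

#' @param params numeric matrix, frames x 6.
#' @param unit rotation unit, `"radians"` (default) or `"degrees"`.
#' @return A `MotionTrace` object.
#' @rdname MotionTrace-class
#' @export
MotionTrace <- function(params, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  params <- as.matrix(params)
  storage.mode(params) <- "double"
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  new("MotionTrace", params = params, unit = unit)
}

#' Frame-wise displacement series
#'
#' Per-frame frame-wise displacement (FD, in mm) summarising head motion:
#' the sum of absolute frame-to-frame changes over the six rigid-body
#' parameters, rotations first converted to arc length on a sphere.
#' FD at the first frame is defined as 0.
#'
#' @slot fd numeric vector of FD values (mm), `fd[1] == 0`.
#' @slot flags logical vector, `TRUE` where FD exceeds the threshold.
#' @slot thresholdMm flagging threshold in mm.
#' @slot sphereRadiusMm sphere radius used for the rotation conversion.
#' @seealso [framewiseDisplacement()], [scrubFrames()].
#' @exportClass FDSeries
setClass("FDSeries",
  representation(fd = "numeric", flags = "logical",
                 thresholdMm = "numeric", sphereRadiusMm = "numeric"))

setValidity("FDSeries", function(object) {
  msg <- NULL
  if (length(object@fd) != length(object@flags))
    msg <- c(msg, "fd and flags must have equal length")
  if (any(object@fd < 0)) msg <- c(msg, "FD values must be non-negative")
  if (length(object@fd) && object@fd[1L] != 0)
    msg <- c(msg, "FD at the first frame must be 0")
  if (is.null(msg)) TRUE else msg
})

#' Pearson functional-connectivity matrix
#'
#' Symmetric regions-by-regions Pearson correlation matrix with unit
#' diagonal, carrying the region label IDs.
#'
#' @slot r correlation matrix.
#' @slot regionIds integer region label IDs.
#' @seealso [correlationMatrix()], [vectorizeUpper()].
#' @exportClass ConnectivityMatrix
setClass("ConnectivityMatrix",
  representation(r = "matrix", regionIds = "integer"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- NULL
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "matrix must be square")
  if (max(abs(r - t(r))) > 1e-12)
    msg <- c(msg, "matrix must be symmetric within 1e-12")
  if (max(abs(diag(r) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
  if (any(r < -1 - 1e-12) || any(r > 1 + 1e-12))
    msg <- c(msg, "entries must lie in [-1, 1]")
  if (length(object@regionIds) != nrow(r))
    msg <- c(msg, "regionIds length must equal matrix dimension")
  if (is.null(msg)) TRUE else msg
})

#' Fisher-z connectivity feature vector
#'
#' The row-major upper triangle of a connectivity matrix, Fisher
#' z-transformed: edge k runs over (1,2), (1,3), ..., (1,R), (2,3), ...
#' For R regions the vector has length R(R-1)/2 (6670 for the 116-region
#' AAL parcellation).
#'
#' @slot z numeric vector of Fisher-z values, length R(R-1)/2.
#' @slot edges integer matrix, one row per edge, columns `i`, `j` (i < j),
#'   giving the region IDs of each feature.
#' @slot nRegions number of regions R.
#' @seealso [vectorizeUpper()], [edgeIndex()], [pairIndex()].
#' @exportClass FeatureVector
setClass("FeatureVector",
  representation(z = "numeric", edges = "matrix", nRegions = "integer"))

setValidity("FeatureVector", function(object) {
  msg <- NULL
  R <- object@nRegions
  if (length(object@z) != R * (R - 1L) / 2L)
    msg <- c(msg, "z length must be R(R-1)/2")
  if (nrow(object@edges) != length(object@z))
    msg <- c(msg, "edges must have one row per feature")
  if (any(!is.finite(object@z))) msg <- c(msg, "z must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Labelled pre/post feature study
#'
#' Samples-by-features Fisher-z connectivity data with class labels
#' (+1 post-intervention, -1 pre-intervention) and subject IDs recording the
#' pairing. Internally a [SummarizedExperiment::SummarizedExperiment] with
#' features as rows and samples as columns; `zMatrix()` returns the
#' conventional samples x features orientation used by the classifier.
#'
#' @seealso [LabeledStudy()], [zMatrix()], [studyLabels()], [loocv()].
#' @exportClass LabeledStudy
setClass("LabeledStudy", contains = "SummarizedExperiment")

setValidity("LabeledStudy", function(object) {
  msg <- NULL
  cd <- colData(object)
  if (!all(c("label", "subject") %in% colnames(cd)))
    return("colData must contain 'label' and 'subject'")
  lab <- cd$label
  if (!all(lab %in% c(-1, 1)))
    msg <- c(msg, "labels must be +1 (post) or -1 (pre)")
  if (!all(is.finite(assay(object))))
    msg <- c(msg, "features must be finite")
  if (any(table(cd$subject, lab) > 1L))
    msg <- c(msg, "each subject may contribute at most one sample per class")
  if (is.null(msg)) TRUE else msg
})

#' @param z numeric matrix, samples x features.
#' @param labels numeric vector of +1 / -1 class labels, one per sample.
#' @param subjects subject identifiers, one per sample (pairing).
#' @return A `LabeledStudy` object.
#' @examples
#' study <- generateFeatureDataset(n_per_class = 5, n_features = 8,
#'                                 informative_idx = 1:2, effect_size = 2,
#'                                 seed = 1)
#' studyLabels(study)
#' @rdname LabeledStudy-class
#' @export
LabeledStudy <- function(z, labels, subjects = seq_len(nrow(z))) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (length(labels) != nrow(z))
    stop("one label per sample is required")
  se <- SummarizedExperiment(
    assays = list(z = t(z)),
    colData = DataFrame(label = as.numeric(labels),
                        subject = as.character(subjects)))
  new("LabeledStudy", se)
}

#' Kendall-tau discriminative scores
#'
#' Per-feature signed Kendall tau between feature values and the +1/-1 class
#' labels, computed over between-class sample pairs with the n^2
#' denominator. The discriminative power of a feature is `abs(tau)`; a
#' positive tau means the feature is larger in the +1 (post) class.
#'
#' @slot tau signed per-feature tau values.
#' @slot nConcordant,nDiscordant per-feature concordant/discordant pair counts.
#' @slot n number of samples used.
#' @seealso [kendallTau()], [rankAndSelect()].
#' @exportClass TauScores
setClass("TauScores",
  representation(tau = "numeric", nConcordant = "numeric",
                 nDiscordant = "numeric", n = "integer"))

#' Consensus connections across cross-validation folds
#'
#' The edges selected in every cross-validation fold, with one sign per edge
#' (+1 increased, -1 decreased post-intervention) taken from tau computed on
#' all samples, and the per-fold selections kept for audit.
#'
#' @slot edges integer feature (edge) indices in the consensus.
#' @slot signs +1/-1 per consensus edge.
#' @slot perFold the per-fold selected index sets.
#' @slot fullTau the all-sample [TauScores-class] used for the signs.
#' @seealso [consensusConnections()], [regionWeights()].
#' @exportClass ConsensusSet
setClass("ConsensusSet",
  representation(edges = "integer", signs = "numeric", perFold = "list",
                 fullTau = "TauScores"))

setValidity("ConsensusSet", function(object) {
  msg <- NULL
  if (length(object@signs) != length(object@edges))
    msg <- c(msg, "one sign per consensus edge is required")
  for (sel in object@perFold)
    if (!all(object@edges %in% sel)) {
      msg <- c(msg, "consensus must be a subset of every fold's selection")
      break
    }
  if (is.null(msg)) TRUE else msg
})

#' Support-vector-classifier configuration
#'
#' The Gaussian RBF kernel width `sigma` (kernel value
#' exp(-||xi - xj||^2 / (2 sigma^2))), the soft-margin penalty `C`, and the
#' number of features `k` retained by Kendall-tau selection in each
#' training fold.
#'
#' @slot sigma RBF kernel width (> 0), default 2.
#' @slot C soft-margin penalty (> 0), default 0.01.
#' @slot k number of selected features (>= 1), default 160.
#' @seealso [svmConfig()], [loocv()].
#' @exportClass SvmConfig
setClass("SvmConfig",
  representation(sigma = "numeric", C = "numeric", k = "integer"))

setValidity("SvmConfig", function(object) {
  msg <- NULL
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@C <= 0) msg <- c(msg, "C must be > 0")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @param sigma RBF kernel width, default 2.
#' @param C soft-margin penalty, default 0.01.
#' @param k number of features retained per training fold, default 160.
#' @return An `SvmConfig` object.
#' @examples
#' svmConfig(sigma = 2, C = 0.01, k = 160)
#' @rdname SvmConfig-class
#' @export
svmConfig <- function(sigma = 2, C = 0.01, k = 160) {
  # Class= must be named: a slot named C would otherwise partially match it
  new(Class = "SvmConfig", sigma = as.numeric(sigma), C = as.numeric(C),
      k = as.integer(k))
}

#' Leave-one-out cross-validation result
#'
#' Per-fold records (held-out sample, selected feature set, predicted label,
#' decision value) and the aggregate generalization rate (GR), sensitivity
#' (post-class samples correctly identified) and specificity (pre-class
#' samples correctly identified).
#'
#' @slot folds data.frame with columns sample, subject, truth, predicted,
#'   decision.
#' @slot selections list of per-fold selected feature indices.
#' @slot metrics named numeric: gr, sensitivity, specificity.
#' @slot config the [SvmConfig-class] used.
#' @seealso [loocv()], [classificationMetrics()].
#' @exportClass CVResult
setClass("CVResult",
  representation(folds = "data.frame", selections = "list",
                 metrics = "numeric", config = "SvmConfig"))

#' Permutation-test result
#'
#' The observed generalization rate GR0, the null GR values from rerunning
#' the entire pipeline (feature selection + SVM + LOOCV) on label-shuffled
#' data, and the add-one permutation p-value
#' p = (1 + #\{GR* >= GR0\}) / (1 + B).
#'
#' @slot gr0 observed generalization rate.
#' @slot nullGr numeric vector of B null generalization rates.
#' @slot p permutation p-value.
#' @slot B number of permutations.
#' @slot scheme `"free"` or `"paired"` label shuffling.
#' @slot seed the seed used.
#' @seealso [permutationTest()].
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(gr0 = "numeric", nullGr = "numeric", p = "numeric",
                 B = "integer", scheme = "character", seed = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- NULL
  if (length(object@nullGr) != object@B)
    msg <- c(msg, "nullGr must have length B")
  if (object@p <= 0 || object@p > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Planted pre/post connectivity effect
#'
#' Ground-truth specification for the synthetic generator: a set of region
#' pairs whose correlation shifts between the pre and post sessions, with a
#' signed shift per edge.
#'
#' @slot edges integer matrix, one row per planted edge, columns `i`, `j`
#'   with i < j (1-based region IDs).
#' @slot deltaR signed correlation shift per edge, each with magnitude < 1.
#' @seealso [plantedEffect()], [generatePairedStudy()].
#' @exportClass PlantedEffect
setClass("PlantedEffect",
  representation(edges = "matrix", deltaR = "numeric"))

setValidity("PlantedEffect", function(object) {
  msg <- NULL
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns (i, j)")
  if (nrow(e) != length(object@deltaR))
    msg <- c(msg, "one deltaR per edge is required")
  if (nrow(e)) {
    if (any(e[, 1L] >= e[, 2L])) msg <- c(msg, "edges must satisfy i < j")
    if (any(e < 1L)) msg <- c(msg, "region IDs are 1-based")
    if (anyDuplicated(paste(e[, 1L], e[, 2L])))
      msg <- c(msg, "edges must be distinct")
    if (any(abs(object@deltaR) >= 1))
      msg <- c(msg, "each |deltaR| must be < 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' @param edges two-column matrix (or vector of length 2) of region pairs,
#'   i < j, 1-based.
#' @param deltaR signed correlation shift, recycled to one value per edge.
#' @return A `PlantedEffect` object.
#' @examples
#' plantedEffect(rbind(c(1, 2), c(3, 4)), deltaR = 0.3)
#' @rdname PlantedEffect-class
#' @export
plantedEffect <- function(edges = matrix(integer(0), 0, 2), deltaR = numeric(0)) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (nrow(edges)) deltaR <- rep_len(as.numeric(deltaR), nrow(edges))
  new("PlantedEffect", edges = edges, deltaR = deltaR)
}

#' Paired pre/post synthetic study
#'
#' One [RoiTimeSeries-class] per subject and session, the planted
#' ground-truth effect, and the seed that generated the study.
#'
#' @slot subjects subject IDs.
#' @slot pre,post named lists of [RoiTimeSeries-class], one per subject.
#' @slot truth the [PlantedEffect-class] ground truth.
#' @slot seed generator seed.
#' @seealso [generatePairedStudy()], [studyFeatures()].
#' @exportClass PairedStudy
setClass("PairedStudy",
  representation(subjects = "character", pre = "list", post = "list",
                 truth = "PlantedEffect", seed = "integer"))

setValidity("PairedStudy", function(object) {
  msg <- NULL
  if (!identical(names(object@pre), object@subjects) ||
      !identical(names(object@post), object@subjects))
    msg <- c(msg, "pre and post must hold one series per subject, in order")
  dims <- unique(lapply(c(object@pre, object@post),
                        function(ts) c(dim(ts@series), ts@tr)))
  if (length(dims) > 1L)
    msg <- c(msg, "all series must share frame count, region count and TR")
  if (is.null(msg)) TRUE else msg
})
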