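#' @rdname accessors
#' @aliases nFrames,RoiTimeSeries-method
setMethod("nFrames", "RoiTimeSeries", function(x) nrow(x@series))

#' @rdname accessors
setMethod("nFrames", "MotionTrace", function(x) nrow(x@params))

#' @rdname accessors
setMethod("nRegions", "RoiTimeSeries", function(x) ncol(x@series))

#' @rdname accessors
setMethod("nRegions", "ConnectivityMatrix", function(x) nrow(x@r))

#' @rdname accessors
setMethod("nRegions", "FeatureVector", function(x) x@nRegions)

#' @rdname accessors
setMethod("seriesMatrix", "RoiTimeSeries", function(x) x@series)

#' @rdname accessors
setMethod("repetitionTime", "RoiTimeSeries", function(x) x@tr)

#' @rdname accessors
setMethod("regionIds", "RoiTimeSeries", function(x) x@regionIds)

#' @rdname accessors
setMethod("regionIds", "ConnectivityMatrix", function(x) x@regionIds)

#' @rdname accessors
setMethod("motionParams", "MotionTrace", function(x) x@params)

#' @rdname accessors
setMethod("rotationUnit", "MotionTrace", function(x) x@unit)

#' @rdname accessors
setMethod("fdValues", "FDSeries", function(x) x@fd)

#' @rdname accessors
setMethod("fdFlags", "FDSeries", function(x) x@flags)

#' @rdname accessors
setMethod("corMatrix", "ConnectivityMatrix", function(x) x@r)

#' @rdname accessors
setMethod("zValues", "FeatureVector", function(x) x@z)

#' @rdname accessors
setMethod("edgeTable", "FeatureVector", function(x) x@edges)

#' @rdname accessors
setMethod("zMatrix", "LabeledStudy", function(x) t(assay(x, "z")))

#' @rdname accessors
setMethod("studyLabels", "LabeledStudy", function(x) colData(x)$label)

#' @rdname accessors
setMethod("studySubjects", "LabeledStudy", function(x) colData(x)$subject)

#' @rdname accessors
setMethod("tauValues", "TauScores", function(x) x@tau)

#' @rdname accessors
setMethod("discriminativePower", "TauScores", function(x) abs(x@tau))

#' @rdname accessors
setMethod("consensusEdges", "ConsensusSet", function(x) x@edges)

#' @rdname accessors
setMethod("edgeSigns", "ConsensusSet", function(x) x@signs)

#' @rdname accessors
setMethod("foldSelections", "ConsensusSet", function(x) x@perFold)

#' @rdname accessors
setMethod("cvMetrics", "CVResult", function(x) x@metrics)

#' @rdname accessors
setMethod("cvFolds", "CVResult", function(x) x@folds)

#' @rdname accessors
setMethod("foldSelections", "CVResult", function(x) x@selections)

#' @rdname accessors
setMethod("pValue", "PermutationResult", function(x) x@p)

#' @rdname accessors
setMethod("nullDistribution", "PermutationResult", function(x) x@nullGr)

#' @rdname regionWeights
#' @aliases regionWeights,ConsensusSet-method
setMethod("regionWeights", "ConsensusSet", function(x, nRegions) {
  R <- as.integer(nRegions)
  w <- numeric(R)
  names(w) <- as.character(seq_len(R))
  if (length(x@edges)) {
    pairs <- edgeIndex(x@edges, R)
    tab <- table(factor(c(pairs[, 1L], pairs[, 2L]), levels = seq_len(R)))
    w[] <- as.numeric(tab)
  }
  w
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries:", nrow(object@series), "frames x",
      ncol(object@series), "regions, TR =", object@tr, "s\n")
})

setMethod("show", "MotionTrace", function(object) {
  cat("MotionTrace:", nrow(object@params),
      "frames, rotations in", object@unit, "\n")
})

setMethod("show", "FDSeries", function(object) {
  cat("FDSeries:", length(object@fd), "frames,",
      sum(object@flags), "flagged (FD >", object@thresholdMm, "mm)\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", nrow(object@r), "x", ncol(object@r),
      "Pearson correlations\n")
})

setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector:", length(object@z), "Fisher-z edges over",
      object@nRegions, "regions\n")
})

setMethod("show", "TauScores", function(object) {
  cat("TauScores:", length(object@tau), "features, n =", object@n,
      "samples; max |tau| =",
      format(max(abs(object@tau)), digits = 4), "\n")
})

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet:", length(object@edges), "consensus connections (",
      sum(object@signs > 0), "increased,", sum(object@signs < 0),
      "decreased ) across", length(object@perFold), "folds\n")
})

setMethod("show", "SvmConfig", function(object) {
  cat("SvmConfig: sigma =", object@sigma, ", C =", object@C,
      ", k =", object@k, "\n")
})

setMethod("show", "CVResult", function(object) {
  m <- object@metrics
  cat(sprintf(
    "CVResult: %d LOOCV folds | GR %.1f%% sensitivity %.1f%% specificity %.1f%%\n",
    nrow(object@folds), 100 * m["gr"], 100 * m["sensitivity"],
    100 * m["specificity"]))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: GR0 = %.3f, B = %d (%s shuffles), p = %.4g\n",
    object@gr0, object@B, object@scheme, object@p))
})

setMethod("show", "PlantedEffect", function(object) {
  cat("PlantedEffect:", nrow(object@edges), "planted edges\n")
})

setMethod("show", "PairedStudy", function(object) {
  ts <- object@pre[[1L]]
  cat("PairedStudy:", length(object@subjects), "subjects x 2 sessions,",
      nrow(ts@series), "frames x", ncol(ts@series), "regions,",
      nrow(object@truth@edges), "planted edges\n")
})
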