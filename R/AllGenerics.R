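#' @name accessors
#' @title Accessors for connMVPA classes
#' @description Small accessor generics for the package's S4 containers.
#' @param x an object of the documented class.
NULL

#' @rdname accessors
#' @return `nFrames()`: the number of time frames.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @return `nRegions()`: the number of regions.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @return `seriesMatrix()`: the frames x regions signal matrix.
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))

#' @rdname accessors
#' @return `repetitionTime()`: TR in seconds.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname accessors
#' @return `regionIds()`: integer region label IDs.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname accessors
#' @return `motionParams()`: the frames x 6 realignment-parameter matrix.
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))

#' @rdname accessors
#' @return `rotationUnit()`: `"radians"` or `"degrees"`.
#' @export
setGeneric("rotationUnit", function(x) standardGeneric("rotationUnit"))

#' @rdname accessors
#' @return `fdValues()`: per-frame FD in mm.
#' @export
setGeneric("fdValues", function(x) standardGeneric("fdValues"))

#' @rdname accessors
#' @return `fdFlags()`: logical, frames exceeding the FD threshold.
#' @export
setGeneric("fdFlags", function(x) standardGeneric("fdFlags"))

#' @rdname accessors
#' @return `corMatrix()`: the Pearson correlation matrix.
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname accessors
#' @return `zValues()`: the Fisher-z feature vector.
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname accessors
#' @return `edgeTable()`: integer matrix mapping feature index to (i, j).
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @return `zMatrix()`: samples x features Fisher-z matrix.
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname accessors
#' @return `studyLabels()`: +1/-1 class labels, one per sample.
#' @export
setGeneric("studyLabels", function(x) standardGeneric("studyLabels"))

#' @rdname accessors
#' @return `studySubjects()`: subject ID per sample.
#' @export
setGeneric("studySubjects", function(x) standardGeneric("studySubjects"))

#' @rdname accessors
#' @return `tauValues()`: signed per-feature Kendall tau.
#' @export
setGeneric("tauValues", function(x) standardGeneric("tauValues"))

#' @rdname accessors
#' @return `discriminativePower()`: `abs(tau)` per feature.
#' @export
setGeneric("discriminativePower",
           function(x) standardGeneric("discriminativePower"))

#' @rdname accessors
#' @return `consensusEdges()`: integer indices of the consensus edges.
#' @export
setGeneric("consensusEdges", function(x) standardGeneric("consensusEdges"))

#' @rdname accessors
#' @return `edgeSigns()`: +1/-1 per consensus edge.
#' @export
setGeneric("edgeSigns", function(x) standardGeneric("edgeSigns"))

#' @rdname accessors
#' @return `cvMetrics()`: named numeric (gr, sensitivity, specificity).
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname accessors
#' @return `cvFolds()`: per-fold prediction records.
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))

#' @rdname accessors
#' @return `foldSelections()`: list of per-fold selected feature indices.
#' @export
setGeneric("foldSelections", function(x) standardGeneric("foldSelections"))

#' @rdname accessors
#' @return `pValue()`: the permutation p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @return `nullDistribution()`: the vector of null statistics.
#' @export
setGeneric("nullDistribution",
           function(x) standardGeneric("nullDistribution"))

#' Region weights of a consensus set
#'
#' The weight of a region is its degree in the consensus graph: the number
#' of consensus connections incident to it. Weights sum to twice the number
#' of consensus edges (handshake lemma).
#'
#' @param x a [ConsensusSet-class].
#' @param nRegions the number of regions R in the parcellation.
#' @return named numeric vector of length `nRegions`.
#' @examples
#' tau <- kendallTau(matrix(rnorm(40), 10, 4), rep(c(1, -1), each = 5))
#' cs <- consensusConnections(list(c(1L, 2L), c(1L, 2L, 3L)), tau)
#' regionWeights(cs, nRegions = 4)
#' @export
setGeneric("regionWeights",
           function(x, nRegions) standardGeneric("regionWeights"))
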