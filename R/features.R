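#' Kendall-tau discriminative score of connectivity features
#'
#' Scores each feature's relevance to the pre/post class distinction with a
#' Kendall tau rank correlation against the +1/-1 labels. Over unordered
#' sample pairs (j < k), a pair is concordant when
#' `sgn(x_j - x_k) = sgn(y_j - y_k) != 0` and discordant when the signs are
#' opposite and non-zero; within-class pairs and exact value ties count as
#' neither. The statistic is
#' \deqn{\tau = (n_c - n_d) / n^2}
#' with n the number of samples, so for balanced classes |tau| is bounded by
#' about 0.25 under this convention. Only the sign and the |tau| ranking are
#' used downstream, and both are invariant to the choice of denominator. A
#' positive tau marks a feature that is larger in the +1 (post) class.
#'
#' @param x numeric vector (one feature) or samples x features matrix.
#' @param labels +1/-1 class labels; both classes must be present.
#' @return A [TauScores-class].
#' @examples
#' kendallTau(c(3, 2, 1, 0), c(1, 1, -1, -1))  # tau = 4/16
#' @export
kendallTau <- function(x, labels) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.numeric(labels)
  n <- nrow(x)
  if (length(labels) != n)
    stop("one label per sample is required")
  if (n < 2L)
    stop("at least 2 samples are required")
  if (!all(labels %in% c(-1, 1)) || length(unique(labels)) < 2L)
    stop("labels must contain both classes (+1 and -1)")
  counts <- .kendallCounts(x, as.integer(labels))
  tau <- (counts[, 1L] - counts[, 2L]) / n^2
  new("TauScores", tau = as.numeric(tau),
      nConcordant = as.numeric(counts[, 1L]),
      nDiscordant = as.numeric(counts[, 2L]), n = as.integer(n))
}

#' Rank features by discriminative power and select the top k
#'
#' Computes per-feature Kendall tau against the class labels and returns the
#' indices of the k features with the largest discriminative power |tau|.
#' Ties in |tau| are broken by ascending feature index, making the selection
#' deterministic.
#'
#' @param study a [LabeledStudy-class], or a samples x features matrix if
#'   `labels` is given.
#' @param k number of features to retain, `1 <= k <= n_features`.
#' @param labels class labels (only when `study` is a plain matrix).
#' @return list with elements `selected` (integer indices, in selection
#'   order) and `scores` (the [TauScores-class]).
#' @examples
#' study <- generateFeatureDataset(10, 30, informative_idx = 1:3,
#'                                 effect_size = 3, seed = 1)
#' rankAndSelect(study, k = 5)$selected
#' @export
rankAndSelect <- function(study, k, labels = NULL) {
  if (is(study, "LabeledStudy")) {
    x <- zMatrix(study)
    labels <- studyLabels(study)
  } else {
    x <- as.matrix(study)
  }
  k <- as.integer(k)
  if (k < 1L || k > ncol(x))
    stop("k must lie in 1..", ncol(x))
  scores <- kendallTau(x, labels)
  ord <- order(-abs(scores@tau), seq_along(scores@tau))
  list(selected = ord[seq_len(k)], scores = scores)
}

#' Consensus connections across cross-validation folds
#'
#' The consensus functional connectivity is the set of features selected in
#' every cross-validation fold. Each consensus edge is assigned one sign
#' from tau computed on the full sample set: +1 for a connection that
#' increased post-intervention, -1 for a decrease. Per-fold selections are
#' retained for audit.
#'
#' @param perFoldSelections list of integer index sets, one per fold.
#' @param fullTau a [TauScores-class] computed on all samples (see
#'   [kendallTau()]).
#' @return A [ConsensusSet-class].
#' @examples
#' tau <- kendallTau(matrix(rnorm(50), 10, 5), rep(c(1, -1), 5))
#' consensusConnections(list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(2L, 3L)), tau)
#' @export
consensusConnections <- function(perFoldSelections, fullTau) {
  if (!length(perFoldSelections))
    stop("at least one fold is required")
  stopifnot(is(fullTau, "TauScores"))
  cons <- Reduce(intersect, perFoldSelections)
  cons <- sort(as.integer(cons))
  signs <- sign(fullTau@tau[cons])
  signs[signs == 0] <- 1  # tau exactly 0: call it an increase, flagged rare
  new("ConsensusSet", edges = cons, signs = as.numeric(signs),
      perFold = lapply(perFoldSelections, as.integer), fullTau = fullTau)
}
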