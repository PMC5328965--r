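#' Gaussian radial-basis kernel
#'
#' The classifier's kernel, k(x1, x2) = exp(-||x1 - x2||^2 / (2 sigma^2)),
#' with sigma = 2 by default so the exponent is -||x1 - x2||^2 / 8.
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param sigma kernel width (> 0), default 2.
#' @return kernel value in (0, 1]; 1 exactly when `x1 == x2`.
#' @examples
#' rbfKernel(c(0, 0), c(2, 2), sigma = 2)  # exp(-1)
#' @export
rbfKernel <- function(x1, x2, sigma = 2) {
  if (length(x1) != length(x2))
    stop("x1 and x2 must have equal length")
  if (sigma <= 0) stop("sigma must be > 0")
  exp(-sum((x1 - x2)^2) / (2 * sigma^2))
}

#' Fitted RBF support vector classifier
#'
#' The solution of the soft-margin dual: support vectors, their
#' coefficients alpha_j * y_j, and the bias b of the decision function
#' f(x) = sum_j alpha_j y_j k(x_j, x) + b.
#'
#' @slot sv support-vector matrix (rows with alpha > 0).
#' @slot coefs alpha_j * y_j per support vector.
#' @slot alpha full alpha vector over the training samples.
#' @slot b bias term.
#' @slot sigma,C kernel width and soft-margin penalty used.
#' @seealso [trainSvm()], [svmDecision()].
#' @exportClass SvmModel
setClass("SvmModel",
  representation(sv = "matrix", coefs = "numeric", alpha = "numeric",
                 b = "numeric", sigma = "numeric", C = "numeric"))

setMethod("show", "SvmModel", function(object) {
  cat("SvmModel: RBF sigma =", object@sigma, ", C =", object@C, ",",
      nrow(object@sv), "support vectors\n")
})

#' Train a soft-margin RBF-kernel SVM
#'
#' Fits the support vector classifier with the Gaussian kernel of
#' [rbfKernel()] and soft-margin penalty C by sequential minimal
#' optimization of the dual problem (maximal-violating-pair working-set
#' selection). The decision function is
#' f(x) = sum_j alpha_j y_j k(x_j, x) + b with 0 <= alpha_j <= C;
#' predictions are sign(f). Features are used unscaled.
#'
#' @param X samples x features numeric matrix.
#' @param y +1/-1 labels; both classes must be present.
#' @param config an [SvmConfig-class] (its `k` slot is not used here).
#' @return An [SvmModel-class].
#' @examples
#' X <- matrix(c(rnorm(20, -2), rnorm(20, 2)), ncol = 1)
#' fit <- trainSvm(X, rep(c(-1, 1), each = 20), svmConfig(C = 1))
#' table(sign(svmDecision(fit, X)))
#' @export
trainSvm <- function(X, y, config = svmConfig()) {
  stopifnot(is(config, "SvmConfig"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("one label per sample is required")
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L)
    stop("both classes (+1 and -1) must be present")
  if (!all(is.finite(X))) stop("features must be finite")
  fit <- .smoTrain(X, y, C = config@C, gamma = 1 / (2 * config@sigma^2))
  keep <- fit$alpha > 0
  # Class= must be named: the slot named C would otherwise partially match it
  new(Class = "SvmModel", sv = X[keep, , drop = FALSE],
      coefs = (fit$alpha * y)[keep], alpha = fit$alpha, b = fit$b,
      sigma = config@sigma, C = config@C)
}

#' Decision values of a fitted SVM
#'
#' Evaluates the decision function f(x) on new samples; a positive value
#' predicts the +1 (post) class.
#'
#' @param model an [SvmModel-class] from [trainSvm()].
#' @param newX samples x features matrix on the same features.
#' @return numeric decision values; `sign()` of each is the prediction.
#' @export
svmDecision <- function(model, newX) {
  stopifnot(is(model, "SvmModel"))
  newX <- as.matrix(newX)
  sv <- model@sv
  d2 <- outer(rowSums(newX^2), rep(1, nrow(sv))) +
    outer(rep(1, nrow(newX)), rowSums(sv^2)) -
    2 * tcrossprod(newX, sv)
  K <- exp(-pmax(d2, 0) / (2 * model@sigma^2))
  as.numeric(K %*% model@coefs) + model@b
}

#' Classification performance metrics
#'
#' The generalization rate (GR) is the overall proportion of samples
#' correctly predicted; sensitivity is the proportion of +1 (post) samples
#' correctly identified and specificity the proportion of -1 (pre) samples
#' correctly identified. GR = (sensitivity * n_post + specificity * n_pre)/n.
#'
#' @param truth true +1/-1 labels.
#' @param predicted predicted +1/-1 labels.
#' @return named numeric vector: `gr`, `sensitivity`, `specificity`.
#' @examples
#' truth <- rep(c(1, -1), each = 25)
#' pred <- c(rep(1, 19), rep(-1, 6), rep(-1, 17), rep(1, 8))
#' classificationMetrics(truth, pred)  # 0.72, 0.76, 0.68
#' @export
classificationMetrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  c(gr = mean(predicted == truth),
    sensitivity = mean(predicted[truth == 1] == 1),
    specificity = mean(predicted[truth == -1] == -1))
}

# Lean LOOCV engine shared by loocv(), sweepGr() and permutationTest().
# Feature selection (top-k |tau| on the training fold only) is recomputed
# inside every fold unless fixed per-fold selections are supplied. The
# per-fold score n_c - n_d (which ranks identically to |tau|, the
# denominator being constant within a fold) is obtained by a leave-one-out
# decomposition: one full-data pass gives the total signed pair count D and
# each sample's own contribution S[i, ]; dropping sample i drops exactly
# its pairs, so the fold-i score is D - S[i, ].
.loocvCore <- function(X, y, sigma, C, k, selections = NULL) {
  n <- nrow(X)
  gamma <- 1 / (2 * sigma^2)
  pred <- numeric(n)
  dec <- numeric(n)
  sel <- vector("list", n)
  if (is.null(selections)) fs <- .kendallFoldScores(X, as.integer(y))
  for (i in seq_len(n)) {
    trIdx <- seq_len(n)[-i]
    ytr <- y[trIdx]
    if (all(ytr == ytr[1L]))
      stop("a training fold lost one class entirely")
    if (is.null(selections)) {
      score <- fs$D - fs$S[i, ]
      s <- order(-abs(score), seq_along(score))[seq_len(k)]
    } else {
      s <- selections[[i]]
    }
    sel[[i]] <- s
    Xtr <- X[trIdx, s, drop = FALSE]
    fit <- .smoTrain(Xtr, ytr, C = C, gamma = gamma)
    xi <- X[i, s]
    kv <- exp(-gamma * colSums((t(Xtr) - xi)^2))
    d <- sum(fit$alpha * ytr * kv) + fit$b
    dec[i] <- d
    pred[i] <- if (d > 0) 1 else -1
  }
  list(pred = pred, decision = dec, selections = sel)
}

#' Leave-one-out cross-validation with nested feature selection
#'
#' For each sample: hold it out, rank features by Kendall-tau discriminative
#' power on the remaining samples only, keep the top `k`, train the RBF-SVM
#' on those features, and predict the held-out sample. The held-out sample
#' never influences feature ranking or training. A study of 25 subject
#' pairs yields exactly 50 folds. Aggregates GR, sensitivity and
#' specificity over the folds.
#'
#' @param study a [LabeledStudy-class] with at least 4 samples.
#' @param config an [SvmConfig-class]; `config@k` features are selected per
#'   fold (capped at the number of available features).
#' @return A [CVResult-class].
#' @examples
#' study <- generateFeatureDataset(10, 40, informative_idx = 1:5,
#'                                 effect_size = 3, seed = 1)
#' loocv(study, svmConfig(C = 1, k = 10))
#' @export
loocv <- function(study, config = svmConfig()) {
  stopifnot(is(study, "LabeledStudy"), is(config, "SvmConfig"))
  X <- zMatrix(study)
  y <- studyLabels(study)
  if (nrow(X) < 4L) stop("at least 4 samples are required for LOOCV")
  k <- min(config@k, ncol(X))
  res <- .loocvCore(X, y, config@sigma, config@C, k)
  folds <- data.frame(sample = seq_len(nrow(X)),
                      subject = studySubjects(study),
                      truth = y, predicted = res$pred,
                      decision = res$decision)
  new("CVResult", folds = folds, selections = res$selections,
      metrics = classificationMetrics(y, res$pred), config = config)
}

#' Hyperparameter sweep over feature count and soft-margin penalty
#'
#' Repeats the full LOOCV (nested selection included) over a grid of
#' feature counts `kGrid` (default 40 to 300 in steps of 20) and penalties
#' `cGrid` (default 0.005 to 2 in steps of 0.05), and reports the GR
#' surface and the maximising grid point. Ties are resolved toward the
#' smallest k, then the smallest C. The procedure reports the sweep maximum
#' directly, which is optimistic as a performance estimate; it mirrors the
#' way such sweeps are conventionally reported.
#'
#' @param study a [LabeledStudy-class].
#' @param kGrid integer vector of feature counts.
#' @param cGrid numeric vector of penalties.
#' @param sigma RBF kernel width (fixed across the sweep, default 2).
#' @return list with `gr` (matrix, kGrid x cGrid), `best`
#'   (list `k`, `C`, `gr`).
#' @examples
#' study <- generateFeatureDataset(8, 30, informative_idx = 1:5,
#'                                 effect_size = 3, seed = 1)
#' sweepGr(study, kGrid = c(5, 10), cGrid = c(0.01, 1))$best
#' @export
sweepGr <- function(study, kGrid = seq(40L, 300L, by = 20L),
                    cGrid = seq(0.005, 2, by = 0.05), sigma = 2) {
  stopifnot(is(study, "LabeledStudy"))
  if (!length(kGrid) || !length(cGrid)) stop("grids must be non-empty")
  X <- zMatrix(study)
  y <- studyLabels(study)
  kGrid <- pmin(as.integer(kGrid), ncol(X))
  gr <- matrix(NA_real_, length(kGrid), length(cGrid),
               dimnames = list(kGrid, cGrid))
  best <- list(k = NA_integer_, C = NA_real_, gr = -Inf)
  for (a in seq_along(kGrid)) {
    for (b in seq_along(cGrid)) {
      res <- .loocvCore(X, y, sigma, cGrid[b], kGrid[a])
      g <- mean(res$pred == y)
      gr[a, b] <- g
      if (g > best$gr) best <- list(k = kGrid[a], C = cGrid[b], gr = g)
    }
  }
  list(gr = gr, best = best)
}
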