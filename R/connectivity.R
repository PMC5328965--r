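#' Pearson correlation matrix of a regional time series
#'
#' Computes the regions-by-regions Pearson functional-connectivity matrix of
#' a [RoiTimeSeries-class]. The result is exactly symmetric with a unit
#' diagonal.
#'
#' @param ts a [RoiTimeSeries-class] with at least 3 frames.
#' @return A [ConnectivityMatrix-class].
#' @details A region with constant signal has no defined correlation and
#'   raises an error naming the region.
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(300), 50, 6), tr = 2)
#' cm <- correlationMatrix(ts)
#' corMatrix(cm)[1:3, 1:3]
#' @export
correlationMatrix <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  x <- ts@series
  if (nrow(x) < 3L)
    stop("at least 3 frames are required for correlation")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop("constant signal in region(s): ",
         paste(ts@regionIds[sds == 0], collapse = ", "))
  r <- cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(ts@regionIds, ts@regionIds)
  new("ConnectivityMatrix", r = r, regionIds = ts@regionIds)
}

#' Fisher z-transform of correlation coefficients
#'
#' `z = artanh(r)`, the variance-stabilizing transform applied to every
#' connectivity feature before classification. Coefficients with
#' `|r| >= 1 - 1e-7` (degenerate, e.g. a region correlated with itself) are
#' clipped to `1 - 1e-7` in magnitude with a warning so the transform stays
#' finite.
#'
#' @param r numeric vector of correlations, `|r| <= 1`.
#' @return numeric vector of Fisher-z values.
#' @examples
#' fisherZ(c(0, 0.5, tanh(1)))
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1))
    stop("correlations must satisfy |r| <= 1")
  lim <- 1 - 1e-7
  if (any(abs(r) >= lim)) {
    warning("correlation(s) with |r| >= 1 - 1e-7 clipped before Fisher z")
    r <- pmin(pmax(r, -lim), lim)
  }
  atanh(r)
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Extracts the row-major upper triangle (i < j) of a connectivity matrix in
#' the fixed edge order (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R) and
#' applies the Fisher z-transform elementwise, yielding the R(R-1)/2
#' features used throughout the pipeline (6670 for 116 regions).
#'
#' @param m a [ConnectivityMatrix-class], or a numeric matrix that is
#'   symmetric within `tol`.
#' @param tol symmetry tolerance for plain-matrix input.
#' @return A [FeatureVector-class].
#' @examples
#' ts <- RoiTimeSeries(matrix(rnorm(300), 50, 6), tr = 2)
#' fv <- vectorizeUpper(correlationMatrix(ts))
#' length(zValues(fv))  # 6*5/2 = 15
#' @export
vectorizeUpper <- function(m, tol = 1e-8) {
  if (is(m, "ConnectivityMatrix")) {
    r <- m@r
    ids <- m@regionIds
  } else {
    r <- as.matrix(m)
    if (nrow(r) != ncol(r) || max(abs(r - t(r))) > tol)
      stop("input matrix is not symmetric within tolerance")
    ids <- seq_len(nrow(r))
  }
  R <- nrow(r)
  k <- seq_len(R * (R - 1L) / 2L)
  edges <- edgeIndex(k, R)
  vals <- r[cbind(edges[, 1L], edges[, 2L])]
  edges[, 1L] <- ids[edges[, 1L]]
  edges[, 2L] <- ids[edges[, 2L]]
  new("FeatureVector", z = fisherZ(vals), edges = edges,
      nRegions = as.integer(R))
}

#' Edge index conversions
#'
#' The fixed row-major upper-triangle convention maps a feature (edge) index
#' k to the region pair (i, j), i < j, and back. `edgeIndex()` and
#' `pairIndex()` are mutual inverses; both are vectorized.
#'
#' @param k integer feature indices in `1:(R(R-1)/2)`.
#' @param i,j region indices with `1 <= i < j <= R`.
#' @param R number of regions.
#' @return `edgeIndex()`: integer matrix with columns `i`, `j`;
#'   `pairIndex()`: integer vector of feature indices.
#' @examples
#' edgeIndex(1:6, R = 4)
#' pairIndex(3, 4, R = 4)  # 6
#' @export
edgeIndex <- function(k, R) {
  k <- as.integer(k)
  R <- as.integer(R)
  kmax <- R * (R - 1L) / 2L
  if (any(k < 1L | k > kmax))
    stop("edge index out of range 1..", kmax)
  # first edge of row i is at offset (i-1)*R - i*(i+1)/2 + 1... invert by
  # solving the cumulative row lengths (R-1, R-2, ...)
  i <- integer(length(k))
  j <- integer(length(k))
  cum <- cumsum(c(0L, (R - 1L):1L))
  row <- findInterval(k - 1L, cum, rightmost.closed = FALSE)
  i <- row
  j <- k - cum[row] + i
  cbind(i = i, j = j)
}

#' @rdname edgeIndex
#' @export
pairIndex <- function(i, j, R) {
  i <- as.integer(i); j <- as.integer(j); R <- as.integer(R)
  if (any(i < 1L | j <= i | j > R))
    stop("region pair out of range: require 1 <= i < j <= R")
  (i - 1L) * R - (i * (i + 1L)) %/% 2L + j
}
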