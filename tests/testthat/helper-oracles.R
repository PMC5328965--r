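# Independent brute-force oracles, deliberately written as plain pairwise
# enumerations so they share no code path with the package internals.

# Kendall tau over unordered sample pairs with the n^2 denominator:
# concordant when sgn(x_j - x_k) = sgn(y_j - y_k) != 0, discordant when the
# signs are opposite and non-zero; anything involving a zero sign counts as
# neither.
bruteTau <- function(x, y) {
  n <- length(x)
  nc <- 0L
  nd <- 0L
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      sx <- sign(x[j] - x[k])
      sy <- sign(y[j] - y[k])
      if (sx == 0 || sy == 0) next
      if (sx == sy) nc <- nc + 1L else nd <- nd + 1L
    }
  }
  (nc - nd) / n^2
}

# Frame-wise displacement: sum of absolute frame-to-frame differences over
# the six parameters, rotations converted to arc length on a sphere.
bruteFD <- function(params, unit = "radians", radius = 50) {
  rot <- params[, 4:6, drop = FALSE]
  if (unit == "degrees") rot <- rot * pi / 180
  p <- cbind(params[, 1:3, drop = FALSE], rot * radius)
  fd <- numeric(nrow(p))
  for (i in 2:nrow(p)) fd[i] <- sum(abs(p[i, ] - p[i - 1L, ]))
  fd
}

# Decision values from the independent libsvm solver (e1071), oriented so
# positive predicts the +1 class.
libsvmDecision <- function(X, y, newX, sigma, C) {
  m <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)), scale = FALSE,
                  kernel = "radial", gamma = 1 / (2 * sigma^2), cost = C)
  pr <- predict(m, newX, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  if (colnames(dv)[1L] == "-1/1") -dv[, 1L] else dv[, 1L]
}
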