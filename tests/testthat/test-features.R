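test_that("Kendall tau matches brute-force pair enumeration", {
  # closed-form toy: 4 samples, perfectly ordered -> nc = 4, nd = 0
  ts <- kendallTau(c(3, 2, 1, 0), c(1, 1, -1, -1))
  expect_equal(tauValues(ts), 0.25)
  expect_equal(ts@nConcordant, 4)
  expect_equal(ts@nDiscordant, 0)

  # all values tied -> tau 0
  expect_equal(tauValues(kendallTau(rep(1, 6), rep(c(1, -1), 3))), 0)

  # antisymmetry under value negation
  set.seed(11)
  x <- rnorm(12)
  y <- rep(c(1, -1), 6)
  expect_equal(tauValues(kendallTau(-x, y)), -tauValues(kendallTau(x, y)))

  # random instances against the independent oracle, ties included
  for (r in 1:50) {
    n <- sample(4:16, 1)
    x <- sample(1:6, n, replace = TRUE)  # forces value ties
    y <- c(rep(1, 2), rep(-1, 2), sample(c(-1, 1), n - 4, replace = TRUE))
    expect_equal(tauValues(kendallTau(x, y)), bruteTau(x, y))
  }

  expect_error(kendallTau(1:4, rep(1, 4)), "both classes")
})

test_that("tau is invariant under strictly monotone feature transforms", {
  set.seed(12)
  x <- rnorm(20)
  y <- rep(c(1, -1), 10)
  t0 <- tauValues(kendallTau(x, y))
  expect_equal(tauValues(kendallTau(exp(x), y)), t0)
  expect_equal(tauValues(kendallTau(x^3 + 5 * x, y)), t0)
})

test_that("|tau| ranking agrees with an independent Kendall implementation", {
  # on tie-free data the |tau| ranking equals the ranking of |tau-b| from
  # stats::cor, whose denominator differs only by a constant factor here
  set.seed(13)
  for (r in 1:20) {
    n <- 2 * sample(4:10, 1)
    p <- 12
    x <- matrix(rnorm(n * p), n, p)
    y <- sample(rep(c(1, -1), n / 2))
    mine <- abs(tauValues(kendallTau(x, y)))
    ref <- abs(apply(x, 2, function(col) cor(col, y, method = "kendall")))
    expect_identical(order(-mine, seq_len(p)), order(-ref, seq_len(p)))
  }
})

test_that("top-k selection is deterministic with index tie-breaks", {
  x <- cbind(a = c(4, 3, 2, 1), b = c(1, 2, 3, 4), c = c(4, 3, 1, 2))
  y <- c(1, 1, -1, -1)
  sel <- rankAndSelect(x, k = 3, labels = y)
  expect_equal(sort(sel$selected), 1:3)
  # features 1 and 2 tie at |tau| = 0.25; lower index first
  expect_equal(sel$selected[1:2], c(1L, 2L))
  expect_equal(rankAndSelect(x, k = 3, labels = y)$selected, sel$selected)
  expect_error(rankAndSelect(x, k = 0, labels = y), "k must")
  expect_error(rankAndSelect(x, k = 4, labels = y), "k must")
})

test_that("consensus is the intersection of fold selections", {
  set.seed(14)
  tau <- kendallTau(matrix(rnorm(60), 10, 6), rep(c(1, -1), 5))
  cs <- consensusConnections(list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(2L, 3L)),
                             tau)
  expect_identical(consensusEdges(cs), c(2L, 3L))
  expect_equal(edgeSigns(cs), sign(tauValues(tau))[2:3])

  # identical selections reproduce the selection
  same <- consensusConnections(list(c(5L, 1L), c(1L, 5L)), tau)
  expect_identical(consensusEdges(same), c(1L, 5L))

  # one fold missing an edge excludes it
  drop <- consensusConnections(list(c(1L, 2L), c(2L)), tau)
  expect_identical(consensusEdges(drop), 2L)

  expect_error(consensusConnections(list(), tau), "at least one fold")
})

test_that("region weights are consensus-graph degrees", {
  tau <- kendallTau(matrix(rnorm(24), 4, 6), c(1, 1, -1, -1))
  # edges 1 and 2 at R = 4 are (1,2) and (1,3)
  cs <- consensusConnections(list(c(1L, 2L)), tau)
  w <- regionWeights(cs, nRegions = 4)
  expect_equal(unname(w), c(2, 1, 1, 0))

  empty <- consensusConnections(list(integer(0)), tau)
  expect_equal(unname(regionWeights(empty, 4)), rep(0, 4))

  # handshake lemma on random consensus sets
  set.seed(15)
  tau10 <- kendallTau(matrix(rnorm(4 * 45), 4, 45), c(1, 1, -1, -1))
  for (r in 1:10) {
    sel <- sort(sample(45, sample(1:20, 1)))
    cs <- consensusConnections(list(sel), tau10)
    expect_equal(sum(regionWeights(cs, 10)), 2 * length(sel))
  }
})
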