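test_that("autoscale centers, scales and round-trips", {
  m <- cbind(f1 = c(1, 2, 3), f2 = c(10, 10, 10))
  rownames(m) <- c("s1", "s2", "s3")
  sc <- autoscale(m, logTransform = FALSE)
  expect_equal(unname(sc@values[, "f1"]), c(-1, 0, 1))  # sample sd = 1
  expect_equal(unname(sc@values[, "f2"]), c(0, 0, 0))
  expect_equal(sc@constantFeatures, "f2")
  expect_equal(sc@scale[["f2"]], 1)
  expect_equal(inverseScaling(sc), m)
  expect_equal(applyScaling(sc, m), sc@values)
  scLog <- autoscale(m, logTransform = TRUE)
  expect_equal(inverseScaling(scLog), m, tolerance = 1e-8)
})

test_that("autoscale refuses incomplete matrices", {
  m <- cbind(f1 = c(1, NA, 3))
  expect_error(autoscale(m), "complete")
})

test_that("a perfect single-feature predictor gives R2Y = 1", {
  y <- rep(c("A", "B"), each = 6)
  yc <- as.numeric(y == "B") - 0.5
  X <- cbind(f1 = yc)
  fit <- fitPLSDA(X, y, A = 1)
  expect_equal(fit@r2y[1], 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(fit@weights[, 1]^2)), 1, tolerance = 1e-12)
})

test_that("three-class PLS-DA separates planted groups in score space", {
  set.seed(2)
  n <- 20; p <- 15
  y <- rep(c("CN", "MCI", "AD"), each = n)
  X <- matrix(rnorm(3 * n * p), 3 * n, p)
  X[y == "MCI", 1] <- X[y == "MCI", 1] + 4
  X[y == "AD", 2] <- X[y == "AD", 2] + 4
  fit <- fitPLSDA(autoscale(X, logTransform = FALSE), y, A = 2)
  expect_equal(ncol(fit@yLoadings), 2)
  expect_equal(nrow(fit@yLoadings), 3)
  # cumulative R2 are within [0,1] and non-decreasing
  expect_true(all(diff(fit@r2x) >= 0) && all(diff(fit@r2y) >= 0))
  expect_true(all(fit@r2x >= 0 & fit@r2x <= 1))
  # group centroids in the 2-D score space are mutually well separated
  cent <- apply(fit@scores, 2, tapply, y, mean)
  dists <- as.matrix(dist(cent))
  within <- mean(apply(fit@scores, 2, tapply, y, sd))
  expect_gt(min(dists[upper.tri(dists)]), 2 * within)
})

test_that("A beyond the rank of X is rejected", {
  X <- cbind(f1 = rnorm(10), f2 = rnorm(10))
  y <- rep(c("A", "B"), 5)
  expect_error(fitPLSDA(X, y, A = 3), "rank")
  expect_error(fitOPLSDA(X, y, nOrtho = 2), "rank")
})

test_that("OPLS-DA with no orthogonal component equals the first PLS
           component", {
  d <- twoClassData(n1 = 15, n2 = 15, p = 12, nSignal = 4, shift = 1.5,
                    seed = 3)
  sc <- autoscale(d$X, logTransform = FALSE)
  opls <- fitOPLSDA(sc, d$y, nOrtho = 0)
  pls <- fitPLSDA(sc, d$y, A = 1)
  tp <- opls@predictiveScores
  t1 <- pls@scores[, 1]
  if (cor(tp, t1) < 0) t1 <- -t1   # sign alignment
  expect_lt(max(abs(tp - t1)), 1e-8)
})

test_that("an orthogonal nuisance direction is absorbed by the orthogonal
           component", {
  set.seed(4)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  yc <- as.numeric(y == "B") - 0.5
  z <- rnorm(n); z <- z - mean(z)
  z <- z - yc * sum(z * yc) / sum(yc^2)      # z strictly orthogonal to y
  X <- cbind(f1 = yc + z, f2 = z)            # nuisance z contaminates f1
  fit <- fitOPLSDA(X, y, nOrtho = 1)
  expect_gt(abs(cor(fit@predictiveScores, yc)), 1 - 1e-8)
  expect_lt(abs(cor(fit@predictiveScores, fit@orthoScores[, 1])), 1e-8)
  expect_gt(fit@r2y, 1 - 1e-8)
})

test_that("VIP closed forms and the normalisation identity hold", {
  # two features, predictive weight (1, 0) -> VIP (sqrt(2), 0)
  y <- rep(c("A", "B"), each = 10)
  yc <- as.numeric(y == "B") - 0.5
  set.seed(6)
  X <- cbind(f1 = yc, f2 = rnorm(20))
  X[, 2] <- X[, 2] - mean(X[, 2])
  X[, 2] <- X[, 2] - yc * sum(X[, 2] * yc) / sum(yc^2)
  fit <- fitOPLSDA(X, y, nOrtho = 0)
  expect_equal(unname(vipScores(fit)), c(sqrt(2), 0), tolerance = 1e-8)
  # random fits: mean(VIP^2) = 1 and w unit norm
  for (s in 1:5) {
    d <- twoClassData(p = 11, nSignal = 3, seed = s)
    m <- fitOPLSDA(autoscale(d$X, logTransform = FALSE), d$y, nOrtho = 1)
    expect_equal(mean(vipScores(m)^2), 1, tolerance = 1e-8)
    expect_equal(sum(m@predictiveWeights^2), 1, tolerance = 1e-8)
  }
})

test_that("predictive and orthogonal scores are mutually orthogonal", {
  d <- twoClassData(n1 = 25, n2 = 25, p = 30, nSignal = 5, seed = 7)
  fit <- fitOPLSDA(autoscale(d$X, logTransform = FALSE), d$y, nOrtho = 3)
  for (h in 1:3) {
    expect_lt(abs(cor(fit@predictiveScores, fit@orthoScores[, h])), 1e-8)
    for (g in seq_len(h - 1))
      expect_lt(abs(cor(fit@orthoScores[, g], fit@orthoScores[, h])),
                1e-6)
  }
})

test_that("the case class takes positive predictive scores", {
  d <- twoClassData(seed = 8)
  fit <- fitOPLSDA(autoscale(d$X, logTransform = FALSE), d$y,
                   classes = c("A", "B"))
  expect_gt(mean(fit@predictiveScores[d$y == "B"]),
            mean(fit@predictiveScores[d$y == "A"]))
})

test_that("Q2 is high for separable data, <= 0 for shuffled labels, and
           never exceeds R2Y", {
  d <- twoClassData(n1 = 30, n2 = 30, p = 20, nSignal = 8, shift = 4,
                    seed = 9)
  q2 <- q2CrossValidate(d$X + 10, d$y, nOrtho = 1, seed = 1,
                        logTransform = FALSE)
  expect_gt(q2, 0.9)
  fit <- fitOPLSDA(autoscale(d$X + 10, logTransform = FALSE), d$y,
                   nOrtho = 1)
  expect_lte(q2, fit@r2y)
  # label shuffles: Q2 <= 0 on average
  set.seed(10)
  q2null <- replicate(30, {
    yPerm <- sample(d$y)
    q2CrossValidate(d$X + 10, yPerm, nOrtho = 1,
                    seed = sample.int(1e6, 1), logTransform = FALSE)
  })
  expect_lt(mean(q2null), 0)
})

test_that("Q2 errors helpfully when a class is smaller than the fold
           count", {
  d <- twoClassData(n1 = 5, n2 = 30, seed = 11)
  expect_error(q2CrossValidate(d$X, d$y, folds = 7, logTransform = FALSE),
               "fewer")
})

test_that("permutation p-values respect their bounds and attain the
           minimum on separable data", {
  d <- twoClassData(n1 = 15, n2 = 15, p = 10, nSignal = 5, shift = 4,
                    seed = 12)
  res <- permutationTest(d$X + 10, d$y, nOrtho = 0, nPerm = 49,
                         seed = 13, logTransform = FALSE)
  expect_equal(res$pQ2, 1 / 50)
  expect_gte(res$pR2, 1 / 50)
  expect_lte(res$pR2, 1)
  expect_length(res$nullQ2, 49)
  expect_true(all(res$nullQ2 <= res$observedQ2))
  expect_error(permutationTest(d$X, d$y, nPerm = 0), "nPerm")
})

test_that("NIPALS PLS-DA scores match an independent implementation", {
  d <- twoClassData(n1 = 12, n2 = 12, p = 8, nSignal = 3, seed = 14)
  sc <- autoscale(d$X, logTransform = FALSE)
  mine <- fitPLSDA(sc, d$y, A = 2)
  ref <- mixOmics::plsda(sc@values, factor(d$y), ncomp = 2,
                         scale = FALSE)
  for (a in 1:2) {
    r <- abs(cor(mine@scores[, a], ref$variates$X[, a]))
    expect_gt(r, 1 - 1e-6)
  }
})
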