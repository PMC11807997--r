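qcFixture <- function() {
  # features with QC CV 0, 1/3, exactly 0.30, and undefined (one value)
  m <- rbind(
    neg_a = c(10, 12, 100, 100, 100),
    neg_b = c(10, 12, 100, 150, 200),
    neg_c = c(10, 12, 70, 100, 130),
    neg_d = c(10, 12, NA, NA, 50))
  colnames(m) <- c("s1", "s2", "QC1", "QC2", "QC3")
  tinySet(m, c("CN", "AD", "QC", "QC", "QC"))
}

test_that("QC CV filter uses sample sd with a strict threshold", {
  res <- cvFilter(qcFixture(), threshold = 0.30)
  rep <- res$report
  expect_equal(rep$cv[rep$feature_id == "neg_a"], 0)
  expect_equal(rep$cv[rep$feature_id == "neg_b"], 50 / 150,
               tolerance = 1e-12)
  expect_equal(rep$cv[rep$feature_id == "neg_c"], 0.30, tolerance = 1e-12)
  expect_true(is.na(rep$cv[rep$feature_id == "neg_d"]))
  # CV = 1/3 > 0.30 excluded; CV exactly 0.30 retained ("over 30%")
  expect_setequal(rownames(res$table), c("neg_a", "neg_c"))
  # undefined CV excluded
  expect_false("neg_d" %in% rownames(res$table))
})

test_that("filtering is idempotent and never alters retained values", {
  x <- qcFixture()
  r1 <- cvFilter(x)
  r2 <- cvFilter(r1$table)
  expect_identical(intensities(r2$table), intensities(r1$table))
  expect_identical(intensities(r1$table),
                   intensities(x)[rownames(r1$table), ])
})

test_that("fewer than two QC samples is an error", {
  m <- matrix(1:4 * 1.0, 2, 2,
              dimnames = list(c("neg_1", "neg_2"), c("s1", "QC1")))
  x <- tinySet(m, c("CN", "QC"))
  expect_error(cvFilter(x), "2 QC")
})

test_that("neighbour count k is 10% of the group size, round half up", {
  set.seed(5)
  mkGroup <- function(n, g) {
    m <- matrix(100 + rnorm(n * 4), 4, n,
                dimnames = list(sprintf("neg_%d", 1:4),
                                sprintf("%s%02d", g, 1:n)))
    m[1, 1] <- NA
    tinySet(m, rep(g, n))
  }
  r10 <- knnImpute(mkGroup(10, "CN"), fraction = 0.10)
  expect_equal(r10$report$k, 1L)
  r15 <- knnImpute(mkGroup(15, "CN"), fraction = 0.10)  # 1.5 rounds up
  expect_equal(r15$report$k, 2L)
  r4 <- knnImpute(mkGroup(4, "CN"), fraction = 0.10)    # floor of 1
  expect_equal(r4$report$k, 1L)
})

test_that("k = 1 copies the nearest neighbour's value", {
  m <- rbind(neg_1 = c(NA, 50, 400),
             neg_2 = c(7, 7, 300),
             neg_3 = c(9, 9, 500))
  colnames(m) <- c("t", "near", "far")
  x <- tinySet(m, rep("CN", 3))
  out <- knnImpute(x, fraction = 0.3)  # k = 1
  expect_equal(intensities(out$table)["neg_1", "t"], 50)
})

test_that("k = 2 averages two equidistant neighbours", {
  m <- rbind(neg_1 = c(NA, 10, 20),
             neg_2 = c(5, 6, 4),
             neg_3 = c(8, 9, 7))
  colnames(m) <- c("t", "n1", "n2")  # both neighbours distance sqrt(2)/...
  x <- tinySet(m, rep("CN", 3))
  out <- knnImpute(x, fraction = 0.67)  # k = 2
  expect_equal(intensities(out$table)["neg_1", "t"], 15)
})

test_that("imputation completes the matrix without touching observed cells", {
  co <- generateCohort(smallDesign())
  filt <- cvFilter(co$negative)$table
  out <- knnImpute(filt)
  m0 <- intensities(filt); m1 <- intensities(out$table)
  expect_false(anyNA(m1))
  obs <- !is.na(m0)
  expect_identical(m1[obs], m0[obs])
  expect_equal(sum(out$report$n_imputed), sum(is.na(m0)))
})

test_that("a feature missing in an entire group is an error", {
  m <- rbind(neg_1 = c(NA, NA, 5), neg_2 = c(1, 2, 3))
  colnames(m) <- c("a", "b", "c")
  x <- tinySet(m, c("CN", "CN", "AD"))
  expect_error(knnImpute(x), "neg_1")
  expect_error(knnImpute(x), "CN")
})

test_that("high-technical-CV features are filtered with high frequency", {
  # aggregate over enough unreliable features that the >=95% exclusion
  # frequency at nQC = 20 is identifiable
  excluded <- total <- 0
  for (s in 1:4) {
    co <- generateCohort(smallDesign(nFeaturesNeg = 150, nFeaturesPos = 40,
                                     propHighCV = 0.3, seed = s))
    res <- cvFilter(co$negative)
    bad <- intersect(co$truth@qcExcludedFeatures, rownames(co$negative))
    total <- total + length(bad)
    excluded <- excluded + sum(!bad %in% rownames(res$table))
  }
  expect_gte(total, 100)
  expect_gte(excluded / total, 0.95)
})

test_that("KNN beats mean imputation on correlated data", {
  # two sample clusters with distinct profiles; MCAR 10%
  set.seed(42)
  p <- 30; n <- 20
  centers <- cbind(matrix(100, p, n / 2), matrix(200, p, n / 2))
  m <- centers + matrix(rnorm(p * n, 0, 5), p, n)
  dimnames(m) <- list(sprintf("neg_%02d", 1:p), sprintf("s%02d", 1:n))
  mask <- matrix(runif(p * n) < 0.10, p, n)
  # keep every feature observed somewhere in the group
  mask[, 1] <- FALSE
  holey <- m; holey[mask] <- NA
  x <- tinySet(holey, rep("CN", n))
  imp <- intensities(knnImpute(x, fraction = 0.10)$table)
  rmseKnn <- sqrt(mean((imp[mask] - m[mask])^2))
  meanImp <- holey
  for (i in seq_len(p))
    meanImp[i, is.na(meanImp[i, ])] <- mean(holey[i, ], na.rm = TRUE)
  rmseMean <- sqrt(mean((meanImp[mask] - m[mask])^2))
  expect_lt(rmseKnn, rmseMean)
})
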