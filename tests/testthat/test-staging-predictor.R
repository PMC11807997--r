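# fixtures: a strongly separable two-group cohort and a null cohort
stagingFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generateCohort(smallDesign(seed = 55))
      prep <- lapply(list(negative = co$negative, positive = co$positive),
                     preprocessTable)
      tabs <- lapply(prep, function(p) p$table[, !isQC(p$table)])
      scr <- screenComparison(tabs, "CN-AD")
      cache <<- list(cohort = co, tables = tabs, screen = scr)
    }
    cache
  }
})

test_that("a perfectly separating feature dominates the tree ranking", {
  set.seed(61)
  n <- 30
  y <- rep(c("CN", "AD"), each = n)
  m <- matrix(rlnorm(20 * 2 * n, 5, 0.3), 20, 2 * n,
              dimnames = list(sprintf("neg_%04d", 1:20),
                              sprintf("s%03d", seq_len(2 * n))))
  m["neg_0001", y == "AD"] <- m["neg_0001", y == "AD"] * 20  # clean split
  tabs <- list(negative = tinySet(m, y))
  rec <- data.frame(feature_id = rownames(m), comparison = "CN-AD",
                    status = "up", p_value = 0.01,
                    vip = 1.5)
  panel <- selectKeyPanel(rec, tabs, "CN-AD", nKeys = 5)
  expect_equal(panel$feature_id[1], "neg_0001")
  expect_gt(panel$importance[1], max(panel$importance[-1]))
})

test_that("fewer differential features than the panel size warns and
           returns them all", {
  sc <- stagingFixture()
  rec <- sc$screen$records[sc$screen$records$status != "ns", ][1:4, ]
  rec$status <- "up"
  expect_warning(panel <- selectKeyPanel(rec, sc$tables, "CN-AD",
                                         nKeys = 10),
                 "smaller")
  expect_equal(sort(panel$feature_id), sort(rec$feature_id))
  expect_error(selectKeyPanel(rec[0, ], sc$tables, "CN-AD"),
               "no differential")
})

test_that("panel selection is deterministic and tree-first", {
  sc <- stagingFixture()
  p1 <- selectKeyPanel(sc$screen$records, sc$tables, "CN-AD", seed = 9)
  p2 <- selectKeyPanel(sc$screen$records, sc$tables, "CN-AD", seed = 9)
  expect_identical(p1, p2)
  expect_lte(nrow(p1), 10)
  expect_true(!is.unsorted(rev(p1$importance[p1$source == "tree"])))
})

test_that("ridge-logistic matches glm when the penalty is negligible", {
  set.seed(62)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n))
  eta <- 0.5 + 1.2 * X[, 1] - 0.7 * X[, 2]
  y01 <- rbinom(n, 1, plogis(eta))
  mine <- metaboStage:::.ridgeLogistic(X, y01, lambda = 1e-10)
  ref <- coef(glm(y01 ~ X, family = binomial()))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("a separable panel yields saturated probabilities yet finite
           coefficients", {
  set.seed(63)
  n <- 20
  y <- rep(c("CN", "AD"), each = n)
  m <- matrix(rlnorm(5 * 2 * n, 5, 0.2), 5, 2 * n,
              dimnames = list(sprintf("neg_%04d", 1:5),
                              sprintf("s%03d", seq_len(2 * n))))
  m["neg_0001", y == "AD"] <- m["neg_0001", y == "AD"] * 15
  tabs <- list(negative = tinySet(m, y))
  mod <- fitStagingModel("neg_0001", tabs, "CN-AD")
  expect_true(all(is.finite(mod@coefficients)))
  pm <- metaboStage:::.panelMatrix("neg_0001", tabs, "CN-AD")
  prob <- predictStaging(mod, pm$X)
  expect_true(all(prob[pm$y == "AD"] >= 0.99))
  expect_true(all(prob[pm$y == "CN"] <= 0.01))
})

test_that("staging coefficients are invariant to feature order", {
  sc <- stagingFixture()
  panel <- selectKeyPanel(sc$screen$records, sc$tables, "CN-AD")
  m1 <- fitStagingModel(panel$feature_id, sc$tables, "CN-AD")
  m2 <- fitStagingModel(rev(panel$feature_id), sc$tables, "CN-AD")
  expect_equal(m1@coefficients[names(m2@coefficients)], m2@coefficients,
               tolerance = 1e-8)
})

test_that("AUC matches the hand example and the pair-counting oracle", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(rocAuc(c(1, 2, 3, 10), c("a", "a", "b", "b"))$auc, 1.0)
  expect_equal(rocAuc(rep(0.5, 8), rep(c("a", "b"), 4))$auc, 0.5)
  set.seed(64)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    labels <- sample(c("ctl", "case"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # with ties
    expect_equal(rocAuc(scores, labels, classes = c("ctl", "case"))$auc,
                 aucPairOracle(scores, labels, "case"),
                 tolerance = 1e-12)
  }
})

test_that("our AUC agrees with pROC", {
  set.seed(65)
  scores <- round(runif(40), 2)
  labels <- rbinom(40, 1, plogis(3 * scores - 1.5))
  if (length(unique(labels)) == 2) {
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(rocAuc(scores, labels, classes = c("0", "1"))$auc, ref,
                 tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone with AUC in [0, 1]", {
  set.seed(66)
  r <- rocAuc(rnorm(30), rbinom(30, 1, 0.5))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  expect_error(rocAuc(1:5, rep("a", 5)), "both classes")
})

test_that("resampling validation: separable data gives AUC 1, null data
           centers on 0.5", {
  # separable
  set.seed(67)
  n <- 20
  y <- rep(c("CN", "AD"), each = n)
  m <- matrix(rlnorm(4 * 2 * n, 5, 0.2), 4, 2 * n,
              dimnames = list(sprintf("neg_%04d", 1:4),
                              sprintf("s%03d", seq_len(2 * n))))
  m["neg_0001", y == "AD"] <- m["neg_0001", y == "AD"] * 15
  tabs <- list(negative = tinySet(m, y))
  res <- randomSamplingValidation("neg_0001", tabs, "CN-AD",
                                  nResamples = 25, seed = 1)
  expect_true(all(res$auc == 1))
  # null: labels independent of intensities
  mNull <- matrix(rlnorm(10 * 60, 5, 0.3), 10, 60,
                  dimnames = list(sprintf("neg_%04d", 1:10),
                                  sprintf("s%03d", 1:60)))
  tabsNull <- list(negative = tinySet(mNull, rep(c("CN", "AD"), 30)))
  resNull <- randomSamplingValidation(rownames(mNull)[1:5], tabsNull,
                                      "CN-AD", nResamples = 60, seed = 2)
  expect_gt(attr(resNull, "mean_auc"), 0.4)
  expect_lt(attr(resNull, "mean_auc"), 0.6)
  # determinism
  resAgain <- randomSamplingValidation(rownames(mNull)[1:5], tabsNull,
                                       "CN-AD", nResamples = 60, seed = 2)
  expect_identical(resNull, resAgain)
})

test_that("groups too small for a stratified split are rejected", {
  m <- matrix(rlnorm(3 * 6, 5, 0.2), 3, 6,
              dimnames = list(sprintf("neg_%d", 1:3),
                              sprintf("s%d", 1:6)))
  tabs <- list(negative = tinySet(m, rep(c("CN", "AD"), c(3, 3))))
  expect_error(randomSamplingValidation("neg_1", tabs, "CN-AD"),
               "too small")
  expect_error(fitStagingModel("neg_9", tabs, "CN-AD"), "neg_9")
})
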