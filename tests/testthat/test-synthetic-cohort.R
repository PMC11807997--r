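test_that("identical designs generate identical cohorts", {
  a <- generateCohort(smallDesign())
  b <- generateCohort(smallDesign())
  expect_identical(intensities(a$negative), intensities(b$negative))
  expect_identical(intensities(a$positive), intensities(b$positive))
  expect_identical(a$metadata, b$metadata)
  expect_identical(pathwaySets(a$pathways), pathwaySets(b$pathways))
  c <- generateCohort(smallDesign(seed = 8))
  expect_false(identical(intensities(a$negative), intensities(c$negative)))
})

test_that("default design reproduces the staged cohort sizes", {
  co <- generateCohort(CohortDesign(seed = 3))
  counts <- table(co$metadata$group[!co$metadata$is_qc])
  expect_equal(unname(counts["CN"]), 62, ignore_attr = TRUE)
  expect_equal(unname(counts["MCI"]), 43, ignore_attr = TRUE)
  expect_equal(unname(counts["AD"]), 57, ignore_attr = TRUE)
  expect_equal(ncol(co$negative), 162 + 20)
})

test_that("planted fold changes are realised in expectation", {
  des <- CohortDesign(
    groupSizes = c(CN = 500, MCI = 5, AD = 500),
    nFeaturesNeg = 10, nFeaturesPos = 10, nQC = 3,
    propHighCV = 0, missingRateRandom = 0, censorProb = 0,
    plantedEffects = data.frame(feature_id = c("neg_0001", "pos_0002"),
                                comparison = "CN-AD",
                                fold_change = c(2.0, 0.5)),
    seed = 99)
  co <- generateCohort(des)
  g <- sampleGroups(co$negative)
  for (tab in list(co$negative, co$positive)) {
    m <- intensities(tab)
    planted <- intersect(rownames(m), c("neg_0001", "pos_0002"))
    fcTrue <- c(neg_0001 = 2.0, pos_0002 = 0.5)[planted]
    fcObs <- rowMeans(m[planted, g == "AD", drop = FALSE]) /
      rowMeans(m[planted, g == "CN", drop = FALSE])
    expect_equal(unname(fcObs), unname(fcTrue), tolerance = 0.05)
    # a non-planted feature stays at ratio ~1
    null <- setdiff(rownames(m), planted)[1]
    expect_equal(mean(m[null, g == "AD"]) / mean(m[null, g == "CN"]), 1,
                 tolerance = 0.1)
  }
})

test_that("truth registry is complete and disjoint from noise", {
  co <- generateCohort(smallDesign())
  allIds <- c(rownames(co$negative), rownames(co$positive))
  plantedIds <- unlist(lapply(co$truth@differentialFeatures,
                              function(d) d$feature_id))
  expect_true(all(plantedIds %in% allIds))
  expect_length(intersect(plantedIds, co$truth@qcExcludedFeatures), 0)
  expect_true(all(co$truth@enrichedPathways %in% names(co$pathways)))
})

test_that("planted pathways hold the configured excess of planted features", {
  co <- generateCohort(smallDesign())
  sets <- pathwaySets(co$pathways)
  bgSets <- sets[grep("^path_bg", names(sets))]
  for (comp in names(co$truth@enrichedPathways)) {
    pid <- co$truth@enrichedPathways[[comp]]
    planted <- co$truth@differentialFeatures[[comp]]$feature_id
    enrRate <- length(intersect(sets[[pid]], planted)) /
      length(sets[[pid]])
    expect_gte(length(intersect(sets[[pid]], planted)), 5)
    bgRate <- mean(vapply(bgSets, function(s)
      length(intersect(s, planted)) / length(s), numeric(1)))
    expect_gt(enrRate, bgRate + 0.2)   # clear excess over background
  }
})

test_that("QC replicates reproduce the requested technical CV", {
  m <- matrix(rep(c(1000, 200), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("neg_1", "neg_2"), sprintf("s%d", 1:4)))
  x <- tinySet(m, rep("CN", 4))
  # zero CV: replicates identical to the pooled mean
  z <- generateQCReplicates(x, nQC = 5, technicalCV = 0, seed = 1)
  qc <- intensities(z)[, isQC(z)]
  expect_equal(unname(qc), matrix(c(1000, 200), 2, 5), ignore_attr = TRUE)
  # cv = 0.5 at n = 1000 replicates: sample CV within 10%
  z2 <- generateQCReplicates(x, nQC = 1000, technicalCV = c(0.5, 0.1),
                             seed = 2)
  qc2 <- intensities(z2)[, isQC(z2)]
  cv <- apply(qc2, 1, sd) / rowMeans(qc2)
  expect_equal(unname(cv[1]), 0.5, tolerance = 0.10)
  expect_equal(unname(cv[2]), 0.1, tolerance = 0.10)
  expect_equal(unname(rowMeans(qc2)), c(1000, 200), tolerance = 0.05)
})

test_that("a single QC replicate is rejected (CV undefined)", {
  m <- matrix(1:4 * 1.0, 2, 2,
              dimnames = list(c("neg_1", "neg_2"), c("s1", "s2")))
  x <- tinySet(m, rep("CN", 2))
  expect_error(generateQCReplicates(x, nQC = 1, technicalCV = 0.1),
               "undefined")
})

test_that("invalid design fields are rejected naming the field", {
  expect_error(CohortDesign(groupSizes = c(CN = 0, MCI = 43, AD = 57)),
               "groupSizes")
  expect_error(CohortDesign(missingRateRandom = 1.5), "missingRateRandom")
  expect_error(CohortDesign(plantedEffects = data.frame(
    feature_id = "neg_0001", comparison = "CN-AD", fold_change = -2)),
    "plantedEffects")
  expect_error(CohortDesign(plantedEffects = data.frame(
    feature_id = "neg_0001", comparison = "AD-CN", fold_change = 2)),
    "plantedEffects")
})
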