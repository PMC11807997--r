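# Synthetic staged-cohort generator with planted ground truth.
#
# Feature intensities are log-normal: each feature draws a log-mean from
# N(baselineLogMean, featureLogSd) and each biological sample adds
# N(0, baselineLogSd) noise on the log scale. A planted effect for a
# comparison adds log(FC) to the case group's log-mean, so the ratio of
# group mean intensities equals FC exactly in expectation. Pooled-QC
# replicates are drawn log-normally around the pooled biological mean with
# the feature's technical CV (the log-normal sdlog is chosen so mean and CV
# are exact). Missingness is MCAR plus left-censoring below a global
# intensity quantile, injected after intensity generation.

#' CohortDesign: parameters of a synthetic staged metabolomics cohort
#'
#' @slot groupSizes named integer c(CN=, MCI=, AD=) biological group sizes.
#' @slot nFeaturesNeg,nFeaturesPos feature counts per ion mode.
#' @slot nQC pooled-QC replicate count (>= 2).
#' @slot baselineLogMean mean of feature log-intensities (natural log).
#' @slot featureLogSd between-feature spread of log-means.
#' @slot baselineLogSd within-group biological log-sd.
#' @slot technicalCVRange uniform range of technical CV for well-behaved
#'   features.
#' @slot highCVRange uniform range for unreliable features (above the 0.30
#'   QC exclusion threshold).
#' @slot propHighCV fraction of features drawn from \code{highCVRange}.
#' @slot plantedEffects data.frame(feature_id, comparison, fold_change);
#'   fold changes act multiplicatively on the raw-intensity scale.
#' @slot missingRateRandom MCAR missingness rate.
#' @slot missingIntensityQuantile global intensity quantile below which
#'   values are preferentially censored.
#' @slot censorProb probability that a below-threshold value is censored.
#' @slot nPathways,pathwaySize,plantedPerPathway pathway-map structure: one
#'   enriched pathway per planted comparison, each seeded with
#'   \code{plantedPerPathway} of that comparison's planted features.
#' @slot seed RNG seed; identical designs generate byte-identical cohorts.
#' @aliases CohortDesign-class
#' @exportClass CohortDesign
setClass("CohortDesign",
         representation(groupSizes = "integer", nFeaturesNeg = "integer",
                        nFeaturesPos = "integer", nQC = "integer",
                        baselineLogMean = "numeric", featureLogSd = "numeric",
                        baselineLogSd = "numeric",
                        technicalCVRange = "numeric", highCVRange = "numeric",
                        propHighCV = "numeric", plantedEffects = "data.frame",
                        missingRateRandom = "numeric",
                        missingIntensityQuantile = "numeric",
                        censorProb = "numeric", nPathways = "integer",
                        pathwaySize = "integer",
                        plantedPerPathway = "integer", seed = "integer"))

setValidity("CohortDesign", function(object) {
  bad <- function(field, why) paste0("invalid '", field, "': ", why)
  msg <- character()
  if (!identical(sort(names(object@groupSizes)), c("AD", "CN", "MCI")))
    msg <- c(msg, bad("groupSizes", "must be named CN, MCI, AD"))
  if (any(object@groupSizes <= 0L))
    msg <- c(msg, bad("groupSizes", "all counts must be > 0"))
  for (field in c("nFeaturesNeg", "nFeaturesPos", "nQC", "nPathways",
                  "pathwaySize", "plantedPerPathway"))
    if (slot(object, field) <= 0L)
      msg <- c(msg, bad(field, "must be > 0"))
  if (object@nQC < 2L) msg <- c(msg, bad("nQC", "need >= 2 QC replicates"))
  for (field in c("missingRateRandom", "missingIntensityQuantile",
                  "censorProb", "propHighCV"))
    if (slot(object, field) < 0 || slot(object, field) > 1)
      msg <- c(msg, bad(field, "rate must be in [0, 1]"))
  pe <- object@plantedEffects
  if (nrow(pe)) {
    if (!all(c("feature_id", "comparison", "fold_change") %in% names(pe)))
      msg <- c(msg, bad("plantedEffects",
                        "needs feature_id, comparison, fold_change"))
    else {
      if (any(pe$fold_change <= 0))
        msg <- c(msg, bad("plantedEffects", "fold changes must be > 0"))
      if (!all(pe$comparison %in% stageComparisons()))
        msg <- c(msg, bad("plantedEffects", "unknown comparison name"))
    }
  }
  if (any(object@technicalCVRange < 0) || any(object@highCVRange < 0))
    msg <- c(msg, bad("technicalCVRange", "CV must be >= 0"))
  if (length(msg)) msg else TRUE
})

#' Construct a CohortDesign
#'
#' Defaults emulate the staged urine-metabolomics study design: biological
#' groups of 62 CN / 43 MCI / 57 AD, two independent ion-mode tables of 100
#' features each with disjoint \code{"neg_"}/\code{"pos_"} ids, 20 pooled-QC
#' replicates, about 10\% of features technically unreliable (QC CV above
#' 0.30), and 20 planted differential features per pairwise comparison at
#' fold changes 2.0 (up) and 0.5 (down).
#'
#' @param groupSizes named vector c(CN=, MCI=, AD=).
#' @param nFeaturesNeg,nFeaturesPos features per ion mode.
#' @param nQC pooled-QC replicates.
#' @param baselineLogMean,featureLogSd,baselineLogSd log-normal intensity
#'   parameters (natural log scale).
#' @param technicalCVRange,highCVRange,propHighCV technical-CV model.
#' @param plantedEffects planted differential features; see
#'   \code{\link{defaultPlantedEffects}}.
#' @param missingRateRandom,missingIntensityQuantile,censorProb missingness
#'   model.
#' @param nPathways,pathwaySize,plantedPerPathway pathway-map structure.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{CohortDesign}.
#' @export
CohortDesign <- function(groupSizes = c(CN = 62, MCI = 43, AD = 57),
                         nFeaturesNeg = 100, nFeaturesPos = 100,
                         nQC = 20,
                         baselineLogMean = log(1e5), featureLogSd = 1.5,
                         baselineLogSd = 0.4,
                         technicalCVRange = c(0.05, 0.20),
                         highCVRange = c(0.40, 0.70),
                         propHighCV = 0.10,
                         plantedEffects = defaultPlantedEffects(
                           nFeaturesNeg, nFeaturesPos),
                         missingRateRandom = 0.02,
                         missingIntensityQuantile = 0.05,
                         censorProb = 0.5,
                         nPathways = 12, pathwaySize = 15,
                         plantedPerPathway = 8,
                         seed = 20250127) {
  new("CohortDesign",
      groupSizes = stats::setNames(as.integer(groupSizes),
                                   names(groupSizes)),
      nFeaturesNeg = as.integer(nFeaturesNeg),
      nFeaturesPos = as.integer(nFeaturesPos), nQC = as.integer(nQC),
      baselineLogMean = baselineLogMean, featureLogSd = featureLogSd,
      baselineLogSd = baselineLogSd,
      technicalCVRange = technicalCVRange, highCVRange = highCVRange,
      propHighCV = propHighCV,
      plantedEffects = as.data.frame(plantedEffects),
      missingRateRandom = missingRateRandom,
      missingIntensityQuantile = missingIntensityQuantile,
      censorProb = censorProb, nPathways = as.integer(nPathways),
      pathwaySize = as.integer(pathwaySize),
      plantedPerPathway = as.integer(plantedPerPathway),
      seed = as.integer(seed))
}

setMethod("show", "CohortDesign", function(object) {
  gs <- object@groupSizes
  cat("CohortDesign:", paste(names(gs), gs, sep = "=", collapse = " "),
      "+", object@nQC, "QC\n")
  cat("  features:", object@nFeaturesNeg, "negative +",
      object@nFeaturesPos, "positive;",
      nrow(object@plantedEffects), "planted effects\n")
})

#' Default planted differential effects
#'
#' Plants 20 differential features per pairwise stage comparison on
#' disjoint feature ids (10 per ion mode: the first half upregulated at the
#' given up fold change, the second half downregulated), mirroring the
#' benchmark layout used throughout the test-suite.
#'
#' @param nFeaturesNeg,nFeaturesPos available features per mode.
#' @param perComparison planted features per comparison (split evenly
#'   across modes).
#' @param fcUp,fcDown fold changes for up-/down-regulated plantings.
#' @param comparisons which comparisons receive plantings.
#' @return data.frame(feature_id, comparison, fold_change).
#' @export
defaultPlantedEffects <- function(nFeaturesNeg = 100, nFeaturesPos = 100,
                                  perComparison = 20, fcUp = 2.0,
                                  fcDown = 0.5,
                                  comparisons = stageComparisons()) {
  perMode <- perComparison %/% 2L
  need <- perMode * length(comparisons)
  if (need > nFeaturesNeg || need > nFeaturesPos)
    stop("not enough features to plant ", perComparison,
         " effects per comparison")
  out <- list()
  for (i in seq_along(comparisons)) {
    idx <- (i - 1L) * perMode + seq_len(perMode)
    ids <- c(sprintf("neg_%04d", idx), sprintf("pos_%04d", idx))
    half <- perMode %/% 2L
    fc <- rep(c(rep(fcUp, half), rep(fcDown, perMode - half)), 2L)
    out[[i]] <- data.frame(feature_id = ids, comparison = comparisons[i],
                           fold_change = fc)
  }
  do.call(rbind, out)
}

.simulateMetadata <- function(design) {
  gs <- design@groupSizes[c("CN", "MCI", "AD")]
  groups <- rep(names(gs), gs)
  ids <- unlist(lapply(names(gs), function(g)
    sprintf("%s%03d", g, seq_len(gs[[g]]))))
  ageMean <- c(CN = 70, MCI = 74, AD = 78)
  md <- data.frame(
    sample_id = ids, group = groups, is_qc = FALSE,
    age = round(stats::rnorm(length(ids), ageMean[groups], 5)),
    gender = sample(c("male", "female"), length(ids), replace = TRUE,
                    prob = c(0.45, 0.55)),
    apoe = ifelse(stats::runif(length(ids)) <
                    c(CN = 0.25, MCI = 0.45, AD = 0.50)[groups],
                  "carrier", "non_carrier"),
    stringsAsFactors = FALSE)
  qc <- data.frame(sample_id = sprintf("QC%02d", seq_len(design@nQC)),
                   group = "QC", is_qc = TRUE, age = NA_real_,
                   gender = NA_character_, apoe = NA_character_,
                   stringsAsFactors = FALSE)
  rbind(md, qc)
}

# draw nQC log-normal replicates around mean m with coefficient of
# variation cv (exact in expectation); cv = 0 collapses to the mean
.qcDraw <- function(m, cv, nQC) {
  s <- sqrt(log1p(cv^2))
  sapply(seq_len(nQC), function(i)
    ifelse(s > 0,
           stats::rlnorm(length(m), log(m) - s^2 / 2, s),
           m))
}

.simulateMode <- function(design, mode, md) {
  prefix <- if (mode == "negative") "neg" else "pos"
  n <- if (mode == "negative") design@nFeaturesNeg else design@nFeaturesPos
  ids <- sprintf("%s_%04d", prefix, seq_len(n))
  mu <- stats::rnorm(n, design@baselineLogMean, design@featureLogSd)
  # planted features stay technically reliable: the differential truth is
  # meant to be recoverable, so only non-planted features can draw an
  # unreliable (QC-excluded) technical CV
  planted <- ids %in% design@plantedEffects$feature_id
  high <- stats::runif(n) < design@propHighCV & !planted
  cv <- ifelse(high,
               stats::runif(n, design@highCVRange[1], design@highCVRange[2]),
               stats::runif(n, design@technicalCVRange[1],
                            design@technicalCVRange[2]))
  names(cv) <- ids

  # per-group log-scale effect shifts from the planted registry
  delta <- matrix(0, n, 3, dimnames = list(ids, c("CN", "MCI", "AD")))
  pe <- design@plantedEffects
  pe <- pe[startsWith(pe$feature_id, prefix), , drop = FALSE]
  if (nrow(pe)) {
    missing <- setdiff(pe$feature_id, ids)
    if (length(missing))
      stop("invalid 'plantedEffects': feature(s) not in table: ",
           paste(missing, collapse = ", "))
    for (r in seq_len(nrow(pe))) {
      case <- comparisonGroups(pe$comparison[r])[["case"]]
      delta[pe$feature_id[r], case] <-
        delta[pe$feature_id[r], case] + log(pe$fold_change[r])
    }
  }

  bio <- md[!md$is_qc, ]
  X <- sapply(seq_len(nrow(bio)), function(j)
    exp(mu + delta[, bio$group[j]] +
          stats::rnorm(n, 0, design@baselineLogSd)))
  dimnames(X) <- list(ids, bio$sample_id)

  pooled <- rowMeans(X)
  qc <- .qcDraw(pooled, cv, design@nQC)
  dimnames(qc) <- list(ids, md$sample_id[md$is_qc])

  # missingness on biological cells only: MCAR + left-censoring
  miss <- matrix(stats::runif(length(X)) < design@missingRateRandom,
                 nrow(X))
  if (design@censorProb > 0 && design@missingIntensityQuantile > 0) {
    thr <- stats::quantile(X, design@missingIntensityQuantile)
    miss <- miss | (X < thr &
                      matrix(stats::runif(length(X)) < design@censorProb,
                             nrow(X)))
  }
  # never leave a feature entirely missing within a biological group
  for (g in c("CN", "MCI", "AD")) {
    cols <- which(bio$group == g)
    allMiss <- which(rowSums(!miss[, cols, drop = FALSE]) == 0L)
    for (f in allMiss)
      miss[f, cols[which.max(X[f, cols])]] <- FALSE
  }
  X[miss] <- NA_real_

  list(set = MetaboSet(cbind(X, qc), mode, sampleData = md),
       cv = cv)
}

.simulatePathways <- function(design, featureIds) {
  pe <- design@plantedEffects
  comps <- unique(pe$comparison)
  sets <- list(); labels <- character(); enriched <- character()
  for (comp in comps) {
    pid <- sprintf("path_enr_%s", tolower(gsub("-", "_", comp)))
    planted <- pe$feature_id[pe$comparison == comp]
    k <- min(design@plantedPerPathway, length(planted))
    members <- c(sample(planted, k),
                 sample(setdiff(featureIds, pe$feature_id),
                        max(0L, design@pathwaySize - k)))
    sets[[pid]] <- members
    labels[pid] <- paste("Planted-enriched pathway", comp)
    enriched[comp] <- pid
  }
  nBg <- max(0L, design@nPathways - length(comps))
  for (i in seq_len(nBg)) {
    pid <- sprintf("path_bg_%02d", i)
    sets[[pid]] <- sample(featureIds, design@pathwaySize)
    labels[pid] <- sprintf("Background pathway %02d", i)
  }
  list(pathways = PathwaySet(sets, labels), enriched = enriched)
}

#' Generate a synthetic staged cohort with known ground truth
#'
#' Produces the two ion-mode feature tables (with pooled-QC replicate
#' columns appended), the sample metadata, a pathway map whose planted
#' pathways are enriched for the planted differential features, and the
#' \linkS4class{SyntheticTruth} registry that makes every downstream stage
#' a recoverable-parameter test. Identical designs (same seed) generate
#' byte-identical outputs.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @return list with elements \code{negative}, \code{positive}
#'   (\linkS4class{MetaboSet}s), \code{metadata} (data.frame),
#'   \code{pathways} (\linkS4class{PathwaySet}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' cohort <- generateCohort(CohortDesign(nQC = 5, seed = 1))
#' cohort$negative
#' cohort$truth
#' @export
generateCohort <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  withSeed(design@seed, {
    md <- .simulateMetadata(design)
    neg <- .simulateMode(design, "negative", md)
    pos <- .simulateMode(design, "positive", md)
    allIds <- c(rownames(intensities(neg$set)),
                rownames(intensities(pos$set)))
    pw <- .simulatePathways(design, allIds)
    pe <- design@plantedEffects
    truth <- new("SyntheticTruth",
                 differentialFeatures = lapply(
                   split(pe, pe$comparison), function(d)
                     data.frame(feature_id = d$feature_id,
                                fold_change = d$fold_change)),
                 enrichedPathways = pw$enriched,
                 qcExcludedFeatures =
                   names(which(c(neg$cv, pos$cv) > 0.30)))
    list(negative = neg$set, positive = pos$set, metadata = md,
         pathways = pw$pathways, truth = truth)
  })
}

#' Append simulated pooled-QC replicate columns to a table
#'
#' QC replicates are drawn log-normally around each feature's pooled
#' biological mean with the requested per-feature technical CV; the
#' expected sample CV of a feature's QC values equals the requested CV
#' (exactly zero CV yields replicates identical to the pooled mean).
#'
#' @param x a \linkS4class{MetaboSet} of biological samples.
#' @param nQC number of QC replicates; at least 2 (a single replicate has
#'   no defined CV).
#' @param technicalCV per-feature CV values, recycled to the feature count.
#' @param seed RNG seed.
#' @return A \linkS4class{MetaboSet} with QC columns appended and flagged.
#' @export
generateQCReplicates <- function(x, nQC, technicalCV, seed = 20250127) {
  if (nQC < 2)
    stop("nQC must be >= 2: the QC coefficient of variation is undefined ",
         "for a single replicate")
  m <- intensities(x)
  cv <- rep_len(technicalCV, nrow(m))
  if (any(cv < 0)) stop("technicalCV must be >= 0")
  pooled <- rowMeans(m, na.rm = TRUE)
  qc <- withSeed(seed, .qcDraw(pooled, cv, as.integer(nQC)))
  colnames(qc) <- sprintf("QC%02d", seq_len(nQC))
  rownames(qc) <- rownames(m)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  md <- data.frame(sample_id = c(colnames(m), colnames(qc)),
                   stringsAsFactors = FALSE)
  md$group <- c(if ("group" %in% names(cd)) as.character(cd$group)
                else rep(NA_character_, ncol(m)),
                rep("QC", nQC))
  md$is_qc <- c(rep(FALSE, ncol(m)), rep(TRUE, nQC))
  MetaboSet(cbind(m, qc), ionMode(x), sampleData = md)
}
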