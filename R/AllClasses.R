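#' MetaboSet: one ion mode's feature-by-sample intensity table
#'
#' The pipeline's central container, a thin extension of
#' \linkS4class{SummarizedExperiment}. A single assay \code{"intensity"}
#' holds raw (untransformed) LC-MS feature intensities with \code{NA}
#' marking missing values; \code{colData} carries the sample metadata
#' (\code{group} in CN/MCI/AD/QC, \code{is_qc}, covariates); the ion mode
#' (\code{"negative"} or \code{"positive"}) lives in \code{metadata()}.
#' Feature identifiers are the rownames and must be unique; generated
#' cohorts prefix them \code{"neg_"}/\code{"pos_"} so the two modes never
#' collide.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @aliases MetaboSet-class
#' @exportClass MetaboSet
setClass("MetaboSet", contains = "SummarizedExperiment")

.validMetaboSet <- function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    m <- SummarizedExperiment::assay(object, "intensity")
    if (!is.numeric(m)) msg <- c(msg, "'intensity' must be numeric")
    else if (any(m[is.finite(m)] < 0))
      msg <- c(msg, "negative finite intensities are not allowed")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "feature ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "sample ids (colnames) must be present and unique")
  }
  mode <- S4Vectors::metadata(object)$ion_mode
  if (is.null(mode) || !mode %in% c("negative", "positive"))
    msg <- c(msg, "metadata()$ion_mode must be 'negative' or 'positive'")
  if (length(msg)) msg else TRUE
}
setValidity("MetaboSet", .validMetaboSet)

#' Construct a MetaboSet
#'
#' @param intensity numeric matrix, features as rows, samples as columns;
#'   \code{NA} marks missing cells. Rownames/colnames are required.
#' @param ionMode \code{"negative"} or \code{"positive"}.
#' @param sampleData optional \code{data.frame} of per-sample metadata with a
#'   \code{sample_id} column matching the intensity columns (any order); a
#'   \code{group} column is coerced to character and an \code{is_qc} flag is
#'   derived from \code{group == "QC"} when absent.
#' @return A \linkS4class{MetaboSet}.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("neg_1", "neg_2"),
#'                                               c("s1", "s2")))
#' MetaboSet(m, "negative")
#' @export
MetaboSet <- function(intensity, ionMode = c("negative", "positive"),
                      sampleData = NULL) {
  ionMode <- match.arg(ionMode)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(intensity))
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    if (!"sample_id" %in% names(sampleData))
      stop("sampleData requires a 'sample_id' column")
    idx <- match(colnames(intensity), sampleData$sample_id)
    if (anyNA(idx))
      stop("sampleData is missing sample(s): ",
           paste(colnames(intensity)[is.na(idx)], collapse = ", "))
    sampleData <- sampleData[idx, setdiff(names(sampleData), "sample_id"),
                             drop = FALSE]
    if ("group" %in% names(sampleData))
      sampleData$group <- as.character(sampleData$group)
    if (!"is_qc" %in% names(sampleData) && "group" %in% names(sampleData))
      sampleData$is_qc <- sampleData$group == "QC"
    cd <- S4Vectors::DataFrame(sampleData, row.names = colnames(intensity))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), colData = cd)
  S4Vectors::metadata(se)$ion_mode <- ionMode
  new("MetaboSet", se)
}

#' @describeIn MetaboSet raw intensity matrix (features x samples).
#' @param x,object a MetaboSet.
#' @param ... unused.
#' @export
setMethod("intensities", "MetaboSet", function(x, ...)
  SummarizedExperiment::assay(x, "intensity"))

#' @describeIn MetaboSet logical matrix, TRUE where the cell is missing.
#' @export
setMethod("missingMask", "MetaboSet", function(x, ...)
  is.na(SummarizedExperiment::assay(x, "intensity")))

#' @describeIn MetaboSet ion mode of the table.
#' @export
setMethod("ionMode", "MetaboSet", function(x, ...)
  S4Vectors::metadata(x)$ion_mode)

#' @describeIn MetaboSet per-sample group labels (character), NA if no
#'   \code{group} column is attached.
#' @export
setMethod("sampleGroups", "MetaboSet", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  g <- if ("group" %in% names(cd)) as.character(cd$group)
       else rep(NA_character_, ncol(x))
  names(g) <- colnames(x)
  g
})

#' @describeIn MetaboSet logical, TRUE for pooled-QC replicate columns.
#' @export
setMethod("isQC", "MetaboSet", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  q <- if ("is_qc" %in% names(cd)) as.logical(cd$is_qc)
       else rep(FALSE, ncol(x))
  q[is.na(q)] <- FALSE
  names(q) <- colnames(x)
  q
})

setMethod("show", "MetaboSet", function(object) {
  cat("MetaboSet (", ionMode(object), " ion mode): ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
  g <- sampleGroups(object)
  if (!all(is.na(g))) {
    tab <- table(g, useNA = "no")
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  cat("  missing cells:", sum(missingMask(object)), "\n")
})

# ---------------------------------------------------------------------------

#' PathwaySet: a metabolite pathway annotation map
#'
#' Maps pathway ids to the sets of feature/metabolite ids annotated to them,
#' with human-readable pathway names. Membership rows are stored with set
#' semantics (duplicates collapse).
#'
#' @slot sets named list of character vectors (pathway id -> member ids).
#' @slot labels named character vector of pathway display names.
#' @aliases PathwaySet-class
#' @exportClass PathwaySet
setClass("PathwaySet",
         representation(sets = "list", labels = "character"))

setValidity("PathwaySet", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "pathway ids must be unique and named")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "pathway member sets must be non-empty")
  if (!identical(sort(names(object@sets)), sort(names(object@labels))))
    msg <- c(msg, "labels must be named by the same pathway ids as sets")
  if (length(msg)) msg else TRUE
})

#' @param sets named list of character vectors of member ids.
#' @param labels named character of display names; defaults to the ids.
#' @rdname PathwaySet-class
#' @export
PathwaySet <- function(sets, labels = NULL) {
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (is.null(labels)) labels <- stats::setNames(names(sets), names(sets))
  new("PathwaySet", sets = sets, labels = labels[names(sets)])
}

#' @rdname PathwaySet-class
#' @param x a PathwaySet.
#' @param ... unused.
#' @export
setMethod("pathwaySets", "PathwaySet", function(x, ...) x@sets)

#' @rdname PathwaySet-class
#' @export
setMethod("pathwayLabels", "PathwaySet", function(x, ...) x@labels)

#' @export
setMethod("length", "PathwaySet", function(x) length(x@sets))

#' @export
setMethod("names", "PathwaySet", function(x) names(x@sets))

setMethod("show", "PathwaySet", function(object) {
  cat("PathwaySet:", length(object@sets), "pathways,",
      length(unique(unlist(object@sets))), "distinct members\n")
})

# ---------------------------------------------------------------------------

#' ScaledMatrix: an autoscaled (and optionally log-transformed) data matrix
#'
#' Samples are rows, features are columns; each column has mean zero and,
#' unless constant, unit sample standard deviation. The stored center/scale
#' (and log flag) make the transform reproducible on new data and invertible.
#'
#' @slot values numeric matrix, samples x features.
#' @slot center per-feature means subtracted (on the transformed scale).
#' @slot scale per-feature divisors (1 for constant features).
#' @slot logTransformed whether log10(x + offset) was applied first.
#' @slot logOffset the offset used inside the log.
#' @slot constantFeatures ids of features that were constant (flagged,
#'   scale forced to 1).
#' @aliases ScaledMatrix-class
#' @exportClass ScaledMatrix
setClass("ScaledMatrix",
         representation(values = "matrix", center = "numeric",
                        scale = "numeric", logTransformed = "logical",
                        logOffset = "numeric", constantFeatures = "character"))

setMethod("show", "ScaledMatrix", function(object) {
  cat("ScaledMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "features",
      if (object@logTransformed) "(log10-transformed)" else "", "\n")
  if (length(object@constantFeatures))
    cat("  constant features:", length(object@constantFeatures), "\n")
})

# ---------------------------------------------------------------------------

#' PLSModel: a NIPALS PLS-DA decomposition
#'
#' @slot scores score matrix T (samples x components).
#' @slot weights weight matrix W (features x components), unit-norm columns.
#' @slot xLoadings X-loading matrix P.
#' @slot yLoadings Y-loading matrix C (classes x components).
#' @slot r2x,r2y cumulative variance explained per component.
#' @slot classes class labels in encoding order.
#' @slot yCenter column means of the one-hot response.
#' @aliases PLSModel-class
#' @exportClass PLSModel
setClass("PLSModel",
         representation(scores = "matrix", weights = "matrix",
                        xLoadings = "matrix", yLoadings = "matrix",
                        r2x = "numeric", r2y = "numeric",
                        classes = "character", yCenter = "numeric"))

setMethod("show", "PLSModel", function(object) {
  a <- ncol(object@scores)
  cat("PLS-DA model:", a, "component(s),",
      nrow(object@weights), "features,",
      length(object@classes), "classes\n")
  cat("  cumulative R2X:", round(object@r2x, 4), "\n")
  cat("  cumulative R2Y:", round(object@r2y, 4), "\n")
})

#' OPLSModel: an OPLS-DA decomposition with a single predictive component
#'
#' Orthogonal components absorb class-unrelated variation; the predictive
#' component carries all class covariance. VIP is computed on the predictive
#' component only and satisfies mean(VIP^2) = 1.
#'
#' @slot predictiveScores t_p, one score per sample.
#' @slot predictiveWeights w_p, unit norm.
#' @slot predictiveLoadings p_p.
#' @slot yLoading scalar c relating t_p to the centered response.
#' @slot orthoScores,orthoWeights,orthoLoadings orthogonal structure
#'   (samples/features x nOrtho).
#' @slot r2y fraction of centered-response variance explained.
#' @slot r2xPred,r2xOrtho fraction of X variance in the predictive /
#'   orthogonal parts.
#' @slot q2 cross-validated Q2 (NA until filled by
#'   \code{\link{q2CrossValidate}}).
#' @slot vip per-feature VIP scores.
#' @slot classes c(reference, case) labels; case scores positive by
#'   convention.
#' @slot yCenter mean of the 0/1 response.
#' @slot nOrtho number of orthogonal components removed.
#' @aliases OPLSModel-class
#' @exportClass OPLSModel
setClass("OPLSModel",
         representation(predictiveScores = "numeric",
                        predictiveWeights = "numeric",
                        predictiveLoadings = "numeric",
                        yLoading = "numeric",
                        orthoScores = "matrix", orthoWeights = "matrix",
                        orthoLoadings = "matrix",
                        r2y = "numeric", r2xPred = "numeric",
                        r2xOrtho = "numeric", q2 = "numeric",
                        vip = "numeric", classes = "character",
                        yCenter = "numeric", nOrtho = "integer"))

setMethod("show", "OPLSModel", function(object) {
  cat("OPLS-DA model (", object@classes[1], " vs ", object@classes[2],
      "): 1 predictive + ", object@nOrtho, " orthogonal component(s)\n",
      sep = "")
  cat("  R2Y =", round(object@r2y, 4),
      " R2X(pred) =", round(object@r2xPred, 4),
      " R2X(ortho) =", round(object@r2xOrtho, 4), "\n")
  if (!is.na(object@q2)) cat("  Q2 =", round(object@q2, 4), "\n")
})

#' @describeIn OPLSModel per-feature VIP scores of the fitted model.
#' @param object an OPLSModel.
#' @param ... unused.
#' @export
setMethod("vipScores", "OPLSModel", function(object, ...) object@vip)

# ---------------------------------------------------------------------------

#' StagingModel: penalised logistic model over a key-metabolite panel
#'
#' Maximum-likelihood logistic regression on autoscaled panel intensities
#' with a weak L2 (ridge) penalty so that perfectly separable panels still
#' yield finite, deterministic coefficients.
#'
#' @slot comparison the stage comparison modeled.
#' @slot classes c(reference, case); the case class has probability -> 1.
#' @slot featureIds panel feature ids, in coefficient order.
#' @slot coefficients named numeric: "(Intercept)" then one per feature,
#'   on the autoscaled input scale.
#' @slot center,scale per-feature autoscaling parameters.
#' @slot logTransformed whether log10 was applied before autoscaling.
#' @slot logOffset offset inside the log10 transform.
#' @slot lambda L2 penalty strength.
#' @aliases StagingModel-class
#' @exportClass StagingModel
setClass("StagingModel",
         representation(comparison = "character", classes = "character",
                        featureIds = "character", coefficients = "numeric",
                        center = "numeric", scale = "numeric",
                        logTransformed = "logical", logOffset = "numeric",
                        lambda = "numeric"))

setMethod("show", "StagingModel", function(object) {
  cat("Staging model for", object@comparison, ":",
      length(object@featureIds), "key metabolites, ridge lambda =",
      object@lambda, "\n")
})

# ---------------------------------------------------------------------------

#' SyntheticTruth: planted ground truth of a generated cohort
#'
#' @slot differentialFeatures named list (comparison -> data.frame with
#'   feature_id, fold_change) of planted effects.
#' @slot enrichedPathways named character (comparison -> pathway id planted
#'   as enriched).
#' @slot qcExcludedFeatures features generated with technical CV > 0.30,
#'   i.e. those the QC filter should remove.
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(differentialFeatures = "list",
                        enrichedPathways = "character",
                        qcExcludedFeatures = "character"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:\n")
  for (comp in names(object@differentialFeatures))
    cat("  ", comp, ": ", nrow(object@differentialFeatures[[comp]]),
        " planted features\n", sep = "")
  cat("  enriched pathways:",
      paste(object@enrichedPathways, collapse = ", "), "\n")
  cat("  high-technical-CV features:",
      length(object@qcExcludedFeatures), "\n")
})
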