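# End-to-end pipeline over a pair of ion-mode tables.

#' Run the full staging pipeline
#'
#' QC CV filtering and group-wise KNN imputation per ion mode, then for
#' each pairwise stage comparison: OPLS-DA screen (VIP / Wilcoxon p / fold
#' change), optional permutation validation, pathway over-representation
#' of the merged differential set, decision-tree key-panel selection,
#' the penalised logistic staging model with its ROC/AUC on the modeling
#' data, and repeated stratified resampling validation.
#'
#' @param negative,positive \linkS4class{MetaboSet}s with QC columns
#'   flagged (e.g. from \code{\link{generateCohort}} or
#'   \code{\link{readFeatureTable}} + metadata).
#' @param pathways a \linkS4class{PathwaySet}.
#' @param config see \code{\link{pipelineConfig}}.
#' @param comparisons stage comparisons to run.
#' @param permutations run the label-permutation validation (costs
#'   \code{n_permutations} full refits per ion mode and comparison).
#' @param seed RNG seed for fold assignment, resampling and permutations;
#'   defaults to the config seed.
#' @return nested list: \code{preprocessing} (tables + reports) and one
#'   entry per comparison with screen, q2/permutation, enrichment, panel,
#'   model, roc and resampling results.
#' @export
runPipeline <- function(negative, positive, pathways,
                        config = pipelineConfig(),
                        comparisons = stageComparisons(),
                        permutations = FALSE, seed = config$seed) {
  prep <- list(
    negative = preprocessTable(negative, config$cv_threshold,
                               config$knn_fraction),
    positive = preprocessTable(positive, config$cv_threshold,
                               config$knn_fraction))
  tables <- list(negative = prep$negative$table,
                 positive = prep$positive$table)
  # biological samples only from here on
  tables <- lapply(tables, function(x) x[, !isQC(x)])
  annotated <- intersect(unique(unlist(pathwaySets(pathways))),
                         unlist(lapply(tables, rownames)))
  out <- list(preprocessing = prep)
  for (comp in comparisons) {
    scr <- screenComparison(tables, comp, config)
    cg <- comparisonGroups(comp)
    validation <- list()
    for (mode in names(tables)) {
      x <- tables[[mode]]
      sel <- sampleGroups(x) %in% cg
      X <- t(intensities(x[, sel]))
      y <- sampleGroups(x)[sel]
      q2 <- q2CrossValidate(X, y, nOrtho = config$n_ortho,
                            folds = config$cv_folds, seed = seed,
                            classes = unname(cg),
                            logTransform = config$log_transform)
      perm <- if (permutations)
        permutationTest(X, y, nOrtho = config$n_ortho,
                        nPerm = config$n_permutations,
                        folds = config$cv_folds, seed = seed,
                        classes = unname(cg),
                        logTransform = config$log_transform)
      validation[[mode]] <- list(q2 = q2, permutation = perm)
    }
    diffIds <- scr$records$feature_id[scr$records$status != "ns"]
    enr <- enrichPathways(intersect(diffIds, annotated), annotated,
                          pathways)
    panel <- selectKeyPanel(scr$records, tables, comp, enrichment = enr,
                            pathways = pathways,
                            nKeys = config$n_key_metabolites,
                            maxDepth = config$tree_max_depth,
                            seed = seed,
                            logTransform = config$log_transform)
    model <- fitStagingModel(panel, tables, comp,
                             lambda = config$ridge_lambda,
                             logTransform = config$log_transform)
    pm <- .panelMatrix(panel$feature_id, tables, comp)
    prob <- predictStaging(model, pm$X)
    roc <- rocAuc(prob, pm$y, pm$classes)
    resample <- randomSamplingValidation(
      panel, tables, comp, nResamples = config$n_resamples,
      testFraction = config$test_fraction,
      lambda = config$ridge_lambda, seed = seed,
      logTransform = config$log_transform)
    out[[comp]] <- list(screen = scr, validation = validation,
                        enrichment = enr, panel = panel, model = model,
                        probabilities = prob, roc = roc,
                        resampling = resample)
  }
  out
}
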