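# The differential-metabolite screen: a feature is called only when all
# three criteria hold jointly (strict inequalities) —
#   VIP > 1 on the OPLS-DA predictive component,
#   two-sided Wilcoxon rank-sum p < 0.05,
#   fold change > 1.25 (up) or < 0.8 (down),
# with fold change = mean(case) / mean(reference) on raw intensities and
# the case group the later disease stage of the comparison.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most 8 values and no ties
#' are present; otherwise the normal approximation with tie correction and
#' continuity correction. Symmetric in its two arguments.
#'
#' @param valuesCase,valuesRef numeric vectors, each of length >= 2.
#' @return two-sided p-value.
#' @export
wilcoxonRankSum <- function(valuesCase, valuesRef) {
  if (length(valuesCase) < 2L || length(valuesRef) < 2L)
    stop("both groups need >= 2 values")
  ties <- anyDuplicated(c(valuesCase, valuesRef)) > 0L
  useExact <- length(valuesCase) <= 8L && length(valuesRef) <= 8L && !ties
  suppressWarnings(
    stats::wilcox.test(valuesCase, valuesRef, alternative = "two.sided",
                       exact = useExact, correct = TRUE)$p.value)
}

#' Fold change between two groups
#'
#' Arithmetic mean of the case group over the arithmetic mean of the
#' reference group, on raw intensities. An undefined ratio (reference mean
#' zero) returns NA; the screen marks such records non-significant.
#'
#' @param valuesCase,valuesRef numeric vectors.
#' @return fold change (case / reference), or NA if undefined.
#' @export
foldChange <- function(valuesCase, valuesRef) {
  mc <- mean(valuesCase); mr <- mean(valuesRef)
  if (!is.finite(mr) || mr == 0) return(NA_real_)
  mc / mr
}

.callStatus <- function(vip, p, fc, vipThreshold = 1, pThreshold = 0.05,
                        fcLow = 0.8, fcHigh = 1.25) {
  ifelse(is.na(fc) | is.na(p), "ns",
         ifelse(vip > vipThreshold & p < pThreshold & fc > fcHigh, "up",
                ifelse(vip > vipThreshold & p < pThreshold & fc < fcLow,
                       "down", "ns")))
}

.screenMode <- function(x, comparison, config) {
  cg <- comparisonGroups(comparison)
  groups <- sampleGroups(x)
  sel <- which(groups %in% cg)
  if (!all(cg %in% groups))
    stop("comparison groups absent from table: ",
         paste(setdiff(cg, groups), collapse = ", "))
  sub <- x[, sel]
  y <- factor(sampleGroups(sub), levels = cg)
  raw <- intensities(sub)
  if (anyNA(raw)) stop("screen requires a complete (imputed) table")
  sc <- autoscale(sub, logTransform = config$log_transform)
  model <- fitOPLSDA(sc, as.character(y), nOrtho = config$n_ortho,
                     classes = unname(cg))
  vip <- vipScores(model)
  caseCols <- y == cg[["case"]]
  pvals <- apply(raw, 1L, function(v)
    wilcoxonRankSum(v[caseCols], v[!caseCols]))
  fc <- apply(raw, 1L, function(v)
    foldChange(v[caseCols], v[!caseCols]))
  data.frame(
    feature_id = rownames(raw), ion_mode = ionMode(x),
    vip = unname(vip[rownames(raw)]), p_value = unname(pvals),
    fold_change = unname(fc), log2_fc = log2(unname(fc)),
    row.names = NULL)
}

#' Screen one pairwise comparison for differential metabolites
#'
#' Fits OPLS-DA per ion mode independently, computes per-feature VIP,
#' Wilcoxon p and raw-intensity fold change, merges the two modes and
#' classifies each feature as up/down/ns under the conjunctive
#' VIP/p/fold-change criteria. A BH-adjusted p column is reported for
#' information only; the call itself uses raw p, mirroring the screen's
#' stated criteria. Volcano coordinates (log2 FC, -log10 p) and the top-15
#' up/down lists by |log2 FC| among significant features are attached.
#'
#' @param tables list with complete \linkS4class{MetaboSet}s
#'   \code{negative} and \code{positive} (either may be omitted).
#' @param comparison one of \code{stageComparisons()}.
#' @param config threshold list, see \code{\link{pipelineConfig}}.
#' @return list with \code{records} (one row per feature), \code{summary}
#'   (up/down/ns counts, overall and per ion mode) and \code{top15}.
#' @export
screenComparison <- function(tables, comparison,
                             config = pipelineConfig()) {
  tabs <- tables[intersect(c("negative", "positive"), names(tables))]
  if (!length(tabs)) stop("no ion-mode tables supplied")
  rec <- do.call(rbind, lapply(tabs, .screenMode, comparison = comparison,
                               config = config))
  rownames(rec) <- NULL
  rec$bh_adjusted_p <- stats::p.adjust(rec$p_value, method = "BH")
  rec$neg_log10_p <- -log10(rec$p_value)
  rec$status <- .callStatus(rec$vip, rec$p_value, rec$fold_change,
                            config$vip_threshold, config$p_threshold,
                            config$fc_low, config$fc_high)
  rec$comparison <- comparison
  rec <- rec[order(rec$feature_id), c(
    "feature_id", "ion_mode", "comparison", "vip", "p_value",
    "bh_adjusted_p", "fold_change", "log2_fc", "neg_log10_p", "status")]
  rownames(rec) <- NULL
  perMode <- table(factor(rec$ion_mode,
                          levels = c("negative", "positive")),
                   factor(rec$status, levels = c("up", "down", "ns")))
  summary <- list(comparison = comparison,
                  up = sum(rec$status == "up"),
                  down = sum(rec$status == "down"),
                  ns = sum(rec$status == "ns"),
                  total = nrow(rec), perMode = perMode)
  sig <- rec[rec$status != "ns", ]
  topN <- function(d, n = 15L)
    utils::head(d[order(-abs(d$log2_fc)), ], n)
  list(records = rec, summary = summary,
       top15 = list(up = topN(sig[sig$status == "up", ]),
                    down = topN(sig[sig$status == "down", ])))
}

#' Pipeline configuration
#'
#' Every tunable threshold of the pipeline in one list; defaults are the
#' study conditions (QC CV 0.30, KNN fraction 0.10, VIP > 1, p < 0.05,
#' FC outside [0.8, 1.25], 200 permutations, 200 resamples, 10 key
#' metabolites, 7 CV folds, 30\% test fraction).
#'
#' @param ... named overrides of the defaults.
#' @return named list of configuration values.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(cv_threshold = 0.30, knn_fraction = 0.10,
              vip_threshold = 1.0, p_threshold = 0.05,
              fc_low = 0.8, fc_high = 1.25,
              n_permutations = 200L, n_resamples = 200L,
              n_key_metabolites = 10L, cv_folds = 7L,
              test_fraction = 0.30, n_ortho = 1L,
              log_transform = TRUE, ridge_lambda = 1e-4,
              tree_max_depth = 5L, seed = 20250127L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration option(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file whose keys override the defaults.
#' @export
readPipelineConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading a YAML config requires the 'yaml' package")
  do.call(pipelineConfig, yaml::read_yaml(path))
}
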