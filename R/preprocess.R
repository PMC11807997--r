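# QC-based feature filtering and group-wise KNN imputation.

#' Filter features by pooled-QC coefficient of variation
#'
#' Computes each feature's CV (sample standard deviation / mean, on raw
#' intensities) over the observed QC replicate values and removes features
#' whose CV strictly exceeds the threshold ("over 30\%"): a feature at
#' exactly the threshold is retained. Features whose QC CV is undefined
#' (fewer than two observed QC values, or QC mean zero) are excluded with
#' \code{cv = NA}. Filtering never alters the retained values and is
#' idempotent.
#'
#' @param x a \linkS4class{MetaboSet} whose QC columns are flagged (see
#'   \code{\link{isQC}}), or supply \code{qcIds} explicitly.
#' @param threshold CV exclusion threshold, default 0.30.
#' @param qcIds optional explicit QC sample ids.
#' @return list with \code{table} (the filtered \linkS4class{MetaboSet})
#'   and \code{report}, a data.frame(feature_id, cv, retained) with the
#'   threshold attached as an attribute.
#' @export
cvFilter <- function(x, threshold = 0.30, qcIds = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (is.null(qcIds)) qcIds <- colnames(x)[isQC(x)]
  if (length(qcIds) < 2)
    stop("need >= 2 QC samples to compute a coefficient of variation")
  m <- intensities(x)
  if (!all(qcIds %in% colnames(m)))
    stop("QC sample(s) not in table: ",
         paste(setdiff(qcIds, colnames(m)), collapse = ", "))
  qc <- m[, qcIds, drop = FALSE]
  cv <- apply(qc, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    mu <- mean(v)
    if (mu == 0) return(NA_real_)
    stats::sd(v) / mu
  })
  retained <- !is.na(cv) & cv <= threshold
  report <- data.frame(feature_id = rownames(m), cv = cv,
                       retained = retained, row.names = NULL)
  attr(report, "threshold") <- threshold
  filtered <- x[retained, ]
  validObject(filtered)
  list(table = filtered, report = report)
}

# scaled Euclidean distance between two sample columns over features
# observed in both; Inf when nothing is shared
.sampleDistances <- function(m) {
  ns <- ncol(m)
  d <- matrix(Inf, ns, ns, dimnames = list(colnames(m), colnames(m)))
  obs <- !is.na(m)
  for (i in seq_len(ns)) {
    d[i, i] <- 0
    for (j in seq_len(ns)[-seq_len(i)]) {
      shared <- obs[, i] & obs[, j]
      k <- sum(shared)
      if (k > 0L)
        d[i, j] <- d[j, i] <- sqrt(sum((m[shared, i] - m[shared, j])^2) / k)
    }
  }
  d
}

#' Group-wise K-nearest-neighbour imputation
#'
#' Imputes missing cells within each sample group independently (diagnostic
#' groups CN/MCI/AD, and the QC pool if its columns contain missing
#' values). The neighbour count is 10\% of the group size
#' (\code{k = max(1, round(fraction * group size))}, round half up).
#' Distance between two samples is the Euclidean distance over features
#' observed in both, scaled by the number of shared observed features; an
#' imputed value is the unweighted mean of the k nearest neighbours'
#' observed values for that feature, with neighbours lacking the feature
#' skipped in favour of the next nearest. Distance ties break by sample-id
#' lexicographic order, so the result is deterministic. Observed cells are
#' never changed; the output has no missing cells.
#'
#' @param x a \linkS4class{MetaboSet} (typically after
#'   \code{\link{cvFilter}}).
#' @param fraction neighbour fraction of the group size, default 0.10.
#' @return list with \code{table} (complete \linkS4class{MetaboSet}) and
#'   \code{report}, a data.frame(group, n_samples, k, n_imputed).
#' @export
knnImpute <- function(x, fraction = 0.10) {
  if (fraction <= 0) stop("fraction must be > 0")
  m <- intensities(x)
  groups <- sampleGroups(x)
  if (all(is.na(groups)))
    stop("sample groups are required for group-wise imputation")
  report <- list()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    sub <- m[, cols, drop = FALSE]
    nMiss <- sum(is.na(sub))
    k <- max(1L, roundHalfUp(fraction * length(cols)))
    if (nMiss > 0L) {
      if (length(cols) < 2L)
        stop("group '", g, "' has fewer than 2 samples; cannot impute")
      allMiss <- rownames(sub)[rowSums(!is.na(sub)) == 0L]
      if (length(allMiss))
        stop("feature(s) missing in all samples of group '", g, "': ",
             paste(allMiss, collapse = ", "))
      d <- .sampleDistances(sub)
      for (j in seq_len(ncol(sub))) {
        missF <- which(is.na(sub[, j]))
        if (!length(missF)) next
        ord <- order(d[j, ], colnames(sub))   # ties by sample id
        ord <- ord[ord != j & is.finite(d[j, ord])]
        for (f in missF) {
          donors <- ord[!is.na(sub[f, ord])]
          if (!length(donors))
            stop("no neighbour observes feature '", rownames(sub)[f],
                 "' in group '", g, "'")
          use <- donors[seq_len(min(k, length(donors)))]
          m[rownames(sub)[f], cols[j]] <- mean(sub[f, use])
        }
      }
    }
    report[[g]] <- data.frame(group = g, n_samples = length(cols), k = k,
                              n_imputed = nMiss)
  }
  out <- x
  SummarizedExperiment::assay(out, "intensity") <- m
  validObject(out)
  list(table = out, report = do.call(rbind, c(report,
                                              list(make.row.names = FALSE))))
}

#' Run QC filtering then imputation for one ion mode
#'
#' Convenience wrapper: \code{\link{cvFilter}} on the QC columns, then
#' \code{\link{knnImpute}} on the retained features.
#'
#' @param x a \linkS4class{MetaboSet} with QC columns flagged.
#' @param cvThreshold QC CV exclusion threshold.
#' @param knnFraction KNN neighbour fraction.
#' @return list(table, cvReport, imputationReport).
#' @export
preprocessTable <- function(x, cvThreshold = 0.30, knnFraction = 0.10) {
  filt <- cvFilter(x, threshold = cvThreshold)
  imp <- knnImpute(filt$table, fraction = knnFraction)
  list(table = imp$table, cvReport = filt$report,
       imputationReport = imp$report)
}
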