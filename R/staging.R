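# Key-metabolite panel selection (CART), penalised logistic staging model,
# ROC/AUC and repeated stratified resampling validation.

# raw panel matrix (samples x features) and labels for one comparison
.panelMatrix <- function(featureIds, tables, comparison) {
  cg <- comparisonGroups(comparison)
  m <- combinedIntensities(tables)
  missing <- setdiff(featureIds, rownames(m))
  if (length(missing))
    stop("panel feature(s) absent from table: ",
         paste(missing, collapse = ", "))
  groups <- sampleGroups(tables[[1L]])[colnames(m)]
  sel <- which(groups %in% cg)
  if (!all(cg %in% groups))
    stop("comparison groups absent from metadata: ",
         paste(setdiff(cg, groups), collapse = ", "))
  X <- t(m[featureIds, sel, drop = FALSE])
  if (anyNA(X)) stop("staging requires complete (imputed) tables")
  list(X = X, y = unname(groups[sel]), classes = unname(cg))
}

#' Select a key-metabolite panel with a classification tree
#'
#' Fits a CART classification tree (Gini impurity, bounded depth) on the
#' autoscaled differential features — restricted to those annotated to
#' significantly enriched pathways when an enrichment result and pathway
#' map are supplied, falling back to all differential features when the
#' restriction leaves fewer than \code{nKeys} candidates — and ranks
#' features by their total impurity decrease. Ties break by smaller
#' univariate p, then feature id. If the tree uses fewer than \code{nKeys}
#' features, the panel is padded from the VIP ranking of the remaining
#' differential features.
#'
#' @param records screen records for the comparison (see
#'   \code{\link{screenComparison}}).
#' @param tables list of complete \linkS4class{MetaboSet}s (both modes).
#' @param comparison the stage comparison.
#' @param enrichment optional \code{\link{enrichPathways}} result used to
#'   restrict candidates.
#' @param pathways the \linkS4class{PathwaySet} behind \code{enrichment}.
#' @param nKeys panel size, default 10.
#' @param maxDepth CART depth bound, default 5.
#' @param pEnrich enrichment p-value cutoff defining "significantly
#'   enriched", default 0.05.
#' @param seed RNG seed (kept for provenance; the fit itself is
#'   deterministic).
#' @param logTransform log10 before autoscaling.
#' @return data.frame(feature_id, importance, source) sorted by decreasing
#'   importance, with the comparison and seed as attributes.
#' @export
selectKeyPanel <- function(records, tables, comparison, enrichment = NULL,
                           pathways = NULL, nKeys = 10, maxDepth = 5,
                           pEnrich = 0.05, seed = 20250127,
                           logTransform = TRUE) {
  rec <- records[records$comparison == comparison &
                   records$status != "ns", , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no differential features for ", comparison,
         "; cannot select a key panel")
  candidates <- rec$feature_id
  if (!is.null(enrichment) && !is.null(pathways)) {
    sig <- enrichment$pathway_id[enrichment$p_value < pEnrich]
    annotated <- unique(unlist(pathwaySets(pathways)[sig]))
    restricted <- intersect(candidates, annotated)
    if (length(restricted) >= nKeys) candidates <- restricted
  }
  if (length(candidates) < nKeys)
    warning("only ", length(candidates), " differential features; ",
            "panel will be smaller than ", nKeys)
  pm <- .panelMatrix(candidates, tables, comparison)
  sc <- .scaleCore(pm$X, logTransform, 1e-9)
  df <- as.data.frame(sc$values)
  alias <- sprintf("f%04d", seq_along(candidates))
  names(df) <- alias
  df$.y <- factor(pm$y, levels = pm$classes)
  fit <- withSeed(seed,
    rpart::rpart(.y ~ ., data = df, method = "class",
                 parms = list(split = "gini"),
                 control = rpart::rpart.control(
                   maxdepth = maxDepth, cp = 0, minsplit = 10,
                   xval = 0)))
  imp <- fit$variable.importance
  importance <- stats::setNames(rep(0, length(candidates)), candidates)
  if (!is.null(imp))
    importance[candidates[match(names(imp), alias)]] <- imp
  pv <- stats::setNames(rec$p_value, rec$feature_id)[candidates]
  ord <- order(-importance, pv, candidates)
  ranked <- candidates[ord]
  used <- ranked[importance[ranked] > 0]
  panel <- utils::head(used, nKeys)
  source <- rep("tree", length(panel))
  if (length(panel) < min(nKeys, nrow(rec))) {
    vipRank <- rec[order(-rec$vip), "feature_id"]
    pad <- setdiff(vipRank, panel)
    need <- min(nKeys, nrow(rec)) - length(panel)
    panel <- c(panel, utils::head(pad, need))
    source <- c(source, rep("vip_pad", min(need, length(pad))))
  }
  out <- data.frame(feature_id = panel,
                    importance = unname(importance[panel]),
                    source = source, row.names = NULL)
  attr(out, "comparison") <- comparison
  attr(out, "seed") <- seed
  out
}

# ridge-penalised logistic regression by Newton iterations with step
# halving; maximises loglik - lambda * sum(beta^2) (intercept unpenalised)
.ridgeLogistic <- function(X, y01, lambda, maxIter = 200, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  objective <- function(b) {
    eta <- drop(Xd %*% b)
    sum(y01 * eta - log1p(exp(eta))) - lambda * sum(b[-1]^2)
  }
  obj <- objective(beta)
  for (it in seq_len(maxIter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    wgt <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(Xd, y01 - mu)) -
      c(0, 2 * lambda * beta[-1])
    H <- crossprod(Xd * wgt, Xd) + diag(c(0, rep(2 * lambda, p - 1L)),
                                        p)
    step <- solve(H, grad)
    newBeta <- beta + step
    newObj <- objective(newBeta)
    halvings <- 0L
    while (newObj < obj && halvings < 40L) {
      step <- step / 2
      newBeta <- beta + step
      newObj <- objective(newBeta)
      halvings <- halvings + 1L
    }
    beta <- newBeta
    if (max(abs(step)) < tol) break
    obj <- newObj
  }
  stats::setNames(beta, colnames(Xd))
}

.fitStagingCore <- function(X, y, classes, lambda, logTransform) {
  sc <- .scaleCore(X, logTransform, 1e-9)
  y01 <- as.numeric(y == classes[2L])
  beta <- .ridgeLogistic(sc$values, y01, lambda)
  list(beta = beta, center = sc$center, scale = sc$scale)
}

#' Fit the logistic staging model on a key panel
#'
#' Maximum-likelihood logistic regression of stage membership on the
#' autoscaled panel intensities with a weak L2 penalty (default 1e-4) so
#' perfectly separable panels still give finite, deterministic
#' coefficients. Coefficients are invariant to the order in which panel
#' features are listed.
#'
#' @param panel a \code{\link{selectKeyPanel}} result or character vector
#'   of feature ids.
#' @param tables list of complete \linkS4class{MetaboSet}s.
#' @param comparison the stage comparison.
#' @param lambda L2 penalty strength.
#' @param logTransform log10 before autoscaling.
#' @return A \linkS4class{StagingModel}.
#' @export
fitStagingModel <- function(panel, tables, comparison, lambda = 1e-4,
                            logTransform = TRUE) {
  ids <- if (is.data.frame(panel)) panel$feature_id else as.character(panel)
  if (!length(ids)) stop("panel is empty")
  pm <- .panelMatrix(ids, tables, comparison)
  fit <- .fitStagingCore(pm$X, pm$y, pm$classes, lambda, logTransform)
  new("StagingModel", comparison = comparison, classes = pm$classes,
      featureIds = ids, coefficients = fit$beta, center = fit$center,
      scale = fit$scale, logTransformed = logTransform, logOffset = 1e-9,
      lambda = lambda)
}

#' Predicted case-class probabilities from a staging model
#'
#' @param model a \linkS4class{StagingModel}.
#' @param tables list of \linkS4class{MetaboSet}s, or a raw
#'   samples-x-features matrix containing the panel features.
#' @return named numeric vector of probabilities of the case class.
#' @export
predictStaging <- function(model, tables) {
  X <- if (is.matrix(tables)) tables[, model@featureIds, drop = FALSE]
       else t(combinedIntensities(tables)[model@featureIds, ,
                                          drop = FALSE])
  Xs <- .scaleCore(X, model@logTransformed, model@logOffset, model@center,
                   model@scale)$values
  eta <- drop(cbind(1, Xs) %*% model@coefficients)
  stats::setNames(stats::plogis(eta), rownames(X))
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formula with half credit for ties; the
#' curve sweeps all distinct score thresholds. The trapezoidal area under
#' the constructed curve is checked against the rank AUC on every call
#' (internal consistency).
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels two-class labels.
#' @param classes optional c(control, case) ordering; default sorted
#'   unique labels, case = second.
#' @return list(thresholds, fpr, tpr, auc).
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc   # 0.75
#' @export
rocAuc <- function(scores, labels, classes = NULL) {
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  pos <- labels == classes[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(th) sum(scores >= th & pos) / n1,
                numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & !pos) / n0,
                numeric(1))
  trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  stopifnot(isTRUE(all.equal(trap, auc, tolerance = 1e-10)))
  list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc)
}

#' Repeated stratified resampling validation of a staging panel
#'
#' Repeats a stratified random train/test split (default 70/30, 200
#' times), refits the staging model (including its autoscaling) on each
#' training split, and reports the held-out AUC and accuracy
#' distributions.
#'
#' @param panel panel data.frame or feature ids.
#' @param tables list of complete \linkS4class{MetaboSet}s.
#' @param comparison the stage comparison.
#' @param nResamples number of random splits, default 200.
#' @param testFraction held-out fraction per group, default 0.30.
#' @param lambda ridge strength of the refits.
#' @param seed RNG seed.
#' @param logTransform log10 before autoscaling.
#' @return data.frame(iteration, auc, accuracy) with mean/sd attributes.
#' @export
randomSamplingValidation <- function(panel, tables, comparison,
                                     nResamples = 200,
                                     testFraction = 0.30, lambda = 1e-4,
                                     seed = 20250127,
                                     logTransform = TRUE) {
  ids <- if (is.data.frame(panel)) panel$feature_id else as.character(panel)
  pm <- .panelMatrix(ids, tables, comparison)
  grpIdx <- split(seq_along(pm$y), pm$y)
  small <- names(grpIdx)[lengths(grpIdx) < 4L]
  if (length(small))
    stop("group(s) too small for a stratified split (need >= 4): ",
         paste(small, collapse = ", "))
  withSeed(seed, {
    res <- lapply(seq_len(nResamples), function(b) {
      test <- unlist(lapply(grpIdx, function(ix)
        sample(ix, max(1L, roundHalfUp(length(ix) * testFraction)))))
      train <- setdiff(seq_along(pm$y), test)
      fit <- .fitStagingCore(pm$X[train, , drop = FALSE], pm$y[train],
                             pm$classes, lambda, logTransform)
      Xte <- .scaleCore(pm$X[test, , drop = FALSE], logTransform, 1e-9,
                        fit$center, fit$scale)$values
      prob <- stats::plogis(drop(cbind(1, Xte) %*% fit$beta))
      yte <- pm$y[test]
      acc <- mean((prob > 0.5) == (yte == pm$classes[2L]))
      data.frame(iteration = b,
                 auc = rocAuc(prob, yte, pm$classes)$auc,
                 accuracy = acc)
    })
    out <- do.call(rbind, res)
    attr(out, "mean_auc") <- mean(out$auc)
    attr(out, "sd_auc") <- stats::sd(out$auc)
    attr(out, "mean_accuracy") <- mean(out$accuracy)
    attr(out, "test_fraction") <- testFraction
    out
  })
}
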