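# PLS-DA and OPLS-DA, written from first principles (NIPALS with
# deflation). The OPLS predictive component carries the class covariance;
# orthogonal components absorb class-unrelated structure. VIP is computed
# on the single predictive component: VIP_j = sqrt(p) |w_pj| / ||w_p||,
# which satisfies mean(VIP^2) = 1 exactly.

.scaleCore <- function(m, logTransform, offset, center = NULL,
                       scale = NULL) {
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("V%d", seq_len(ncol(m)))
  if (logTransform) m <- log10(m + offset)
  if (is.null(center)) center <- colMeans(m)
  v <- sweep(m, 2L, center)
  constant <- character()
  if (is.null(scale)) {
    scale <- apply(v, 2L, stats::sd)
    constant <- colnames(v)[!is.na(scale) & scale == 0]
    scale[scale == 0 | is.na(scale)] <- 1
  }
  list(values = sweep(v, 2L, scale, "/"), center = center, scale = scale,
       constant = constant)
}

#' Autoscale a complete intensity matrix
#'
#' Optionally applies \code{log10(x + offset)}, then mean-centers and
#' scales each feature to unit sample standard deviation. Constant features
#' are centered to zero, flagged, and given scale 1. The stored
#' center/scale make the transform invertible
#' (\code{\link{inverseScaling}}) and applicable to new data
#' (\code{\link{applyScaling}}).
#'
#' @param x a complete \linkS4class{MetaboSet} (features x samples) or a
#'   numeric samples-x-features matrix.
#' @param logTransform apply log10 first? Default TRUE, the conventional
#'   variance-stabilisation for untargeted LC-MS intensities.
#' @param offset small positive offset inside the log.
#' @return A \linkS4class{ScaledMatrix} (samples x features).
#' @export
autoscale <- function(x, logTransform = TRUE, offset = 1e-9) {
  m <- if (is(x, "MetaboSet")) t(intensities(x)) else as.matrix(x)
  if (anyNA(m))
    stop("autoscale requires a complete matrix; impute first")
  sc <- .scaleCore(m, logTransform, offset)
  new("ScaledMatrix", values = sc$values, center = sc$center,
      scale = sc$scale, logTransformed = logTransform, logOffset = offset,
      constantFeatures = sc$constant)
}

#' @rdname autoscale
#' @param sm a \linkS4class{ScaledMatrix}.
#' @param newdata samples-x-features matrix (raw scale) to transform with
#'   the stored parameters.
#' @export
applyScaling <- function(sm, newdata) {
  m <- as.matrix(newdata)[, names(sm@center), drop = FALSE]
  .scaleCore(m, sm@logTransformed, sm@logOffset, sm@center, sm@scale)$values
}

#' @rdname autoscale
#' @export
inverseScaling <- function(sm) {
  m <- sweep(sweep(sm@values, 2L, sm@scale, "*"), 2L, sm@center, "+")
  if (sm@logTransformed) m <- 10^m - sm@logOffset
  m
}

.asValues <- function(X) {
  if (is(X, "ScaledMatrix")) X@values else as.matrix(X)
}

.binaryResponse <- function(y, classes = NULL) {
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(unique(y)) < 2L)
    stop("response is constant; two classes are required")
  if (length(classes) != 2L || !all(y %in% classes))
    stop("exactly two classes are required")
  y01 <- as.numeric(y == classes[2L])
  list(y01 = y01, yc = y01 - mean(y01), classes = classes,
       yCenter = mean(y01))
}

#' Fit a PLS-DA model by NIPALS
#'
#' Multi-class discriminant PLS: the response is the centered one-hot
#' class-membership matrix; components are extracted by NIPALS with
#' deflation of both blocks. Weight columns are unit norm and the reported
#' R2X/R2Y are cumulative.
#'
#' @param X a \linkS4class{ScaledMatrix} or an already-scaled
#'   samples-x-features matrix.
#' @param y class labels (2 or more classes).
#' @param A number of components; must not exceed the rank of X.
#' @param tol,maxIter NIPALS convergence controls.
#' @return A \linkS4class{PLSModel}.
#' @export
fitPLSDA <- function(X, y, A = 2, tol = 1e-10, maxIter = 500) {
  Xc <- .asValues(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  rk <- qr(Xc)$rank
  if (A > rk)
    stop("A = ", A, " exceeds the rank of X (", rk, ")")
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  yCenter <- colMeans(Y)
  Yc <- sweep(Y, 2L, yCenter)
  ssx0 <- sum(Xc^2); ssy0 <- sum(Yc^2)
  p <- ncol(Xc); n <- nrow(Xc)
  Tm <- matrix(0, n, A); W <- P <- matrix(0, p, A)
  C <- matrix(0, ncol(Y), A, dimnames = list(colnames(Y), NULL))
  r2x <- r2y <- numeric(A)
  for (a in seq_len(A)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    for (it in seq_len(maxIter)) {
      w <- drop(crossprod(Xc, u))
      w <- w / sqrt(sum(w^2))
      tt <- drop(Xc %*% w)
      cc <- drop(crossprod(Yc, tt)) / sum(tt^2)
      uNew <- drop(Yc %*% cc) / sum(cc^2)
      if (sqrt(sum((uNew - u)^2)) < tol * sqrt(sum(uNew^2))) {
        u <- uNew; break
      }
      u <- uNew
    }
    pp <- drop(crossprod(Xc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, cc)
    Tm[, a] <- tt; W[, a] <- w; P[, a] <- pp; C[, a] <- cc
    r2x[a] <- 1 - sum(Xc^2) / ssx0
    r2y[a] <- 1 - sum(Yc^2) / ssy0
  }
  rownames(W) <- rownames(P) <- colnames(.asValues(X))
  rownames(Tm) <- rownames(.asValues(X))
  new("PLSModel", scores = Tm, weights = W, xLoadings = P, yLoadings = C,
      r2x = r2x, r2y = r2y, classes = levels(y), yCenter = yCenter)
}

# core OPLS fit on a scaled matrix and centered binary response
.oplsCore <- function(Xs, yc, nOrtho) {
  ssx0 <- sum(Xs^2)
  w <- drop(crossprod(Xs, yc)) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  n <- nrow(Xs); p <- ncol(Xs)
  To <- matrix(0, n, nOrtho); Wo <- Po <- matrix(0, p, nOrtho)
  r2xo <- 0
  for (h in seq_len(nOrtho)) {
    tt <- drop(Xs %*% w)
    pp <- drop(crossprod(Xs, tt)) / sum(tt^2)
    wo <- pp - sum(w * pp) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      stop("no orthogonal variation left to remove (component ", h, ")")
    wo <- wo / nwo
    to <- drop(Xs %*% wo)
    po <- drop(crossprod(Xs, to)) / sum(to^2)
    Xs <- Xs - tcrossprod(to, po)
    To[, h] <- to; Wo[, h] <- wo; Po[, h] <- po
    r2xo <- r2xo + sum(to^2) * sum(po^2) / ssx0
  }
  tt <- drop(Xs %*% w)
  pp <- drop(crossprod(Xs, tt)) / sum(tt^2)
  cc <- sum(yc * tt) / sum(tt^2)
  list(w = w, t = tt, p = pp, c = cc, To = To, Wo = Wo, Po = Po,
       r2y = 1 - sum((yc - tt * cc)^2) / sum(yc^2),
       r2xPred = sum(tt^2) * sum(pp^2) / ssx0, r2xOrtho = r2xo)
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures for a two-class response:
#' the first PLS weight vector \code{w = X'y / (y'y)} (normalised) defines
#' the predictive direction; each orthogonal component is built from the
#' part of the X-loading orthogonal to \code{w} and deflated from X before
#' the final predictive component is extracted. The response is the
#' centered 0/1 class indicator. The predictive score sign is chosen so the
#' case class (second of \code{classes}, i.e. the later disease stage) has
#' positive mean score.
#'
#' @param X a \linkS4class{ScaledMatrix} or already-scaled matrix
#'   (samples x features).
#' @param y two-class labels.
#' @param nOrtho number of orthogonal components (>= 0); with 0 the
#'   predictive component equals the first PLS-DA component.
#' @param classes optional c(reference, case) ordering; defaults to sorted
#'   unique labels.
#' @return An \linkS4class{OPLSModel} (Q2 slot \code{NA}; fill it with
#'   \code{\link{q2CrossValidate}}).
#' @export
fitOPLSDA <- function(X, y, nOrtho = 1, classes = NULL) {
  Xs <- .asValues(X)
  resp <- .binaryResponse(y, classes)
  if (nOrtho < 0) stop("nOrtho must be >= 0")
  rk <- qr(Xs)$rank
  if (nOrtho >= rk)
    stop("nOrtho = ", nOrtho, " must be smaller than the rank of X (",
         rk, ")")
  fit <- .oplsCore(Xs, resp$yc, as.integer(nOrtho))
  # sign convention: case group scores positive
  caseIdx <- resp$y01 == 1
  if (mean(fit$t[caseIdx]) < mean(fit$t[!caseIdx])) {
    fit$w <- -fit$w; fit$t <- -fit$t; fit$p <- -fit$p; fit$c <- -fit$c
  }
  vip <- sqrt(ncol(Xs)) * abs(fit$w)   # ||w|| = 1
  names(vip) <- colnames(Xs)
  names(fit$w) <- names(fit$p) <- colnames(Xs)
  names(fit$t) <- rownames(Xs)
  new("OPLSModel", predictiveScores = fit$t, predictiveWeights = fit$w,
      predictiveLoadings = fit$p, yLoading = fit$c,
      orthoScores = fit$To, orthoWeights = fit$Wo,
      orthoLoadings = fit$Po, r2y = fit$r2y, r2xPred = fit$r2xPred,
      r2xOrtho = fit$r2xOrtho, q2 = NA_real_, vip = vip,
      classes = resp$classes, yCenter = resp$yCenter,
      nOrtho = as.integer(nOrtho))
}

# held-out prediction with a fitted OPLS core: strip orthogonal structure
# from the new data, then project on the predictive weight
.oplsPredict <- function(fit, Xnew) {
  for (h in seq_len(ncol(fit$To))) {
    to <- drop(Xnew %*% fit$Wo[, h])
    Xnew <- Xnew - tcrossprod(to, fit$Po[, h])
  }
  drop(Xnew %*% fit$w) * fit$c
}

# Q2 with the current RNG stream (no reseeding); X is raw samples x
# features, scaling refit inside each training fold
.q2Core <- function(X, y, nOrtho, folds, classes, logTransform,
                    offset = 1e-9) {
  resp <- .binaryResponse(y, classes)
  fold <- stratifiedFolds(y, folds)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    sc <- .scaleCore(X[tr, , drop = FALSE], logTransform, offset)
    ytr <- resp$y01[tr]
    fit <- .oplsCore(sc$values, ytr - mean(ytr), nOrtho)
    Xte <- .scaleCore(X[te, , drop = FALSE], logTransform, offset,
                      sc$center, sc$scale)$values
    yhat <- .oplsPredict(fit, Xte) + mean(ytr)
    press <- press + sum((resp$y01[te] - yhat)^2)
  }
  1 - press / sum(resp$yc^2)
}

#' Cross-validated Q2 of an OPLS-DA configuration
#'
#' Stratified k-fold cross-validation in which both the autoscaling
#' parameters and the OPLS-DA model are refit inside each training fold;
#' Q2 = 1 - PRESS / total sum of squares of the centered response over the
#' held-out predictions. Q2 <= 0 indicates no predictive value.
#'
#' @param X raw complete samples-x-features matrix (unscaled; scaling
#'   happens per fold).
#' @param y two-class labels; each class must have at least \code{folds}
#'   samples.
#' @param nOrtho orthogonal components.
#' @param folds number of folds, default 7.
#' @param seed RNG seed for the fold assignment.
#' @param classes optional c(reference, case).
#' @param logTransform apply log10 inside each fold's scaling.
#' @return Q2 (numeric scalar).
#' @export
q2CrossValidate <- function(X, y, nOrtho = 1, folds = 7, seed = 20250127,
                            classes = NULL, logTransform = TRUE) {
  X <- as.matrix(X)
  withSeed(seed, .q2Core(X, y, nOrtho, folds, classes, logTransform))
}

#' Label-permutation validation of an OPLS-DA model
#'
#' Refits the full model (including cross-validated Q2, with the same
#' number of orthogonal components) under \code{nPerm} uniformly random
#' label permutations and reports empirical p-values with the +1
#' correction: \code{p = (1 + #\{null >= observed\}) / (nPerm + 1)}, so p
#' ranges over [1/(nPerm+1), 1] and the minimum is attained when no
#' permutation matches the observed fit.
#'
#' @param X raw complete samples-x-features matrix.
#' @param y two-class labels.
#' @param nOrtho orthogonal components.
#' @param nPerm number of permutations, default 200.
#' @param folds CV folds for Q2.
#' @param seed RNG seed.
#' @param classes optional c(reference, case).
#' @param logTransform apply log10 inside scaling.
#' @return list(observedR2Y, observedQ2, nullR2Y, nullQ2, pR2, pQ2, nPerm,
#'   seed).
#' @export
permutationTest <- function(X, y, nOrtho = 1, nPerm = 200, folds = 7,
                            seed = 20250127, classes = NULL,
                            logTransform = TRUE) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  X <- as.matrix(X)
  withSeed(seed, {
    sc <- autoscale(X, logTransform = logTransform)
    obsFit <- fitOPLSDA(sc, y, nOrtho = nOrtho, classes = classes)
    obsQ2 <- .q2Core(X, y, nOrtho, folds, classes, logTransform)
    nullR2 <- nullQ2 <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
      yPerm <- sample(y)
      nullR2[b] <- fitOPLSDA(sc, yPerm, nOrtho = nOrtho,
                             classes = classes)@r2y
      nullQ2[b] <- .q2Core(X, yPerm, nOrtho, folds, classes, logTransform)
    }
    list(observedR2Y = obsFit@r2y, observedQ2 = obsQ2,
         nullR2Y = nullR2, nullQ2 = nullQ2,
         pR2 = (1 + sum(nullR2 >= obsFit@r2y)) / (nPerm + 1),
         pQ2 = (1 + sum(nullQ2 >= obsQ2)) / (nPerm + 1),
         nPerm = nPerm, seed = seed)
  })
}
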