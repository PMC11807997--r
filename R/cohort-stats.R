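# Cohort description statistics: chi-square contingency tests on
# categorical variables, Kruskal-Wallis + pairwise Mann-Whitney with
# Bonferroni correction on continuous measures, Hotelling's T2 for
# multivariate normal comparisons, and the normality gate that routes
# between the parametric and rank-based branches.

#' Pearson chi-square test of independence
#'
#' No continuity correction — the convention that reproduces the printed
#' cohort-description p-values from their counts. Expected counts are
#' row x column / total with df = (r-1)(c-1); a low-expected-count flag
#' (any expected < 5) is attached but the test is still computed.
#'
#' @param counts r x c matrix of non-negative counts with positive row and
#'   column sums.
#' @return list(observed, expected, statistic, df, p.value, low_expected).
#' @examples
#' gender <- rbind(male = c(27, 14, 22), female = c(30, 29, 40))
#' chiSquareIndependence(gender)$p.value   # 0.253
#' @export
chiSquareIndependence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal row/column; drop empty categories first")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(observed = counts, expected = ht$expected,
       statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, low_expected = any(ht$expected < 5))
}

#' Kruskal-Wallis omnibus test with Bonferroni-corrected pairwise
#' Mann-Whitney comparisons
#'
#' The omnibus three-group p-value uses the tie-corrected Kruskal-Wallis
#' statistic; all three pairwise two-sided Mann-Whitney U p-values are
#' reported with a significance flag at the Bonferroni level 0.05/3.
#'
#' @param values numeric vector.
#' @param groups group labels of the same length (3 groups, each >= 2
#'   values).
#' @return list(overall.p, pairwise) where pairwise is a
#'   data.frame(comparison, p, bonferroni_significant).
#' @export
kruskalThenPairwise <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stop("every group needs >= 2 values")
  overall <- stats::kruskal.test(values, groups)$p.value
  pairs <- utils::combn(levels(groups), 2L)
  nPairs <- ncol(pairs)
  pw <- apply(pairs, 2L, function(pr) {
    a <- values[groups == pr[1L]]; b <- values[groups == pr[2L]]
    suppressWarnings(stats::wilcox.test(a, b,
                                        alternative = "two.sided")$p.value)
  })
  list(overall.p = overall,
       pairwise = data.frame(
         comparison = apply(pairs, 2L, paste, collapse = "-"),
         p = pw,
         bonferroni_significant = pw < 0.05 / nPairs,
         row.names = NULL))
}

#' Hotelling's two-sample T-squared test
#'
#' T2 = (n1 n2 / (n1 + n2)) d' S_pooled^-1 d with d the mean difference
#' and S_pooled the pooled covariance;
#' F = T2 (n1 + n2 - dim - 1) / (dim (n1 + n2 - 2)) with
#' (dim, n1 + n2 - dim - 1) degrees of freedom. Intended for
#' low-dimensional summaries (model scores, selected covariates), not the
#' full feature matrix.
#'
#' @param groupA,groupB numeric matrices (samples x variables) or vectors.
#' @return list(T2, F, df1, df2, p.value).
#' @export
hotellingT2 <- function(groupA, groupB) {
  A <- as.matrix(groupA); B <- as.matrix(groupB)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between groups")
  n1 <- nrow(A); n2 <- nrow(B); d <- ncol(A)
  if (n1 + n2 - 2 <= d)
    stop("combined sample size minus 2 must exceed the dimension; ",
         "reduce the dimension (e.g. use model scores)")
  delta <- colMeans(A) - colMeans(B)
  Sp <- ((n1 - 1) * stats::cov(A) + (n2 - 1) * stats::cov(B)) /
    (n1 + n2 - 2)
  Sinv <- tryCatch(solve(Sp), error = function(e)
    stop("pooled covariance is singular; reduce the dimension"))
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(delta) %*% Sinv %*% delta)
  Fstat <- T2 * (n1 + n2 - d - 1) / (d * (n1 + n2 - 2))
  list(T2 = T2, F = Fstat, df1 = d, df2 = n1 + n2 - d - 1,
       p.value = stats::pf(Fstat, d, n1 + n2 - d - 1,
                           lower.tail = FALSE))
}

#' Normality gate
#'
#' Shapiro-Wilk at alpha = 0.05 within each group; the variable is routed
#' to the parametric branch (Hotelling) only if every group passes.
#' Groups with fewer than 3 values, or constant values, are treated as
#' non-normal with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha per-group Shapiro-Wilk level.
#' @return list(route = "normal"|"non-normal", p = per-group p-values).
#' @export
normalityGate <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  p <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3L) {
      warning("group '", g, "' has fewer than 3 values; ",
              "treated as non-normal")
      return(NA_real_)
    }
    if (stats::sd(v) == 0) {
      warning("group '", g, "' is constant; treated as non-normal")
      return(NA_real_)
    }
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  route <- if (all(!is.na(p)) && all(p > alpha)) "normal" else "non-normal"
  list(route = route, p = p)
}

#' Cohort description table
#'
#' Builds a cohort-description summary from sample metadata: categorical
#' covariates get level-by-group counts and a Pearson chi-square p-value;
#' continuous covariates get median (P25, P75) per group with the
#' normality-gated omnibus test (Kruskal-Wallis when any group is
#' non-normal) and Bonferroni-flagged pairwise comparisons.
#'
#' @param metadata data.frame with \code{group} (CN/MCI/AD; QC rows are
#'   dropped) and covariate columns.
#' @param covariates covariate column names; defaults to every column
#'   except sample_id/group/is_qc.
#' @return named list, one entry per covariate.
#' @export
cohortStats <- function(metadata, covariates = NULL) {
  md <- metadata[!(metadata$group %in% "QC"), , drop = FALSE]
  if (is.null(covariates))
    covariates <- setdiff(names(md), c("sample_id", "group", "is_qc"))
  out <- list()
  for (v in covariates) {
    x <- md[[v]]
    keep <- !is.na(x)
    g <- factor(md$group[keep], levels = c("AD", "MCI", "CN"))
    x <- x[keep]
    if (is.numeric(x)) {
      gate <- withCallingHandlers(normalityGate(x, g),
                                  warning = function(w)
                                    invokeRestart("muffleWarning"))
      res <- kruskalThenPairwise(x, g)
      qs <- tapply(x, g, function(v)
        sprintf("%.3g (%.3g, %.3g)", stats::median(v),
                stats::quantile(v, 0.25), stats::quantile(v, 0.75)))
      out[[v]] <- list(type = "continuous", route = gate$route,
                       summary = qs, overall.p = res$overall.p,
                       pairwise = res$pairwise)
    } else {
      counts <- table(factor(x), g)
      out[[v]] <- list(type = "categorical",
                       counts = unclass(counts),
                       test = chiSquareIndependence(unclass(counts)))
    }
  }
  out
}
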