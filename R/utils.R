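# internal helpers

# Evaluate expr with a private RNG stream; global .Random.seed restored after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# round-half-up (base round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise stage comparisons
#'
#' The three pairwise comparisons between disease stages, ordered
#' CN < MCI < AD. The reference group is the earlier stage, the case
#' group the later stage; fold changes are case mean / reference mean.
#'
#' @param name Comparison name, one of \code{"CN-MCI"}, \code{"CN-AD"},
#'   \code{"MCI-AD"}.
#' @return Named character vector with elements \code{reference} and
#'   \code{case}.
#' @examples
#' comparisonGroups("CN-AD")
#' @export
comparisonGroups <- function(name) {
  valid <- c("CN-MCI", "CN-AD", "MCI-AD")
  if (length(name) != 1L || !name %in% valid)
    stop("unknown comparison '", name, "'; must be one of ",
         paste(valid, collapse = ", "))
  parts <- strsplit(name, "-", fixed = TRUE)[[1L]]
  c(reference = parts[1L], case = parts[2L])
}

#' @rdname comparisonGroups
#' @export
stageComparisons <- function() c("CN-AD", "CN-MCI", "MCI-AD")

# stack the two ion-mode matrices (features x samples) over shared samples
combinedIntensities <- function(tables) {
  mats <- lapply(tables, intensities)
  shared <- Reduce(intersect, lapply(mats, colnames))
  if (length(shared) == 0L) stop("ion-mode tables share no samples")
  do.call(rbind, lapply(mats, function(m) m[, shared, drop = FALSE]))
}

# stratified fold assignment: within each class, shuffled cyclic fold ids
stratifiedFolds <- function(y, folds) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < folds)
      stop("class '", lev, "' has ", length(idx), " samples, fewer than ",
           folds, " folds; use fewer folds")
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}
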