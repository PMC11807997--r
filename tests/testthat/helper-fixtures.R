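# Small in-code fixtures shared across test files.

# a tiny MetaboSet with explicit groups and QC columns
tinySet <- function(intensity, groups, mode = "negative") {
  md <- data.frame(sample_id = colnames(intensity), group = groups,
                   stringsAsFactors = FALSE)
  MetaboSet(intensity, mode, sampleData = md)
}

# fast small cohort design for pipeline-level tests
smallDesign <- function(...) {
  args <- list(groupSizes = c(CN = 20, MCI = 15, AD = 20),
               nFeaturesNeg = 40, nFeaturesPos = 40, nQC = 10,
               plantedEffects = defaultPlantedEffects(40, 40,
                                                      perComparison = 10),
               nPathways = 8, pathwaySize = 10, plantedPerPathway = 5,
               seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(CohortDesign, args)
}

# two-class gaussian data with planted mean shifts on the first nSignal
# features; returns a raw (positive) matrix suitable for log-free scaling
twoClassData <- function(n1 = 30, n2 = 30, p = 20, nSignal = 5,
                         shift = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p,
              dimnames = list(sprintf("s%03d", seq_len(n1 + n2)),
                              sprintf("f%03d", seq_len(p))))
  y <- rep(c("A", "B"), c(n1, n2))
  if (nSignal > 0)
    X[y == "B", seq_len(nSignal)] <- X[y == "B", seq_len(nSignal)] + shift
  list(X = X, y = y)
}
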