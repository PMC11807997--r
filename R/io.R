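# Tabular IO: feature tables, sample metadata, pathway maps.
# Feature tables are features-as-rows: row 1 = sample ids, column 1 =
# feature ids. Delimiter is auto-detected from {tab, comma}. Empty cells
# and the configured sentinel tokens are missing; "0" is a measured zero.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))) "\t"
  else ","
}

#' Read a feature intensity table
#'
#' Parses a TSV/CSV feature-by-sample intensity matrix into a
#' \linkS4class{MetaboSet}. The first row holds sample ids, the first
#' column feature ids. Empty cells and \code{missingTokens} become missing
#' values; any other non-numeric cell is an error reporting its row and
#' column. Zeros are kept as measured intensities.
#'
#' @param path file path.
#' @param ionMode \code{"negative"} or \code{"positive"}.
#' @param missingTokens character tokens treated as missing (besides the
#'   empty cell).
#' @return A \linkS4class{MetaboSet} (no sample metadata attached).
#' @seealso \code{\link{writeFeatureTable}}
#' @export
readFeatureTable <- function(path, ionMode = c("negative", "positive"),
                             missingTokens = c("", "NA")) {
  ionMode <- match.arg(ionMode)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detectSep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[cells %in% missingTokens] <- NA_character_
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell '", cells[bad[1L, , drop = FALSE]],
         "' at feature row ", bad[1L, 1L], " (", ids[bad[1L, 1L]],
         "), sample column ", bad[1L, 2L],
         " (", colnames(cells)[bad[1L, 2L]], ")")
  dimnames(vals) <- list(ids, colnames(cells))
  MetaboSet(vals, ionMode)
}

#' Write a feature intensity table
#'
#' Inverse of \code{\link{readFeatureTable}}: missing cells are written as
#' empty fields so that a read/write round trip is the identity.
#'
#' @param x a \linkS4class{MetaboSet}.
#' @param path output path.
#' @param sep field delimiter, tab by default.
#' @export
writeFeatureTable <- function(x, path, sep = "\t") {
  m <- intensities(x)
  out <- cbind(feature_id = rownames(m),
               as.data.frame(m, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a delimited file with at least \code{sample_id} and \code{group}
#' columns; \code{group} must be one of CN, MCI, AD, QC. An \code{is_qc}
#' column is derived from the group when absent. All remaining columns are
#' kept as covariates.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detectSep(path)
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group"))
    if (!col %in% names(md))
      stop("metadata is missing required column '", col, "'")
  md$sample_id <- as.character(md$sample_id)
  md$group <- as.character(md$group)
  bad <- setdiff(unique(md$group), c("CN", "MCI", "AD", "QC"))
  if (length(bad))
    stop("unknown group token(s): ", paste(bad, collapse = ", "),
         " (allowed: CN, MCI, AD, QC)")
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]),
               collapse = ", "))
  if (!"is_qc" %in% names(md)) md$is_qc <- md$group == "QC"
  md$is_qc <- as.logical(md$is_qc)
  md
}

#' @rdname readSampleMetadata
#' @param md metadata data.frame.
#' @param path output path.
#' @export
writeSampleMetadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a pathway annotation map
#'
#' The on-disk format is a long TSV with columns \code{pathway_id},
#' \code{pathway_name}, \code{metabolite_id}; rows are aggregated into
#' member sets (repeated rows collapse).
#'
#' @param path file path.
#' @return \code{readPathwayMap}: a \linkS4class{PathwaySet}.
#' @export
readPathwayMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detectSep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("pathway_id", "pathway_name", "metabolite_id"))
    if (!col %in% names(tab))
      stop("pathway map is missing required column '", col, "'")
  sets <- split(as.character(tab$metabolite_id),
                as.character(tab$pathway_id))
  labels <- vapply(split(as.character(tab$pathway_name),
                         as.character(tab$pathway_id)),
                   function(v) v[1L], character(1))
  PathwaySet(sets, labels)
}

#' @rdname readPathwayMap
#' @param pathways a \linkS4class{PathwaySet}.
#' @export
writePathwayMap <- function(pathways, path) {
  sets <- pathwaySets(pathways)
  labels <- pathwayLabels(pathways)
  tab <- data.frame(
    pathway_id = rep(names(sets), lengths(sets)),
    pathway_name = rep(labels[names(sets)], lengths(sets)),
    metabolite_id = unlist(sets, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Persist / restore a SyntheticTruth registry as JSON
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
  obj <- list(
    differential_features = lapply(truth@differentialFeatures, function(df)
      list(feature_id = df$feature_id, fold_change = df$fold_change)),
    enriched_pathways = as.list(truth@enrichedPathways),
    qc_excluded_features = truth@qcExcludedFeatures)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SyntheticTruth",
      differentialFeatures = lapply(obj$differential_features, function(e)
        data.frame(feature_id = as.character(e$feature_id),
                   fold_change = as.numeric(e$fold_change))),
      enrichedPathways = unlist(obj$enriched_pathways),
      qcExcludedFeatures = as.character(obj$qc_excluded_features))
}

#' Cohort-description contingency tables
#'
#' Loads the categorical (yes/no or level-by-group) contingency tables of a
#' staged cohort description from a long TSV with columns \code{variable},
#' \code{level}, \code{AD}, \code{MCI}, \code{CN}. The package ships the
#' published staged Alzheimer's urine cohort's demographic tables
#' (57 AD / 43 MCI / 62 CN participants) in
#' \code{inst/extdata/cohort_contingency.tsv}.
#'
#' @param path TSV path; defaults to the shipped cohort description.
#' @return named list of level-by-group count matrices, one per variable.
#' @examples
#' tabs <- readContingencyTables()
#' chiSquareIndependence(tabs$gender)$p.value
#' @export
readContingencyTables <- function(path = system.file(
    "extdata", "cohort_contingency.tsv", package = "metaboStage")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  lapply(split(tab, factor(tab$variable, levels = unique(tab$variable))),
         function(d) {
           m <- as.matrix(d[, c("AD", "MCI", "CN")])
           rownames(m) <- d$level
           m
         })
}
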