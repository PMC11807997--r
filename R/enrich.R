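# Pathway over-representation by the hypergeometric upper tail.

#' Pathway over-representation analysis
#'
#' For each pathway, tests whether the differential set overlaps the
#' pathway more than expected by chance under the hypergeometric
#' distribution: with N background features, K of them in the pathway, n
#' differential and x overlapping,
#' p = sum_\{k = x..min(K, n)\} C(K, k) C(N-K, n-k) / C(N, n)
#' (upper tail; x = 0 gives p = 1). The background universe is the
#' annotated, QC-passing feature set; differential ids from both ion modes
#' are merged before testing, as pathway identity is mode-agnostic.
#' Results are sorted by p with BH adjustment across the tested pathways.
#'
#' @param differential character vector of differential feature ids; must
#'   be a subset of \code{background}.
#' @param background character vector of universe feature ids (typically
#'   all annotated features that survived preprocessing).
#' @param pathways a \linkS4class{PathwaySet}.
#' @return data.frame with one row per pathway with at least one annotated
#'   background member: pathway_id, pathway_name, n_background,
#'   n_in_pathway, n_differential, n_overlap, rich_factor, p_value,
#'   bh_adjusted_p, overlap_ids.
#' @examples
#' pw <- PathwaySet(list(p1 = c("a", "b", "c"), p2 = c("d", "e")))
#' enrichPathways(c("a", "b"), letters[1:6], pw)
#' @export
enrichPathways <- function(differential, background, pathways) {
  differential <- unique(as.character(differential))
  background <- unique(as.character(background))
  stray <- setdiff(differential, background)
  if (length(stray))
    stop("differential id(s) absent from background: ",
         paste(stray, collapse = ", "))
  N <- length(background)
  n <- length(differential)
  sets <- pathwaySets(pathways)
  labels <- pathwayLabels(pathways)
  rows <- lapply(names(sets), function(pid) {
    inPath <- intersect(sets[[pid]], background)
    K <- length(inPath)
    if (K == 0L) return(NULL)
    overlap <- intersect(inPath, differential)
    x <- length(overlap)
    p <- if (x == 0L) 1 else
      stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, pathway_name = unname(labels[pid]),
               n_background = N, n_in_pathway = K, n_differential = n,
               n_overlap = x, rich_factor = if (K > 0) x / K else NA_real_,
               p_value = p,
               overlap_ids = paste(sort(overlap), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway_id = character(), pathway_name = character(),
                      n_background = integer(), n_in_pathway = integer(),
                      n_differential = integer(), n_overlap = integer(),
                      rich_factor = numeric(), p_value = numeric(),
                      bh_adjusted_p = numeric(),
                      overlap_ids = character()))
  out$bh_adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway_id),
             c("pathway_id", "pathway_name", "n_background",
               "n_in_pathway", "n_differential", "n_overlap",
               "rich_factor", "p_value", "bh_adjusted_p", "overlap_ids")]
  rownames(out) <- NULL
  out
}
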