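## Knowledge-base utilities around the filter itself: supplement a reading
## set with database interactions co-cited by the papers that were read, and
## retrieve candidate papers for reading from database citations. Only the
## sources that carry citations (BioGRID and Reactome) are searched.

#' Expand a reading set with co-cited database interactions
#'
#' Finds knowledge-base interactions that cite any of the papers the
#' reading engines processed — interactions present in those papers that
#' the readers may have missed. Returned interactions are marked as
#' database expansions and as lacking direction (presence sources record
#' that an interaction is known, not which way it points).
#'
#' @param readingRefs character vector of paper identifiers that were read.
#' @param kb a \linkS4class{KnowledgeBase}.
#' @return data.frame: one row per (pair, source) with \code{a}, \code{b},
#'   \code{source}, \code{citingPapers}, \code{sharedPapers} (which reading
#'   refs it shares), \code{flag} = \code{"db-expansion"},
#'   \code{directed} = \code{FALSE}; sorted by pair key.
#' @export
expandByCitation <- function(readingRefs, kb) {
  hits <- interactionsCiting(kb, readingRefs)
  if (nrow(hits) == 0) {
    hits$flag <- character(0)
    hits$directed <- logical(0)
    return(hits)
  }
  hits$flag <- "db-expansion"
  hits$directed <- FALSE
  hits
}

#' Retrieve candidate papers from database citations
#'
#' Searches the citation-carrying presence tables for papers cited by at
#' least one interaction involving at least one query protein, and ranks
#' them by how many qualifying interactions cite them (ties broken by
#' paper identifier). Query proteins may be given in any namespace the
#' cross-map knows; an unresolvable query protein is skipped with a
#' warning. An optional allow-list (e.g. of open-access papers) restricts
#' the output.
#'
#' @param proteins character vector of query protein identifiers.
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param allowList optional character vector of admissible paper IDs.
#' @return data.frame with \code{paper} and \code{nInteractions}, ranked.
#' @export
retrievePapers <- function(proteins, kb, allowList = NULL) {
  canon <- character(0)
  for (p in proteins) {
    r <- resolveId(p, "protein", kb@idMap, "string")
    if (r$status == "ok") canon <- c(canon, r$id)
    else warning("query protein could not be resolved, skipping: ", p)
  }
  empty <- data.frame(paper = character(0), nInteractions = integer(0),
                      stringsAsFactors = FALSE)
  if (length(canon) == 0) return(empty)
  hits <- interactionsInvolving(kb, canon)
  if (nrow(hits) == 0) return(empty)
  ## count each interaction pair once per paper, regardless of source
  pairPapers <- unique(do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    papers <- splitPapers(hits$citingPapers[i])
    if (length(papers) == 0) return(NULL)
    data.frame(pair = paste(hits$a[i], hits$b[i], sep = "|"),
               paper = papers, stringsAsFactors = FALSE)
  })))
  if (is.null(pairPapers) || nrow(pairPapers) == 0) return(empty)
  if (!is.null(allowList))
    pairPapers <- pairPapers[pairPapers$paper %in% allowList, , drop = FALSE]
  if (nrow(pairPapers) == 0) return(empty)
  tally <- table(pairPapers$paper)
  out <- data.frame(paper = names(tally),
                    nInteractions = as.integer(tally),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$nInteractions, out$paper), , drop = FALSE]
  rownames(out) <- NULL
  out
}
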