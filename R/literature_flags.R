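## Non-database criteria: potentially-novel (recent publication year) and
## between-paper duplicate (same grounded interaction extracted from several
## distinct papers) flags. Both are computed on a canonical interaction key
## that ignores direction and effect sign, since the databases the filter
## emulates are sign-agnostic.

## canonical key: interaction class + unordered pair of canonical IDs (falls
## back to normalized raw IDs for rows that did not resolve)
canonicalEventKey <- function(events) {
  a <- if ("canonA" %in% names(events)) events$canonA
       else rep(NA_character_, nrow(events))
  b <- if ("canonB" %in% names(events)) events$canonB
       else rep(NA_character_, nrow(events))
  normRaw <- function(id, type) {
    id <- trimws(id)
    chem <- type == "chemical"
    id[chem] <- vapply(id[chem], function(x) {
      n <- normalizeChemicalId(x)$id
      if (is.na(n)) x else n
    }, "")
    id
  }
  fallbackA <- normRaw(events$regulatedId, events$regulatedType)
  fallbackB <- normRaw(events$regulatorId, events$regulatorType)
  a <- ifelse(is.na(a), fallbackA, a)
  b <- ifelse(is.na(b), fallbackB, b)
  cls <- if ("class" %in% names(events)) events$class
         else mapply(classifyInteraction, events$regulatedType,
                     events$regulatorType)
  op <- orderPair(a, b)
  paste(cls, op$a, op$b, sep = "|")
}

#' Count distinct-paper support per interaction
#'
#' Groups events by their canonical key (class + unordered canonical pair;
#' effect and direction are ignored) and collects the set of distinct
#' papers reporting each. Repeats inside one paper collapse: a within-paper
#' duplicate is not multi-paper evidence.
#'
#' @param events event data.frame (see \code{\link{readExtracted}}).
#' @return named list, key -> character vector of distinct references.
#' @export
countPaperSupport <- function(events) {
  key <- canonicalEventKey(events)
  lapply(split(events$reference, key), function(refs) sort(unique(refs)))
}

#' Assign literature flags to every event
#'
#' \code{novel} is true when the publication-year criterion is active, the
#' row's year is known, and the year is strictly after the threshold
#' ("published after 2014" selects 2015 onward). \code{dupCount} is the
#' number of distinct papers reporting the row's interaction (>= 1 for any
#' row present), \code{dupCriterion} compares it to the policy's minimum,
#' and \code{withinPaperDuplicate} marks rows whose (interaction, paper)
#' combination occurs more than once. Inactive criteria are false for all
#' rows, never \code{NA}.
#'
#' @param events event data.frame; years taken from its \code{year} column.
#' @param minYear earliest publication year threshold (strict) or \code{NA}.
#' @param minDupPapers least required distinct-paper count (>= 2) or
#'   \code{NA}.
#' @return data.frame with columns \code{novel}, \code{dupCount},
#'   \code{dupCriterion}, \code{withinPaperDuplicate},
#'   \code{yearKnown}; row order matches the input.
#' @export
assignLiteratureFlags <- function(events, minYear = NA, minDupPapers = NA) {
  key <- canonicalEventKey(events)
  support <- countPaperSupport(events)
  dupCount <- vapply(support[key], length, 0L)
  pairKey <- paste(key, events$reference, sep = "\1")
  withinDup <- ave(seq_along(pairKey), pairKey, FUN = length) > 1
  yearKnown <- !is.na(events$year)
  novel <- if (is.na(minYear)) rep(FALSE, nrow(events))
           else yearKnown & events$year > minYear
  dupCriterion <- if (is.na(minDupPapers)) rep(FALSE, nrow(events))
                  else dupCount >= minDupPapers
  data.frame(novel = novel, dupCount = dupCount,
             dupCriterion = dupCriterion,
             withinPaperDuplicate = withinDup,
             yearKnown = yearKnown, stringsAsFactors = FALSE)
}
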