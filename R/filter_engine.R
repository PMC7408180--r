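## Core selection: classify each event, resolve its identifiers, look the
## pair (or annotation) up in the knowledge base, and apply the threshold
## policy. Effect sign, direction and the reference listed are never
## consulted during matching.

#' Construct a threshold policy
#'
#' @param escoreMin,dscoreMin,tscoreMin subscore thresholds on the 0-1000
#'   scale, \code{NA} = no constraint.
#' @param combine \code{"any"} (at least one active comparison passes) or
#'   \code{"all"} (every active comparison passes).
#' @param inclusive compare with \code{>=} (the default) or \code{>}.
#' @param evidenceKinds optional subset of
#'   \code{c("experimental","electronic","other")} restricting which
#'   annotation curation kinds support a protein-process event.
#' @param minYear earliest-publication-year criterion (strict) or \code{NA}.
#' @param minDupPapers least distinct-paper count (>= 2) or \code{NA}.
#' @param nondbMode \code{"off"}, \code{"flag_only"} or \code{"union"}.
#' @return a \linkS4class{ThresholdPolicy}.
#' @export
thresholdPolicy <- function(escoreMin = 0, dscoreMin = 0, tscoreMin = 0,
                            combine = c("any", "all"), inclusive = TRUE,
                            evidenceKinds = character(0), minYear = NA,
                            minDupPapers = NA,
                            nondbMode = c("off", "flag_only", "union")) {
  new("ThresholdPolicy",
      escoreMin = as.numeric(escoreMin), dscoreMin = as.numeric(dscoreMin),
      tscoreMin = as.numeric(tscoreMin), combine = match.arg(combine),
      inclusive = inclusive, evidenceKinds = as.character(evidenceKinds),
      minYear = as.numeric(minYear), minDupPapers = as.numeric(minDupPapers),
      nondbMode = match.arg(nondbMode))
}

SUPPORTED_CLASSES <- c("PPI", "PCI", "PBPI")

resolveEventElements <- function(events, kb) {
  n <- nrow(events)
  cls <- mapply(classifyInteraction, events$regulatedType,
                events$regulatorType, USE.NAMES = FALSE)
  canonA <- canonB <- rep(NA_character_, n)
  mapStatus <- rep("ok", n)
  for (i in seq_len(n)) {
    if (!cls[i] %in% SUPPORTED_CLASSES) next
    ra <- resolveId(events$regulatedId[i], events$regulatedType[i], kb@idMap)
    rb <- resolveId(events$regulatorId[i], events$regulatorType[i], kb@idMap)
    if (ra$status == "ambiguous" || rb$status == "ambiguous")
      mapStatus[i] <- "ambiguous"
    else if (ra$status == "unmapped" || rb$status == "unmapped")
      mapStatus[i] <- "unmapped"
    if (ra$status == "ok") canonA[i] <- ra$id
    if (rb$status == "ok") canonB[i] <- rb$id
  }
  events$class <- cls
  events$canonA <- canonA
  events$canonB <- canonB
  events$mapStatus <- mapStatus
  events
}

#' Look up all knowledge-base support for one event
#'
#' Routes by interaction class: protein pairs are searched in the scored
#' table and both presence tables, protein-chemical pairs in the scored
#' chemical table, protein-process pairs in the annotation table. Classes
#' with no backing database (chemical-chemical, chemical-process,
#' process-process, OTHER) report \code{unsupported_type}; events whose
#' identifiers did not resolve report \code{unmapped} with all evidence
#' fields absent.
#'
#' @param event one-row event data.frame (see \code{\link{readExtracted}}).
#' @param kb a \linkS4class{KnowledgeBase}.
#' @return list: \code{class}, \code{status} (\code{ok}/\code{unmapped}/
#'   \code{ambiguous}/\code{unsupported_type}), \code{matched},
#'   \code{escore}, \code{dscore}, \code{tscore}, \code{presenceSources},
#'   \code{pbpEvidence}, \code{citingPapers}.
#' @export
lookupSupport <- function(event, kb) {
  prepared <- prepareSupport(event, kb)
  list(class = prepared$class[1],
       status = if (prepared$class[1] %in% SUPPORTED_CLASSES)
                  prepared$mapStatus[1] else "unsupported_type",
       matched = prepared$matched[1],
       escore = prepared$escore[1], dscore = prepared$dscore[1],
       tscore = prepared$tscore[1],
       presenceSources = splitPapers(prepared$presenceSources[1]),
       pbpEvidence = splitPapers(prepared$pbpEvidence[1]),
       citingPapers = splitPapers(prepared$citingPapers[1]))
}

## classify + resolve + knowledge-base lookup for every row; adds support
## columns but applies no policy (sweeps re-use the prepared table)
prepareSupport <- function(events, kb) {
  events <- resolveEventElements(events, kb)
  n <- nrow(events)
  matched <- rep(FALSE, n)
  escore <- dscore <- tscore <- rep(NA_integer_, n)
  presence <- pbpEv <- citing <- rep("", n)
  for (i in seq_len(n)) {
    if (!events$class[i] %in% SUPPORTED_CLASSES ||
        events$mapStatus[i] != "ok") next
    a <- events$canonA[i]; b <- events$canonB[i]
    if (events$class[i] == "PPI") {
      q <- queryPpi(kb, a, b)
      if (!is.null(q)) {
        matched[i] <- TRUE
        escore[i] <- q$escore; dscore[i] <- q$dscore; tscore[i] <- q$tscore
        presence[i] <- paste(q$presenceSources, collapse = ";")
        citing[i] <- paste(q$citingPapers, collapse = ";")
      }
    } else if (events$class[i] == "PCI") {
      types <- c(events$regulatedType[i], events$regulatorType[i])
      prot <- if (types[1] == "protein") a else b
      chem <- if (types[1] == "chemical") a else b
      q <- queryPci(kb, prot, chem)
      if (!is.null(q)) {
        matched[i] <- TRUE
        escore[i] <- q$escore; dscore[i] <- q$dscore; tscore[i] <- q$tscore
      }
    } else if (events$class[i] == "PBPI") {
      types <- c(events$regulatedType[i], events$regulatorType[i])
      prot <- if (types[1] == "protein") a else b
      proc <- if (types[1] == "biological-process") a else b
      q <- queryPbp(kb, prot, proc)
      if (nrow(q)) {
        matched[i] <- TRUE
        pbpEv[i] <- paste(sort(unique(q$evidenceKind)), collapse = ";")
      }
    }
  }
  events$matched <- matched
  events$escore <- escore; events$dscore <- dscore; events$tscore <- tscore
  events$presenceSources <- presence
  events$pbpEvidence <- pbpEv
  events$citingPapers <- citing
  events$citingPaperCount <- lengths(lapply(citing, splitPapers))
  events
}

#' Does a support record pass the database thresholds?
#'
#' For scored classes every non-absent subscore threshold is an active
#' comparison; \code{combine} decides whether one or all must pass.
#' Presence-only protein pairs (known to BioGRID/Reactome but unscored)
#' have nothing to compare: they pass only when every active threshold is
#' zero-and-inclusive. Protein-process events pass when matched and, if an
#' evidence-kind filter is set, at least one annotation's curation kind is
#' allowed. Unmatched records never pass.
#'
#' @param support list from \code{\link{lookupSupport}} (or a one-row slice
#'   of a prepared event table).
#' @param policy a \linkS4class{ThresholdPolicy}.
#' @return list with \code{pass} (logical) and \code{reason} (character).
#' @export
passesPolicy <- function(support, policy) {
  if (!isTRUE(support$matched))
    return(list(pass = FALSE, reason = "not-in-kb"))
  cmp <- if (policy@inclusive) `>=` else `>`
  if (support$class == "PBPI") {
    kinds <- support$pbpEvidence
    if (is.character(kinds) && length(kinds) == 1)
      kinds <- splitPapers(kinds)
    if (length(policy@evidenceKinds) == 0 ||
        any(kinds %in% policy@evidenceKinds))
      return(list(pass = TRUE, reason = "db-annotation"))
    return(list(pass = FALSE, reason = "evidence-kind-excluded"))
  }
  thr <- c(escore = policy@escoreMin, dscore = policy@dscoreMin,
           tscore = policy@tscoreMin)
  active <- !is.na(thr)
  scores <- c(escore = support$escore, dscore = support$dscore,
              tscore = support$tscore)
  if (all(is.na(scores))) {
    ## presence-only match: no scores to compare
    vacuous <- !any(active) || all(thr[active] == 0 & policy@inclusive)
    if (vacuous) return(list(pass = TRUE, reason = "db-presence"))
    return(list(pass = FALSE, reason = "presence-only-below-threshold"))
  }
  if (!any(active)) return(list(pass = TRUE, reason = "db-match"))
  ok <- cmp(scores[active], thr[active])
  pass <- if (policy@combine == "any") any(ok) else all(ok)
  list(pass = pass,
       reason = if (pass) "db-threshold" else "below-threshold")
}

#' Filter a reading set against the knowledge base
#'
#' Partitions the input four ways: events of a class with no backing
#' database are \code{unsupported_type}; events whose identifiers cannot be
#' resolved (or resolve ambiguously) are \code{unmapped}; the rest are
#' \code{selected} or \code{discarded} by \code{\link{passesPolicy}}.
#' Literature flags are always computed and reported. With
#' \code{nondbMode = "union"}, a mapped supported-class row that failed the
#' database thresholds is still selected when the novelty or duplicate
#' criterion holds (its reason records which); with \code{"flag_only"} the
#' flags are attached but selection stays database-only.
#'
#' @param events event data.frame (see \code{\link{readExtracted}}).
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param policy a \linkS4class{ThresholdPolicy}.
#' @param years optional reference-to-year named vector or side-table path
#'   (rows with unknown year can never be flagged novel).
#' @return a \linkS4class{FilterResult}.
#' @export
filterInteractions <- function(events, kb, policy = thresholdPolicy(),
                               years = NULL) {
  prepared <- prepareSupport(events, kb)
  finalizeFilter(prepared, policy, years)
}

## policy application over an already-prepared support table
finalizeFilter <- function(prepared, policy, years = NULL) {
  if (!is.null(years)) {
    if (is.character(years) && length(years) == 1 && file.exists(years))
      years <- readYearTable(years)
    known <- prepared$reference %in% names(years)
    prepared$year[known] <- as.integer(years[prepared$reference[known]])
  }
  if (is.null(prepared$year)) prepared$year <- NA_integer_
  useNondb <- policy@nondbMode != "off"
  flags <- assignLiteratureFlags(prepared,
    minYear = if (useNondb) policy@minYear else NA,
    minDupPapers = if (useNondb) policy@minDupPapers else NA)
  prepared$novel <- flags$novel
  prepared$dupCount <- flags$dupCount
  prepared$withinPaperDuplicate <- flags$withinPaperDuplicate

  n <- nrow(prepared)
  verdict <- reason <- character(n)
  for (i in seq_len(n)) {
    if (!prepared$class[i] %in% SUPPORTED_CLASSES) {
      verdict[i] <- "unsupported_type"; reason[i] <- "unsupported-class"
    } else if (prepared$mapStatus[i] != "ok") {
      verdict[i] <- "unmapped"
      reason[i] <- if (prepared$mapStatus[i] == "ambiguous")
        "ambiguous-grounding" else "unmapped"
    } else {
      p <- passesPolicy(prepared[i, ], policy)
      if (p$pass) {
        verdict[i] <- "selected"; reason[i] <- p$reason
      } else if (policy@nondbMode == "union" &&
                 (flags$novel[i] || flags$dupCriterion[i])) {
        verdict[i] <- "selected"
        reason[i] <- if (flags$dupCriterion[i] && flags$novel[i])
          "nondb-novel+duplicates"
        else if (flags$dupCriterion[i]) "nondb-duplicates" else "nondb-novel"
      } else {
        verdict[i] <- "discarded"; reason[i] <- p$reason
      }
    }
  }
  prepared$matchStatus <- ifelse(prepared$class %in% SUPPORTED_CLASSES,
                                 ifelse(prepared$mapStatus != "ok",
                                        prepared$mapStatus,
                                        ifelse(prepared$matched, "matched",
                                               "not-in-kb")),
                                 "unsupported-class")
  prepared$verdict <- verdict
  prepared$reason <- reason
  summary <- list(
    n_input = n,
    n_selected = sum(verdict == "selected"),
    n_discarded = sum(verdict == "discarded"),
    n_unmapped = sum(verdict == "unmapped"),
    n_unsupported = sum(verdict == "unsupported_type"),
    n_ambiguous = sum(prepared$mapStatus == "ambiguous"),
    pct_selected = 100 * sum(verdict == "selected") / max(1L, n),
    by_class = as.list(table(prepared$class)),
    by_reason = as.list(table(reason)))
  new("FilterResult", events = prepared, policy = policy, summary = summary)
}

#' Partition accessors for a filter result
#'
#' @param result a \linkS4class{FilterResult}.
#' @return the rows of the corresponding partition (input order preserved).
#' @export
selectedEvents <- function(result)
  result@events[result@events$verdict == "selected", , drop = FALSE]

#' @rdname selectedEvents
#' @export
discardedEvents <- function(result)
  result@events[result@events$verdict == "discarded", , drop = FALSE]

#' @rdname selectedEvents
#' @export
unmappedEvents <- function(result)
  result@events[result@events$verdict == "unmapped", , drop = FALSE]

#' @rdname selectedEvents
#' @export
unsupportedEvents <- function(result)
  result@events[result@events$verdict == "unsupported_type", , drop = FALSE]

#' @rdname selectedEvents
#' @export
filterSummary <- function(result) result@summary
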