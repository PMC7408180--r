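## Tabular machine-reading event format: nine named columns, one extracted
## event per row (regulated element, regulator element, effect, source paper,
## evidence sentence).

EVENT_COLUMNS <- c("Regulated", "Regulated type", "Regulated ID",
                   "Regulator", "Regulator type", "Regulator ID",
                   "Effect", "Reference", "Evidence")

RESULT_COLUMNS <- c("Interaction class", "Match status", "Escore", "Dscore",
                    "Tscore", "Presence sources", "Citing paper count",
                    "Novel", "Duplicate count", "Verdict", "Reason")

normalizeElementType <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ _]", "-", x)
  x[!x %in% ELEMENT_TYPES] <- "other"
  x
}

displayElementType <- function(x) gsub("-", " ", x)

#' Read a machine-reading event table
#'
#' Parses the tab-separated nine-column event dialect. Element types are
#' normalized to the internal enum; raw identifiers are preserved verbatim
#' (normalization for matching happens at filter time). Rows with a blank
#' identifier are kept and flagged as unmapped downstream, never dropped.
#' Publication years come from an optional tenth column
#' (\code{Publication year}) or from a reference-to-year side table.
#'
#' @param path tab-separated file with a header naming the nine columns.
#' @param years optional named numeric vector (reference -> year) or
#'   two-column side-table path readable by \code{\link{readYearTable}}.
#' @return data.frame with columns \code{regulated}, \code{regulatedType},
#'   \code{regulatedId}, \code{regulator}, \code{regulatorType},
#'   \code{regulatorId}, \code{effect}, \code{reference}, \code{evidence},
#'   \code{year}, \code{row} (input row index, order preserved).
#' @export
readExtracted <- function(path, years = NULL) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE,
                    quote = "\"")
  miss <- setdiff(EVENT_COLUMNS, names(tab))
  if (length(miss))
    stop("event file is missing required column(s): ",
         paste(miss, collapse = ", "))
  ev <- data.frame(regulated = tab$Regulated,
                   regulatedType = normalizeElementType(tab$`Regulated type`),
                   regulatedId = tab$`Regulated ID`,
                   regulator = tab$Regulator,
                   regulatorType = normalizeElementType(tab$`Regulator type`),
                   regulatorId = tab$`Regulator ID`,
                   effect = tab$Effect,
                   reference = tab$Reference,
                   evidence = tab$Evidence,
                   stringsAsFactors = FALSE)
  ev$year <- if ("Publication year" %in% names(tab))
    suppressWarnings(as.integer(tab$`Publication year`))
    else rep(NA_integer_, nrow(ev))
  if (!is.null(years)) {
    if (is.character(years) && length(years) == 1 && file.exists(years))
      years <- readYearTable(years)
    known <- ev$reference %in% names(years)
    ev$year[known] <- as.integer(years[ev$reference[known]])
  }
  ev$row <- seq_len(nrow(ev))
  ev
}

#' Write a machine-reading event table
#'
#' Inverse of \code{\link{readExtracted}}: emits the nine-column dialect
#' (element types in their display form, e.g. "biological process"), plus a
#' \code{Publication year} column when requested. Fields are quoted, so
#' evidence text containing tabs survives the round trip.
#'
#' @param events data.frame as returned by \code{\link{readExtracted}}.
#' @param path output file.
#' @param includeYear write the optional tenth column.
#' @export
writeExtracted <- function(events, path, includeYear = FALSE) {
  out <- data.frame(events$regulated, displayElementType(events$regulatedType),
                    events$regulatedId, events$regulator,
                    displayElementType(events$regulatorType),
                    events$regulatorId, events$effect, events$reference,
                    events$evidence, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- EVENT_COLUMNS
  if (includeYear) out$`Publication year` <- events$year
  writeTsv(out, path)
  invisible(path)
}

writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = TRUE, row.names = FALSE,
              na = "", eol = "\n")
}

#' Read a reference-to-publication-year side table
#'
#' @param path two-column tab-separated file (header \code{reference},
#'   \code{year}).
#' @return named integer vector, names are references.
#' @export
readYearTable <- function(path) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  setNames(as.integer(tab$year), tab$reference)
}

#' Classify an interaction by its participant element types
#'
#' The class is a symmetric function of the two element types alone:
#' protein-protein (PPI), protein-chemical (PCI), protein-process (PBPI),
#' chemical-chemical (CCI), chemical-process (CBPI), process-process
#' (BPBPI). Anything involving a protein family or an unrecognized type is
#' OTHER and excluded from database matching (no shared identifier
#' namespace).
#'
#' @param typeA,typeB element types (see \code{ELEMENT_TYPES}).
#' @return one of \code{"PPI"}, \code{"PCI"}, \code{"PBPI"}, \code{"CCI"},
#'   \code{"CBPI"}, \code{"BPBPI"}, \code{"OTHER"}.
#' @export
classifyInteraction <- function(typeA, typeB) {
  pair <- sort(c(typeA, typeB))
  if (any(pair %in% c("protein-family", "other"))) return("OTHER")
  key <- paste(pair, collapse = "+")
  switch(key,
         "protein+protein" = "PPI",
         "chemical+protein" = "PCI",
         "biological-process+protein" = "PBPI",
         "chemical+chemical" = "CCI",
         "biological-process+chemical" = "CBPI",
         "biological-process+biological-process" = "BPBPI",
         "OTHER")
}

#' Write a filter result table
#'
#' Repeats the nine input columns and appends, per row, everything the
#' knowledge base reported: interaction class, match status, the three
#' subscores, presence sources, citing-paper count, the novelty flag and
#' between-paper duplicate count, and the selection verdict with its
#' reason.
#'
#' @param result a \linkS4class{FilterResult}.
#' @param path output file.
#' @export
writeResults <- function(result, path) {
  ev <- result@events
  out <- data.frame(ev$regulated, displayElementType(ev$regulatedType),
                    ev$regulatedId, ev$regulator,
                    displayElementType(ev$regulatorType), ev$regulatorId,
                    ev$effect, ev$reference, ev$evidence,
                    ev$class, ev$matchStatus, ev$escore, ev$dscore, ev$tscore,
                    ev$presenceSources, ev$citingPaperCount,
                    ifelse(ev$novel, "yes", "no"), ev$dupCount,
                    ev$verdict, ev$reason,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(EVENT_COLUMNS, RESULT_COLUMNS)
  writeTsv(out, path)
  invisible(path)
}

#' Read back a filter result table
#'
#' @param path file written by \code{\link{writeResults}}.
#' @return data.frame in the internal column layout (see
#'   \code{\link{readExtracted}} plus the support/verdict columns).
#' @export
readResults <- function(path) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE,
                    quote = "\"")
  miss <- setdiff(c(EVENT_COLUMNS, RESULT_COLUMNS), names(tab))
  if (length(miss))
    stop("result file is missing required column(s): ",
         paste(miss, collapse = ", "))
  ev <- data.frame(regulated = tab$Regulated,
                   regulatedType = normalizeElementType(tab$`Regulated type`),
                   regulatedId = tab$`Regulated ID`,
                   regulator = tab$Regulator,
                   regulatorType = normalizeElementType(tab$`Regulator type`),
                   regulatorId = tab$`Regulator ID`,
                   effect = tab$Effect, reference = tab$Reference,
                   evidence = tab$Evidence,
                   class = tab$`Interaction class`,
                   matchStatus = tab$`Match status`,
                   escore = suppressWarnings(as.integer(tab$Escore)),
                   dscore = suppressWarnings(as.integer(tab$Dscore)),
                   tscore = suppressWarnings(as.integer(tab$Tscore)),
                   presenceSources = tab$`Presence sources`,
                   citingPaperCount = as.integer(tab$`Citing paper count`),
                   novel = tab$Novel == "yes",
                   dupCount = as.integer(tab$`Duplicate count`),
                   verdict = tab$Verdict, reason = tab$Reason,
                   stringsAsFactors = FALSE)
  ev$row <- seq_len(nrow(ev))
  ev
}
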