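#' @import methods
#' @importFrom utils read.delim read.table write.table head capture.output type.convert
#' @importFrom stats setNames runif ave
NULL

SCORE_MAX <- 1000L

ELEMENT_TYPES <- c("protein", "chemical", "biological-process",
                   "protein-family", "other")

INTERACTION_CLASSES <- c("PPI", "PCI", "PBPI", "CCI", "CBPI", "BPBPI", "OTHER")

EVIDENCE_KINDS <- c("experimental", "electronic", "other")

PRESENCE_SOURCES <- c("biogrid", "reactome")

#' Identifier cross-mapping table
#'
#' Holds the three-way mapping between STRING-style protein identifiers
#' (Ensembl-protein shaped, used by the scored interaction tables), UniProt
#' accessions (used by pathway and annotation sources and by extracted
#' events) and official gene symbols (used by physical-interaction dumps).
#' Any field of a triple may be missing; lookups work through whichever
#' fields are present.
#'
#' @slot triples data.frame with character columns \code{stringId},
#'   \code{uniprotId}, \code{geneSymbol}; \code{NA} marks an absent field.
#' @export
setClass("IdentityMap", representation(triples = "data.frame"))

setValidity("IdentityMap", function(object) {
  tr <- object@triples
  need <- c("stringId", "uniprotId", "geneSymbol")
  if (!all(need %in% names(tr)))
    return(sprintf("triples must have columns %s", paste(need, collapse = ", ")))
  if (nrow(tr) > 0 && any(rowSums(!is.na(tr[need])) == 0))
    return("every triple must have at least one non-missing field")
  TRUE
})

#' Unified interaction knowledge base
#'
#' The six-table store the filter queries: scored protein-protein
#' interactions (three confidence subscores per pair), unscored
#' protein-protein presence records with their citing papers, scored
#' protein-chemical interactions, protein-to-biological-process annotations,
#' and the identifier cross-map. Pairs are keyed order-insensitively
#' (stored as (min, max) under lexicographic order).
#'
#' @slot ppiScored data.frame: \code{a}, \code{b} (canonical protein IDs,
#'   \code{a <= b}), integer \code{escore}, \code{dscore}, \code{tscore}.
#' @slot ppiPresence data.frame: \code{a}, \code{b}, \code{source}
#'   (\code{"biogrid"} or \code{"reactome"}), \code{citingPapers}
#'   (semicolon-joined sorted paper IDs, possibly "").
#' @slot pci data.frame: \code{protein}, \code{chemical} (bare numeric CID as
#'   character), \code{stereo} (\code{"s"}, \code{"m"} or \code{""}),
#'   \code{escore}, \code{dscore}, \code{tscore}.
#' @slot pbp data.frame: \code{protein} (canonical ID), \code{uniprot}
#'   (accession as it appeared in the annotation file), \code{goTerm},
#'   \code{evidenceCode}, \code{evidenceKind}.
#' @slot idMap \linkS4class{IdentityMap}.
#' @slot species single taxon identifier (default "9606"); rows for other
#'   taxa are skipped at load time.
#' @slot metadata list: per-source load counts, skipped-row counts, file
#'   names, unresolved-identifier log.
#' @export
setClass("KnowledgeBase",
  representation(ppiScored = "data.frame", ppiPresence = "data.frame",
                 pci = "data.frame", pbp = "data.frame",
                 idMap = "IdentityMap", species = "character",
                 metadata = "list"))

setValidity("KnowledgeBase", function(object) {
  msg <- character(0)
  sc <- object@ppiScored
  if (nrow(sc) > 0) {
    bad <- sc$escore < 0 | sc$escore > SCORE_MAX |
           sc$dscore < 0 | sc$dscore > SCORE_MAX |
           sc$tscore < 0 | sc$tscore > SCORE_MAX
    if (any(bad)) msg <- c(msg, "ppiScored subscores must lie in [0, 1000]")
    if (any(sc$a > sc$b)) msg <- c(msg, "ppiScored pairs must be stored (min, max)")
  }
  pc <- object@pci
  if (nrow(pc) > 0) {
    bad <- pc$escore < 0 | pc$escore > SCORE_MAX |
           pc$dscore < 0 | pc$dscore > SCORE_MAX |
           pc$tscore < 0 | pc$tscore > SCORE_MAX
    if (any(bad)) msg <- c(msg, "pci subscores must lie in [0, 1000]")
  }
  pb <- object@pbp
  if (nrow(pb) > 0) {
    if (!all(grepl("^GO:[0-9]{7}$", pb$goTerm)))
      msg <- c(msg, "pbp goTerm must match GO: followed by 7 digits")
    if (!all(pb$evidenceKind %in% EVIDENCE_KINDS))
      msg <- c(msg, "pbp evidenceKind must be experimental/electronic/other")
  }
  pr <- object@ppiPresence
  if (nrow(pr) > 0 && !all(pr$source %in% PRESENCE_SOURCES))
    msg <- c(msg, "ppiPresence source must be biogrid or reactome")
  if (length(object@species) != 1) msg <- c(msg, "species must be a single value")
  if (length(msg)) msg else TRUE
})

#' Interaction selection policy
#'
#' Bundles the database thresholds (one per confidence subscore, each on the
#' 0-1000 scale, \code{NA} meaning no constraint), how active subscore
#' comparisons combine (\code{"any"}: at least one must pass; \code{"all"}:
#' every active one must pass), whether comparisons are inclusive
#' (\code{>=}) or exclusive (\code{>}), an optional evidence-kind filter for
#' protein-process annotations, and the two non-database criteria: earliest
#' allowed publication year (strict: "after 2014" selects years >= 2015) and
#' the least number of distinct papers reporting the same interaction.
#' \code{nondbMode} controls whether the non-database criteria are ignored
#' (\code{"off"}), attached as flags only (\code{"flag_only"}), or unioned
#' into the selection (\code{"union"}).
#'
#' @slot escoreMin,dscoreMin,tscoreMin numeric threshold or \code{NA}.
#' @slot combine \code{"any"} or \code{"all"}.
#' @slot inclusive logical; \code{TRUE} compares with \code{>=}.
#' @slot evidenceKinds character subset of
#'   \code{c("experimental","electronic","other")}; empty = no filter.
#' @slot minYear numeric year or \code{NA}.
#' @slot minDupPapers numeric (>= 2) or \code{NA}.
#' @slot nondbMode \code{"off"}, \code{"flag_only"} or \code{"union"}.
#' @export
setClass("ThresholdPolicy",
  representation(escoreMin = "numeric", dscoreMin = "numeric",
                 tscoreMin = "numeric", combine = "character",
                 inclusive = "logical", evidenceKinds = "character",
                 minYear = "numeric", minDupPapers = "numeric",
                 nondbMode = "character"))

setValidity("ThresholdPolicy", function(object) {
  msg <- character(0)
  for (nm in c("escoreMin", "dscoreMin", "tscoreMin")) {
    v <- slot(object, nm)
    if (length(v) != 1) msg <- c(msg, sprintf("%s must be length 1", nm))
    else if (!is.na(v) && (v < 0 || v > SCORE_MAX))
      msg <- c(msg, sprintf("%s must lie in [0, 1000]", nm))
  }
  if (!object@combine %in% c("any", "all"))
    msg <- c(msg, "combine must be 'any' or 'all'")
  if (!object@nondbMode %in% c("off", "flag_only", "union"))
    msg <- c(msg, "nondbMode must be off/flag_only/union")
  if (length(object@evidenceKinds) &&
      !all(object@evidenceKinds %in% EVIDENCE_KINDS))
    msg <- c(msg, "evidenceKinds must be within experimental/electronic/other")
  if (!is.na(object@minDupPapers) && object@minDupPapers < 2)
    msg <- c(msg, "minDupPapers must be >= 2")
  active <- !is.na(object@escoreMin) || !is.na(object@dscoreMin) ||
    !is.na(object@tscoreMin) || length(object@evidenceKinds) > 0 ||
    !is.na(object@minYear) || !is.na(object@minDupPapers)
  if (!active)
    msg <- c(msg, "at least one selection criterion must be active")
  if (length(msg)) msg else TRUE
})

#' Result of filtering a reading set
#'
#' Partitions the input events four ways — \code{selected},
#' \code{discarded} (found wanting under the policy), \code{unmapped}
#' (grounding could not be resolved) and \code{unsupported_type} (classes
#' with no backing database) — and carries, per row, all support found in
#' the knowledge base (subscores, presence sources, citing papers,
#' annotation evidence) plus the literature flags.
#'
#' @slot events data.frame: the input columns plus support, flag, verdict
#'   and reason columns (one row per input event, input order preserved).
#' @slot policy the \linkS4class{ThresholdPolicy} applied.
#' @slot summary list of partition and per-class tallies.
#' @export
setClass("FilterResult",
  representation(events = "data.frame", policy = "ThresholdPolicy",
                 summary = "list"))

setValidity("FilterResult", function(object) {
  ev <- object@events
  if (!"verdict" %in% names(ev)) return("events must carry a verdict column")
  if (!all(ev$verdict %in% c("selected", "discarded", "unmapped",
                             "unsupported_type")))
    return("verdict must be one of selected/discarded/unmapped/unsupported_type")
  s <- object@summary
  if (!is.null(s$n_input) && s$n_input != nrow(ev))
    return("summary n_input inconsistent with events")
  TRUE
})

setMethod("show", "IdentityMap", function(object) {
  tr <- object@triples
  cat(sprintf("IdentityMap with %d triples (%d STRING-style, %d UniProt, %d symbols)\n",
              nrow(tr), sum(!is.na(tr$stringId)), sum(!is.na(tr$uniprotId)),
              sum(!is.na(tr$geneSymbol))))
})

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase (species ", object@species, ")\n", sep = "")
  cat(sprintf("  scored PPI pairs     : %d\n", nrow(object@ppiScored)))
  cat(sprintf("  PPI presence records : %d (biogrid %d, reactome %d)\n",
              nrow(object@ppiPresence),
              sum(object@ppiPresence$source == "biogrid"),
              sum(object@ppiPresence$source == "reactome")))
  cat(sprintf("  scored PCI pairs     : %d\n", nrow(object@pci)))
  cat(sprintf("  GO annotations       : %d\n", nrow(object@pbp)))
  cat(sprintf("  ID-map triples       : %d\n", nrow(object@idMap@triples)))
})

setMethod("show", "ThresholdPolicy", function(object) {
  fmt <- function(v) if (is.na(v)) "-" else as.character(v)
  cat(sprintf(
    "ThresholdPolicy: escore %s %s, dscore %s %s, tscore %s %s (combine %s)\n",
    if (object@inclusive) ">=" else ">", fmt(object@escoreMin),
    if (object@inclusive) ">=" else ">", fmt(object@dscoreMin),
    if (object@inclusive) ">=" else ">", fmt(object@tscoreMin),
    object@combine))
  if (length(object@evidenceKinds))
    cat("  annotation evidence:", paste(object@evidenceKinds, collapse = ","), "\n")
  cat(sprintf("  non-database: mode %s, min year %s, min papers %s\n",
              object@nondbMode, fmt(object@minYear), fmt(object@minDupPapers)))
})

setMethod("show", "FilterResult", function(object) {
  s <- object@summary
  cat(sprintf(
    "FilterResult: %d events -> %d selected (%.2f%%), %d discarded, %d unmapped, %d unsupported type\n",
    s$n_input, s$n_selected, 100 * s$n_selected / max(1, s$n_input),
    s$n_discarded, s$n_unmapped, s$n_unsupported))
})
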