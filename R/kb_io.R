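## Persistence: dump-dialect exporters (shared with the fixture generator so
## export(load(file)) is a fixed point) and the single-file store.

combineScores <- function(e, d, t) {
  as.integer(round(SCORE_MAX *
    (1 - (1 - e / SCORE_MAX) * (1 - d / SCORE_MAX) * (1 - t / SCORE_MAX))))
}

writeLinesLF <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

formatChemicalId <- function(chemical, stereo) {
  sprintf("CID%s%08d", ifelse(nzchar(stereo), stereo, "m"),
          as.integer(chemical))
}

#' Export the scored protein-protein table in the STRING links dialect
#'
#' Writes the whitespace-delimited links-detailed layout, re-attaching the
#' taxon prefix. Channels not stored (neighborhood, fusion) are written as
#' zero and the combined score is recomputed from the three stored
#' subscores with the standard independent-evidence combination.
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param path output file.
#' @export
exportStringLinks <- function(kb, path) {
  sc <- sortCanonical(kb@ppiScored, c("a", "b"))
  pre <- paste0(kb@species, ".")
  lines <- c(
    "protein1 protein2 neighborhood fusion experimental database textmining combined_score",
    if (nrow(sc)) sprintf("%s%s %s%s 0 0 %d %d %d %d", pre, sc$a, pre, sc$b,
                          sc$escore, sc$dscore, sc$tscore,
                          combineScores(sc$escore, sc$dscore, sc$tscore)))
  writeLinesLF(lines, path)
  invisible(path)
}

#' Export the protein-chemical table in the STITCH links dialect
#' @inheritParams exportStringLinks
#' @export
exportStitchLinks <- function(kb, path) {
  pc <- sortCanonical(kb@pci, c("protein", "chemical"))
  pre <- paste0(kb@species, ".")
  lines <- c("chemical protein experimental database textmining combined_score",
             if (nrow(pc)) sprintf("%s %s%s %d %d %d %d",
                                   formatChemicalId(pc$chemical, pc$stereo),
                                   pre, pc$protein, pc$escore, pc$dscore,
                                   pc$tscore,
                                   combineScores(pc$escore, pc$dscore, pc$tscore)))
  writeLinesLF(lines, path)
  invisible(path)
}

gafLine <- function(uniprot, symbol, goTerm, code, taxon) {
  paste(c("UniProtKB", uniprot, symbol, "", goTerm, "GO_REF:0000002", code,
          "", "P", "", "", "protein", paste0("taxon:", taxon), "20200101",
          "GO_Central", "", ""), collapse = "\t")
}

#' Export protein-to-process annotations as a GAF 2.1 file
#' @inheritParams exportStringLinks
#' @export
exportGaf <- function(kb, path) {
  pb <- sortCanonical(kb@pbp, c("protein", "goTerm", "evidenceCode"))
  sym <- vapply(pb$uniprot, function(u) {
    hit <- idMapLookup(kb@idMap, u, "uniprot")
    if (nrow(hit) && !is.na(hit$geneSymbol[1])) hit$geneSymbol[1] else u
  }, "", USE.NAMES = FALSE)
  lines <- c("!gaf-version: 2.1",
             if (nrow(pb)) mapply(gafLine, pb$uniprot, sym, pb$goTerm,
                                  pb$evidenceCode,
                                  MoreArgs = list(taxon = kb@species)))
  writeLinesLF(lines, path)
  invisible(path)
}

## map a canonical protein ID back to the namespace a presence dialect uses
backMap <- function(map, ids, col) {
  vapply(ids, function(id) {
    hit <- idMapLookup(map, id, "string")
    v <- hit[[col]][!is.na(hit[[col]])]
    if (length(v)) sort(v)[1] else id
  }, "", USE.NAMES = FALSE)
}

#' Export presence records in the BioGRID tab dialect
#'
#' One row per (pair, citing paper), interactors as official gene symbols.
#' @inheritParams exportStringLinks
#' @export
exportBiogrid <- function(kb, path) {
  pr <- kb@ppiPresence[kb@ppiPresence$source == "biogrid", , drop = FALSE]
  pr <- sortCanonical(pr, c("a", "b"))
  rows <- character(0)
  if (nrow(pr)) {
    symA <- backMap(kb@idMap, pr$a, "geneSymbol")
    symB <- backMap(kb@idMap, pr$b, "geneSymbol")
    rows <- unlist(lapply(seq_len(nrow(pr)), function(i) {
      papers <- splitPapers(pr$citingPapers[i])
      if (length(papers) == 0) papers <- ""
      sprintf("%s\t%s\t%s", symA[i], symB[i], papers)
    }))
  }
  writeLinesLF(c("OFFICIAL_SYMBOL_A\tOFFICIAL_SYMBOL_B\tPUBMED_ID", rows), path)
  invisible(path)
}

#' Export presence records in the Reactome pair dialect
#'
#' One row per pair, interactors as UniProt accessions, citing papers
#' pipe-joined.
#' @inheritParams exportStringLinks
#' @export
exportReactome <- function(kb, path) {
  pr <- kb@ppiPresence[kb@ppiPresence$source == "reactome", , drop = FALSE]
  pr <- sortCanonical(pr, c("a", "b"))
  rows <- character(0)
  if (nrow(pr)) {
    uniA <- backMap(kb@idMap, pr$a, "uniprotId")
    uniB <- backMap(kb@idMap, pr$b, "uniprotId")
    papers <- vapply(pr$citingPapers, function(cp)
      paste(splitPapers(cp), collapse = "|"), "", USE.NAMES = FALSE)
    rows <- sprintf("%s\t%s\t%s", uniA, uniB, papers)
  }
  writeLinesLF(c("uniprot_a\tuniprot_b\tpubmed_ids", rows), path)
  invisible(path)
}

#' Export the identifier cross-map as a three-column alias table
#'
#' @param map an \linkS4class{IdentityMap}.
#' @param path output file.
#' @export
exportAliases <- function(map, path) {
  tr <- map@triples
  tr <- tr[do.call(order, tr), , drop = FALSE]
  fmt <- function(x) ifelse(is.na(x), "", x)
  writeLinesLF(c("string_id\tuniprot_id\tgene_symbol",
                 if (nrow(tr)) sprintf("%s\t%s\t%s", fmt(tr$stringId),
                                       fmt(tr$uniprotId), fmt(tr$geneSymbol))),
               path)
  invisible(path)
}

KB_STORE_MAGIC <- "#EventSieveKB\t1"

writeSection <- function(name, df) {
  fmt <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }
  body <- if (nrow(df) == 0) character(0) else
    do.call(paste, c(lapply(df, fmt), sep = "\t"))
  c(paste0("##", name), paste(names(df), collapse = "\t"), body)
}

#' Persist a knowledge base to a single file
#'
#' The store is a sectioned plain-text serialization of the six tables
#' (scored PPI, PPI presence, scored PCI, process annotations, identifier
#' map) plus species and load metadata; \code{\link{readKnowledgeBase}}
#' restores an identical object.
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param path output file.
#' @export
writeKnowledgeBase <- function(kb, path) {
  meta <- jsonlite::toJSON(kb@metadata, auto_unbox = TRUE)
  lines <- c(KB_STORE_MAGIC,
             paste0("#species\t", kb@species),
             paste0("#meta\t", meta),
             writeSection("ppi_scored", kb@ppiScored),
             writeSection("ppi_presence", kb@ppiPresence),
             writeSection("pci", kb@pci),
             writeSection("pbp", kb@pbp),
             writeSection("id_map", kb@idMap@triples))
  writeLinesLF(lines, path)
  invisible(path)
}

parseSection <- function(lines, intCols = character(0), naCols = character(0)) {
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                 header), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    mat <- t(vapply(parts, function(p) c(p, rep("", length(header) - length(p))),
                    character(length(header))))
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- header
  }
  for (cl in intCols) df[[cl]] <- as.integer(df[[cl]])
  for (cl in naCols) df[[cl]][df[[cl]] == ""] <- NA_character_
  rownames(df) <- NULL
  df
}

#' Restore a knowledge base from its single-file store
#'
#' @param path file written by \code{\link{writeKnowledgeBase}}.
#' @return a \linkS4class{KnowledgeBase}.
#' @export
readKnowledgeBase <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != KB_STORE_MAGIC)
    stop("not a knowledge-base store file: ", path)
  species <- sub("^#species\t", "", lines[startsWith(lines, "#species\t")][1])
  metaLine <- sub("^#meta\t", "", lines[startsWith(lines, "#meta\t")][1])
  meta <- jsonlite::fromJSON(metaLine, simplifyVector = TRUE)
  meta$unresolved <- as.character(meta$unresolved %||% character(0))
  secStart <- which(startsWith(lines, "##"))
  secName <- sub("^##", "", lines[secStart])
  secEnd <- c(secStart[-1] - 1L, length(lines))
  sec <- setNames(lapply(seq_along(secStart), function(i)
    lines[(secStart[i] + 1L):secEnd[i]]), secName)
  kb <- newKnowledgeBase(species = species)
  kb@ppiScored <- parseSection(sec$ppi_scored,
                               intCols = c("escore", "dscore", "tscore"))
  kb@ppiPresence <- parseSection(sec$ppi_presence)
  kb@pci <- parseSection(sec$pci, intCols = c("escore", "dscore", "tscore"))
  kb@pbp <- parseSection(sec$pbp)
  kb@idMap <- new("IdentityMap",
                  triples = parseSection(sec$id_map,
                                         naCols = c("stringId", "uniprotId",
                                                    "geneSymbol")))
  kb@metadata <- meta
  validObject(kb)
  kb
}

#' Build a knowledge base from dump files
#'
#' Convenience wrapper: loads the alias table first (identifier resolution
#' is needed by the other loaders), then each provided dump, and optionally
#' persists the result.
#'
#' @param string,stitch,gaf,biogrid,reactome,aliases dump file paths
#'   (\code{NULL} to skip a source; \code{aliases} is required when any
#'   source needing identifier resolution is given).
#' @param species taxon to load.
#' @param out optional path for the single-file store.
#' @return a \linkS4class{KnowledgeBase}.
#' @export
buildKnowledgeBase <- function(string = NULL, stitch = NULL, gaf = NULL,
                               biogrid = NULL, reactome = NULL,
                               aliases = NULL, species = "9606", out = NULL) {
  idMap <- if (is.null(aliases)) emptyIdentityMap() else loadAliases(aliases)
  kb <- newKnowledgeBase(idMap, species)
  if (!is.null(string)) kb <- loadStringLinks(kb, string)
  if (!is.null(stitch)) kb <- loadStitchLinks(kb, stitch)
  if (!is.null(gaf)) kb <- loadGoGaf(kb, gaf)
  if (!is.null(biogrid)) kb <- loadBiogrid(kb, biogrid)
  if (!is.null(reactome)) kb <- loadReactome(kb, reactome)
  if (!is.null(out)) writeKnowledgeBase(kb, out)
  kb
}
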