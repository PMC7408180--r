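## Unified interaction knowledge base: loaders for the public dump dialects
## and keyed query operations. All protein identifiers are canonicalized to
## the STRING-style namespace at load time (the cross-map is keyed on it);
## unordered pairs are materialized as (min, max) under lexicographic order.

#' Create an empty knowledge base
#'
#' @param idMap an \linkS4class{IdentityMap} (needed before loading sources
#'   that use gene symbols or UniProt accessions).
#' @param species taxon identifier; rows for other taxa are skipped.
#' @return an empty \linkS4class{KnowledgeBase}.
#' @export
newKnowledgeBase <- function(idMap = emptyIdentityMap(), species = "9606") {
  new("KnowledgeBase",
      ppiScored = data.frame(a = character(0), b = character(0),
                             escore = integer(0), dscore = integer(0),
                             tscore = integer(0), stringsAsFactors = FALSE),
      ppiPresence = data.frame(a = character(0), b = character(0),
                               source = character(0),
                               citingPapers = character(0),
                               stringsAsFactors = FALSE),
      pci = data.frame(protein = character(0), chemical = character(0),
                       stereo = character(0), escore = integer(0),
                       dscore = integer(0), tscore = integer(0),
                       stringsAsFactors = FALSE),
      pbp = data.frame(protein = character(0), uniprot = character(0),
                       goTerm = character(0), evidenceCode = character(0),
                       evidenceKind = character(0), stringsAsFactors = FALSE),
      idMap = idMap, species = as.character(species),
      metadata = list(counts = list(), skipped = list(), files = list(),
                      unresolved = character(0)))
}

orderPair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

stripSpeciesPrefix <- function(ids, species) {
  pre <- paste0(species, ".")
  sub(paste0("^", species, "\\."), "", ids, fixed = FALSE)
}

speciesOfId <- function(ids) {
  m <- regmatches(ids, regexpr("^[0-9]+(?=\\.)", ids, perl = TRUE))
  out <- rep(NA_character_, length(ids))
  out[grepl("^[0-9]+\\.", ids)] <-
    sub("\\..*$", "", ids[grepl("^[0-9]+\\.", ids)])
  out
}

parseScore <- function(x) {
  v <- suppressWarnings(as.integer(x))
  frac <- suppressWarnings(as.numeric(x)) %% 1 != 0
  bad <- is.na(v) | v < 0 | v > SCORE_MAX | (!is.na(frac) & frac)
  v[bad] <- NA_integer_
  v
}

## collapse duplicate scored pairs to the max of each subscore
dedupScored <- function(df, keyCols) {
  key <- do.call(paste, c(df[keyCols], sep = "\1"))
  if (!anyDuplicated(key)) return(df)
  agg <- lapply(split(seq_len(nrow(df)), key), function(ix) {
    r <- df[ix[1], , drop = FALSE]
    r$escore <- max(df$escore[ix]); r$dscore <- max(df$dscore[ix])
    r$tscore <- max(df$tscore[ix])
    r
  })
  do.call(rbind, agg[order(names(agg))])
}

sortCanonical <- function(df, keyCols) {
  if (nrow(df) == 0) return(df)
  df <- df[do.call(order, df[keyCols]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

bumpCount <- function(kb, what, n) {
  kb@metadata$counts[[what]] <- (kb@metadata$counts[[what]] %||% 0L) + as.integer(n)
  kb
}

`%||%` <- function(x, y) if (is.null(x)) y else x

joinPapers <- function(x) paste(sort(unique(x[nzchar(x)])), collapse = ";")
splitPapers <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Load STRING protein-links-detailed scored interactions
#'
#' Reads the whitespace-delimited links-detailed dialect and stores one
#' scored record per unordered protein pair of the configured species. Only
#' the experimental, curated-database and text-mining subscores are kept;
#' the other channels (neighborhood, fusion, co-expression, ...) are
#' ignored. Rows for other taxa are skipped and counted; rows with a
#' malformed score are skipped with a warning naming the line. Repeated
#' pairs keep the maximum of each subscore.
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param path links-detailed file (header row; columns must include
#'   \code{protein1}, \code{protein2}, \code{experimental},
#'   \code{database}, \code{textmining}).
#' @param species taxon to load (default: the knowledge base's).
#' @return the updated \linkS4class{KnowledgeBase}; the number of rows
#'   ingested is recorded under \code{kbLoadCounts(kb)$string_rows}.
#' @export
loadStringLinks <- function(kb, path, species = kb@species) {
  tab <- read.table(path, header = TRUE, colClasses = "character",
                    check.names = FALSE)
  need <- c("protein1", "protein2", "experimental", "database", "textmining")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("STRING links file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tab) == 0) return(bumpCount(kb, "string_rows", 0))
  sp1 <- speciesOfId(tab$protein1); sp2 <- speciesOfId(tab$protein2)
  keep <- (is.na(sp1) | sp1 == species) & (is.na(sp2) | sp2 == species)
  kb <- bumpCount(kb, "string_skipped_species", sum(!keep))
  tab <- tab[keep, , drop = FALSE]
  e <- parseScore(tab$experimental); d <- parseScore(tab$database)
  t <- parseScore(tab$textmining)
  badRow <- is.na(e) | is.na(d) | is.na(t)
  if (any(badRow)) {
    warning("skipping ", sum(badRow), " STRING row(s) with malformed scores (line ",
            paste(which(keep)[badRow] + 1L, collapse = ", "), ")")
    kb <- bumpCount(kb, "string_skipped_malformed", sum(badRow))
  }
  tab <- tab[!badRow, , drop = FALSE]
  e <- e[!badRow]; d <- d[!badRow]; t <- t[!badRow]
  op <- orderPair(stripSpeciesPrefix(tab$protein1, species),
                  stripSpeciesPrefix(tab$protein2, species))
  newRec <- data.frame(a = op$a, b = op$b, escore = e, dscore = d, tscore = t,
                       stringsAsFactors = FALSE)
  kb@ppiScored <- sortCanonical(
    dedupScored(rbind(kb@ppiScored, newRec), c("a", "b")), c("a", "b"))
  kb@metadata$files$string <- basename(path)
  validObject(kb)
  bumpCount(kb, "string_rows", nrow(newRec))
}

#' Load STITCH protein-chemical scored interactions
#'
#' Same layout and rules as \code{\link{loadStringLinks}} but keyed by
#' (protein, chemical). Chemical identifiers (\code{CIDs...}/\code{CIDm...})
#' are normalized to bare numeric compound IDs with the stereo/merged flag
#' retained.
#'
#' @inheritParams loadStringLinks
#' @param path links file with columns \code{chemical}, \code{protein},
#'   \code{experimental}, \code{database}, \code{textmining}.
#' @return updated \linkS4class{KnowledgeBase}.
#' @export
loadStitchLinks <- function(kb, path, species = kb@species) {
  tab <- read.table(path, header = TRUE, colClasses = "character",
                    check.names = FALSE)
  need <- c("chemical", "protein", "experimental", "database", "textmining")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("STITCH links file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(tab) == 0) return(bumpCount(kb, "stitch_rows", 0))
  sp <- speciesOfId(tab$protein)
  keep <- is.na(sp) | sp == species
  kb <- bumpCount(kb, "stitch_skipped_species", sum(!keep))
  tab <- tab[keep, , drop = FALSE]
  e <- parseScore(tab$experimental); d <- parseScore(tab$database)
  t <- parseScore(tab$textmining)
  chem <- lapply(tab$chemical, normalizeChemicalId)
  chemId <- vapply(chem, `[[`, "", "id")
  stereo <- vapply(chem, `[[`, "", "stereo")
  badRow <- is.na(e) | is.na(d) | is.na(t) | is.na(chemId)
  if (any(badRow)) {
    warning("skipping ", sum(badRow),
            " STITCH row(s) with malformed scores or chemical IDs (line ",
            paste(which(keep)[badRow] + 1L, collapse = ", "), ")")
    kb <- bumpCount(kb, "stitch_skipped_malformed", sum(badRow))
  }
  newRec <- data.frame(protein = stripSpeciesPrefix(tab$protein, species),
                       chemical = chemId, stereo = stereo,
                       escore = e, dscore = d, tscore = t,
                       stringsAsFactors = FALSE)[!badRow, , drop = FALSE]
  kb@pci <- sortCanonical(
    dedupScored(rbind(kb@pci, newRec), c("protein", "chemical")),
    c("protein", "chemical"))
  kb@metadata$files$stitch <- basename(path)
  validObject(kb)
  bumpCount(kb, "stitch_rows", nrow(newRec))
}

gafEvidenceKind <- function(code) {
  kind <- rep("other", length(code))
  kind[code %in% c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")] <- "experimental"
  kind[code == "IEA"] <- "electronic"
  kind
}

#' Load GO annotations from a GAF file
#'
#' Parses GAF 2.x (17 tab-separated columns, \code{!} comment lines).
#' Evidence codes are mapped to three curation kinds: \code{IEA} is
#' electronic, the experimental family (\code{EXP}, \code{IDA}, \code{IPI},
#' \code{IMP}, \code{IGI}, \code{IEP}) is experimental, everything else is
#' other. Rows whose qualifier contains \code{NOT} are excluded (they
#' assert the absence of the association). The annotated accession is
#' resolved to the canonical protein namespace through the knowledge base's
#' identifier map when possible.
#'
#' @inheritParams loadStringLinks
#' @param path GAF file.
#' @return updated \linkS4class{KnowledgeBase}.
#' @export
loadGoGaf <- function(kb, path) {
  lines <- readLines(path)
  dataIx <- which(!startsWith(lines, "!") & nzchar(lines))
  if (length(dataIx) == 0) return(bumpCount(kb, "gaf_rows", 0))
  ## field count from tab count (strsplit drops trailing empty fields)
  nf <- lengths(gregexpr("\t", lines[dataIx], fixed = TRUE)) + 1L
  if (any(nf != 17))
    stop("GAF format error: expected 17 columns, got ", nf[nf != 17][1],
         " at line ", dataIx[nf != 17][1])
  parts <- strsplit(lines[dataIx], "\t", fixed = TRUE)
  mat <- do.call(rbind, lapply(parts, function(p) c(p, rep("", 17L - length(p)))))
  qualifier <- mat[, 4]; uniprot <- mat[, 2]; goTerm <- mat[, 5]
  code <- mat[, 7]
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  kb <- bumpCount(kb, "gaf_excluded_not", sum(!keep))
  uniprot <- uniprot[keep]; goTerm <- goTerm[keep]; code <- code[keep]
  canon <- uniprot
  for (i in seq_along(uniprot)) {
    r <- resolveId(uniprot[i], "protein", kb@idMap, "string")
    if (r$status == "ok") canon[i] <- r$id
    else kb@metadata$unresolved <- unique(c(kb@metadata$unresolved, uniprot[i]))
  }
  newRec <- data.frame(protein = canon, uniprot = uniprot, goTerm = goTerm,
                       evidenceCode = code,
                       evidenceKind = gafEvidenceKind(code),
                       stringsAsFactors = FALSE)
  all <- unique(rbind(kb@pbp, newRec))
  kb@pbp <- sortCanonical(all, c("protein", "goTerm", "evidenceCode"))
  kb@metadata$files$gaf <- basename(path)
  validObject(kb)
  bumpCount(kb, "gaf_rows", nrow(newRec))
}

mergePresence <- function(existing, newRec) {
  all <- rbind(existing, newRec)
  if (nrow(all) == 0) return(all)
  key <- paste(all$a, all$b, all$source, sep = "\1")
  merged <- lapply(split(seq_len(nrow(all)), key), function(ix) {
    r <- all[ix[1], , drop = FALSE]
    r$citingPapers <- joinPapers(unlist(lapply(all$citingPapers[ix], splitPapers)))
    r
  })
  sortCanonical(do.call(rbind, merged), c("a", "b", "source"))
}

loadPresenceDialect <- function(kb, path, source, colmap, idNamespace) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(unlist(colmap), names(tab))
  if (length(miss))
    stop(source, " file is missing required column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(tab)
  if (n == 0) return(bumpCount(kb, paste0(source, "_rows"), 0))
  resolveVec <- function(ids) {
    vapply(ids, function(id) {
      r <- resolveId(id, "protein", kb@idMap, "string")
      if (r$status == "ok") r$id else NA_character_
    }, "", USE.NAMES = FALSE)
  }
  a <- resolveVec(tab[[colmap$a]]); b <- resolveVec(tab[[colmap$b]])
  unres <- is.na(a) | is.na(b)
  if (any(unres)) {
    kb@metadata$unresolved <- unique(c(kb@metadata$unresolved,
      tab[[colmap$a]][is.na(a)], tab[[colmap$b]][is.na(b)]))
    kb <- bumpCount(kb, paste0(source, "_skipped_unresolved"), sum(unres))
  }
  papers <- tab[[colmap$pubmed]][!unres]
  op <- orderPair(a[!unres], b[!unres])
  ## one input row may carry several paper IDs separated by "|"
  papers <- vapply(strsplit(papers, "|", fixed = TRUE),
                   function(p) joinPapers(trimws(p)), "")
  newRec <- data.frame(a = op$a, b = op$b, source = source,
                       citingPapers = papers, stringsAsFactors = FALSE)
  kb@ppiPresence <- mergePresence(kb@ppiPresence, newRec)
  kb@metadata$files[[source]] <- basename(path)
  validObject(kb)
  bumpCount(kb, paste0(source, "_rows"), sum(!unres))
}

#' Load BioGRID physical-interaction records
#'
#' BioGRID rows identify interactors by official gene symbol and carry the
#' PubMed identifier of the reporting paper; they have no confidence score,
#' so they are stored as presence records (the interaction is known) with
#' their citing papers retained. Symbols are resolved to the canonical
#' protein namespace; rows with an unresolvable symbol are skipped and the
#' symbols logged. Duplicate pairs union their citing papers. The column
#' names drift between releases, so they are configurable.
#'
#' @inheritParams loadStringLinks
#' @param path tab-separated BioGRID dump.
#' @param colmap named list mapping roles \code{a}, \code{b},
#'   \code{pubmed} to column names in the file.
#' @return updated \linkS4class{KnowledgeBase}.
#' @export
loadBiogrid <- function(kb, path,
                        colmap = list(a = "OFFICIAL_SYMBOL_A",
                                      b = "OFFICIAL_SYMBOL_B",
                                      pubmed = "PUBMED_ID")) {
  loadPresenceDialect(kb, path, "biogrid", colmap, "symbol")
}

#' Load Reactome interaction pairs
#'
#' Reactome pairs identify interactors by UniProt accession and may carry a
#' pipe-separated list of literature references; like BioGRID they are
#' unscored and stored as presence records.
#'
#' @inheritParams loadBiogrid
#' @export
loadReactome <- function(kb, path,
                         colmap = list(a = "uniprot_a", b = "uniprot_b",
                                       pubmed = "pubmed_ids")) {
  loadPresenceDialect(kb, path, "reactome", colmap, "uniprot")
}

#' Per-source load counts
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @return named list of rows ingested / skipped per source.
#' @export
kbLoadCounts <- function(kb) kb@metadata$counts

#' Query protein-protein support
#'
#' Looks the unordered pair up in the scored table and in both presence
#' tables; order of the arguments does not matter. Absence is a value, not
#' an error.
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param a,b canonical protein identifiers.
#' @return \code{NULL} when no table contains the pair; otherwise a list
#'   with \code{escore}/\code{dscore}/\code{tscore} (\code{NA} when the
#'   pair is only in presence tables), \code{presenceSources} (character
#'   vector) and \code{citingPapers} (character vector).
#' @export
queryPpi <- function(kb, a, b) {
  op <- orderPair(a, b)
  sc <- kb@ppiScored
  si <- which(sc$a == op$a & sc$b == op$b)
  pr <- kb@ppiPresence
  pi <- which(pr$a == op$a & pr$b == op$b)
  if (length(si) == 0 && length(pi) == 0) return(NULL)
  list(escore = if (length(si)) sc$escore[si[1]] else NA_integer_,
       dscore = if (length(si)) sc$dscore[si[1]] else NA_integer_,
       tscore = if (length(si)) sc$tscore[si[1]] else NA_integer_,
       presenceSources = sort(unique(pr$source[pi])),
       citingPapers = sort(unique(unlist(lapply(pr$citingPapers[pi],
                                                splitPapers)))))
}

#' Query protein-chemical support
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param protein canonical protein identifier.
#' @param chemical chemical identifier (normalized internally).
#' @return \code{NULL} when absent; otherwise a list with the three
#'   subscores and the stereo flag.
#' @export
queryPci <- function(kb, protein, chemical) {
  chem <- normalizeChemicalId(chemical)$id
  pc <- kb@pci
  i <- which(pc$protein == protein & pc$chemical == chem)
  if (length(i) == 0) return(NULL)
  list(escore = pc$escore[i[1]], dscore = pc$dscore[i[1]],
       tscore = pc$tscore[i[1]], stereo = pc$stereo[i[1]])
}

#' Query protein-to-process annotations
#'
#' Requires the exact GO accession: no ontology propagation to ancestors or
#' alternate IDs is attempted.
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param protein canonical protein identifier.
#' @param goTerm GO accession (\code{GO:} + 7 digits).
#' @return data.frame of matching annotations (zero rows when absent).
#' @export
queryPbp <- function(kb, protein, goTerm) {
  pb <- kb@pbp
  pb[pb$protein == protein & pb$goTerm == goTerm, , drop = FALSE]
}

#' Presence interactions citing any of a set of papers
#'
#' Searches the sources that carry citations (BioGRID and Reactome) for
#' interactions whose citing papers intersect the query set.
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param papers character vector of paper identifiers.
#' @return data.frame (\code{a}, \code{b}, \code{source},
#'   \code{citingPapers}, \code{sharedPapers}) sorted by pair key.
#' @export
interactionsCiting <- function(kb, papers) {
  pr <- kb@ppiPresence
  if (length(papers) == 0 || nrow(pr) == 0)
    return(cbind(pr[0, , drop = FALSE], sharedPapers = character(0)))
  shared <- vapply(pr$citingPapers, function(cp)
    paste(sort(intersect(splitPapers(cp), papers)), collapse = ";"), "",
    USE.NAMES = FALSE)
  out <- pr[nzchar(shared), , drop = FALSE]
  out$sharedPapers <- shared[nzchar(shared)]
  sortCanonical(out, c("a", "b", "source"))
}

#' Presence interactions touching any of a set of proteins
#'
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param proteins character vector of canonical protein identifiers.
#' @return data.frame of presence records where either participant is in
#'   the query set, sorted by pair key.
#' @export
interactionsInvolving <- function(kb, proteins) {
  pr <- kb@ppiPresence
  hit <- pr$a %in% proteins | pr$b %in% proteins
  sortCanonical(pr[hit, , drop = FALSE], c("a", "b", "source"))
}
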