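#' Load an identifier alias table
#'
#' Reads the three-column cross-mapping between STRING-style protein IDs,
#' UniProt accessions and official gene symbols. Blank fields are allowed
#' (there is no guarantee all three namespaces are known for a protein), but
#' a row with every field blank is a format error.
#'
#' @param path tab-separated file with header columns
#'   \code{string_id}, \code{uniprot_id}, \code{gene_symbol}.
#' @return an \linkS4class{IdentityMap}.
#' @export
loadAliases <- function(path) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("string_id", "uniprot_id", "gene_symbol")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("alias file is missing required column(s): ", paste(miss, collapse = ", "))
  tr <- data.frame(stringId = blankToNA(tab$string_id),
                   uniprotId = blankToNA(tab$uniprot_id),
                   geneSymbol = blankToNA(tab$gene_symbol),
                   stringsAsFactors = FALSE)
  allBlank <- rowSums(!is.na(tr)) == 0
  if (any(allBlank))
    stop("alias file row(s) with all fields blank: line ",
         paste(which(allBlank) + 1L, collapse = ", "))
  new("IdentityMap", triples = tr)
}

blankToNA <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  x
}

emptyIdentityMap <- function() {
  new("IdentityMap", triples = data.frame(
    stringId = character(0), uniprotId = character(0),
    geneSymbol = character(0), stringsAsFactors = FALSE))
}

#' Look up mapping triples by any identifier
#'
#' @param map an \linkS4class{IdentityMap}.
#' @param id a single identifier in any of the three namespaces.
#' @param namespace one of \code{"string"}, \code{"uniprot"},
#'   \code{"symbol"}, or \code{"any"} to search all three.
#' @return data.frame of matching triples (possibly zero rows). Gene symbols
#'   match case-insensitively; accessions match exactly.
#' @export
idMapLookup <- function(map, id, namespace = c("any", "string", "uniprot", "symbol")) {
  namespace <- match.arg(namespace)
  tr <- map@triples
  hitS <- !is.na(tr$stringId) & tr$stringId == id
  hitU <- !is.na(tr$uniprotId) & tr$uniprotId == id
  hitG <- !is.na(tr$geneSymbol) & toupper(tr$geneSymbol) == toupper(id)
  hit <- switch(namespace, string = hitS, uniprot = hitU, symbol = hitG,
                any = hitS | hitU | hitG)
  tr[hit, , drop = FALSE]
}

#' Infer an element type from the shape of its identifier
#'
#' Grounded identifiers carry their namespace in their shape: GO accessions
#' (\code{GO:} + 7 digits) denote biological processes, UniProt accessions
#' or Ensembl-protein-style IDs denote proteins, bare numbers denote
#' PubChem chemicals, and PFAM/InterPro accessions denote protein families.
#'
#' @param id identifier string.
#' @return one of \code{"protein"}, \code{"chemical"},
#'   \code{"biological-process"}, \code{"protein-family"}, \code{"other"}.
#' @export
inferElementType <- function(id) {
  id <- trimws(id)
  if (grepl("^GO:[0-9]{7}$", id)) return("biological-process")
  if (grepl("^(PF[0-9]{5}|IPR[0-9]{6})$", id)) return("protein-family")
  if (grepl("^[0-9 ]+$", id) && nzchar(gsub(" ", "", id))) return("chemical")
  if (grepl("^CID[sm]?[0-9]+$", id)) return("chemical")
  if (grepl("^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9][A-Z][A-Z0-9]{2}[0-9])$", id))
    return("protein")
  if (grepl("^(9606\\.)?ENSP[0-9]+$", id) || grepl("^SYNP[0-9]+$", id))
    return("protein")
  "other"
}

#' Normalize a chemical identifier
#'
#' Strips STITCH \code{CIDs}/\code{CIDm} prefixes (retaining the
#' stereo/merged flag), internal whitespace and leading zeros, yielding the
#' bare numeric PubChem compound ID as a string.
#'
#' @param id raw chemical identifier (e.g. \code{"CIDm00216239"} or a
#'   printed form like \code{"216 239"}).
#' @return list with \code{id} (bare digits, no leading zeros) and
#'   \code{stereo} (\code{"s"}, \code{"m"} or \code{""}).
#' @export
normalizeChemicalId <- function(id) {
  id <- gsub("[[:space:]]", "", id)
  stereo <- ""
  m <- regmatches(id, regexec("^CID([sm]?)([0-9]+)$", id))[[1]]
  if (length(m) == 3) {
    stereo <- m[2]
    id <- m[3]
  }
  id <- sub("^0+(?=[0-9])", "", id, perl = TRUE)
  if (!grepl("^[0-9]+$", id)) return(list(id = NA_character_, stereo = stereo))
  list(id = id, stereo = stereo)
}

#' Resolve an element identifier into a target namespace
#'
#' Routes protein identifiers through the alias table; GO accessions and
#' chemical identifiers pass through after syntactic validation (chemicals
#' are normalized to bare numeric IDs). Protein-family and other element
#' types are always unmapped — they are excluded from filtering because
#' they have no identifier namespace the backing databases share.
#' Resolution never guesses: if several mapping triples match, the result
#' is \code{"ambiguous"} and carries all candidates.
#'
#' @param id raw identifier string.
#' @param elementType one of the element types (see
#'   \code{\link{inferElementType}}).
#' @param map an \linkS4class{IdentityMap} (used for proteins).
#' @param target target namespace: \code{"string"}, \code{"uniprot"} or
#'   \code{"symbol"} for proteins; ignored for chemicals and processes.
#' @return list with \code{status} (\code{"ok"}, \code{"unmapped"} or
#'   \code{"ambiguous"}), \code{id} (canonical ID or \code{NA}) and
#'   \code{candidates} (character vector, nonempty when ambiguous).
#' @export
resolveId <- function(id, elementType, map, target = "string") {
  out <- function(status, cid = NA_character_, cands = character(0))
    list(status = status, id = cid, candidates = cands)
  id <- trimws(id)
  if (!nzchar(id) || is.na(id)) return(out("unmapped"))
  if (elementType %in% c("protein-family", "other")) return(out("unmapped"))
  if (elementType == "biological-process") {
    if (grepl("^GO:[0-9]{7}$", id)) return(out("ok", id))
    return(out("unmapped"))
  }
  if (elementType == "chemical") {
    norm <- normalizeChemicalId(id)
    if (is.na(norm$id)) return(out("unmapped"))
    return(out("ok", norm$id))
  }
  # protein: route through the mapping table
  col <- switch(target, string = "stringId", uniprot = "uniprotId",
                symbol = "geneSymbol",
                stop("unknown target namespace: ", target))
  hits <- idMapLookup(map, id, "any")
  vals <- unique(hits[[col]][!is.na(hits[[col]])])
  if (length(vals) == 0) return(out("unmapped"))
  if (length(vals) > 1) return(out("ambiguous", cands = sort(vals)))
  out("ok", vals)
}
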