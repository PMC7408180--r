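## Independent brute-force oracles. These re-derive expected results by
## linear scans over the raw dump files and by naive set arithmetic; they
## deliberately share no code with the package's keyed store or policy
## engine.

oracleReadDumps <- function(files) {
  al <- read.delim(files$aliases, colClasses = "character")
  al[al == ""] <- NA
  st <- read.table(files$string, header = TRUE, colClasses = "character")
  st$protein1 <- sub("^9606\\.", "", st$protein1)
  st$protein2 <- sub("^9606\\.", "", st$protein2)
  sti <- read.table(files$stitch, header = TRUE, colClasses = "character")
  sti$protein <- sub("^9606\\.", "", sti$protein)
  sti$chem <- sub("^0+", "", sub("^CID[sm]?", "", sti$chemical))
  gafLines <- readLines(files$gaf)
  gafLines <- gafLines[!startsWith(gafLines, "!") & nzchar(gafLines)]
  gf <- do.call(rbind, lapply(strsplit(gafLines, "\t"), function(p)
    c(p, rep("", 17 - length(p)))[c(2, 4, 5, 7)]))
  gaf <- data.frame(uniprot = gf[, 1], qualifier = gf[, 2], go = gf[, 3],
                    code = gf[, 4], stringsAsFactors = FALSE)
  gaf <- gaf[!grepl("NOT", gaf$qualifier), , drop = FALSE]
  bg <- read.delim(files$biogrid, colClasses = "character")
  rc <- read.delim(files$reactome, colClasses = "character")
  list(aliases = al, string = st, stitch = sti, gaf = gaf,
       biogrid = bg, reactome = rc)
}

## scan the alias table for any-field matches; return all STRING-style ids
oracleResolveProtein <- function(id, al) {
  hit <- (!is.na(al$string_id) & al$string_id == id) |
         (!is.na(al$uniprot_id) & al$uniprot_id == id) |
         (!is.na(al$gene_symbol) & toupper(al$gene_symbol) == toupper(id))
  unique(al$string_id[hit & !is.na(al$string_id)])
}

oracleChem <- function(id) {
  id <- gsub("[[:space:]]", "", id)
  id <- sub("^CID[sm]?", "", id)
  id <- sub("^0+(?=[0-9])", "", id, perl = TRUE)
  if (grepl("^[0-9]+$", id)) id else NA_character_
}

oracleClass <- function(tA, tB) {
  p <- sort(c(tA, tB))
  if (any(p %in% c("protein-family", "other"))) return("OTHER")
  if (identical(p, c("protein", "protein"))) return("PPI")
  if (identical(p, c("chemical", "protein"))) return("PCI")
  if (identical(p, c("biological-process", "protein"))) return("PBPI")
  if (identical(p, c("chemical", "chemical"))) return("CCI")
  if (identical(p, c("biological-process", "chemical"))) return("CBPI")
  if (identical(p, c("biological-process", "biological-process"))) return("BPBPI")
  "OTHER"
}

## evidence code -> curation kind, written as a lookup table
oracleEvKind <- function(code) {
  tab <- c(EXP = "experimental", IDA = "experimental", IPI = "experimental",
           IMP = "experimental", IGI = "experimental", IEP = "experimental",
           IEA = "electronic")
  ifelse(code %in% names(tab), tab[code], "other")
}

## all database evidence for one event, by scanning every raw dump row
oracleSupportRow <- function(ev, dumps) {
  out <- list(class = oracleClass(ev$regulatedType, ev$regulatorType),
              status = "ok", matched = FALSE,
              escore = NA_integer_, dscore = NA_integer_,
              tscore = NA_integer_, presence = character(0),
              citing = character(0), kinds = character(0))
  if (!out$class %in% c("PPI", "PCI", "PBPI")) {
    out$status <- "unsupported_type"
    return(out)
  }
  al <- dumps$aliases
  resolveOne <- function(id, type) {
    id <- trimws(id)
    if (type == "protein") {
      r <- oracleResolveProtein(id, al)
      if (length(r) == 1) r else if (length(r) == 0) "UNMAPPED" else "AMBIG"
    } else if (type == "chemical") {
      r <- oracleChem(id)
      if (is.na(r)) "UNMAPPED" else r
    } else if (type == "biological-process") {
      if (grepl("^GO:[0-9]{7}$", id)) id else "UNMAPPED"
    } else "UNMAPPED"
  }
  ra <- resolveOne(ev$regulatedId, ev$regulatedType)
  rb <- resolveOne(ev$regulatorId, ev$regulatorType)
  if ("AMBIG" %in% c(ra, rb)) { out$status <- "ambiguous"; return(out) }
  if ("UNMAPPED" %in% c(ra, rb)) { out$status <- "unmapped"; return(out) }
  if (out$class == "PPI") {
    st <- dumps$string
    hit <- (st$protein1 == ra & st$protein2 == rb) |
           (st$protein1 == rb & st$protein2 == ra)
    if (any(hit)) {
      out$matched <- TRUE
      out$escore <- max(as.integer(st$experimental[hit]))
      out$dscore <- max(as.integer(st$database[hit]))
      out$tscore <- max(as.integer(st$textmining[hit]))
    }
    bg <- dumps$biogrid
    bgA <- vapply(bg[[1]], function(s) {
      r <- oracleResolveProtein(s, al); if (length(r) == 1) r else NA }, "")
    bgB <- vapply(bg[[2]], function(s) {
      r <- oracleResolveProtein(s, al); if (length(r) == 1) r else NA }, "")
    bHit <- !is.na(bgA) & !is.na(bgB) &
            ((bgA == ra & bgB == rb) | (bgA == rb & bgB == ra))
    if (any(bHit)) {
      out$matched <- TRUE
      out$presence <- c(out$presence, "biogrid")
      out$citing <- c(out$citing, bg[[3]][bHit])
    }
    rcTab <- dumps$reactome
    rcA <- vapply(rcTab[[1]], function(s) {
      r <- oracleResolveProtein(s, al); if (length(r) == 1) r else NA }, "")
    rcB <- vapply(rcTab[[2]], function(s) {
      r <- oracleResolveProtein(s, al); if (length(r) == 1) r else NA }, "")
    rHit <- !is.na(rcA) & !is.na(rcB) &
            ((rcA == ra & rcB == rb) | (rcA == rb & rcB == ra))
    if (any(rHit)) {
      out$matched <- TRUE
      out$presence <- c(out$presence, "reactome")
      out$citing <- c(out$citing,
                      unlist(strsplit(rcTab[[3]][rHit], "|", fixed = TRUE)))
    }
    out$presence <- sort(unique(out$presence))
    out$citing <- sort(unique(out$citing[nzchar(out$citing)]))
  } else if (out$class == "PCI") {
    prot <- if (ev$regulatedType == "protein") ra else rb
    chem <- if (ev$regulatedType == "chemical") ra else rb
    sti <- dumps$stitch
    hit <- sti$protein == prot & sti$chem == chem
    if (any(hit)) {
      out$matched <- TRUE
      out$escore <- max(as.integer(sti$experimental[hit]))
      out$dscore <- max(as.integer(sti$database[hit]))
      out$tscore <- max(as.integer(sti$textmining[hit]))
    }
  } else {
    prot <- if (ev$regulatedType == "protein") ra else rb
    proc <- if (ev$regulatedType == "biological-process") ra else rb
    gaf <- dumps$gaf
    gafCanon <- vapply(gaf$uniprot, function(u) {
      r <- oracleResolveProtein(u, al); if (length(r) == 1) r else u }, "")
    hit <- gafCanon == prot & gaf$go == proc
    if (any(hit)) {
      out$matched <- TRUE
      out$kinds <- sort(unique(unname(oracleEvKind(gaf$code[hit]))))
    }
  }
  out
}

## independent re-statement of the pass/fail predicate
oraclePasses <- function(sup, pol) {
  if (!sup$matched) return(FALSE)
  if (sup$class == "PBPI")
    return(length(pol$kinds) == 0 || any(sup$kinds %in% pol$kinds))
  thr <- c(pol$e, pol$d, pol$t)
  sc <- c(sup$escore, sup$dscore, sup$tscore)
  if (all(is.na(sc)))  # presence-only: passes only under a vacuous policy
    return(all(is.na(thr) | (thr == 0 & pol$inclusive)))
  checks <- logical(0)
  for (i in 1:3) {
    if (is.na(thr[i])) next
    checks <- c(checks,
                if (pol$inclusive) sc[i] >= thr[i] else sc[i] > thr[i])
  }
  if (length(checks) == 0) return(TRUE)
  if (pol$combine == "any") any(checks) else all(checks)
}

## four-way partition + support of a whole reading set, brute force
oracleFilter <- function(events, dumps, pol) {
  sups <- lapply(seq_len(nrow(events)), function(i)
    oracleSupportRow(events[i, ], dumps))
  verdict <- vapply(sups, function(s) {
    if (s$status == "unsupported_type") "unsupported_type"
    else if (s$status %in% c("unmapped", "ambiguous")) "unmapped"
    else if (oraclePasses(s, pol)) "selected" else "discarded"
  }, "")
  list(support = sups, verdict = verdict)
}

oraclePrecisionRecall <- function(selected, correct) {
  ov <- length(intersect(selected, correct))
  list(precision = if (length(selected)) ov / length(selected) else NA_real_,
       recall = if (length(correct)) ov / length(correct) else NA_real_)
}

defaultOraclePolicy <- function(e = 0, d = 0, t = 0, combine = "any",
                                inclusive = TRUE, kinds = character(0)) {
  list(e = e, d = d, t = t, combine = combine, inclusive = inclusive,
       kinds = kinds)
}
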