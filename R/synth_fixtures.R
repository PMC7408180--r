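## Seeded generator of miniature knowledge-base dumps (in the real public
## dialects) and labeled synthetic reading sets, so every other module is
## testable offline with known ground truth. Identifiers are drawn from
## disjoint synthetic namespaces shaped like real accessions (UniProt-like,
## Ensembl-protein-like, GO-like, numeric chemical) so the
## namespace-inference logic is exercised. The generator makes no attempt to
## match real-database score marginals or network topology.

#' Specify a synthetic fixture
#'
#' Defaults describe the emulated study conditions: a reading set of a few
#' hundred events (the size at which manual filtration stops being
#' practical), about half of which find database support, a tenth
#' grounding failures, a sprinkle of excluded element types, between-paper
#' duplicates planted in groups of 2/4/6 distinct papers, and publication
#' years straddling the recent-publication boundary.
#'
#' @param seed integer seed; same seed, byte-identical files.
#' @param nProteins,nChemicals,nProcesses entity pool sizes.
#' @param nPpi,nPci,nPbp scored-table sizes; \code{nBiogrid},
#'   \code{nReactome} presence-table sizes; \code{nGafNot} NOT-qualified
#'   annotation rows (excluded at load).
#' @param scoreDist \code{"zero-inflated"} (a \code{zeroProb} point mass at
#'   0, else uniform on 1..1000 — subscores of real scored databases are
#'   mostly zero) or \code{"uniform"} on 0..1000.
#' @param zeroProb point mass at score 0 under \code{"zero-inflated"}.
#' @param nPapers size of the citation pool shared by presence tables and
#'   the reading set.
#' @param readingSetSize total event rows emitted.
#' @param fracSupported,fracUnmapped,fracOtherType base-row mix; the
#'   remainder is grounded-but-unsupported. \code{fracDuplicate} and
#'   \code{fracWithinDup} are extra rows spent on between-paper duplicate
#'   groups and within-paper repeats.
#' @param fracRecent fraction of references published after
#'   \code{recentAfter}.
#' @param yearRange inclusive publication-year range.
#' @param recentAfter the novelty boundary year.
#' @param labelFlipSupported fraction of supported rows judged incorrect;
#'   \code{labelCorrectUnsupported} fraction of unsupported rows judged
#'   correct — so precision below 1 is exercised.
#' @return a \code{fixtureSpec} list.
#' @export
fixtureSpec <- function(seed = 1L, nProteins = 60, nChemicals = 15,
                        nProcesses = 12, nPpi = 120, nPci = 40, nPbp = 50,
                        nBiogrid = 30, nReactome = 20, nGafNot = 3,
                        scoreDist = c("zero-inflated", "uniform"),
                        zeroProb = 0.35, nPapers = 60,
                        readingSetSize = 300, fracSupported = 0.5,
                        fracUnmapped = 0.1, fracOtherType = 0.05,
                        fracDuplicate = 0.12, fracWithinDup = 0.04,
                        fracRecent = 0.3, yearRange = c(2005, 2018),
                        recentAfter = 2014, labelFlipSupported = 0.1,
                        labelCorrectUnsupported = 0.15) {
  spec <- list(seed = as.integer(seed), nProteins = nProteins,
               nChemicals = nChemicals, nProcesses = nProcesses,
               nPpi = nPpi, nPci = nPci, nPbp = nPbp, nBiogrid = nBiogrid,
               nReactome = nReactome, nGafNot = nGafNot,
               scoreDist = match.arg(scoreDist), zeroProb = zeroProb,
               nPapers = nPapers, readingSetSize = readingSetSize,
               fracSupported = fracSupported, fracUnmapped = fracUnmapped,
               fracOtherType = fracOtherType, fracDuplicate = fracDuplicate,
               fracWithinDup = fracWithinDup, fracRecent = fracRecent,
               yearRange = yearRange, recentAfter = recentAfter,
               labelFlipSupported = labelFlipSupported,
               labelCorrectUnsupported = labelCorrectUnsupported)
  stopifnot(spec$fracSupported + spec$fracUnmapped + spec$fracOtherType <= 1,
            all(unlist(spec[c("nPpi", "nPci", "nPbp", "nBiogrid",
                              "nReactome", "readingSetSize")]) >= 0))
  if (spec$nPpi + spec$nBiogrid + spec$nReactome >
      choose(spec$nProteins, 2))
    stop("infeasible spec: more protein pairs requested than combinatorially possible")
  if (spec$nPci > spec$nProteins * spec$nChemicals ||
      spec$nPbp > spec$nProteins * spec$nProcesses)
    stop("infeasible spec: more pairs requested than combinatorially possible")
  class(spec) <- "fixtureSpec"
  spec
}

drawScores <- function(n, spec) {
  if (spec$scoreDist == "uniform") return(sample(0:1000, n, replace = TRUE))
  z <- stats::runif(n) < spec$zeroProb
  s <- sample(1:1000, n, replace = TRUE)
  s[z] <- 0L
  as.integer(s)
}

samplePairs <- function(ids, n, exclude = character(0)) {
  seen <- exclude
  out <- matrix(character(0), ncol = 2)
  while (nrow(out) < n) {
    p <- sort(sample(ids, 2))
    key <- paste(p, collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    out <- rbind(out, p)
  }
  out
}

#' Generate a miniature knowledge base in the public dump dialects
#'
#' Emits six files — STRING links-detailed, STITCH links-detailed, GAF 2.1,
#' BioGRID tab, Reactome pairs, and the alias table — that parse under the
#' package's loaders. The same seed yields byte-identical files.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory (created if needed).
#' @return list: \code{kb} (the in-memory \linkS4class{KnowledgeBase} the
#'   files serialize), \code{files} (named paths), \code{papers} (the
#'   citation pool), \code{spec}.
#' @export
generateKbFixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n <- spec$nProteins
  stringIds <- sprintf("ENSP%011d", sort(sample(1:9999999, n)))
  uniprots <- sprintf("P%05d", sort(sample(10000:99999, n)))
  symbols <- sprintf("SYG%d", seq_len(n))
  ## a few triples miss a namespace (never the STRING-style key)
  missSym <- sample(n, max(1, round(0.1 * n)))
  missUni <- sample(setdiff(seq_len(n), missSym), max(1, round(0.05 * n)))
  triples <- data.frame(stringId = stringIds, uniprotId = uniprots,
                        geneSymbol = symbols, stringsAsFactors = FALSE)
  triples$geneSymbol[missSym] <- NA_character_
  triples$uniprotId[missUni] <- NA_character_
  idMap <- new("IdentityMap", triples = triples)
  papers <- sprintf("PMC%06d", sort(sample(1:999999, spec$nPapers)))
  chemicals <- as.character(sort(sample(100:999999, spec$nChemicals)))
  processes <- sprintf("GO:%07d", sort(sample(1:9999999, spec$nProcesses)))

  kb <- newKnowledgeBase(idMap, "9606")
  if (spec$nPpi > 0) {
    pp <- samplePairs(stringIds, spec$nPpi)
    kb@ppiScored <- sortCanonical(data.frame(
      a = pp[, 1], b = pp[, 2],
      escore = drawScores(spec$nPpi, spec),
      dscore = drawScores(spec$nPpi, spec),
      tscore = drawScores(spec$nPpi, spec), stringsAsFactors = FALSE),
      c("a", "b"))
  }
  presence <- NULL
  withSym <- stringIds[!is.na(triples$geneSymbol)]
  withUni <- stringIds[!is.na(triples$uniprotId)]
  if (spec$nBiogrid > 0) {
    bp <- samplePairs(withSym, spec$nBiogrid)
    presence <- data.frame(a = bp[, 1], b = bp[, 2], source = "biogrid",
                           citingPapers = vapply(seq_len(spec$nBiogrid),
                             function(i) joinPapers(sample(papers,
                               sample(1:3, 1))), ""),
                           stringsAsFactors = FALSE)
  }
  if (spec$nReactome > 0) {
    rp <- samplePairs(withUni, spec$nReactome)
    presence <- rbind(presence, data.frame(
      a = rp[, 1], b = rp[, 2], source = "reactome",
      citingPapers = vapply(seq_len(spec$nReactome),
        function(i) joinPapers(sample(papers, sample(1:3, 1))), ""),
      stringsAsFactors = FALSE))
  }
  if (!is.null(presence))
    kb@ppiPresence <- sortCanonical(presence, c("a", "b", "source"))
  if (spec$nPci > 0) {
    combos <- expand.grid(protein = stringIds, chemical = chemicals,
                          stringsAsFactors = FALSE)
    pick <- combos[sample(nrow(combos), spec$nPci), , drop = FALSE]
    kb@pci <- sortCanonical(data.frame(
      protein = pick$protein, chemical = pick$chemical,
      stereo = sample(c("m", "s"), spec$nPci, replace = TRUE, prob = c(.8, .2)),
      escore = drawScores(spec$nPci, spec),
      dscore = drawScores(spec$nPci, spec),
      tscore = drawScores(spec$nPci, spec), stringsAsFactors = FALSE),
      c("protein", "chemical"))
  }
  gafCodes <- c("IDA", "IMP", "EXP", "IEA", "TAS", "ISS", "IC")
  if (spec$nPbp > 0) {
    combos <- expand.grid(protein = withUni, process = processes,
                          stringsAsFactors = FALSE)
    pick <- combos[sample(nrow(combos), spec$nPbp), , drop = FALSE]
    uni <- triples$uniprotId[match(pick$protein, triples$stringId)]
    kb@pbp <- sortCanonical(data.frame(
      protein = pick$protein, uniprot = uni, goTerm = pick$process,
      evidenceCode = sample(gafCodes, spec$nPbp, replace = TRUE),
      stringsAsFactors = FALSE), c("protein", "goTerm", "evidenceCode"))
    kb@pbp$evidenceKind <- gafEvidenceKind(kb@pbp$evidenceCode)
    kb@pbp <- sortCanonical(kb@pbp, c("protein", "goTerm", "evidenceCode"))
  }
  validObject(kb)

  files <- list(string = file.path(dir, "string_links.txt"),
                stitch = file.path(dir, "stitch_links.txt"),
                gaf = file.path(dir, "annotations.gaf"),
                biogrid = file.path(dir, "biogrid.tab"),
                reactome = file.path(dir, "reactome.tab"),
                aliases = file.path(dir, "aliases.tsv"))
  exportStringLinks(kb, files$string)
  exportStitchLinks(kb, files$stitch)
  exportGaf(kb, files$gaf)
  if (spec$nGafNot > 0) {
    ## NOT-qualified rows: present in the dump, excluded by the loader
    notUni <- sample(triples$uniprotId[!is.na(triples$uniprotId)],
                     spec$nGafNot, replace = TRUE)
    notLines <- vapply(seq_len(spec$nGafNot), function(i) {
      l <- gafLine(notUni[i], notUni[i],
                   sample(processes, 1), sample(gafCodes, 1), "9606")
      p <- strsplit(l, "\t", fixed = TRUE)[[1]]
      p <- c(p, rep("", 17L - length(p)))
      p[4] <- "NOT"
      paste(p, collapse = "\t")
    }, "")
    cat(notLines, file = files$gaf, sep = "\n", append = TRUE)
    cat("\n", file = files$gaf, append = TRUE)
  }
  exportBiogrid(kb, files$biogrid)
  exportReactome(kb, files$reactome)
  exportAliases(idMap, files$aliases)
  list(kb = kb, files = files, papers = papers, spec = spec,
       chemicals = chemicals, processes = processes)
}

## pool of KB interactions expressible as events (proteins need a UniProt
## accession, since events ground proteins to UniProt)
supportedEventPool <- function(kbFix) {
  kb <- kbFix$kb
  tr <- kb@idMap@triples
  uniOf <- function(sid) tr$uniprotId[match(sid, tr$stringId)]
  pool <- list()
  sc <- kb@ppiScored
  if (nrow(sc)) {
    ua <- uniOf(sc$a); ub <- uniOf(sc$b)
    ok <- !is.na(ua) & !is.na(ub)
    pool$ppi <- data.frame(class = "PPI", idA = ua[ok], idB = ub[ok],
                           keyA = sc$a[ok], keyB = sc$b[ok],
                           stringsAsFactors = FALSE)
  }
  pr <- unique(kb@ppiPresence[c("a", "b")])
  if (nrow(pr)) {
    scKey <- paste(sc$a, sc$b)
    pr <- pr[!paste(pr$a, pr$b) %in% scKey, , drop = FALSE]  # presence-only
    ua <- uniOf(pr$a); ub <- uniOf(pr$b)
    ok <- !is.na(ua) & !is.na(ub)
    if (any(ok))
      pool$presence <- data.frame(class = "PPI", idA = ua[ok], idB = ub[ok],
                                  keyA = pr$a[ok], keyB = pr$b[ok],
                                  stringsAsFactors = FALSE)
  }
  pc <- kb@pci
  if (nrow(pc)) {
    up <- uniOf(pc$protein)
    ok <- !is.na(up)
    ## idA is the chemical (events print the chemical as one participant)
    pool$pci <- data.frame(class = "PCI", idA = pc$chemical[ok],
                           idB = up[ok], keyA = pc$protein[ok],
                           keyB = pc$chemical[ok], stringsAsFactors = FALSE)
  }
  pb <- unique(kb@pbp[c("protein", "uniprot", "goTerm")])
  if (nrow(pb)) {
    pool$pbp <- data.frame(class = "PBPI", idA = pb$uniprot,
                           idB = pb$goTerm, keyA = pb$protein,
                           keyB = pb$goTerm, stringsAsFactors = FALSE)
  }
  do.call(rbind, pool)
}

spaceOutChemical <- function(id) {
  if (nchar(id) < 4) return(id)
  cut <- nchar(id) - 3
  paste(substr(id, 1, cut), substr(id, cut + 1, nchar(id)))
}

#' Generate a labeled synthetic reading set
#'
#' Assembles an event table in the nine-column dialect whose composition is
#' planted and recorded: rows supported by the generated knowledge base,
#' grounded rows absent from it, grounding failures (accessions outside the
#' alias table), excluded element types, between-paper duplicate groups
#' across 2/4/6 distinct papers, within-paper repeats, and publication
#' years on both sides of the novelty boundary. Judgment labels are correct
#' for supported rows and incorrect otherwise, with configurable
#' label-noise fractions so imperfect precision is exercised.
#'
#' @param spec the \code{\link{fixtureSpec}} used for the knowledge base.
#' @param kbFix result of \code{\link{generateKbFixtures}}.
#' @param dir output directory.
#' @return list: \code{files} (events, years, labels, groundTruth paths)
#'   and \code{groundTruth} (per-row data.frame: planted kind, class,
#'   in-KB flag, label, reference, year, planted distinct-paper count,
#'   within-paper-repeat flag, expected zero-threshold verdict).
#' @export
generateReadingSet <- function(spec, kbFix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1000L)
  n <- spec$readingSetSize
  nDupExtra <- round(spec$fracDuplicate * n)
  nWithin <- round(spec$fracWithinDup * n)
  nBase <- n - nDupExtra - nWithin
  nSup <- round(spec$fracSupported * n)
  nUnm <- round(spec$fracUnmapped * nBase)
  nOther <- round(spec$fracOtherType * nBase)
  nUns <- nBase - nSup - nUnm - nOther
  stopifnot(nUns >= 0)

  pool <- supportedEventPool(kbFix)
  if (nSup > nrow(pool))
    stop("infeasible spec: reading set needs more supported interactions than the KB offers")
  tr <- kbFix$kb@idMap@triples
  sup <- pool[sample(nrow(pool), nSup), , drop = FALSE]
  sup$kind <- "supported"

  ## grounded but absent from every KB table: fresh protein pairs
  usable <- tr$uniprotId[!is.na(tr$uniprotId)]
  uns <- NULL
  kbTabs <- kbFix$kb
  seen <- c(paste(kbTabs@ppiScored$a, kbTabs@ppiScored$b),
            paste(kbTabs@ppiPresence$a, kbTabs@ppiPresence$b))
  while (is.null(uns) || nrow(uns) < nUns) {
    u <- sample(usable, 2)
    sid <- tr$stringId[match(u, tr$uniprotId)]
    key <- paste(sort(sid), collapse = " ")
    if (key %in% seen) next
    seen <- c(seen, key)
    uns <- rbind(uns, data.frame(class = "PPI", idA = u[1], idB = u[2],
                                 keyA = sort(sid)[1], keyB = sort(sid)[2],
                                 kind = "unsupported",
                                 stringsAsFactors = FALSE))
  }

  ## grounding failures: UniProt-shaped accessions outside the alias table
  ghost <- sprintf("Q%05d", sample(10000:99999, max(1, 2 * nUnm)))
  ghost <- ghost[!ghost %in% tr$uniprotId][seq_len(nUnm)]
  unm <- if (nUnm > 0) data.frame(class = "PPI", idA = ghost,
                                  idB = sample(usable, nUnm, replace = TRUE),
                                  keyA = ghost, keyB = ghost,
                                  kind = "unmapped", stringsAsFactors = FALSE)
  oth <- if (nOther > 0) data.frame(
    class = "OTHER", idA = sprintf("PF%05d", sample(1:99999, nOther)),
    idB = sample(usable, nOther, replace = TRUE),
    keyA = "family", keyB = "family", kind = "other",
    stringsAsFactors = FALSE)
  base <- rbind(sup[c("class", "idA", "idB", "keyA", "keyB", "kind")],
                uns, unm, oth)

  ## references and years
  papers <- kbFix$papers
  base$reference <- sample(papers, nrow(base), replace = TRUE)
  refs <- sort(unique(papers))
  recent <- stats::runif(length(refs)) < spec$fracRecent
  yearOf <- ifelse(recent,
                   sample(seq(spec$recentAfter + 1, spec$yearRange[2]),
                          length(refs), replace = TRUE),
                   sample(seq(spec$yearRange[1], spec$recentAfter),
                          length(refs), replace = TRUE))
  names(yearOf) <- refs

  ## between-paper duplicate groups (2/4/6 distinct papers) and
  ## within-paper repeats, spent from the extra-row budget
  rows <- base
  dupSizes <- c(2L, 4L, 6L)
  budget <- nDupExtra
  gi <- 0L
  dupEligible <- which(base$kind %in% c("supported", "unsupported"))
  while (budget > 0 && length(dupEligible) > 0) {
    size <- dupSizes[gi %% 3L + 1L]
    gi <- gi + 1L
    extra <- min(size - 1L, budget)
    pick <- sample(dupEligible, 1)
    dupEligible <- setdiff(dupEligible, pick)
    otherRefs <- sample(setdiff(papers, base$reference[pick]), extra)
    clone <- base[rep(pick, extra), , drop = FALSE]
    clone$reference <- otherRefs
    rows <- rbind(rows, clone)
    budget <- budget - extra
  }
  if (nWithin > 0) {
    pick <- sample(which(base$kind == "supported"), nWithin, replace = TRUE)
    clone <- base[pick, , drop = FALSE]  # same reference: within-paper repeat
    rows <- rbind(rows, clone)
  }
  rows <- rows[sample(nrow(rows)), , drop = FALSE]
  rownames(rows) <- NULL

  ## materialize the event dialect
  nameOf <- function(id) {
    i <- match(id, tr$uniprotId)
    ifelse(!is.na(i) & !is.na(tr$geneSymbol[i]), tolower(tr$geneSymbol[i]),
           tolower(id))
  }
  m <- nrow(rows)
  typeB <- rep("protein", m)
  typeA <- ifelse(rows$class == "PCI", "chemical",
                  ifelse(rows$class == "PBPI", "biological process",
                         ifelse(rows$class == "OTHER", "protein family",
                                "protein")))
  idA <- rows$idA
  spaced <- rows$class == "PCI" & stats::runif(m) < 0.25
  idA[spaced] <- vapply(idA[spaced], spaceOutChemical, "")
  flip <- rows$class == "PPI" & stats::runif(m) < 0.5
  events <- data.frame(
    regulated = ifelse(rows$class == "PBPI", paste0("process-", rows$idB),
                       nameOf(rows$idA)),
    regulatedType = normalizeElementType(ifelse(flip, typeB, typeA)),
    regulatedId = ifelse(flip, rows$idB, idA),
    regulator = nameOf(rows$idB),
    regulatorType = normalizeElementType(ifelse(flip, typeA, typeB)),
    regulatorId = ifelse(flip, idA, rows$idB),
    effect = sample(c("increases", "decreases"), m, replace = TRUE),
    reference = rows$reference,
    evidence = sprintf("Sentence reporting that %s regulates %s.",
                       nameOf(rows$idB), nameOf(rows$idA)),
    stringsAsFactors = FALSE)
  ## PBPI events name the process as the regulated element
  pb <- rows$class == "PBPI"
  events$regulatedId[pb] <- rows$idB[pb]
  events$regulatedType[pb] <- "biological-process"
  events$regulatorId[pb] <- rows$idA[pb]
  events$regulatorType[pb] <- "protein"
  events$regulator[pb] <- nameOf(rows$idA[pb])
  ## one evidence string with an embedded tab exercises field quoting
  if (m > 0) events$evidence[1] <- paste0(events$evidence[1], "\tsee Fig 2")
  events$year <- as.integer(yearOf[events$reference])
  events$row <- seq_len(m)

  ## labels: correct tracks database support, with planted noise
  inKb <- rows$kind == "supported"
  correct <- inKb
  supIdx <- which(inKb)
  flipSup <- sample(supIdx, round(spec$labelFlipSupported * length(supIdx)))
  correct[flipSup] <- FALSE
  unsIdx <- which(rows$kind == "unsupported")
  flipUns <- sample(unsIdx, round(spec$labelCorrectUnsupported * length(unsIdx)))
  correct[flipUns] <- TRUE

  ## planted per-row literature facts, recomputed from the emitted rows
  gKey <- paste(rows$class, rows$keyA, rows$keyB, rows$idA, rows$idB)
  dupCount <- vapply(split(rows$reference, gKey), function(r)
    length(unique(r)), 0L)[gKey]
  withinDup <- ave(seq_len(m), paste(gKey, rows$reference),
                   FUN = length) > 1
  groundTruth <- data.frame(
    row = seq_len(m), kind = rows$kind, class = rows$class,
    inKb = inKb, correct = correct, reference = rows$reference,
    year = events$year, dupCount = as.integer(dupCount),
    withinPaperDuplicate = withinDup,
    expectedVerdict = c(supported = "selected", unsupported = "discarded",
                        unmapped = "unmapped",
                        other = "unsupported_type")[rows$kind],
    stringsAsFactors = FALSE)

  files <- list(events = file.path(dir, "events.tsv"),
                years = file.path(dir, "years.tsv"),
                labels = file.path(dir, "labels.tsv"),
                groundTruth = file.path(dir, "ground_truth.tsv"))
  writeExtracted(events, files$events)
  writeTsv(data.frame(reference = refs, year = as.integer(yearOf),
                      stringsAsFactors = FALSE), files$years)
  writeTsv(data.frame(row = seq_len(m),
                      label = ifelse(correct, "correct", "incorrect"),
                      stringsAsFactors = FALSE), files$labels)
  writeTsv(groundTruth, files$groundTruth)
  list(files = files, groundTruth = groundTruth, events = events,
       yearOf = yearOf)
}

#' Generate the golden-set case-study fixture
#'
#' Emulates validating a filtered reading set against a small published
#' model: a reading set of a few hundred events contains a planted "golden"
#' subset whose knowledge-base text-mining scores are high, inside a
#' background of supported interactions with unconstrained scores and of
#' unsupported noise. Raising the text-mining threshold should enrich the
#' selection for golden interactions.
#'
#' @param seed integer seed.
#' @param nEvents total reading-set size.
#' @param nGolden size of the golden subset.
#' @return list: \code{kb}, \code{events}, \code{golden} (logical per
#'   event row).
#' @export
generateGoldenStudy <- function(seed = 1L, nEvents = 260, nGolden = 14) {
  set.seed(seed + 2000L)
  n <- 120
  stringIds <- sprintf("ENSP%011d", sort(sample(1:9999999, n)))
  uniprots <- sprintf("P%05d", sort(sample(10000:99999, n)))
  triples <- data.frame(stringId = stringIds, uniprotId = uniprots,
                        geneSymbol = sprintf("SYG%d", seq_len(n)),
                        stringsAsFactors = FALSE)
  kb <- newKnowledgeBase(new("IdentityMap", triples = triples), "9606")
  nSupported <- round(0.65 * nEvents)
  pp <- samplePairs(stringIds, nSupported)
  golden <- seq_len(nSupported) <= nGolden
  kb@ppiScored <- sortCanonical(data.frame(
    a = pp[, 1], b = pp[, 2],
    escore = sample(0:1000, nSupported, replace = TRUE),
    dscore = sample(0:1000, nSupported, replace = TRUE),
    tscore = ifelse(golden, sample(820:1000, nSupported, replace = TRUE),
                    sample(0:1000, nSupported, replace = TRUE)),
    stringsAsFactors = FALSE), c("a", "b"))
  uniOf <- function(sid) triples$uniprotId[match(sid, triples$stringId)]
  nNoise <- nEvents - nSupported
  ghost <- sprintf("Q%05d", sample(10000:99999, nNoise))
  events <- data.frame(
    regulated = "x", regulatedType = "protein",
    regulatedId = c(uniOf(pp[, 1]), ghost),
    regulator = "y", regulatorType = "protein",
    regulatorId = c(uniOf(pp[, 2]), sample(uniprots, nNoise, replace = TRUE)),
    effect = "increases",
    reference = sprintf("PMC%06d", sample(1:999999, nEvents, replace = TRUE)),
    evidence = "sentence", stringsAsFactors = FALSE)
  events$year <- NA_integer_
  events$row <- seq_len(nEvents)
  list(kb = kb, events = events,
       golden = c(golden, rep(FALSE, nNoise)))
}
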