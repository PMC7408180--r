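## Shared fixture builders. Studies are generated programmatically at test
## time and cached per (seed, size) within a test run.

.studyCache <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

smallSpec <- function(seed, ...) {
  args <- list(seed = seed, nProteins = 40, nChemicals = 8, nProcesses = 8,
               nPpi = 60, nPci = 20, nPbp = 25, nBiogrid = 15,
               nReactome = 10, readingSetSize = 120)
  args <- utils::modifyList(args, list(...))
  do.call(fixtureSpec, args)
}

## noise-free labels: correct <=> supported by the knowledge base
cleanSpec <- function(seed, ...) {
  smallSpec(seed, labelFlipSupported = 0, labelCorrectUnsupported = 0, ...)
}

makeStudy <- function(spec) {
  key <- paste0("s", spec$seed, "_", spec$readingSetSize, "_",
                spec$labelFlipSupported, "_", spec$nPpi)
  if (!is.null(.studyCache[[key]])) return(.studyCache[[key]])
  dir <- file.path(tempdir(), paste0("study_", key))
  kbFix <- generateKbFixtures(spec, dir)
  rs <- generateReadingSet(spec, kbFix, dir)
  kb <- buildKnowledgeBase(string = kbFix$files$string,
                           stitch = kbFix$files$stitch,
                           gaf = kbFix$files$gaf,
                           biogrid = kbFix$files$biogrid,
                           reactome = kbFix$files$reactome,
                           aliases = kbFix$files$aliases)
  events <- readExtracted(rs$files$events, years = rs$files$years)
  labels <- readLabels(rs$files$labels, nrow(events))
  study <- list(spec = spec, kbFix = kbFix, rs = rs, kb = kb,
                events = events, labels = labels,
                groundTruth = rs$groundTruth)
  .studyCache[[key]] <- study
  study
}

## a tiny hand-written alias table used by identifier tests
demoAliasFile <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("string_id\tuniprot_id\tgene_symbol", rows), path)
  path
}
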