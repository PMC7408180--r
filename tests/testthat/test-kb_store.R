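writeStringFile <- function(rows, path = tempfile()) {
  writeLines(c("protein1 protein2 neighborhood fusion experimental database textmining combined_score",
               rows), path)
  path
}

test_that("STRING loader: counts, species filter, unordered-pair symmetry", {
  kb <- newKnowledgeBase()
  path <- writeStringFile(c(
    "9606.ENSP01 9606.ENSP02 0 0 500 100 200 600",
    "9606.ENSP02 9606.ENSP01 0 0 500 100 200 600",  # same pair, other order
    "9606.ENSP01 9606.ENSP03 0 0 0 0 900 900",
    "10090.ENSP09 10090.ENSP08 0 0 1 1 1 3"))       # wrong species
  kb <- loadStringLinks(kb, path)
  expect_equal(kbLoadCounts(kb)$string_rows, 3)
  expect_equal(kbLoadCounts(kb)$string_skipped_species, 1)
  expect_equal(nrow(kb@ppiScored), 2)  # 2 rows collapsed to 1 unordered pair
  expect_identical(queryPpi(kb, "ENSP01", "ENSP02"),
                   queryPpi(kb, "ENSP02", "ENSP01"))
  expect_equal(queryPpi(kb, "ENSP01", "ENSP02")$escore, 500)
  expect_null(queryPpi(kb, "ENSP01", "ENSP99"))
})

test_that("STRING loader errors name missing columns, skips malformed scores", {
  bad <- tempfile()
  writeLines(c("protein1 protein2 experimental database",
               "a b 1 2"), bad)
  expect_error(loadStringLinks(newKnowledgeBase(), bad), "textmining")
  mal <- writeStringFile(c("9606.A 9606.B 0 0 500 100 200 600",
                           "9606.A 9606.C 0 0 1200 0 0 1200",   # out of range
                           "9606.A 9606.D 0 0 xx 0 0 0"))       # non-integer
  expect_warning(kb <- loadStringLinks(newKnowledgeBase(), mal), "line")
  expect_equal(kbLoadCounts(kb)$string_rows, 1)
  expect_equal(kbLoadCounts(kb)$string_skipped_malformed, 2)
})

test_that("duplicate scored pairs keep the maximum of each subscore", {
  path <- writeStringFile(c("9606.A 9606.B 0 0 500 100 200 600",
                            "9606.B 9606.A 0 0 100 300 100 400"))
  kb <- loadStringLinks(newKnowledgeBase(), path)
  q <- queryPpi(kb, "A", "B")
  expect_equal(c(q$escore, q$dscore, q$tscore), c(500, 300, 200))
})

test_that("STITCH loader: header-only file, identity lookup, chemical normalization", {
  empty <- tempfile()
  writeLines("chemical protein experimental database textmining combined_score",
             empty)
  kb <- loadStitchLinks(newKnowledgeBase(), empty)
  expect_equal(kbLoadCounts(kb)$stitch_rows, 0)
  one <- tempfile()
  writeLines(c("chemical protein experimental database textmining combined_score",
               "CIDm00216239 9606.ENSP05 450 10 20 470"), one)
  kb <- loadStitchLinks(newKnowledgeBase(), one)
  expect_equal(queryPci(kb, "ENSP05", "216239")$escore, 450)
  ## spaced printed form of the same compound id matches too
  expect_equal(queryPci(kb, "ENSP05", "216 239")$escore, 450)
  expect_null(queryPci(kb, "ENSP05", "999"))
})

test_that("GAF loader maps evidence codes and excludes NOT annotations", {
  gaf <- tempfile()
  mk <- function(uni, go, code, qual = "") paste(
    c("UniProtKB", uni, uni, qual, go, "REF", code, "", "P", "", "",
      "protein", "taxon:9606", "20200101", "X", "", ""), collapse = "\t")
  writeLines(c("!gaf-version: 2.1",
               mk("P25445", "GO:0006915", "IDA"),
               mk("P25445", "GO:0006915", "IEA"),
               mk("P00001", "GO:0008150", "TAS"),
               mk("P00002", "GO:0008150", "IMP", qual = "NOT")), gaf)
  kb <- loadGoGaf(newKnowledgeBase(), gaf)
  expect_equal(kbLoadCounts(kb)$gaf_rows, 3)
  expect_equal(kbLoadCounts(kb)$gaf_excluded_not, 1)
  ann <- queryPbp(kb, "P25445", "GO:0006915")
  expect_setequal(ann$evidenceKind, c("experimental", "electronic"))
  expect_equal(queryPbp(kb, "P00001", "GO:0008150")$evidenceKind, "other")
  expect_equal(nrow(queryPbp(kb, "P00002", "GO:0008150")), 0)
  bad <- tempfile()
  writeLines(c("!gaf", "only\tthree\tcols"), bad)
  expect_error(loadGoGaf(newKnowledgeBase(), bad), "line 2")
})

test_that("BioGRID merges duplicate pairs, unioning citing papers", {
  map <- loadAliases(demoAliasFile(c("ENSPA\tP00001\tGENEA",
                                     "ENSPB\tP00002\tGENEB",
                                     "ENSPC\tP00003\tGENEC")))
  bg <- tempfile()
  writeLines(c("OFFICIAL_SYMBOL_A\tOFFICIAL_SYMBOL_B\tPUBMED_ID",
               "GENEA\tGENEB\tPMC000001",
               "GENEB\tGENEA\tPMC000002",   # same pair, second paper
               "GENEA\tGENEC\tPMC000003"), bg)
  kb <- loadBiogrid(newKnowledgeBase(map), bg)
  expect_equal(nrow(kb@ppiPresence), 2)
  q <- queryPpi(kb, "ENSPA", "ENSPB")
  expect_equal(q$presenceSources, "biogrid")
  expect_equal(q$citingPapers, c("PMC000001", "PMC000002"))
})

test_that("Reactome pairs are found as presence records under either order", {
  map <- loadAliases(demoAliasFile(c("ENSPCAT\tP35222\tCTNNB1",
                                     "ENSPAXI\tO15169\tAXIN1")))
  rc <- tempfile()
  writeLines(c("uniprot_a\tuniprot_b\tpubmed_ids",
               "O15169\tP35222\tPMC4102778"), rc)
  kb <- loadReactome(newKnowledgeBase(map), rc)
  q <- queryPpi(kb, "ENSPCAT", "ENSPAXI")
  expect_equal(q$presenceSources, "reactome")
  expect_true(is.na(q$escore))
  expect_identical(q, queryPpi(kb, "ENSPAXI", "ENSPCAT"))
})

test_that("every query agrees with a linear scan of the raw dumps", {
  study <- makeStudy(smallSpec(7))
  dumps <- oracleReadDumps(study$kbFix$files)
  kb <- study$kb
  ## scored PPI pairs
  st <- dumps$string
  for (i in seq_len(nrow(st))) {
    q <- queryPpi(kb, st$protein1[i], st$protein2[i])
    expect_equal(q$escore, as.integer(st$experimental[i]))
    expect_equal(q$dscore, as.integer(st$database[i]))
    expect_equal(q$tscore, as.integer(st$textmining[i]))
  }
  ## scored PCI pairs
  sti <- dumps$stitch
  for (i in seq_len(nrow(sti))) {
    q <- queryPci(kb, sti$protein[i], sti$chem[i])
    expect_equal(q$escore, as.integer(sti$experimental[i]))
  }
  ## annotations
  gaf <- dumps$gaf
  for (i in seq_len(nrow(gaf))) {
    canon <- oracleResolveProtein(gaf$uniprot[i], dumps$aliases)
    if (length(canon) != 1) canon <- gaf$uniprot[i]
    ann <- queryPbp(kb, canon, gaf$go[i])
    expect_true(unname(oracleEvKind(gaf$code[i])) %in% ann$evidenceKind)
  }
  ## no stored subscore outside [0, 1000]
  expect_true(all(kb@ppiScored$escore >= 0 & kb@ppiScored$escore <= 1000))
  expect_true(all(unlist(kb@pci[c("escore", "dscore", "tscore")]) >= 0))
  expect_true(all(unlist(kb@pci[c("escore", "dscore", "tscore")]) <= 1000))
})

test_that("citation and protein searches equal brute-force filters", {
  study <- makeStudy(smallSpec(7))
  kb <- study$kb
  pr <- kb@ppiPresence
  allPapers <- sort(unique(unlist(strsplit(pr$citingPapers, ";"))))
  ## empty query
  expect_equal(nrow(interactionsCiting(kb, character(0))), 0)
  query <- allPapers[seq(1, length(allPapers), by = 3)]
  got <- interactionsCiting(kb, query)
  want <- which(vapply(strsplit(pr$citingPapers, ";"), function(p)
    length(intersect(p, query)) > 0, TRUE))
  expect_setequal(paste(got$a, got$b, got$source),
                  paste(pr$a[want], pr$b[want], pr$source[want]))
  ## results are sorted deterministically by pair key
  expect_false(is.unsorted(paste(got$a, got$b, got$source)))
  prots <- unique(c(pr$a[1], pr$b[2]))
  inv <- interactionsInvolving(kb, prots)
  wantInv <- which(pr$a %in% prots | pr$b %in% prots)
  expect_setequal(paste(inv$a, inv$b, inv$source),
                  paste(pr$a[wantInv], pr$b[wantInv], pr$source[wantInv]))
})
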