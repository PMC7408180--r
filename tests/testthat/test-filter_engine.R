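test_that("support lookup routes by class and matches the raw dumps", {
  study <- makeStudy(smallSpec(7))
  dumps <- oracleReadDumps(study$kbFix$files)
  ev <- study$events
  for (i in seq_len(nrow(ev))) {
    got <- lookupSupport(ev[i, ], study$kb)
    want <- oracleSupportRow(ev[i, ], dumps)
    expect_equal(got$class, want$class, info = paste("row", i))
    expect_equal(got$status, want$status, info = paste("row", i))
    expect_equal(got$matched, want$matched, info = paste("row", i))
    expect_equal(got$escore, want$escore, info = paste("row", i))
    expect_equal(got$dscore, want$dscore, info = paste("row", i))
    expect_equal(got$tscore, want$tscore, info = paste("row", i))
    expect_equal(got$presenceSources, want$presence, info = paste("row", i))
    expect_equal(got$citingPapers, want$citing, info = paste("row", i))
    if (want$class == "PBPI" && want$matched)
      expect_equal(got$pbpEvidence, want$kinds, info = paste("row", i))
  }
})

test_that("a presence-only pair matches without subscores", {
  map <- loadAliases(demoAliasFile(c("ENSPA\tP00001\tGENEA",
                                     "ENSPB\tP00002\tGENEB")))
  rc <- tempfile()
  writeLines(c("uniprot_a\tuniprot_b\tpubmed_ids", "P00001\tP00002\tPMC1"), rc)
  kb <- loadReactome(newKnowledgeBase(map), rc)
  ev <- data.frame(regulated = "a", regulatedType = "protein",
                   regulatedId = "P00001", regulator = "b",
                   regulatorType = "protein", regulatorId = "P00002",
                   effect = "increases", reference = "PMCX",
                   evidence = "s", year = NA_integer_, row = 1L,
                   stringsAsFactors = FALSE)
  s <- lookupSupport(ev, kb)
  expect_true(s$matched)
  expect_true(is.na(s$escore))
  expect_equal(s$presenceSources, "reactome")
  ## selectable at zero inclusive thresholds, rejected above them and
  ## under an exclusive zero
  expect_true(passesPolicy(s, thresholdPolicy(0, 0, 0))$pass)
  expect_false(passesPolicy(s, thresholdPolicy(200, NA, NA))$pass)
  expect_false(passesPolicy(s, thresholdPolicy(0, NA, NA,
                                               inclusive = FALSE))$pass)
})

test_that("random support records and policies agree with an independent predicate", {
  set.seed(99)
  for (rep in seq_len(200)) {
    cls <- sample(c("PPI", "PCI", "PBPI"), 1)
    matched <- runif(1) < 0.8
    presenceOnly <- cls == "PPI" && runif(1) < 0.3
    sup <- list(class = cls, matched = matched,
                escore = NA_integer_, dscore = NA_integer_,
                tscore = NA_integer_, pbpEvidence = character(0))
    if (matched && cls != "PBPI" && !presenceOnly) {
      sup$escore <- sample(0:1000, 1); sup$dscore <- sample(0:1000, 1)
      sup$tscore <- sample(0:1000, 1)
    }
    if (matched && cls == "PBPI")
      sup$pbpEvidence <- sample(c("experimental", "electronic", "other"),
                                sample(1:2, 1))
    for (k in seq_len(20)) {
      thr <- function() if (runif(1) < 0.3) NA else sample(c(0, 200, 400, 600,
                                                             800, 1000), 1)
      pol <- list(e = thr(), d = thr(), t = thr(),
                  combine = sample(c("any", "all"), 1),
                  inclusive = runif(1) < 0.5,
                  kinds = if (runif(1) < 0.5) character(0)
                          else sample(c("experimental", "electronic",
                                        "other"), sample(1:2, 1)))
      if (all(is.na(c(pol$e, pol$d, pol$t))) && length(pol$kinds) == 0)
        pol$e <- 0
      got <- passesPolicy(sup, thresholdPolicy(
        escoreMin = pol$e, dscoreMin = pol$d, tscoreMin = pol$t,
        combine = pol$combine, inclusive = pol$inclusive,
        evidenceKinds = pol$kinds))
      want <- oraclePasses(list(matched = sup$matched, class = sup$class,
                                escore = sup$escore, dscore = sup$dscore,
                                tscore = sup$tscore,
                                kinds = sup$pbpEvidence), pol)
      expect_equal(got$pass, want)
    }
  }
})

test_that("the exclusive zero threshold guarantees experimental evidence", {
  study <- makeStudy(smallSpec(5))
  pol <- thresholdPolicy(escoreMin = 0, dscoreMin = NA, tscoreMin = NA,
                         inclusive = FALSE)
  res <- filterInteractions(study$events, study$kb, pol)
  sel <- selectedEvents(res)
  scored <- sel[sel$class %in% c("PPI", "PCI"), ]
  expect_gt(nrow(scored), 0)
  expect_true(all(!is.na(scored$escore)))
  expect_true(all(scored$escore > 0))
  ## all-zero score record fails the exclusive policy
  zero <- list(class = "PPI", matched = TRUE, escore = 0L, dscore = 0L,
               tscore = 0L, pbpEvidence = character(0))
  expect_false(passesPolicy(zero, pol)$pass)
  expect_true(passesPolicy(zero, thresholdPolicy(0, NA, NA))$pass)
})

test_that("filtering partitions the input and matches the brute-force oracle", {
  for (seed in c(3, 8)) {
    study <- makeStudy(smallSpec(seed))
    dumps <- oracleReadDumps(study$kbFix$files)
    pol <- thresholdPolicy(escoreMin = 400, dscoreMin = 0, tscoreMin = 200,
                           combine = "any")
    res <- filterInteractions(study$events, study$kb, pol)
    want <- oracleFilter(study$events, dumps,
                         defaultOraclePolicy(e = 400, d = 0, t = 200))
    expect_identical(res@events$verdict, want$verdict)
    s <- filterSummary(res)
    expect_equal(s$n_selected + s$n_discarded + s$n_unmapped +
                 s$n_unsupported, nrow(study$events))
  }
})

test_that("raising any single subscore threshold never adds a selection", {
  study <- makeStudy(smallSpec(4))
  grid <- seq(0, 1000, by = 200)
  for (score in c("escoreMin", "dscoreMin", "tscoreMin")) {
    prev <- NULL
    for (t in grid) {
      args <- list(escoreMin = 0, dscoreMin = 0, tscoreMin = 0,
                   combine = "all")
      args[[score]] <- t
      res <- filterInteractions(study$events, study$kb,
                                do.call(thresholdPolicy, args))
      sel <- selectedEvents(res)$row
      if (!is.null(prev)) expect_true(all(sel %in% prev))
      prev <- sel
    }
  }
})

test_that("requiring all subscores selects a subset of requiring any", {
  study <- makeStudy(smallSpec(4))
  for (t in c(0, 400, 800)) {
    selAll <- selectedEvents(filterInteractions(study$events, study$kb,
      thresholdPolicy(t, t, t, combine = "all")))$row
    selAny <- selectedEvents(filterInteractions(study$events, study$kb,
      thresholdPolicy(t, t, t, combine = "any")))$row
    expect_true(all(selAll %in% selAny))
  }
})

test_that("without non-database rescue, selection implies a database match", {
  study <- makeStudy(smallSpec(4))
  res <- filterInteractions(study$events, study$kb,
                            thresholdPolicy(0, 0, 0, nondbMode = "off"))
  expect_true(all(selectedEvents(res)$matched))
})

test_that("non-database union rescues flagged rows; flag_only does not", {
  study <- makeStudy(smallSpec(6))
  base <- thresholdPolicy(800, 800, 800, combine = "all")
  resOff <- filterInteractions(study$events, study$kb, base,
                               years = study$rs$yearOf)
  union <- thresholdPolicy(800, 800, 800, combine = "all", minYear = 2014,
                           minDupPapers = 2, nondbMode = "union")
  resU <- filterInteractions(study$events, study$kb, union,
                             years = study$rs$yearOf)
  flagOnly <- thresholdPolicy(800, 800, 800, combine = "all",
                              minYear = 2014, minDupPapers = 2,
                              nondbMode = "flag_only")
  resF <- filterInteractions(study$events, study$kb, flagOnly,
                             years = study$rs$yearOf)
  selOff <- selectedEvents(resOff)$row
  selU <- selectedEvents(resU)$row
  expect_true(all(selOff %in% selU))
  expect_gt(length(selU), length(selOff))
  rescued <- selectedEvents(resU)
  rescued <- rescued[rescued$reason %in% c("nondb-novel", "nondb-duplicates",
                                           "nondb-novel+duplicates"), ]
  expect_true(all(rescued$novel | rescued$dupCount >= 2))
  expect_identical(selectedEvents(resF)$row, selOff)
  ## flags are still attached in flag_only mode
  expect_true(any(resF@events$novel | resF@events$dupCount >= 2))
})

test_that("filtering is deterministic: identical runs give identical output files", {
  study <- makeStudy(smallSpec(4))
  run <- function() {
    res <- filterInteractions(study$events, study$kb,
                              thresholdPolicy(200, NA, NA),
                              years = study$rs$yearOf)
    p <- tempfile(); writeResults(res, p)
    readBin(p, "raw", file.size(p))
  }
  expect_identical(run(), run())
})

test_that("policy validity is enforced", {
  expect_error(thresholdPolicy(NA, NA, NA), "criterion")
  expect_error(thresholdPolicy(escoreMin = 1200), "1000")
  expect_error(thresholdPolicy(0, 0, 0, minDupPapers = 1), ">= 2")
})
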