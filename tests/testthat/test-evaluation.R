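test_that("precision and recall follow their set-arithmetic definitions", {
  ## identity: selected == correct
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  pr <- precisionRecall(c(1, 2), labels)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  ## empty selection: precision absent, recall zero
  pr <- precisionRecall(integer(0), labels)
  expect_true(is.na(pr$precision))
  expect_equal(pr$recall, 0)
  ## no correct rows: recall absent
  pr <- precisionRecall(1:2, rep(FALSE, 4))
  expect_true(is.na(pr$recall))
  expect_equal(pr$precision, 0)
  ## missing label for a selected row is an error naming the row
  expect_error(precisionRecall(3, c(TRUE, TRUE, NA)), "3")
  ## 200-row random fixtures against brute-force set arithmetic
  set.seed(17)
  for (rep in 1:10) {
    lab <- runif(200) < 0.4
    sel <- sample(200, sample(0:200, 1))
    got <- precisionRecall(sel, lab)
    want <- oraclePrecisionRecall(sel, which(lab))
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
  }
})

test_that("single-subscore sweeps recompute per grid point and recall never rises", {
  study <- makeStudy(smallSpec(3))
  dumps <- oracleReadDumps(study$kbFix$files)
  correct <- which(study$labels)
  for (score in c("escore", "tscore")) {
    sw <- singleScoreSweep(study$events, study$kb, study$labels, score)
    expect_equal(sw$threshold, seq(0, 1000, 200))
    ## brute-force recomputation at every grid point
    for (i in seq_len(nrow(sw))) {
      pol <- defaultOraclePolicy(e = NA, d = NA, t = NA)
      pol[[substr(score, 1, 1)]] <- sw$threshold[i]
      want <- oracleFilter(study$events, dumps, pol)
      wantPr <- oraclePrecisionRecall(which(want$verdict == "selected"),
                                      correct)
      expect_equal(sw$precision[i], wantPr$precision)
      expect_equal(sw$recall[i], wantPr$recall)
    }
    expect_true(all(diff(sw$recall) <= 0))
    expect_true(all(diff(sw$nSelected) <= 0))
  }
})

test_that("the 125-cell combination grid and its marginal means are exact", {
  study <- makeStudy(smallSpec(3))
  cs <- combinationSweep(study$events, study$kb, study$labels)
  expect_equal(nrow(cs$grid), 125)
  expect_equal(nrow(cs$marginals), 15)
  ## spot-check grid cells against direct filtering
  for (i in c(1, 37, 125)) {
    cell <- cs$grid[i, ]
    res <- filterInteractions(study$events, study$kb,
      thresholdPolicy(cell$escoreMin, cell$dscoreMin, cell$tscoreMin,
                      combine = "all"))
    pr <- precisionRecall(selectedEvents(res)$row, study$labels)
    expect_equal(cell$precision, pr$precision)
    expect_equal(cell$recall, pr$recall)
  }
  ## every marginal mean equals an independent average over its 25 cells
  for (j in seq_len(nrow(cs$marginals))) {
    m <- cs$marginals[j, ]
    col <- paste0(m$score, "Min")
    cells <- cs$grid[cs$grid[[col]] == m$value, ]
    expect_equal(nrow(cells), 25)
    expect_equal(m$meanPrecision, mean(cells$precision, na.rm = TRUE))
    expect_equal(m$meanRecall, mean(cells$recall, na.rm = TRUE))
  }
  ## the all-zero cell agrees with a zero single-score sweep under "all"
  zero <- cs$grid[cs$grid$escoreMin == 0 & cs$grid$dscoreMin == 0 &
                  cs$grid$tscoreMin == 0, ]
  res0 <- filterInteractions(study$events, study$kb,
                             thresholdPolicy(0, 0, 0, combine = "all"))
  pr0 <- precisionRecall(selectedEvents(res0)$row, study$labels)
  expect_equal(zero$precision, pr0$precision)
  expect_equal(zero$recall, pr0$recall)
})

test_that("nested (stricter) policies never gain recall", {
  study <- makeStudy(smallSpec(3))
  sw <- singleScoreSweep(study$events, study$kb, study$labels, "escore")
  expect_true(all(diff(sw$recall) <= 0))
  cs <- combinationSweep(study$events, study$kb, study$labels)
  g <- cs$grid
  base <- g$recall[g$escoreMin == 0 & g$dscoreMin == 0 & g$tscoreMin == 0]
  expect_true(all(g$recall <= base + 1e-12))
})

test_that("with labels tied to database support, zero thresholds recover everything", {
  study <- makeStudy(cleanSpec(21))
  res <- filterInteractions(study$events, study$kb, thresholdPolicy(0, 0, 0))
  pr <- precisionRecall(selectedEvents(res)$row, study$labels)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
})

test_that("augmentation unions never lose recall and report exact additions", {
  study <- makeStudy(smallSpec(6))
  base <- thresholdPolicy(600, 600, 600, combine = "all")
  augs <- list(list(minYear = 2014), list(minDupPapers = 2),
               list(minDupPapers = 4), list(minDupPapers = 6),
               list(minYear = 2014, minDupPapers = 2))
  tab <- augmentedEval(study$events, study$kb, study$labels, base, augs,
                       years = study$rs$yearOf)
  expect_equal(nrow(tab), length(augs) + 1)
  expect_true(all(tab$recall >= tab$recall[tab$label == "base"]))
  ## +N equals a direct count of correct rows gained over the base selection
  correct <- which(study$labels)
  baseSel <- selectedEvents(filterInteractions(study$events, study$kb, base,
                                               years = study$rs$yearOf))$row
  for (i in seq_along(augs)) {
    aug <- augs[[i]]
    pol <- thresholdPolicy(600, 600, 600, combine = "all",
                           minYear = if (is.null(aug$minYear)) NA
                                     else aug$minYear,
                           minDupPapers = if (is.null(aug$minDupPapers)) NA
                                          else aug$minDupPapers,
                           nondbMode = "union")
    sel <- selectedEvents(filterInteractions(study$events, study$kb, pol,
                                             years = study$rs$yearOf))$row
    expect_equal(tab$addedTrue[i + 1],
                 length(setdiff(intersect(sel, correct),
                                intersect(baseSel, correct))))
  }
  ## an augmentation that can add nothing reports zero
  none <- augmentedEval(study$events, study$kb, study$labels, base,
                        list(list(minYear = 2050)),
                        years = study$rs$yearOf)
  expect_equal(none$addedTrue[2], 0L)
  expect_equal(none$recall[2], none$recall[1])
})
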