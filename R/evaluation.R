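## Evaluation harness: precision/recall of the selection against human
## judgment, single-subscore threshold sweeps, the full three-subscore
## combination grid with marginal averaging, and augmentation tables that
## union the non-database criteria into a base policy.

#' Read a human-judgment label file
#'
#' @param path two-column tab-separated file (header \code{row},
#'   \code{label}; labels \code{correct}/\code{incorrect}).
#' @param n expected number of rows being evaluated.
#' @return logical vector of length \code{n}: is each row judged correct.
#' @export
readLabels <- function(path, n) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  idx <- as.integer(tab$row)
  if (anyNA(idx) || any(idx < 1) || any(idx > n) || anyDuplicated(idx))
    stop("label file rows must uniquely index 1..", n)
  out <- rep(NA, n)
  out[idx] <- tab$label == "correct"
  out
}

#' Precision and recall of a selection against judgment labels
#'
#' Precision is the fraction of selected rows judged correct; recall the
#' fraction of correct rows that were selected. An empty denominator is
#' reported as \code{NA} (explicitly absent), never coerced to 0 or 1.
#'
#' @param selected integer vector of selected row indices.
#' @param labels logical vector over all evaluated rows (\code{TRUE} =
#'   judged correct). A missing label for a selected row is an error.
#' @return list: \code{precision}, \code{recall}, \code{nSelected},
#'   \code{nCorrect}, \code{nOverlap}.
#' @export
precisionRecall <- function(selected, labels) {
  if (length(selected) && (any(selected < 1 | selected > length(labels))))
    stop("selected index out of range of the label vector")
  if (length(selected) && anyNA(labels[selected]))
    stop("label missing for selected row(s): ",
         paste(selected[is.na(labels[selected])], collapse = ", "))
  correct <- which(!is.na(labels) & labels)
  overlap <- length(intersect(selected, correct))
  list(precision = if (length(selected)) overlap / length(selected)
                   else NA_real_,
       recall = if (length(correct)) overlap / length(correct) else NA_real_,
       nSelected = length(selected), nCorrect = length(correct),
       nOverlap = overlap)
}

selectedIndices <- function(result) {
  ev <- result@events
  ev$row[ev$verdict == "selected"]
}

#' Sweep one subscore threshold
#'
#' Varies a single subscore threshold along a grid while the other two are
#' unconstrained, and reports precision/recall at every grid point.
#'
#' @param events event data.frame.
#' @param kb a \linkS4class{KnowledgeBase}.
#' @param labels logical judgment vector over the events.
#' @param score which subscore to sweep: \code{"escore"}, \code{"dscore"}
#'   or \code{"tscore"}.
#' @param grid threshold grid (default 0 to 1000 in steps of 200).
#' @param inclusive comparison operator bit (see
#'   \code{\link{thresholdPolicy}}).
#' @return data.frame: \code{score}, \code{threshold}, \code{precision},
#'   \code{recall}, \code{nSelected}, \code{nCorrect}, \code{nOverlap}.
#' @export
singleScoreSweep <- function(events, kb, labels,
                             score = c("escore", "dscore", "tscore"),
                             grid = seq(0, 1000, by = 200),
                             inclusive = TRUE) {
  score <- match.arg(score)
  prepared <- prepareSupport(events, kb)
  rows <- lapply(grid, function(t) {
    args <- list(escoreMin = NA, dscoreMin = NA, tscoreMin = NA,
                 combine = "any", inclusive = inclusive)
    args[[paste0(sub("score", "", score), "scoreMin")]] <- t
    pol <- do.call(thresholdPolicy, args)
    res <- finalizeFilter(prepared, pol)
    pr <- precisionRecall(selectedIndices(res), labels)
    data.frame(score = score, threshold = t, precision = pr$precision,
               recall = pr$recall, nSelected = pr$nSelected,
               nCorrect = pr$nCorrect, nOverlap = pr$nOverlap,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full three-subscore combination grid with marginal means
#'
#' Evaluates every combination of the three subscore thresholds over the
#' grid (5 values each, 125 combinations, all active comparisons must
#' pass), then averages: for each subscore held at each grid value, the
#' mean precision and recall over the 25 combinations of the other two.
#'
#' @inheritParams singleScoreSweep
#' @param grid per-subscore threshold grid (default 0 to 800 in steps of
#'   200).
#' @return list with \code{grid} (one row per combination:
#'   \code{escoreMin}, \code{dscoreMin}, \code{tscoreMin},
#'   \code{precision}, \code{recall}, \code{nSelected}) and
#'   \code{marginals} (\code{score}, \code{value}, \code{meanPrecision},
#'   \code{meanRecall}; means taken over the defined cells).
#' @export
combinationSweep <- function(events, kb, labels,
                             grid = seq(0, 800, by = 200),
                             inclusive = TRUE) {
  prepared <- prepareSupport(events, kb)
  cells <- expand.grid(escoreMin = grid, dscoreMin = grid, tscoreMin = grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    pol <- thresholdPolicy(escoreMin = cells$escoreMin[i],
                           dscoreMin = cells$dscoreMin[i],
                           tscoreMin = cells$tscoreMin[i],
                           combine = "all", inclusive = inclusive)
    r <- finalizeFilter(prepared, pol)
    pr <- precisionRecall(selectedIndices(r), labels)
    c(precision = pr$precision, recall = pr$recall, nSelected = pr$nSelected)
  })
  res <- do.call(rbind, res)
  gridTab <- cbind(cells, as.data.frame(res))
  marginals <- do.call(rbind, lapply(c("escoreMin", "dscoreMin", "tscoreMin"),
    function(col) {
      do.call(rbind, lapply(grid, function(v) {
        slice <- gridTab[gridTab[[col]] == v, , drop = FALSE]
        data.frame(score = sub("Min", "", col), value = v,
                   meanPrecision = mean(slice$precision, na.rm = TRUE),
                   meanRecall = mean(slice$recall, na.rm = TRUE),
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(gridTab) <- rownames(marginals) <- NULL
  list(grid = gridTab, marginals = marginals)
}

#' Evaluate non-database augmentations of a base policy
#'
#' For each augmentation (a publication-year criterion, a between-paper
#' duplicate criterion, or both), selection becomes the union of the base
#' database selection and the rows meeting the literature criteria; the
#' report gives precision, recall, and how many additional correct rows
#' the augmentation contributed over the base policy.
#'
#' @inheritParams singleScoreSweep
#' @param basePolicy the database-threshold policy to augment.
#' @param augmentations list of lists with fields \code{minYear} and/or
#'   \code{minDupPapers}.
#' @param years optional reference-to-year map or side-table path.
#' @return data.frame: one row for the base policy then one per
#'   augmentation, with \code{label}, \code{precision}, \code{recall},
#'   \code{nSelected}, \code{addedTrue}.
#' @export
augmentedEval <- function(events, kb, labels, basePolicy,
                          augmentations, years = NULL) {
  prepared <- prepareSupport(events, kb)
  base <- finalizeFilter(prepared, basePolicy, years)
  baseSel <- selectedIndices(base)
  basePr <- precisionRecall(baseSel, labels)
  correct <- which(!is.na(labels) & labels)
  baseTrue <- intersect(baseSel, correct)
  rows <- list(data.frame(label = "base", precision = basePr$precision,
                          recall = basePr$recall,
                          nSelected = basePr$nSelected, addedTrue = 0L,
                          stringsAsFactors = FALSE))
  for (aug in augmentations) {
    pol <- thresholdPolicy(
      escoreMin = basePolicy@escoreMin, dscoreMin = basePolicy@dscoreMin,
      tscoreMin = basePolicy@tscoreMin, combine = basePolicy@combine,
      inclusive = basePolicy@inclusive,
      evidenceKinds = basePolicy@evidenceKinds,
      minYear = aug$minYear %||% NA,
      minDupPapers = aug$minDupPapers %||% NA,
      nondbMode = "union")
    res <- finalizeFilter(prepared, pol, years)
    sel <- selectedIndices(res)
    pr <- precisionRecall(sel, labels)
    lbl <- paste(c(if (!is.null(aug$minYear))
                     paste0("after-", aug$minYear),
                   if (!is.null(aug$minDupPapers))
                     paste0(aug$minDupPapers, "+dups")), collapse = "+")
    rows[[length(rows) + 1L]] <-
      data.frame(label = lbl, precision = pr$precision, recall = pr$recall,
                 nSelected = pr$nSelected,
                 addedTrue = length(setdiff(intersect(sel, correct),
                                            baseTrue)),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
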