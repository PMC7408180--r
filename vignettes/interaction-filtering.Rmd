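---
title: "Filtering machine-reading events against interaction databases"
author: "EventSieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering machine-reading events against interaction databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EventSieve)
```

## The problem and the procedure

Automated model assembly needs interactions, and machine reading supplies
them in bulk: a single literature query can yield hundreds to thousands of
extracted events, a substantial fraction of which are wrong — the reader
grounded an entity to the wrong identifier, or asserted a relation the
sentence does not support. Curated interaction databases are the natural
arbiter: if an extracted protein pair is known to STRING, BioGRID or
Reactome, confidence in the event rises; if it is unknown everywhere, the
event is either an error or genuinely novel.

EventSieve operationalizes this in four steps per event:

1. **Classify** by the two participant element types. Only three classes
   have a backing database — protein–protein (PPI), protein–chemical
   (PCI) and protein–biological-process (PBPI). Chemical–chemical,
   chemical–process, process–process and anything involving a protein
   family or unrecognized type are reported as `unsupported_type`:
   there is no shared identifier namespace to search.
2. **Resolve** identifiers. Events ground proteins to UniProt accessions,
   while the scored tables are keyed by STRING-style (Ensembl-protein
   shaped) identifiers and BioGRID uses official gene symbols; a
   three-way cross-map connects them. GO accessions and PubChem compound
   IDs pass through after syntactic validation (compound IDs are
   normalized: `CIDs`/`CIDm` prefixes, internal whitespace and leading
   zeros stripped). A row that cannot be resolved — or that resolves
   ambiguously — is routed to `unmapped` and never guessed at.
3. **Look up** all support: STRING subscores plus BioGRID/Reactome
   presence and citing papers for PPIs, STITCH subscores for PCIs, GO
   annotations with their curation kind for PBPIs. Every field found is
   reported whether or not the row is selected.
4. **Select** under a `ThresholdPolicy` (below). Direction, effect sign
   and the listed reference are deliberately never consulted: the backing
   databases are largely direction- and sign-agnostic, so a matching pair
   is selected even if the reader got the sign wrong.

The output partitions the input exactly into `selected`, `discarded`,
`unmapped` and `unsupported_type`, with per-row support, flags, verdict
and reason.

## The threshold model

Scored matches carry three independent confidence subscores on the
integer scale 0–1000: `escore` (experimental evidence of physical
binding), `dscore` (membership in curated pathway databases) and `tscore`
(abstract co-mention text mining). A policy holds:

| parameter | default | meaning |
|---|---|---|
| `escoreMin`, `dscoreMin`, `tscoreMin` | 0 | per-subscore thresholds, 0–1000; `NA` = no constraint |
| `combine` | `"any"` | at least one active comparison must pass, vs `"all"` |
| `inclusive` | `TRUE` | compare with `>=`; `FALSE` gives strict `>` |
| `evidenceKinds` | none | restrict PBPI support to experimental/electronic/other curation |
| `minYear` | `NA` | novelty boundary (strict: "after 2014" means 2015+) |
| `minDupPapers` | `NA` | least distinct papers reporting the interaction (>= 2) |
| `nondbMode` | `"off"` | `"flag_only"` attaches flags; `"union"` also selects on them |

The `inclusive` bit exists because both conventions are genuinely useful:
`escore >= 0` is the most permissive scored policy (any match passes),
while `escore > 0` guarantees at least one source of experimental data.
Raising any threshold shrinks the selection monotonically — this is a
tested invariant, as is `all ⊆ any` at equal thresholds.

Three semantic decisions deserve explanation:

* **Presence-only matches.** BioGRID and Reactome carry no scores; a pair
  found only there is a real match ("this interaction is known") but has
  nothing to compare against a positive threshold. Such rows pass only
  when every active threshold is zero-and-inclusive, and fail under any
  positive or strict threshold. A pair that is in STRING *and* a presence
  table is judged on its STRING scores, with the presence sources
  reported alongside.
* **Duplicate dump rows.** When the same pair appears twice in a scored
  dump, the maximum of each subscore is kept — conservative toward
  selection, and order-independent. Presence duplicates union their
  citing papers.
* **Union scope.** With `nondbMode = "union"`, the novelty and duplicate
  criteria rescue rows that are mapped, of a supported class, and failed
  the database thresholds. Unmapped rows stay unmapped (grounding is
  still broken) and unsupported types stay unsupported; the literature
  criteria measure support for an *interaction*, which requires knowing
  what the interaction is.

## Literature flags

Both non-database criteria work on a canonical interaction key: the
interaction class plus the unordered pair of canonical identifiers.
Direction and effect sign are ignored — two papers reporting opposite
signs for the same pair still count as two supporting papers, matching
the sign-agnostic databases the filter emulates. Repeats of an
interaction *within* one paper collapse to a single supporting paper;
they are flagged separately (`withinPaperDuplicate`) but never counted as
between-paper evidence. The novelty comparison is strict at the boundary
("published after 2014" selects 2015 onward) and a row with an unknown
year can never be flagged novel. Inactive criteria evaluate to `FALSE`
for every row rather than `NA`, so downstream logic needs no special
cases.

## Evaluation harness

`precisionRecall` uses the standard definitions over human judgment
labels: precision = selected-and-correct / selected, recall =
selected-and-correct / correct. An empty denominator is reported as `NA`
— explicitly absent — rather than coerced to 0 or 1, and the counts are
always reported alongside so the caller can tell the cases apart.
`singleScoreSweep` varies one subscore threshold over 0–1000 in steps of
200 with the other two unconstrained; `combinationSweep` evaluates all
125 combinations of the three thresholds over {0, 200, 400, 600, 800}
under `combine = "all"` (the point of combining is conjunction), then
averages: for each subscore held at each value, the mean over the 25
cells of the other two. Cells where precision is undefined (nothing
selected) are dropped from the mean rather than imputed.
`augmentedEval` reports, per augmentation, precision, recall and the
number of *correct* rows the union added over the base policy.

## The synthetic-data generator

No real database dumps ship with the package; `generateKbFixtures` and
`generateReadingSet` emit miniature files in the genuine dialects
(STRING/STITCH links-detailed, GAF 2.1, BioGRID tab, Reactome pairs, the
alias table) with fully known ground truth. The defaults describe the
study conditions the package is tested under: a reading set of 300
events — the scale at which manual filtration stops being practical —
of which half find database support, a tenth are grounding failures
(UniProt-shaped accessions absent from the cross-map, emulating the
classic "DSB is a double-stranded break, not a protein" error), 5%
involve excluded element types, and the rest are grounded but unknown to
any database. Between-paper duplicate groups are planted across 2, 4 and
6 distinct papers (beyond 6 is rare in practice), a few within-paper
repeats exercise the collapse rule, and publication years straddle the
2014 novelty boundary with 30% of references recent. Subscores are
zero-inflated (point mass 0.35 at zero, else uniform on 1–1000) because
most subscores in real scored databases are zero; a uniform option
exists. Judgment labels are correct-iff-supported with planted noise
(10% of supported rows judged incorrect, 15% of unsupported judged
correct) so imperfect precision is exercised; noise-free labels give the
full-recovery identity precision = recall = 1 at zero thresholds.

Identifiers are drawn from disjoint synthetic namespaces *shaped* like
real accessions so the namespace-inference logic is exercised, but the
generator makes no attempt to match real score marginals, network
topology, or the relative sizes of the public databases. Passing tests
therefore demonstrate the correctness of the mechanics — parsing,
resolution, lookup, thresholding, counting, evaluation — not the
real-world precision/recall of any particular threshold choice, which
depends on the reading engine and database releases in use.

A separate fixture, `generateGoldenStudy`, emulates validating filtered
output against a small published model: 14 "golden" interactions with
high text-mining scores planted in a 260-event reading set. Raising the
tscore threshold strictly enriches the selection for the golden subset —
the qualitative trend such a case study shows.

## Numerical and storage choices

* Unordered pairs are materialized as (min, max) under lexicographic
  order; all pair queries are order-insensitive by construction.
* Retrieval ranks papers by the number of qualifying interactions citing
  them, ties broken by paper identifier — the ranking metric is package
  plumbing (retrieval itself is the requirement), chosen deterministic.
* The knowledge base persists as a single sectioned plain-text file with
  the tables sorted canonically, so write–read–write is byte-stable and
  diffs are meaningful. Dump exporters share their formatting with the
  generator, making export-after-load a fixed point; channels not stored
  (neighborhood, fusion, …) are written as zero and the combined score is
  recomputed with the standard independent-evidence combination.
* Self-interactions are looked up like any pair (databases contain
  homodimers); empty inputs yield empty, valid outputs everywhere.
* Gene symbols compare case-insensitively (their case varies across
  sources); accessions compare exactly. GO matching requires the exact
  accession — no ontology propagation and no tolerance for obsolete or
  alternate IDs.
* The open-access restriction in paper retrieval is approximated by an
  optional caller-supplied allow-list, since open-access status is not in
  the dumps.

## Problem sizes

The test suite runs on studies of 120–300 events over knowledge bases of
60–230 records; the oracle-equivalence check covers 20 seeded studies,
and the grid check recomputes all 125 cells independently. These sizes
give exact, exhaustive cross-checks while keeping the default test run
fast; all scaling-sensitive code paths (keyed lookup vs linear scan) are
compared at these sizes, where both are tractable.

## Limitations

The filter validates *existence*, not mechanism: it never checks
direction, sign, or the effect string, so a selected interaction can
still be causally wrong. Protein families and complexes are excluded for
want of a shared namespace. Exact GO matching means an annotation to a
child term does not support an event grounded to the parent. And the
package deliberately contains no download clients: the knowledge base is
built from whatever dump files the user supplies, and its coverage is
theirs.
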