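# EventSieve

Machine-reading engines can extract thousands of biomolecular events from
the literature — far more than a curator can check, and with frequent
grounding and omission errors. Before such events are fed into automated
model assembly, they need to be filtered down to the ones that curated
interaction databases actually support. EventSieve implements that filter
for systems biologists working with tabular machine-reading output: it
builds a local, unified interaction knowledge base from public database
dumps and selects the extracted events that clear user-chosen confidence
thresholds.

## What it does

Each extracted event is a row with two grounded participants (UniProt
accession, GO term or PubChem compound ID), an effect, a source paper and
an evidence sentence. EventSieve classifies every event by its participant
types — protein–protein (PPI), protein–chemical (PCI),
protein–biological-process (PBPI), or an unsupported class — resolves the
identifiers through a STRING/UniProt/gene-symbol cross-map, and looks the
pair up in the knowledge base:

* **PPI** — STRING scored links plus BioGRID and Reactome presence
  records (with their citing papers),
* **PCI** — STITCH scored links,
* **PBPI** — GO annotations with their curation evidence kind.

Scored matches carry three confidence subscores on the 0–1000 scale: the
*escore* (physical-binding experiments), *dscore* (curated pathway
databases) and *tscore* (abstract co-mention text mining). A
`ThresholdPolicy` selects events by comparing each active subscore
threshold (`>=` or strict `>`, combined with *any* or *all*), e.g.
`escore > 0` guarantees every selected interaction has at least one source
of experimental evidence. Events whose identifiers cannot be resolved are
discarded as unmapped; every row is reported with all the support found.

Two literature-based criteria complement the database thresholds: a
*potentially novel* flag (published strictly after a threshold year) and a
*between-paper duplicate* flag (the same grounded interaction extracted
from at least *k* distinct papers; repeats within one paper never count).
These can be attached as flags or unioned into the selection.

Around the core filter the package provides citation-based expansion
(knowledge-base interactions co-cited by the papers that were read), paper
retrieval (candidate papers ranked by how many interactions involving
query proteins cite them), a precision/recall evaluation harness
(single-subscore sweeps over 0–1000, the 125-combination threshold grid
with marginal averaging, and augmentation tables), and a seeded generator
of miniature dump files in the real public dialects so everything is
testable offline.

## Worked example

A complete synthetic study — generate dump files and a 300-event reading
set, build the knowledge base, filter with an exclusive experimental-score
threshold, and score the selection against the bundled judgment labels:

```r
library(EventSieve)

spec  <- fixtureSpec(seed = 7)
kbFix <- generateKbFixtures(spec, "fx")
rs    <- generateReadingSet(spec, kbFix, "fx")

kb <- buildKnowledgeBase(string = kbFix$files$string,
                         stitch = kbFix$files$stitch,
                         gaf = kbFix$files$gaf,
                         biogrid = kbFix$files$biogrid,
                         reactome = kbFix$files$reactome,
                         aliases = kbFix$files$aliases)
kb
#> KnowledgeBase (species 9606)
#>   scored PPI pairs     : 120
#>   PPI presence records : 50 (biogrid 30, reactome 20)
#>   scored PCI pairs     : 40
#>   GO annotations       : 50
#>   ID-map triples       : 60

events <- readExtracted(rs$files$events, years = rs$files$years)
res <- filterInteractions(events, kb,
  thresholdPolicy(escoreMin = 0, dscoreMin = NA, tscoreMin = NA,
                  inclusive = FALSE))   # escore > 0
res
#> FilterResult: 300 events -> 114 selected (38.00%), 148 discarded,
#>   25 unmapped, 13 unsupported type

labels <- readLabels(rs$files$labels, nrow(events))
pr <- precisionRecall(selectedEvents(res)$row, labels)
sprintf("precision %.3f, recall %.3f", pr$precision, pr$recall)
#> "precision 0.895, recall 0.596"
```

38% of the reading set clears the `escore > 0` policy: every one of those
114 events is backed by experimental evidence in the knowledge base, 89.5%
of them were also judged correct by the (synthetic) human labels, and the
strict threshold pays for that precision with recall. Unmapped rows are
the planted grounding failures; unsupported-type rows involve protein
families and other classes no backing database covers.

The same operations are exposed as a command line:

```sh
eventsieve fixtures --seed 7 --out fx
eventsieve build --string fx/string_links.txt --stitch fx/stitch_links.txt \
  --gaf fx/annotations.gaf --biogrid fx/biogrid.tab --reactome fx/reactome.tab \
  --aliases fx/aliases.tsv --out kb.db
eventsieve filter --input fx/events.tsv --kb kb.db --escore 0 --exclusive \
  --out selected.tsv --report report.json
```

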