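---
title: "Linking free-text addresses to a structured gazetteer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking free-text addresses to a structured gazetteer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addrlink)
```

## The problem

Health and administrative registers record addresses as free text:
`"Flat 1, 5 Brunswick Rd"`, `"17 Wilson Street, Cowdenbeath KY4 9DQ"`, or a
locally understood name with no textual overlap with the official form.
Downstream geospatial work (identifying care-home residents, housing
transitions, resource allocation) needs each of these linked to the unique
property identifier of a structured gazetteer in which every property is one
row with 11 standardised fields (organisation, sub-building, building
number, thoroughfare, localities, post town, postcode).

This is a record-linkage problem with a twist: the free text is
*semi-structured*, so there is no prior knowledge of which characters
correspond to which gazetteer field, and inputs carry typos, abbreviations,
alternative flat formats, wrong postcodes, and omitted or redundant region
words. `addrlink` implements a probabilistic pipeline:

1. **Gazetteer augmentation** — alternative renderings of standard records
   (abbreviations, `ST`→`SAINT`, `FLAT 1, 5` ↔ `5/1`, number ranges,
   optional local-knowledge aliases) are added as variant rows that keep
   their canonical identifier.
2. **Input preprocessing** — character cleaning, then knowledge-based
   completion (a dependent locality implies its post town, learned from the
   gazetteer itself) and deletion (county words the gazetteer never uses).
3. **Fuzzy field-to-text alignment** — the core engine; see below.
4. **Tree blocking** — the gazetteer becomes a layered tree; a parsed
   postcode descends one layer (or post town + thoroughfare descend two) to
   a local subtree that can be scored exhaustively.
5. **Random-forest matching** — each candidate pair is summarised by 52
   alignment features; the forest's vote fraction is the match confidence
   `s`, thresholded at `t` (default 0.5).

## The alignment engine

To locate a gazetteer field inside free text we run Needleman–Wunsch global
alignment twice and keep the better result:

* **Token route.** Both strings are tokenised on non-word characters and the
  token sequences are aligned; two tokens count as equal when their
  Damerau–Levenshtein distance divided by the longer length is ≤ 0.2 (less
  than one error in five letters — typos mostly occur in words of five or
  more letters). This catches `BRUNSWIK` ≈ `BRUNSWICK` but refuses
  `ST` ≈ `STREET` (4/6).
* **String route.** The raw character sequences are aligned; afterwards each
  *field token span* is kept only if ≥ 80% of its characters aligned to
  identical input characters (the character-level equivalent of the 0.2
  threshold). This is what resolves concatenations: `GREENBANK` cannot
  token-match `GREEN BANK`, but character alignment recovers both spans.

Each alignment yields: the fraction of input characters aligned, the
fraction of field characters aligned, their harmonic mean `M`, the number of
insertions `I` opened inside the aligned region, and the character-frequency
cosine `F` between the field and the matched text. The summary score is

$$S = M - 0.01\,I + 0.1\,F$$

and the route with the higher `S` wins (ties go to the token route, which is
the more conservative of the two).

The Damerau–Levenshtein distance is implemented in its unrestricted
(Lowrance–Wagner) form rather than the common restricted recurrence: the
unrestricted form is a true metric (the restricted one violates the triangle
inequality), which the property suite exercises.

## Blocking by tree search

The gazetteer is converted to a tree whose layers are fields in a fixed
broad-to-specific order; each node partitions its parent's records by one
field's value, and each leaf is one record. Two trees are built: one rooted
at `POSTCODE` (one-step descent when a postcode parses out of the input) and
one rooted at `POST_TOWN` then `THOROUGHFARE` (two-step descent otherwise).
At each descent step every child's name is aligned against the input and the
best summary score wins.

Below the blocked node, scoring is breadth-first: each child name is aligned
against that branch's input, and the aligned character positions are
*redacted* (masked positionally, preserving coordinates) before recursing,
so a candidate's fields can never consume the same input characters twice.
Per-field alignments are assembled at the leaves.

**Blocking floor.** A fixed floor on `S` itself would be wrong: `S` contains
the input-side percentage, whose denominator is the whole (remaining) input,
so even a perfectly matched postcode child of a normal-length address scores
`S` ≈ 0.4. The floor is therefore applied to the best child's *matched name
fraction* (`pct_field` ≥ 0.5 by default): a child must have at least half of
its name matched to count as a block. Inputs with neither a usable postcode
nor a town/thoroughfare pair fail blocking and are reported unmatchable at
that stage — a known limitation of filter-style blocking.

**Fallback.** If the postcode route blocks but the best classifier score
stays below `t` and a town hint exists, the town/thoroughfare route is
retried and the better result kept. This recovers most wrong-postcode
inputs.

## The matching classifier

Each candidate pair becomes 52 features: 4 per field × 11 fields (input-side
percentage, field-side percentage, insertions, character cosine) plus 8
overall summaries (mean cosine over non-empty fields; digit and
single-character counts in the unaligned residue of the input and of the
record's fields; sums of the two percentages and of the harmonic means).
Counts are used where a flag would also have been defensible (counts subsume
flags); the mean cosine averages over non-empty fields only.

A random forest suits this feature set: many features are exactly zero
(records fill only some fields), the features are strongly collinear, and
probability output is wanted. No tree-ensemble package is available in the
target environment, so the package carries its own bagged-CART
implementation (gini splits, `mtry = ⌊√p⌋ = 7`, unlimited depth, 500 trees
by default, seeded and fully deterministic). The averaged leaf class
fraction is used directly as the confidence score, uncalibrated. Training
pairs: the annotated true match is the positive; negatives are the other
candidates of the same blocked postcode (capped at 20 per positive to bound
class imbalance on dense postcodes).

## Evaluation

`evaluate_matches()` reports raw accuracy `c/n` (correct top-1 over all
inputs), adjusted accuracy `c/p` (over the inputs a human annotator could
match; `NA` with an explicit marker when `p = 0`), top-k accuracy, the
breakdown of not-matchable inputs, and a threshold sweep cross-tabulating
top-1 correctness against acceptance (`s ≥ t`) with precision, recall and F1
per threshold — the data behind a lift curve (`autoplot()`).

## The synthetic world

The real gazetteer and register addresses are licensed and confidential, so
the package ships a generator that emulates their structure at toy scale:

* `make_toy_gazetteer()` builds towns (reserved fake `ZZ` outcodes, so no
  fixture can collide with a real address), dependent localities subsumed in
  towns, streets, postcodes shared by runs of ~4 neighbouring properties,
  25% flats and 12% organisation names by default.
* `corruption_profile()` holds independent per-operation rates. Defaults
  anchor to observed real-data shares where published counterparts exist —
  abbreviations 0.3, not-in-database 0.024, too-broad 0.006, wrong postcode
  0.01 — and to a plausible 0.1 where none does (typo, locality dropout,
  county insertion); flat-format flips follow the flat share (0.25).
* `make_benchmark()` samples records stratified by postcode (round-robin:
  every postcode represented before any repeats, mirroring proportional
  postcode sampling) and emits inputs plus truth annotations.

What the generator does **not** emulate: realistic name/frequency
distributions, correlated corruption (real typos cluster by writer),
free-text idiosyncrasies like room numbers or duplicated lines, and genuine
local-knowledge aliases. A green synthetic benchmark therefore establishes
that the machinery recovers the modelled variation taxonomy — not that the
headline real-data accuracies transfer to any particular register.

## Numerical and design choices

* NW scoring is the simplest deterministic scheme: match +1, mismatch −1,
  gap −1, linear gaps; traceback ties prefer the diagonal.
* DL normalisation divides by the longer token (symmetric).
* `I` counts gap openings strictly inside the matched region; flanking
  unaligned text is expected in free text and not penalised.
* `F` compares the field against the concatenation of its matched input
  spans — it measures the quality of what was matched, not the whole input.
* Input-side percentages use the not-yet-redacted input as denominator at
  the time each field is aligned, which keeps features comparable across
  fields after redaction. A consequence worth knowing: even a perfect match
  has per-field `M < 1` for all but the last-aligned field, so the sum of
  harmonic means is below the non-empty-field count.
* The 80% span rule is applied to *field* token spans (the natural reading;
  the input side has no reliable token boundaries after redaction).
* Augmented variants never get new identifiers; every match reports the
  canonical identifier, and a variant whose rendering collides with a
  different property is dropped and logged.
* The alias table stores its free text in `BUILDING_NAME` and inherits the
  canonical record's postcode and post town, so aliased inputs still block.
* Exact classifier-probability ties between candidates (possible when two
  records differ only in how fields share the same input characters, e.g. a
  flat number swapped with the building number) break by the candidates'
  total alignment score, then lexicographically by identifier;
  all randomness (generator, negative sampling, forest) is seeded, making
  every pipeline output byte-reproducible.
* The augmentation rule registry is a stand-in: the original system's full
  transformation list is not public, so the registry ships the four
  best-documented families (abbreviations, saint forms, flat formats,
  number ranges) and is user-extensible via `abbreviations` and custom
  rules.

## Limitations

Semantic similarity (e.g. `home` ≈ `house`) is out of scope, as are affine
gap penalties, local alignment, LSH/ANN blocking for inputs with no usable
postcode or town, optimal assignment of fields to input spans, and
one-to-many linkage of too-broad inputs. Acceptance-level end-to-end checks
run the 500-record world at a 120-input benchmark per seed with a 300-tree
forest to stay inside test-time budgets; the defaults (500 trees) are used
for real work.

## A worked miniature

```{r example, eval = FALSE}
gaz <- make_toy_gazetteer(500, seed = 11)
db <- build_linkage_db(gaz)

train <- make_benchmark(gaz, 260, corruption_profile(
  typo = 0.05, abbreviation = 0.3, flat_flip = 0.25, wrong_postcode = 0,
  locality_dropout = 0.1, county_insertion = 0.1, not_in_db = 0,
  too_broad = 0), seed = 21)
ts <- assemble_training(train$inputs, train$annotations, db,
                        negatives_cap = 10, seed = 31)
model <- train_matcher(ts, ntree = 300, seed = 41)

bench <- make_benchmark(gaz, 120, corruption_profile(), seed = 51)
preds <- match_addresses(bench$inputs, db, model)
ev <- evaluate_matches(preds, bench$annotations)
glance(ev)
autoplot(ev)
```
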