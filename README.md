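# addrlink

Probabilistic linkage of free-text addresses to a structured UK-style
address gazetteer.

Health and administrative registers record addresses as free text —
`"Flat 1, 5 Brunswick Rd"`, `"17 Wilson Street, Cowdenbeath KY4 9DQ"` — while
geospatial analysis needs each input linked to the unique property
identifier of a standardised gazetteer (one row per property, 11 address
fields). The text is semi-structured and noisy: typos, abbreviations,
alternative flat formats, wrong postcodes, missing or redundant region
words. `addrlink` is for data engineers and researchers who need this
linkage with a tunable confidence score instead of hard rules.

## Method

For an input string *s* and a gazetteer record *d*, every field of *d* is
located inside *s* by Needleman–Wunsch global alignment run two ways — over
tokens (two tokens equal when their Damerau–Levenshtein distance, divided
by the longer length, is ≤ 0.2) and over raw characters (each field token
span kept only if ≥ 80% of its characters align) — keeping whichever has
the higher summary score

> S = M − 0.01·I + 0.1·F,

where M is the harmonic mean of the fractions aligned on the input and
field sides, I the insertions opened inside the aligned region, and F the
character-frequency cosine of field vs matched text. Search is blocked by
descending a layered tree of the (augmented) gazetteer — one step on a
parsed postcode, or two steps on post town + thoroughfare — then every
record in the blocked subtree is scored breadth-first with positional
redaction, summarised as 52 alignment features, and classified by a seeded
random forest whose vote fraction is the match probability `s`; a match is
accepted when `s ≥ t` (default `t = 0.5`). Evaluation reports raw accuracy
c/n, adjusted accuracy c/p (over humanly matchable inputs), top-k accuracy
and a precision/recall/F1 threshold sweep.

## Worked example

Everything below is synthetic (reserved `ZZ` postcodes; no real addresses):

```r
library(addrlink)

gaz <- make_toy_gazetteer(300, seed = 42)     # 300 properties, 2 towns
db  <- build_linkage_db(gaz)                  # augment + blocking trees
db
#> <linkage_db>
#>  records:   300 (+480 augmented variants)
#>  postcodes: 88
#>  towns:     2

train <- make_benchmark(gaz, 150, corruption_profile(
  typo = 0.05, abbreviation = 0.3, flat_flip = 0.25, wrong_postcode = 0,
  locality_dropout = 0.1, county_insertion = 0.1, not_in_db = 0,
  too_broad = 0), seed = 1)
ts    <- assemble_training(train$inputs, train$annotations, db,
                           negatives_cap = 10, seed = 2)
model <- train_matcher(ts, ntree = 300, seed = 3)
model
#> <match_model> 300 trees, mtry 7, trained on 529 pairs (150 match); OOB accuracy 0.991

bench <- make_benchmark(gaz, 100, corruption_profile(), seed = 4)
preds <- match_addresses(bench$inputs, db, model)
head(preds, 2)
#>   input_id  rank uprn      score accepted route    failure_reason
#> 1        1     1 U000165 0.997    TRUE     postcode <NA>
#> 2        1     2 U000166 0.00350  FALSE    postcode <NA>

evaluate_matches(preds, bench$annotations)
#> <linkage_eval> n = 100, matchable p = 94, correct c = 94
#>   raw accuracy      0.940
#>   adjusted accuracy 1.000
#>   top-5 adjusted    1.000
#>   at t = 0.50: precision 0.989, recall 1.000, F1 0.995
```

Reading this: the default corruption profile injects ~2.4% not-in-database
and ~0.6% too-broad inputs, so 94 of the 100 inputs are humanly matchable;
all 94 are recovered at rank 1 (adjusted accuracy 1.000), which caps raw
accuracy at 0.940. The precision below 1 at `t = 0.5` comes from a
not-in-database injection confidently matched to its nearest real
neighbour — exactly the failure mode the threshold sweep exposes. The
rank-1 score (0.997) towers over the same-postcode runner-up (0.0035) —
that margin is what the threshold `t` trades on, and
`autoplot(evaluate_matches(...))` draws the precision/recall/F1 lift curve.
`tidy(model)` shows the forest leaning on the mean character cosine,
building-number and residual-digit features, as expected when competitors
share street and postcode.

A thin CLI wraps the same functions
(`exec/addrlink synth|build-db|train|match|evaluate|align`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance quantities from
scratch — it generates a synthetic gazetteer, runs the full
clean/complete/block/align path on a rendered address, builds the feature
vector for a candidate pair, and writes the measured values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
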