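---
title: "Developing boolean search strategies with hedgedev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing boolean search strategies with hedgedev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedgedev)
```

## The procedure and its assumptions

A search strategy for a bibliographic database is an ordered list of
boolean queries whose union (possibly minus an exclusion clause) defines
the retrieved set.  `hedgedev` models strategy development as an
optimization over a *candidate pool*: a set of queries, each already
evaluated to the records it retrieves from a labelled corpus, with a
*dual gold standard* — the full set of relevant records across source
databases and the internal subset indexed in the target database.  The
dual denominator matters because a strategy cannot retrieve what the
database lacks: overall sensitivity (full-set denominator) is capped at
the internal/full ratio, while within-database sensitivity isolates the
strategy's own performance from database coverage.

Assumptions inherited from this design:

* relevance is a fixed binary label per record (screening disagreements
  and label noise are upstream concerns);
* retrieval is boolean — a record is in or out; there is no ranking;
* the corpus is a faithful snapshot of the target database's searchable
  fields; candidate queries were conceived elsewhere (controlled
  vocabulary plus text analysis of relevant records) — term *discovery*
  is out of scope, the pool is an input.

## Query language semantics

The engine reproduces the Ovid dialect used in published strategies.
Choices that were genuinely open and how they were fixed:

* **Tokenization.** Lowercase; hyphens, slashes and all punctuation are
  token boundaries, so `off-label` ≡ `off label`.  This is required for
  truncated phrases such as `off label*` to behave as published
  strategies report.
* **Wildcards.** `*` (and `$`) match any trailing characters, `?`
  matches *zero or one* character (so `li?en?e` covers
  licence/license/licene), `#` exactly one.  Patterns consisting only of
  wildcards are rejected.
* **Proximity.** `x adjN y` requires the two operand windows in the same
  field instance with at most N−1 intervening tokens, in either order.
  Chained proximity (`drug adj2 label adj2 us*`) parses
  left-associatively and each matched window anchors the next test at
  its span, which may differ from the (undocumented) vendor semantics
  for chained groups; the choice is recorded here rather than asserted
  as vendor-identical.  Proximity and phrases never cross field
  instances — each subject heading is its own instance.
* **Field codes.** `.ti.`/`.ab.`/`.ab,ti.` are the obvious scopes;
  `.mp.` = title + abstract + subject headings; `.af.` additionally
  searches publication type and accession numbers.  The live OvidSP
  `.af.` covers fields this data model does not store (e.g. manufacturer
  names) — a documented divergence, and the package's `.mp.` ⊂ `.af.`
  holds by construction.  `.sh.` matches a whole subject heading exactly
  (case-insensitively); thesaurus explosion requires a vocabulary tree
  and is out of scope — narrower headings are listed explicitly when
  needed.
* **Precedence.** `adjN` binds tighter than `not`/`and`, which bind
  tighter than `or`; unscoped terms default to `.mp.` (the interface
  default).  A trailing field code binds to the preceding parenthesized
  group or the whole preceding phrase.
* **Serialization.** `parse_query(serialize_query(x))` is structurally
  `x` for every tree; parenthesization is normalized, not preserved.

## Metrics and presentation

Sensitivity, precision and NNR are kept at full floating precision
internally; presentation rounds *half away from zero* (1 decimal for
single-query tables, 2 for cumulative strategy tables) because that is
how published performance tables are rendered — banker's rounding would
reproduce some cells wrongly (88.05 must print 88.1).  An empty
retrieval has *undefined* precision (`NA`), deliberately distinct from a
precision of zero.

## Optimizers

* **Sensitivity-maximizing** (`maximize_sensitivity`): greedy set-cover —
  repeatedly add the query with the largest marginal gain in relevant
  records, stopping at zero marginal gain.  Because the objective is
  pure union coverage without a budget, greedy-to-exhaustion attains the
  exhaustive optimum; the exhaustive mode (all subsets, capped at
  `K = 12` queries) exists to verify exactly that on small pools.
  Enumerating all combinations of a 77-query pool (2^77 subsets) is not
  attempted.  Ties break by higher single-query precision, then label
  order — the tie-break is total, so runs are reproducible without
  seeds.  The stopping rule uses no minimum-gain threshold: published
  cumulative tables admit gains of a single record.
* **Frontier** (`enumerate_frontier`): exhaustive subset enumeration up
  to the cap, otherwise a deterministic beam search over add-one
  expansions that keeps the best expansions by sensitivity *and* by
  precision so both ends of the trade-off stay explored; all visited
  points are Pareto-filtered.
* **Best trade-off** (`best_tradeoff`): the selection rule behind a
  published "best trade-off" scatter is typically unstated, so the
  criterion is pluggable: minimal Euclidean distance to the ideal point
  (100, 100) is the default (treating a sensitivity point and a
  precision point as exchangeable), with max-F1 and the knee
  (max perpendicular distance to the endpoint chord) as alternatives.
  Ties go to the higher-sensitivity point.
* **NOT refinement** (`not_refinement`): candidate exclusion terms are
  accepted when frequent among the irrelevant retrieved records
  (default ≥ 2%) and rare among the relevant ones (default ≤ 0.2%).
  The defaults are deliberately asymmetric by an order of magnitude: the
  clause exists to buy precision at near-zero sensitivity cost.  The
  accepted terms are appended as one line,
  `(or/1-K) not (t1 or t2 ...).af.`, and the precision gain and
  sensitivity cost are reported.  A NOT clause can only shrink the
  retrieved set, so sensitivity never increases — the tests assert this
  on fuzzed strategies.

## Statistical tests

Paired retrieval comparisons use McNemar's test on the discordant counts.
The exact variant doubles the smaller binomial tail and caps at 1 (the
common convention; at p = 1/2 the doubling rule and the
likelihood-ordering rule coincide by symmetry).  The chi-square variant
is the uncorrected `(b − c)²/(b + c)` — uncorrected because that is the
arithmetic behind published statistics of this kind.  The `auto` mode
switches to exact below `b + c = 25`.  Near `b = c` the doubled-tail
exact p exceeds the uncorrected chi-square p by up to ~0.08 (a property
of the conventions, not an implementation artifact); it tracks the
continuity-corrected approximation to within 0.001 for `b + c ≥ 100`.
Independent strata are compared with Fisher's exact test (two-sided by
summing hypergeometric probabilities ≤ the observed table's — the
standard convention, delegated to `stats::fisher.test`).

## The synthetic generator

`generate_corpus()` emulates the statistical structure the analysis
assumes, not natural language: filler text is token soup from a fixed
neutral vocabulary that is *verified at build time* not to match any
planted pattern, so every engine hit is a planted hit.  Defaults encode
the study conditions of a two-database off-label gold standard: 60%
prevalence of relevant records (4067/6785), 94.6% of them in-database
(3846/4067), and a year distribution putting 90.5% of records in
2001–2011 against 9.5% in 1988–2000.  Each query spec plants an
instantiation of its pattern (wildcards resolved) into the targeted
field of relevant in-database documents at the target within-database
sensitivity and into irrelevant documents at the rate implied by the
target precision; infeasible precision targets are rejected before
generation.

Two planting modes: `"exact"` hits the target counts exactly
(hypergeometric assignment of which documents carry the match), making
optimizer and table tests deterministic; `"bernoulli"` plants
independently per document for statistical property tests
(target-recovery within binomial confidence bounds).  Duplicate and
triplicate records are cloned with perturbed accessions and titles so
deduplication is testable; clones of planted documents also match their
query and the manifest accounts for them.

Two deliberate restrictions: (i) query specs must be plantable shapes
(terms, phrases, `adjN` chains, one field code) — boolean combinations
are exercised through the engine, not planted; (ii) specs must not
interfere (one query's pattern may not match another's planted tokens),
checked conservatively at token level before generation.  Overlapping
query families — the realistic situation where `off label` and
`off label*` retrieve nested sets — are modelled with
`generate_retrieval_matrix()` instead, which draws per-(query, document)
memberships directly.  Consequently, passing generator-based tests shows
the engine/metrics/optimizer machinery is correct on corpora with known
truth; it does not show robustness to real bibliographic text
(morphology, indexing inconsistency, reporting quality), which no
synthetic corpus of this kind can establish.

## Problem sizes and numerical choices

The test suite and the acceptance script run the engine-vs-oracle
equivalence on corpora of up to 200 documents, optimizer agreement on
pools of up to 12 queries over 100 documents across dozens of seeded
replicates, and generator target recovery at n = 4000 documents — sizes
chosen so that the brute-force oracles (per-document sliding-window
matching, full subset enumeration) remain exact references.  All
randomness flows through explicit integer seeds; generation is
byte-identical under a repeated seed.  Degenerate inputs are defined
rather than left to chance: empty retrievals have `NA` precision,
`b + c = 0` McNemar tables return p = 1 flagged degenerate, empty
corpora retrieve nothing, and dedup refuses to merge contradictory
relevance labels.

## Known limitations

* No thesaurus explosion, stemming, spelling correction or ranking —
  boolean retrieval only.
* The local `.af.` scope is narrower than the vendor's (fields not in
  the data model), and chained-adj span semantics are a documented
  choice rather than a vendor-verified one.
* Deduplication keys (shared accession; normalized title + year) are
  configurable policy, because vendors do not publish their clustering
  keys; a first-author key is not available in this data model.
* The beam search above the exhaustive cap explores a deterministic
  subset of combinations; its frontier is a lower bound on the true
  Pareto set (exact up to the cap, verified against enumeration).
* NNR and precision are undefined (not zero) for empty retrievals;
  downstream code must handle `NA`.
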