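# hedgedev

Development and validation of boolean search strategies ("hedges", also
called search filters) for bibliographic databases such as OvidSP EMBASE
and MEDLINE.

## The problem

Systematic reviewers and information specialists need search strategies
that find as close to *all* relevant records on a topic as possible
(sensitivity) without drowning the screener in irrelevant ones
(precision).  Developing such a strategy against a database like EMBASE
means: screening a reference set of records into relevant/irrelevant (the
**gold standard**), running many candidate queries, measuring each one,
and combining the best of them with boolean operators — then, often,
NOT-ing out content that is frequent among the irrelevant retrievals.
A worked case throughout this package is the retrieval of reports on
*off-label drug use* (prescribing outside the approved dose, indication,
route or age group) in OvidSP EMBASE, where the best single query is
`off label*.af.` and combined strategies push overall sensitivity from
77.5% to 94%.

`hedgedev` makes every step of that workflow reproducible offline:

* an **Ovid-dialect query engine** — boolean `OR`/`AND`/`NOT`, proximity
  `adjN`, truncation `*`, wildcards `?`/`#`, quoted phrases, field codes
  (`.af.`, `.mp.`, `.ab.`, `.ti.`, `.ab,ti.`, `.sh.`), strategy line
  references (`or/1-22`) — evaluated against local labelled corpora;
* **retrieval diagnostics** against a dual gold standard;
* **optimizers** that assemble sensitivity-maximizing OR-chains, explore
  the sensitivity x precision Pareto frontier, and refine a strategy with
  NOT-exclusion terms;
* the **hypothesis tests** used to compare strategies (exact/chi-square
  McNemar for paired retrievals, Fisher's exact test for independent
  strata);
* a **synthetic corpus generator** that plants query matches at
  configured sensitivity/precision so the whole pipeline is testable
  without database access.

## The metrics

For a query or strategy retrieving `R` records of which `r` are relevant,
with `G` relevant records in the reference set:

```
sensitivity = 100 * r / G        (recall; "overall" uses the full
                                  cross-database gold standard as G,
                                  "within-database" the subset indexed
                                  in the target database)
precision   = 100 * r / R        (positive predictive value)
NNR         = 100 / precision    (records to read per relevant record)
```

Strategies are compared on paired retrievals of the same reference set
with McNemar's test (discordant counts `b`, `c`; exact variant doubles
the smaller binomial tail of `min(b, c)` in `b + c` trials at p = 1/2;
chi-square variant refers `(b − c)² / (b + c)` to χ²₁), and across
independent strata with Fisher's exact test.

## Worked example

Fit a sensitivity-maximizing strategy on a synthetic corpus with three
planted candidate queries:

```r
library(hedgedev)

gen <- generate_corpus(generator_config(
  n_docs = 1000, seed = 1,
  query_specs = list(
    list(query = "off label*.af.",            sensitivity = 0.82, precision = 0.88),
    list(query = "unlicense*.af.",            sensitivity = 0.30, precision = 0.55),
    list(query = "(unapprove* adj2 us*).ab.", sensitivity = 0.20, precision = 0.90))))

fit <- hedge_fit(gen$corpus,
                 c("off label*.af.", "unlicense*.af.",
                   "(unapprove* adj2 us*).ab."),
                 gold = gen$gold, objective = "sensitivity")
summary(fit)
```

```
Boolean search strategy fit (objective: sensitivity)
Candidate pool: 3 queries; strategy: 3 lines

Relevant retrieved: 503 of 692 retrieved
Overall sensitivity: 83.97%  Within-database sensitivity: 88.87%  Precision: 72.69%

Cumulative performance by strategy line:
                      label n_relevant_retrieved n_retrieved sensitivity_full
1            off label*.af.                  464         527            77.46
2            unlicense*.af.                  491         669            81.97
3 (unapprove* adj2 us*).ab.                  503         692            83.97
  sensitivity_internal precision
1                81.98     88.05
2                86.75     73.39
3                88.87     72.69
```

Reading the output: the dominant query alone finds 77.46% of all relevant
records (81.98% of those the database holds) at 88.05% precision; each
further OR-ed line adds relevant records (sensitivity rises to 83.97%) at
a precision cost (falls to 72.69%).  `predict(fit, new_corpus)` applies
the fitted strategy elsewhere; `objective = "balanced"` instead selects
the Pareto point closest to the ideal (100, 100), and
`not_terms = c("stent*", "veterinar*")` appends a NOT-exclusion line.

Comparing two searches that respectively miss 1880 and 222 relevant
records:

```r
mcnemar_retrieval(1880, 222, variant = "chi2")
#> McNemar chi-square test (1 df)
#>   statistic = 1307.78
#>   p-value = < 2.2e-16
```

The package also ships the reference off-label strategies for OvidSP
EMBASE — `reference_strategy("hsss")` (32 lines,
sensitivity-maximizing) and `reference_strategy("balanced")` (23 lines,
ending in `(or/1-22) not (stent* or veterinar*).af.`) — together with
their contingency counts (`reference_table()`), from which every
published percentage is recomputable.

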