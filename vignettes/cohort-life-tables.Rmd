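---
title: "Methods: cohort life tables with eligibility-gated bootstrap intervals"
author: "canlife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort life tables with eligibility-gated bootstrap intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canlife)
```

## The estimator

`canlife` builds *complete cohort life tables*: every age interval is one
year, except the final open interval "n and over". Given the lifespans of a
deceased-only cohort, each lifespan `t` falls in the half-open interval
`[x, x+1)` with `x = floor(t)`. Per interval the package tabulates

* `d_x` — deaths in the interval;
* `l_x = Σ_{i≥x} d_i` — dogs alive at exact age `x`;
* `q̂_x = d_x / l_x` — interval death probability;
* `â_x = Σ(t − x) / d_x` over the interval's deaths — the mean fraction of
  the last year of life lived (in the open row, the mean years lived past
  its start, which may exceed 1);
* `L_x = (l_x − d_x) + â_x d_x` — dog-years lived in the interval (open
  row: `â_n d_n`);
* `T_x = Σ_{i≥x} L_i` and `ê_x = T_x / l_x`.

Two identities follow algebraically and are asserted in the test suite to
machine precision: `ê_0` equals the cohort's mean age at death, and more
generally `ê_x` equals the mean residual lifespan of the animals that
survived to `x`. The open row has `l = d`, `q̂ = 1` and `ê = â`. These exact
identities are the package's primary correctness oracle: every table built
from individual lifespans is compared against a brute-force
`mean(t[t >= x] - x)`.

A decreasing `ê_x` with age is a *plausibility* criterion, not a law: the
tests assert it only on synthetic cohorts generated under increasing
hazards, where it must hold up to sampling noise.

### The eligibility rule

A stratum only supports a publishable table if every closed interval holds
at least `min_per_interval = 3` deaths and the open final interval at least
`min_last_interval = 11`. The per-interval floor makes `â_x` an average over
more than one animal; the last-interval floor stabilises the tail that every
`ê_x` integrates over. The start of the open interval is chosen as the
largest age whose tail death count still meets the last-interval minimum —
a well-defined rule that reproduces the published overall table's "20 and
over" row; other selection procedures (e.g. fixing n in advance) would be
defensible, and the rule is therefore configurable through
`eligibility_rule()`. Ineligible strata are returned *flagged* rather than
raised as errors, because the bootstrap needs to evaluate eligibility per
replicate without exceptions as control flow; the CLI refuses to publish
them. No interval merging is attempted to rescue an ineligible stratum.

A closed interval with zero deaths leaves `â_x` undefined; the builder
records it as `NA` and sets `L_x = l_x` (a full year lived by every
survivor). Published-quality tables never contain such rows — the
eligibility rule forbids them — but the builder must not crash on them.

## Cleaning and lifespans

Records are excluded with the first applicable reason in a fixed order:
death date outside the observation window (default 2016-01-01 to
2020-07-31), negative lifespan, missing birth or death date, missing sex.
The fixed order makes exclusion logs reproducible, and the log always
reconciles: exclusions plus inclusions equal the input count. Records with a
death date but no birth date are handled here, in cleaning, rather than at
screening time.

Lifespans are day counts divided by 365.25 — the standard leap-safe
epidemiological convention; the alternative (calendar-anniversary
arithmetic) differs by less than a day and complicates leap-day handling.
Dates are parsed strictly (ISO-8601 unless a dialect supplies an explicit
format); silent locale guessing is a classic source of corrupted lifespans,
so unparseable dates become *absent with a warning* and fall to the
missing-date exclusion.

## Screening grammar

The candidate-death screen applies one term list to the clinical-note field
and another to the treatment field (the shipped defaults are the term lists
in `inst/extdata/search_terms.yaml`). Text is case-folded and split on
punctuation/whitespace. The grammar decisions, where common clinical search
engines vary:

* bare terms match **whole tokens** ("euth" does not hit "euthanasia");
  a substring mode exists as an explicit switch (`bare_mode = "substring"`)
  because source systems differ and guessing a default silently changes the
  candidate set;
* `term*` matches token prefixes; `"put to sleep"` matches consecutive
  tokens; `["bury" and "home"]` requires all words anywhere in the field;
* `"home bury" ~ k` is **unordered**: all phrase words within a window
  allowing up to `k` intervening tokens, in either order. Ordered proximity
  is the other defensible reading; unordered matches burial notes written
  both ways and errs towards recall, which suits a screen that is followed
  by manual confirmation.

The matcher is validated by exhaustive equivalence against a naive
token-window scanner on randomly generated notes. Screening only *flags*
candidates; confirming deaths is a human review step outside the package's
scope, and `screening_precision()` summarises that review's outcome.

## Bootstrap intervals

Confidence intervals for `ê_x` come from an empirical bootstrap: resample
`n` animals with replacement, rebuild the table, and keep the replicate only
if it meets the eligibility rule. Because the life table depends on the data
only through the multiset of lifespans, resampling is implemented as one
multinomial draw over the distinct lifespan values per replicate —
distributionally identical to resampling individuals, and it lets a whole
batch of replicates be reduced with a handful of matrix operations
(`ê_x = (A_x + M_x − x·l_x)/l_x` with `A`, `M`, `l` reverse cumulative sums
of per-interval statistics).

Decisions where the method is underdetermined:

* **Interval type.** Percentile intervals (type-7 interpolated quantiles at
  `(1−level)/2` and `1−(1−level)/2`) are the default; the basic/pivotal
  interval is available via `method = "basic"`. The percentile method
  matches the near-symmetric intervals life-expectancy estimates produce at
  these cohort sizes.
* **Rejected replicates are not replaced** by default, so accepted ≤
  requested iterations; `topup = TRUE` redraws until the requested count
  (capped at 10× attempts). Both are defensible; the count of accepted
  iterations is always reported.
* **Short replicates.** A replicate's table may end at an earlier open
  interval than the point estimate's. Ages present in fewer than 50% of
  accepted replicates get no bounds (with a log note): a quantile over a
  support that keeps shrinking answers a different question at each age.
  The 50% cut-off is a recorded package decision, not an external standard.
* A percentile interval can, in pathological cases, exclude the point
  estimate; this is logged, never "corrected".

A fixed seed makes the whole procedure bit-reproducible. Zero accepted
replicates is an estimation error that reports the rejection rate.

## The synthetic registry

The generator exists so that every stage — screening included — can be
exercised and validated without clinical data. It draws, per animal: a
breed stratum, sex and neuter status, a birth date from a birth-year
process, a lifespan from the stratum's hazard schedule, and emits the
record *only if* the death date falls inside the observation window,
mirroring a deceased-only case definition (no alive-at-end censoring
records exist in such a registry). Clinical notes carry death phrases drawn
from the screening term families (with a configurable fraction of neutral
notes), and missing sex/date fractions are configurable.

Hazard forms: `constant` (exponential, closed-form everything — the main
analytic oracle), `gompertz_makeham` (hazard `λ + a·e^{bt}`, sampled by
inverting the cumulative hazard with a vectorised Newton iteration started
from an upper bound, so convergence is monotone; remaining life expectancy
by adaptive quadrature with tolerance 1e-8, cross-checked against fine-grid
trapezoid integration to 1e-6), and `piecewise_interval` (per-year death
probabilities with uniform within-interval deaths; the last probability
must be 1). The demonstration parameters λ = 0.01, a = 5e-4, b = 0.55 give
`ê_0` ≈ 11 years and a death-probability profile that rises with age after
a flat early stretch — shaped like real companion-dog tables, but stated as
a demo configuration, not a fit to any population.

A birth process with exponential growth rate `g > 0` emulates *popularity
bias*: in a deceased-only cohort drawn from a rapidly growing population,
young animals contribute disproportionately many deaths, biasing `ê_0`
downward. The tests check the direction of this effect, not a magnitude.

What the generator does **not** emulate: breed-specific calibrated
mortality, seasonality, clustering by clinic, informative missingness,
misrecorded (rather than missing) dates, and the under-capture of early
puppy deaths that precede first registration. Passing tests therefore show
the *estimator pipeline* is correct under its stated assumptions, not that
any particular real registry satisfies them.

## Validation scale

The test suite validates at sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances: exact-identity checks on random cohorts up
to n = 500; parameter recovery against the analytic Gompertz–Makeham
expectancy at n = 100,000 (within 3 Monte-Carlo standard errors at ages 0,
5, 10); interval-coverage estimation over 200 simulated cohorts of
n = 2,000 with 600 bootstrap iterations each (binomial tolerance around the
nominal 95%); and a 1/√n check on interval width across n = 500–8,000.
The published-table reproduction uses the packaged aggregate fixture with
10,000 bootstrap iterations on its 30,563-animal pseudo-cohort.

## A full synthetic run

```{r pipeline, eval = FALSE}
cfg <- registry_config(n = 20000, missing_sex = 0.002)
registry <- simulate_registry(cfg, seed = 1)

terms <- default_search_terms()
matcher <- compile_terms(terms$note_terms, terms$treatment_terms)
candidates <- screen_records(registry, matcher)

cleaned <- apply_inclusion_filters(registry)
cohort <- add_breed_strata(cleaned$cohort)
demography_summary(cohort)

strata <- stratify(cohort, c("overall", "sex"))
tables <- lapply(names(strata$sex), function(lab) {
  bootstrap_life_table(strata$sex[[lab]], iterations = 2000, seed = 2,
                       stratum = c(scheme = "sex", label = lab))$table
})
names(tables) <- names(strata$sex)
compare_strata(tables, ages = c(0L, 5L, 10L))
```

## Known limitations

* Internal precision for `â_x` is full double precision; only the report
  rendering rounds (3 decimals for probabilities, 2 for years). Rebuilding
  a table from *printed* 2-decimal `â` values therefore carries a small,
  bounded rounding error (< 0.005 years in `ê`), which is why rebuilt and
  originally published dog-year columns can differ in the second decimal
  while every `ê` agrees at print precision.
* Neuter status is a single dichotomy at death; age at neutering is not
  modelled.
* No abridged (multi-year) intervals other than the final open row, no
  analytic (Chiang-style) variances, and no BCa or studentised bootstrap.
* The breed classifier ships as a compact configuration file covering the
  breeds used in the examples; real deployments should supply a full
  taxonomy file in the same format.
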