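---
title: "Severity scoring and standardized W statistics for ED cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity scoring and standardized W statistics for ED cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edies)
```

## The problem

In-hospital and short-term mortality are the standard outcome indicators for
emergency-department (ED) care, but crude mortality confounds performance
with case mix: an ED receiving sicker patients has higher mortality whatever
the quality of its care. Trauma care solved this decades ago with
TRISS-based W statistics — excess survivors per 100 patients relative to a
severity model — and their case-mix-standardized variant Ws. This package
carries that methodology to the general ED population, using a severity
score computable from arrival data alone (no laboratory values), so that an
ED's severity-adjusted survival can be compared against a reference
population, and so that the statistical behavior of the Ws confidence
intervals can be verified by simulation.

## The score

The EDIES sums eight integer item scores: sex (male 1), cause of visit
(disease 2, other 0), AVPU consciousness (A 0, V 2, P 3, U 7), and binned
age, systolic blood pressure, heart rate, respiratory rate and pulse
oximetry, with inclusive upper bounds (`value <= bound`). Totals range 0–39.
`builtin_edies()` ships the published table; `score_record()` /
`score_cohort()` apply it.

The published respiratory-rate bins leave (33, 35] unmapped (`<= 33` scores
1; the next printed bin starts above 35). The package reads the final bin as
`> 33 -> 2`, treating the printed 35 as a typographical artifact, because
contiguous bins are the only interpretation under which every physiologic
value is scoreable. `builtin_edies(strict_rr = TRUE)` preserves the printed
gap and raises an error for values inside it, so the effect of the choice
is auditable. Values 34–35 occur in real cohorts, so the default is the
closed reading.

### Rebuilding a table from data

`fit_logistic()` + `integerize()` reproduce the published construction
procedure: arbitrary real-valued scores are assigned to ranges of each
variable (a required user input — the original arbitrary scores were never
published, only their products), mortality is regressed on those item scores
by maximum likelihood, and each bin's final score is
`round(2 * coefficient * arbitrary_score)`, rounding halves away from zero.
The away-from-zero convention is forced by the published pair
(coefficient 0.786, final score 2): `2 * 0.786 = 1.572` rounds to 2 either
way, but half-to-even would make the rule non-deterministic at exact halves,
and away-from-zero is the convention clinical point systems use. Negative
products floor at zero with a warning. Variable removal for
multicollinearity (diastolic pressure) or sign reversal (body temperature)
is an explicit user decision, not an automated search — no algorithm for it
was published, and silently automating variable selection would make tables
irreproducible.

The optimizer is a damped Newton iteration (step-halving on likelihood
decrease), converging when the largest score-equation residual drops below
1e-8, with a 100-iteration cap and a divergence check (|coefficient| > 30)
that turns complete separation into an informative error rather than a
silently saturated fit.

## The reference

`builtin_reference()` stores the published reference: predicted survival
probability per score (single scores 0–21 plus a grouped ">= 22" bucket) and
severity strata ({0}, ..., {16}, {17–18}, {>= 19}) with counts from the
1,836,577-record construction cohort. Two deliberate fidelity choices:

* The printed survival probability at score 14 (0.95177) breaks the
  otherwise monotone decline (0.69430 at 13, 0.59030 at 15) and is plausibly
  a misprint of 0.65177. It is stored **as printed** and flagged
  (`nonmonotone_warning`), never smoothed: the fixture's job is anchor
  fidelity, and any correction would be a guess.
* The Ps buckets and the Ws strata are independent groupings by design; a
  score of 20 is predicted by its own Ps bucket but standardized inside the
  ">= 19" stratum.

`derive_reference()` rebuilds both parts from any scored cohort (survivor
proportion per bucket, stratum fractions from counts). An empty bucket is
recorded as missing with a warning rather than interpolated; computation
that later needs it fails loudly. Interpolation would silently fabricate a
survival model exactly where the data are thinnest.

## The W and standardized W statistics

For stratum $j$: $W_j = 100 (O_j - E_j)/n_j$ with
$E_j = \sum_{i \in j} P_{s_i}$, and
$\mathrm{var}(W_j) = (100/n_j)^2 \sum_{i \in j} P_{s_i}(1-P_{s_i})$.
Then $W_s = \sum_j f_j W_j$ with reference fractions $f_j$,
$\mathrm{se} = (\sum_j f_j^2 \mathrm{var}(W_j))^{1/2}$, and a fixed
two-sided 95% interval $W_s \pm 1.96\,\mathrm{se}$ (no other levels are
exposed; the methodology is defined at 95%).

The variance uses the *predicted* probabilities (null-model binomial
variance). The cited Ws methodology admits minor variants here; this one was
selected because, applied to the full built-in reference, it reproduces the
published 2016 interval half-width (computed 0.0204 against the printed
0.021). `variance = "observed"` substitutes observed stratum proportions as
a sensitivity analysis.

Strata with no cohort records are dropped and the remaining reference
fractions renormalized, with a warning and a `renormalized` flag. The
alternative — treating an empty stratum as contributing 0 — would bias Ws
toward zero for small cohorts; renormalization keeps Ws a weighted mean of
estimated quantities. The published cohorts populate every stratum, so this
is a package design choice for small-cohort use.

## The coverage experiment

`coverage_experiment()` checks that the 95% intervals behave: compute the
population Ws once, draw many samples, and count how often each sample's
interval contains the population value. Samples are simple random draws or
stratified draws matching a *discretized gamma* severity target: the
gamma(shape, rate) density integrated over $[s, s+1)$ per score $s$
(integration, not point evaluation — exact for the implied continuous
severity model), renormalized over the population's scores, then converted
to per-stratum sample counts by largest-remainder apportionment (counts sum
exactly to the sample size). Shape 9 / rate 1 manufactures a severe case
mix (mean score 9); shape 3.4 / rate 1.1 a non-severe one. Within-stratum
sampling is without replacement by default — a sample of 30,000 from a
~2M-record population plausibly was — falling back to with-replacement with
a warning when a stratum's quota exceeds its size.

Seed policy: a master seed spawns one sub-seed per replicate, so replicates
are independent and each is individually reproducible; identical scenario +
seed reproduces the result bit-identically.

On a calibrated million-record synthetic population, 1000 replicates of
30,000 give coverage near 95% for all three scenarios (the acceptance suite
asserts [93, 97]). The gamma scenarios tend to sit slightly *above* 95%:
severity reweighting concentrates quotas in small high-score strata, where
without-replacement sampling has a non-trivial finite-population correction
the variance formula ignores — the intervals are mildly conservative there,
consistent with the above-nominal coverages reported for the original
severe/non-severe experiments.

## The synthetic generator

`generate_population()` stands in for the (unavailable) national registry.
It is a *stated world*, not a tuning knob: per-score counts are the
largest-remainder apportionment of the published reference score
distribution (so the empirical distribution matches exactly, not just in
expectation), and each record dies with probability $1 - P_s$ from the
published survival curve, independently.

Defaults fixed once:

* The grouped reference rows are expanded uniformly: {17–18} splits in
  half; {>= 19} splits over scores 19–22, one per remaining survival
  bucket. Scores 23–39 get zero default frequency (the construction
  cohort's scores topped out at 35, and no finer resolution than the
  grouped rows was published). This keeps every survival bucket populated
  while placing the tail mass where the reference puts it.
* With `emit_vitals = TRUE`, each record receives concrete field values
  that score back exactly to its assigned total: an item-score composition
  is drawn uniformly among all compositions summing to the target (counted
  by dynamic programming over the eight items; the suffix-count table also
  drives the uniform draw), a bin is drawn uniformly among bins carrying
  that item score, and a value uniformly inside the bin. Open-ended bins
  use physiologic caps: age 110, SBP 300, HR 250, RR 60, SpO2 100.
* Body temperature and diastolic pressure are uninformative fillers
  (normal around 36.6 °C / 80 mmHg): the final model excludes them, and the
  exclusion cascade deliberately never requires them.

What the generator does **not** emulate: joint correlation among vitals
(a real hypotensive patient is also tachycardic; here items are dependent
only through the score total), diagnosis mix, time-to-event structure, and
any per-score frequency detail above the published grouped rows. A green
test therefore establishes that the *statistical machinery* is correct for
populations with the published marginals — not that the score is clinically
valid, which requires registry data (the published discrimination, AUROC
0.883, is out of reach here and is deliberately not asserted).

`inject_exclusions()` appends records violating each exclusion rule —
age under 15, ED transfer, arrival in cardiac arrest, missing variable,
SBP above 300 mmHg, SpO2 above 100% — with an exact injection log, so the
cascade's bookkeeping is testable record-for-record. Exclusion reasons are
tallied under the first failing rule in a fixed precedence order
(under_15, transfer_out, arrival_arrest, missing_variable,
implausible_value); no order was published, and a fixed order is what makes
exclusion reports reproducible and additive. A record with an unrecorded
age is tallied as missing_variable: the under-15 gate cannot fire on an
unknown age. Both systolic and diastolic pressures are checked against the
300 mmHg plausibility ceiling (the published wording, "blood pressure above
300 mmHg", does not distinguish them).

## Numerical and interface choices

* Bin lookup is `findInterval` with inclusive upper bounds on real values;
  no pre-rounding of measurements.
* All apportionments (generator score counts, stratified quotas) use the
  largest-remainder method with deterministic tie-breaking, so counts sum
  exactly and runs are reproducible.
* Serialization is JSON throughout (`jsonlite`, `digits = NA` so no
  precision is lost); reports embed the package version and an MD5 checksum
  of any built-in table used.
* The AUROC is the tie-corrected Mann–Whitney estimator computed from
  ranks; with ~23 distinct score values ties dominate, and the rank form
  handles them exactly in O(n log n).

## Known limitations

* The built-in reference inherits any misprint in its source, by design
  (score 14's survival probability being the suspect case).
* The Ws interval is a fixed-fraction normal approximation; it is mildly
  conservative under strong severity reweighting (finite-population
  effects) and anti-conservative for very small cohorts where stratum
  counts are tiny.
* The generator's independence assumptions make it unsuitable for studying
  anything but score-marginal behavior — e.g. it cannot probe how vital
  -sign measurement error propagates into Ws.
* The arbitrary pre-regression bin scores of the original construction are
  unrecoverable; `score_builder` can rebuild a table from *your* bin
  scores, but cannot re-derive the published one from data.
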