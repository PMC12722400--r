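---
title: "Methods: disproportionality and DDI signal detection in spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and DDI signal detection in spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignals)
```

## The case/non-case model

Spontaneous-report databases have no exposure denominator, so absolute
risks are not identifiable; what can be measured is *disproportionality*:
whether an adverse-event preferred term (PT) occupies a larger share of
the target drug's reports than of everyone else's. `pvsignals` implements
the case/non-case design: after cleaning, every report in which the
target ingredient appears as primary or secondary suspect (and whose
indication for the target is not on the exclusion list) is a *case*;
every other report is a *non-case*. Counting is report-level — a PT
listed twice on one report counts once — so for each PT the four cells
are

|               | target PT | other PTs |
|---------------|-----------|-----------|
| cases         | a         | b         |
| non-cases     | c         | d         |

and the reporting odds ratio is `ROR = (a/c)/(b/d) = ad/(bc)`, with the
Woolf (log-normal) interval
`exp(ln ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`. The screen requires at
least `min_reports = 5` case reports (a false-positive guard standard in
this literature) and a CI lower bound strictly above 1. The
assumptions worth keeping in mind: reporting behaviour is taken as
exchangeable between cases and non-cases given the PT (no
channeling/notoriety correction), cells are large enough for the
log-normal approximation, and no multiple-testing adjustment is applied —
the run manifest records how many PTs were tested instead.

### Numerical choices

* **The normal multiplier.** `ror()` derives `z` from `ci_level` via the
  normal quantile by default, but accepts an explicit `z`. Published
  disproportionality tables use the conventional two-decimal multiplier
  (1.96 at 95%), and at extreme RORs the difference between 1.96 and
  `qnorm(0.975) = 1.959964` is visible in the second decimal of the
  bound, so reproduction of published tables should pass `z = 1.96`.
* **Zero cells.** No continuity correction is applied: a zero `a` yields
  a point estimate of 0, a zero `c` is non-estimable, and both are
  carried with `estimable = FALSE` rather than dropped. The ≥ 5-report
  floor makes corrections moot for anything that can become a signal.
* **Rounding.** Estimates are kept at full precision internally;
  table-precision rendering uses `round_half_up()` (half away from zero),
  matching how published tables round.
* **Boundary.** A CI lower bound of exactly 1 is *not* a signal; the rule
  is a strict inequality.

## Cleaning

Deduplication runs in a fixed order: same-CASEID versions first (most
recent FDA receipt date wins, ties broken by highest PRIMARYID), then
deleted-case removal, then field-match deduplication (reports identical
on sex, age, country, event date, and the sorted PT, ingredient and
indication sets; the highest PRIMARYID survives). Removing deleted cases
*before* the field-match pass prevents a deleted report's content from
surviving through a tie-break. Two further conventions: the event date
participates in the field-match key at its stored precision (a year-only
date matches only another year-only date), and missing values match each
other — the plain reading of "same values". Every removal decrements a
counter that ends up in the run manifest, and raw report count equals
survivors plus the three removal counters by construction.

## Stratified contrasts

For sex (women vs men) and age group (older adults ≥ 65 vs adults
18–64), stratum-specific RORs are computed within each stratum's own
case/non-case universe, and the relative ROR is their ratio with the
combined-variance interval
`exp(ln(ROR1/ROR2) ± z·sqrt(Σ eight reciprocal cells))`. A stratum is
declared higher-reporting only under the dual criterion: its own ROR
lower bound above 1 *and* the relative-ROR lower bound above 1. No
interaction p-value is computed — the dual criterion is the decision
rule, exactly as used in practice. The relative ROR is always formed from
unrounded stratum RORs; rounding the inputs first produces visible
discrepancies in the second decimal. The age analysis defaults to reports
whose age unit is explicitly years (`age_years_only = TRUE`), the
restriction used for subgroup analyses in this literature; a blank age
unit is otherwise treated as years (the database convention), while an
unrecognised unit code makes the age missing and is counted.

Missing-stratum reports are excluded from the stratified analysis only —
they remain in the main screen. Reports below the ≥ 5 floor in either
stratum are not evaluable for the contrast.

## Time-to-onset and seriousness

TTO is the difference in days between the earliest day-precision therapy
start for the target drug and the event date. Partial dates cannot yield
a defined difference, so month- and year-precision records count as
unavailable rather than being imputed; negative differences are data
errors and are excluded and counted, not clamped. Seriousness follows the
outcome-code table: a report is serious iff it carries at least one of
DE, LT, HO, DS, CA, RI, OT; reports without outcome rows are non-serious.
Group contrasts call the standard tests — `stats::wilcox.test()`
(Mann-Whitney, tie-corrected normal approximation under ties, exact for
small untied samples) and `stats::chisq.test()` (Pearson, uncorrected).

## Drug–drug-interaction scores

For a triple (target drug A, concomitant drug B, AE), eligibility
requires the AE to be a signal not overlapping the treated indication
(the default exclusions are anxiety, depression, panic attack, completed
suicide, suicidal ideation, suicide attempt), and B to appear as PS, SS
or interacting — never concomitant-only — in at least 3 case reports with
that AE.

The association rule `B → A ∩ AE` is scored by

* `confidence = n_AB1 / (n_AB+ + n_B+)` — the probability of the
  A-with-AE event among B-exposed reports of the chosen universe;
* `support = (n_AB1 + n_A1) / n_++` — its marginal probability;
* `lift = confidence / support`, `conviction = (1 − support)/(1 − confidence)`.

The universe for these counts defaults to the case reports, under which
`n_B+` (B without A) is structurally zero and confidence reduces to
P(AE | B among cases) — the only probabilistically coherent reading of
the printed denominators; `all_reports` is available as a config choice.
The risk-scale measures always use the four exposure cells over *all*
reports (a case-only universe has no A-unexposed cell): with cell risks
`p_ij`,

* `AI = p11 − p10 − p01 + p00` (> 0: super-additive),
* `MI = p11·p00/(p10·p01)` (> 1: super-multiplicative),
* `CRR = PRR_{A∩B} / max(PRR_A, PRR_B)` (> 2: combination signal), where
  each PRR contrasts one *exclusive* exposure cell (A-and-B, A-not-B,
  B-not-A) against all remaining reports. The exclusive-cell reading is
  forced by the boundary construction the scores must satisfy — two
  drugs that each double the event rate with a quadrupling combination
  must land at CRR = 2 — and parallels the "risk ratio drug A not drug
  B" terms of MI.

Verdicts use the unrounded scores with strict inequalities (lift > 1 and
conviction > 1; the sensitivity threshold lift > 2 is reported
separately; AI > 0; MI > 1; CRR > 2). A conviction of a rule with
confidence 1 is `Inf` and flagged. Any non-estimable score fails the
conjunction but the triple stays in the output.

## The synthetic generator

`simulate_reports()` emulates the statistical structure the pipeline
assumes, with every planted effect recorded as ground truth:

* demographics with realistic margins for a psychiatric case series
  (62/38 female/male among non-missing with 9% missing sex; ages
  ~N(46, 16) truncated to 12–95 with 30% missing; 78% US reports; ~60%
  serious);
* drug exposures as independent Bernoulli draws with per-drug role
  distributions; the target carries its brand name on 30% of rows so
  dictionary normalisation is exercised;
* PT sets as independent per-PT Bernoulli draws whose odds are
  multiplied by planted single-drug signals (so the measured ROR
  approximates the odds multiplier at low baseline); a report drawing no
  catalog PT receives a neutral catch-all term kept out of the catalog so
  baselines stay calibrated;
* planted drug-pair interactions override the affected PT's probability
  cell-wise on the *risk* scale — multiplicative strength *m* sets
  `p11 = (p10·p01/p00)·m` so MI recovers *m* exactly in expectation;
  additive strength sets the analogous excess — because AI and MI are
  risk-scale quantities;
* sex effects are *effect modifiers* of the target-drug signal (the
  female odds multiplier applies to target-exposed reports): a marginal
  reporting effect common to cases and non-cases would cancel from the
  stratum-specific ROR and be undetectable by design;
* onset times are log-normal with seriousness-specific medians (60 days
  serious, 2 non-serious; sdlog 1.3), event dates sit in 2015–2024 with
  5%/2% month/year-precision and configurable missingness, and therapy
  starts are back-computed as event − TTO for the target drug;
* duplicates are injected as clones: same-caseid versions with a later
  FDA date (so the *clone* must survive caseid dedup) and field-match
  clones under a fresh caseid (so the clone, having the higher
  PRIMARYID, must survive the field-match pass); a fraction of caseids
  is listed as deleted.

What the generator does **not** emulate: real marginal PT/drug
frequencies, within-report PT correlation (off by default), reporting
waves, notoriety effects, or free-text noise in drug names beyond the
brand/ingredient split. Passing tests therefore certify the pipeline's
arithmetic and decision rules on structurally realistic data, not its
robustness to the full messiness of production extracts.

## Problem sizes used by the property tests

Chosen for statistical head-room at reasonable runtime, and fixed:
Woolf-CI coverage over 4,000 simulated 2×2 tables (expected cells ≥ 80);
null false-signal rates pooled over three 20,000-report bundles;
duplicate-recall and group-by oracles at 2,500 reports with 6%/4%
injection; lift/conviction independence as 60 draws of 50,000-report
count sets; MI recovery as the mean over 20 bundles of 50,000 reports
with exposures 0.15/0.15, baseline risk 0.025, single-drug risk ratios 2,
planted multiplicative strength 5; DDI verdict recovery over 100 bundles
of 5,000 reports under the same cell design; brute-force enumeration
cross-checks at ≤ 50 reports.

## Known limitations

Comparator analyses keep target-and-comparator co-exposed reports as
cases by default (`keep_coexposed = TRUE`); whether to drop them is a
genuine modelling choice left to the user. The field-match duplicate key
treats age at face value (45 years and 540 months do not match). The DDI
counts cannot reproduce published interaction tables whose exact count
definitions live in unpublished supplementary material; the package's
definitions are documented above and verified against brute-force
enumeration instead. Bayesian shrinkage measures and probabilistic
record linkage are out of scope.
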