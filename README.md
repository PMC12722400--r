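# pvsignals

Case/non-case disproportionality analysis and drug–drug-interaction (DDI)
signal detection for FAERS-style spontaneous adverse-event reports, with a
synthetic report generator so the whole pipeline is testable end to end
without downloading the database.

## Who this is for

Pharmacovigilance analysts and pharmacoepidemiologists screening a target
drug (the motivating use case is intranasal esketamine for
treatment-resistant depression) against the FDA Adverse Event Reporting
System: which adverse-event preferred terms (PTs) are reported
disproportionally often, whether reporting differs by sex or age, how
quickly events follow the start of therapy, and which concomitant drugs
look like interaction partners for specific events.

## What it computes

**Cleaning.** Quarterly `$`-delimited extracts (DEMO/DRUG/REAC/OUTC/THER/
INDI) are read, validated for referential integrity, deduplicated
(same-CASEID versions: most recent FDA receipt date wins, ties to highest
PRIMARYID; then field-match clones identical on sex, age, country, event
date and the sorted PT/drug/indication sets), and purged of deleted cases.
Brand names are mapped to active ingredients through a user-supplied
dictionary table.

**Disproportionality.** With `a` target-AE reports among the target-drug
cases, `b` the other case reports, `c`/`d` the same split among all other
reports:

    ROR = (a/c) / (b/d),   95% CI = exp( ln ROR ± z·√(1/a + 1/b + 1/c + 1/d) )

A PT is a signal when it has ≥ 5 case reports and the CI lower bound
exceeds 1. A comparator-restricted sensitivity analysis (e.g. venlafaxine)
re-runs the screen against an active-comparator population.

**Stratified contrasts.** Sex- and age-stratified RORs, with the relative
ROR (women/men, older adults/adults) and its combined-variance CI; a
stratum reports an AE more when both its own ROR lower bound and the
relative-ROR lower bound exceed 1.

**Time-to-onset and seriousness.** TTO in days from the earliest
day-precision target-drug therapy start to the event date; seriousness
from the OUTC codes (DE/LT/HO/DS/CA/RI/OT); Mann-Whitney and chi-squared
contrasts of age, weight, TTO and sex between serious and non-serious
cases.

**DDI scores.** For each eligible (AE, concomitant drug B) pair: the
association-rule lift and conviction of `B → A ∩ AE`, the additive
(`AI = p11 − p10 − p01 + p00 > 0`) and multiplicative
(`MI = p11·p00 / (p10·p01) > 1`) interaction scores on the exposure-cell
risks, and the combination risk ratio
(`CRR = PRR_{A∩B} / max(PRR_A, PRR_B) > 2`).

## Worked example

```r
library(pvsignals)

sim    <- simulate_reports(sim_config(n_reports = 20000, seed = 42))
bundle <- dedup_fieldmatch(remove_deleted(dedup_caseid(sim$bundle)))
cd     <- case_definition("esketamine")
flags  <- flag_cases(bundle, cd)
signals <- screen_signals(build_contingency_all(bundle, flags))
head(signals, 5)
```

```
                 pt   a     ror ci_low ci_high is_signal
1      Dissociation  81 175.565 90.700 339.839      TRUE
2          Sedation 104 110.202 68.606 177.019      TRUE
3     Euphoric mood  15  33.571 14.653  76.912      TRUE
4 Suicidal ideation  41  12.832  8.642  19.056      TRUE
5         Dry mouth  23   2.191  1.417   3.386      TRUE
```

The generator planted odds multipliers of 500/100/25/10 on the first four
terms for the target drug; at 948 cases out of 19,750 cleaned reports the
screen recovers them in order (rare-event RORs sit below the planted odds
ratios because the case population is finite), plus the occasional
borderline noise signal such as dry mouth. The DDI stage then scores every
signal AE against concomitant drugs co-reported in ≥ 3 cases:

```r
ddi_analysis(bundle, flags, signals, cd)[, c("ae", "drug_b", "n_both_ae",
                                             "lift", "conviction", "mi")]
```

At three co-reported cases the interaction scores are deliberately noisy —
the report floor matches screening practice, not a variance guarantee —
which is why the verdicts combine five criteria before flagging a pair.

Or in one call, writing `signals.tsv`, `signals_comparator.tsv`,
`stratified_sex.tsv`, `stratified_age.tsv`, `tto.tsv`, `seriousness.tsv`,
`ddi.tsv` and `run_manifest.json`:

```r
run_pipeline(run_config(bundle = sim$bundle, output_dir = "out", seed = 1))
```

## Limits

Only the modern (post-2014) quarterly ASCII dialect is supported; no
network access, no Bayesian shrinkage measures (IC/EBGM), and no
probabilistic record linkage beyond the two deterministic duplicate rules.
The synthetic generator aims for structural realism (multi-table linkage,
roles, partial dates, duplicates, planted effects of known strength), not
for the marginal distributions of any real database. See the methods
vignette (`vignettes/pharmacovigilance-methods.Rmd`) for model details and
design choices.
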