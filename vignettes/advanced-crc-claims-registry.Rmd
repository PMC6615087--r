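---
title: "Estimating the incidence of advanced colorectal cancer from claims and registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the incidence of advanced colorectal cancer from claims and registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(advcrc)
```

## The estimation problem

Population rates of *advanced* colorectal cancer (CRC) — disease with
regional lymph-node involvement (UICC stage III) or distant metastases
(UICC stage IV) — are a key monitoring quantity: metastatic disease drives
CRC mortality, and a decline in its incidence is the earliest measurable
dividend of endoscopic screening. Two data sources can supply such rates in
Germany, each with a characteristic blind spot:

* **population-based cancer registries** record TNM stage, but the N/M
  information is incomplete: a share of cases is notified by pathologists
  only (who never see staging work-ups), and a tumor may be reported "M0"
  before the metastasis work-up is finished;
* **statutory health-insurance claims** contain no stage field at all, but
  they do contain ICD-10-GM diagnosis codes for secondary malignant
  neoplasms — C77 (lymph nodes) and C78–C79 (other/distant sites) — whose
  timing relative to the first CRC code can be used to *reconstruct* stage
  at diagnosis.

This package implements both estimation routes, direct age standardization
of the resulting rates, the comparison analyses between the routes, and a
synthetic-data generator that produces claims and registry data with known
ground truth so that every rule of the pipeline is testable without the
access-restricted originals.

## The claims algorithm

German claims have two structural quirks the algorithm is built around:
outpatient diagnoses carry only a calendar quarter (plus a mandatory
certainty flag: *confirmed*, *suspected*, *status post*, *excluded*),
while inpatient discharge diagnoses are exact-dated and carry a position
(main/secondary/admission; admission diagnoses are never used).

For a target calendar year, `identifyIncidentCases()` applies four rules:

1. **Entry.** Cohort entry is the first qualifying CRC code (C18–C20) in
   the year; outpatient codes qualify only when *confirmed*, inpatient
   codes only in main or secondary position. An outpatient entry is dated
   to the first day of its quarter; if a qualifying inpatient code exists
   in the entry quarter, its exact date is used instead. Same-day ties are
   broken inpatient-main, then inpatient-secondary, then outpatient, then
   by code string.
2. **Confirmation.** At least one *additional* qualifying CRC code record
   must appear in the entry quarter or the following `confirm_quarters`
   (default 2) quarters, i.e. within roughly 6–9 months.
3. **Washout.** No CRC code — outpatient *confirmed* or *status post*, or
   inpatient main/secondary — may occur in the 4-year preobservation window
   before entry. The window is measured as `round(4 × 365.25)` days ending
   the day before entry; a quarter-granular outpatient code from an
   *earlier* quarter counts as inside the window if its quarter overlaps
   it. Outpatient codes in the entry quarter itself cannot be ordered
   against the entry date and therefore never wash out — a convention
   forced by quarter granularity.
4. **Continuity and age.** The person must be continuously insured — no
   uncovered stretch longer than 15 days, whether leading, internal or
   trailing — from 4 years before entry through December 31 of the year,
   and be at least 5 years old.

`stageCases()` then scans the entry quarter plus `n_following_quarters`
(default 1, i.e. codes within 3–6 months) for qualifying C77/C78–C79 codes
(inpatient main/secondary, or outpatient *confirmed* — suspected or
status-post metastasis codes never stage a case): any C78–C79 code makes
the case stage IV; otherwise any C77 makes it stage III; otherwise it is
non-advanced. The three labels partition the cases, and because windows
only grow, the stage-IV set at window 0 is contained in the set at window
1, which is contained in the set at window 2 — the basis of the
window-sensitivity analysis (`windowSensitivity()`).

Two auxiliary checks probe the credibility of the staging:
`inpatientEvidenceSummary()` reports how many stage-IV assignments rest on
an inpatient discharge diagnosis (high-validity codes), and
`medicationCrosscheck()` counts non-advanced-classified cases that
nevertheless received a drug essentially only given in advanced CRC
(bevacizumab-class agents), an upper bound on missed advanced cancers.

### Conventions the data force, and the choices made

* **Ages are attained ages**: the age used in year $y$ is $y -$ birth
  year, for cases and denominators alike. Claims carry only the birth
  year, so any finer convention is fictitious precision; using one
  convention on both sides guarantees that every case is counted in the
  age band of its own denominator stratum. The reference date for the
  denominator is December 31.
* **The case continuity window runs through December 31** of the entry
  year rather than stopping at entry. This is what keeps the numerator a
  subset of the denominator (which requires insurance through the
  reference date); for the 4-year preobservation period itself the two
  formulations coincide.
* **Confirmation counts records, not distinct code values** — a second
  visit coded C18.9 confirms an initial C18.9. The entry record itself
  does not self-confirm.
* **The medication cross-check percentage** uses the full CRC subsample as
  its default denominator; relating the flagged count to the non-advanced
  cases only is available via `denominator = "non_advanced"`. Both
  conventions are defensible; the default matches the one used in the
  benchmark analysis this package follows.
* **Sensitivity windows move only the staging scan**, never cohort entry
  or confirmation: the question they answer is how long after diagnosis
  metastasis codes keep arriving.

## The registry classification

`classifyTnm()` is a total function of the recorded N and M status (T is
irrelevant to the advanced/non-advanced distinction): M1 means stage IV;
N+ with M0 means stage III; N+ with M missing is advanced but
*unstratifiable* between III and IV; N0/M0 is non-advanced; every other
pattern (N missing without M1, N0 with M missing) is *not classifiable*.
"MX" and empty fields are both treated as missing before classification —
missingness is always explicit and never silently coerced to M0.

Because roughly a third of registry records lack the N/M information to be
classified, `applyScenario()` implements the bracketing assumptions used
in the scenario analyses: ignore the not-classifiable records; assume they
were all non-advanced; or — for the III/IV split — assume all
unstratifiable-advanced records were stage IV. The last is an extreme
assumption by construction: it moves every ambiguous advanced record in
the direction that maximally favors the registry stage-IV rate, while
leaving the advanced total invariant.

## Rates and standardization

All rates are per 100,000 and directly standardized to the old (1976)
European Standard Population on 18 five-year age bands (0–4 … 85+),
weights `espWeights()` summing to 100,000:

$$\mathrm{ASIR} = \frac{\sum_b w_b \, (c_b/n_b)}{\sum_b w_b} \times 10^5 .$$

Bands with neither cases nor person-time contribute zero; a band with
cases but no person-time is an error, not a silent `NaN`. Two identities
pin the implementation: uniform band rates are returned unchanged to
machine precision, and a study population with exactly the ESP age
structure makes the ASIR equal the crude rate. Claims-based rates use the
continuously insured persons of `eligiblePersons()` as denominators;
registry-based rates use the whole population
(`populationDenominators()`), mirroring the insured-versus-inhabitants
asymmetry of the real sources. Displayed rates are rounded to one decimal
(half away from zero), percent declines to integers; full precision is
kept internally.

## The synthetic generator

`simulateClaimsRegistry()` draws a population, at most one ground-truth
CRC per person, and then *codes* that truth the way the two real sources
would:

* **claims**: an initial C18–C20 code (inpatient main with probability
  `p_initial_inpatient`, else outpatient confirmed), a confirmatory code
  within two quarters with probability `p_confirmation_code`,
  stage-dependent C77/C78–C79 codes at quarter lags 0–2, advanced-therapy
  dispensations for true stage IV, recurring *status post* codes for
  prevalent cancers, insurance gaps, and noise (non-cancer codes,
  *suspected*/*excluded* CRC work-ups, admission-position codes);
* **registry**: a faithful (N, M) record — (N0, M0), (N+, M0) or
  (N+, M1) by true stage — distorted by pathologist-only notification
  (both statuses missing), premature M0 (a true IV recorded M0 with N kept)
  and independent N/M missingness, thinned by reporting completeness.

Defaults are chosen to be realistic for the German setting where no
published value exists: the age structure approximates the German pyramid;
the stage-specific incidence schedule uses the steep exponential age rise
typical of CRC, scaled so that the *true* age-standardized rates match the
2008 claims-based benchmark values (stage IV 15.2/10.4 per 100,000 in
men/women, stage III 6.4/4.0, non-advanced 38/23), with a −2.3%/year trend
on stage IV reproducing the observed 15–18% decline over eight years.
Coding sensitivities (e.g. 90% confirmation, 85% C77 emission for stage
III, 95% C78–C79 emission for stage IV of which 85% inpatient) are
illustrative — no published estimates for German claims exist — so the
rates the pipeline *measures* on default synthetic data sit some 30% below
the true schedule. That attrition is a feature: it reproduces the
qualitative situation in which an ascertainment algorithm under-counts an
unknown true incidence, while parameter-recovery tests use perfect-coding
configurations in which the measured and true rates must agree exactly.

What the generator deliberately does **not** emulate: survival and
post-diagnosis mortality (spells simply end; incidence, not prognosis, is
the estimand), multiple primaries per person, tumor progression dynamics,
geographic or insurer heterogeneity, and coding that varies by provider.
Tests passing on this generator therefore validate the *rules* of the
pipeline and the directional behavior of the reporting mechanisms — they
cannot certify coding sensitivities in any real claims database.

Everything is deterministic given `rng_seed` (mandatory, no default):
each generator stage derives its own sub-seed, so population, events,
claims and registry are individually reproducible.

## Numerical and testing choices

* Quarters are handled on a linear index (`4*year + quarter − 1`), so all
  windows work across year boundaries; days matter only for look-back,
  continuity and inpatient dates.
* Rounding of displayed values is half-away-from-zero (with a `1e-9`
  guard against binary-representation ties), not banker's rounding.
* The cross-check of the claims pipeline against an independent
  per-person, day-by-day rule interpreter runs on fifty randomized
  200-person populations with case-rich incidence (so each fixture
  actually exercises entry, confirmation, washout, gaps and staging), and
  demands exact equality of the staged case tables.
* Parameter recovery uses 100,000 persons and a flat advanced incidence
  of 20/100,000 with perfect coding; the claims ASIR must land within 3
  Poisson standard errors of the truth, and claims- and registry-based
  ASIRs must agree within 3 combined standard errors.
* The mechanism-direction experiment (premature M0 at 0.3,
  pathologist-only at 0.1) uses 100,000 adults and stage III/IV incidence
  of 60/150 per 100,000 — sized beforehand so that the expected stage-III
  surplus in the registry (≈ +17 cases per stratum-year) exceeds its
  Monte-Carlo standard deviation (≈ 4) by more than four standard
  deviations, making a direction flip by chance negligible.

## Known limitations

* Affected *distant* lymph nodes are coded C77 like regional ones, so the
  claims route cannot separate them; truly distant nodal disease is
  misclassified toward stage III. The real-world consequence is that
  claims-based stage-IV rates are, if anything, conservative.
* C77–C79 codes carry no link to a primary tumor; in patients with
  multiple cancers the metastasis may belong to a different primary. The
  generator does not model this (one cancer per person).
* The registry route cannot stratify advanced cancers with M missing;
  everything downstream of that ambiguity is scenario analysis, not
  estimation.
* Confidence intervals for ASIRs are out of scope; all uncertainty
  handling in the tests is by explicit Monte-Carlo/Poisson error bounds.
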