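---
title: "Harmonising diverse cohort data with a C-Surv schema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising diverse cohort data with a C-Surv schema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(csurv)
```

## The problem

Data discovery — finding out which cohort studies hold variables relevant
to a planned analysis, before requesting access — depends on
harmonisation: making differently measured variables inferentially
comparable under a common target definition. `csurv` implements a
harmonisation engine for this purpose. Its target model is a core list of
124 neurodegeneration-relevant variables structured by the C-Surv data
taxonomy, whose level-1 layer comprises 18 *data themes* (Administration,
Sociodemographic, ..., Molecular). The engine is evaluated against four
deliberately diverse synthetic cohorts emulating an occupational cohort
(`airwave`), a social-science ageing cohort (`elsa`), a genetics cohort
(`genscot`) and a neurodegeneration cohort (`memento`).

Harmonisation here is intentionally simple and generic — the goal is
discovery, not hypothesis-specific pooling — so three strategies suffice:

* **Simple calibration (SC)**: direct mapping of the source variable onto
  the target, possibly with unit conventions (cm, kg, mm/hg, mg/dl,
  pg/ml, mm^3, hours, m/sec), Gregorian `yyyy-mm-dd` dates (times of day
  truncated), and manual text lookup for cause of death (an ICD-11
  chapter stub) and medication counts.
* **Algorithmic transformation (AT)**: rule-based recoding or inference.
  Most AT items reduce to a yes/no (present/absent) format, inferred in
  three ways: a recorded diagnosis date implies presence
  (`date_presence`), a symptom rating score meets a cut-off
  (`score_threshold`), or a proxy field carries a trigger label
  (`proxy_condition`, e.g. self-reported heart disease standing in for
  angina and myocardial infarction). Nine variables need genuinely
  interpretive recodes: ethnicity, cohabitation, education, income,
  smoking, housing type, and the three exercise indicators.
* **Standardisation (S)**: the six non-clinical cognitive performance
  scores are z-scored within dataset, with a skew-conditional natural-log
  transform (below).

Out of scope by design: free-text NLP, latent-variable modelling,
multiple imputation, longitudinal/wave-level harmonisation, and
cross-currency conversion (income is quantiled in local currency).

## The schema and its two strategy tags

The packaged schema (`csurv_file("csurv_core_124.json")`) stores, per
variable, a stable snake_case id, theme, harmonisation rule text, target
codebook or units — and *two* strategy tags. The published core list
labels many yes/no items (e.g. the 18 family-disease-history variables)
as simple calibrations, while the utility evaluation classifies all
yes/no-format items produced by inference or recoding as algorithmic:
over the 120 represented variables the applied split is 61 directly
mapped, 53 algorithmic (44 yes/no plus the nine interpretive ones) and 6
standardised. The schema therefore carries `declared_strategy` (the core
list column) and `applied_strategy` (the evaluation classification), and
`strategy_tally()` counts either. Analytics use the applied tag.

Two encoding choices worth noting: the duplicated amyloid-beta assay rows
are disambiguated as plasma vs CSF analytes (`abeta_42_plasma`,
`abeta_42_csf`, ...), and the air-pollution item is treated as the
"pollution (grime in house)" row of the physical-environment theme — one
of the four variables found in no cohort (with the loneliness scale, the
MCI indicator and the ADAS-Cog score).

## Standardisation: the skew-conditional log rule

`zscore_standardise()` computes z-scores with the sample standard
deviation (n−1 denominator). When the raw sample's absolute skewness is
at or above the threshold, scores are first shifted so their minimum is 1
(shift = 1 − min, only when min < 1, so zero or negative counts stay
finite) and log-transformed; the shift, the measured skewness and the
transform are all recorded in provenance.

The skewness estimator is the moment-based Fisher–Pearson coefficient
g1 = m3 / m2^{3/2}. The reference skews that motivated the rule for the
six cognitive scores are −0.42, −0.42, −0.11, 0.31, 1.09 and −0.54: a
threshold of |skew| ≥ 1.0 separates the single strongly right-skewed
score (choice reaction time, 1.09) from all the rest, which is exactly
the behaviour the fixture test asserts on synthetic samples constructed
to those skews (gamma quantiles with shape (2/|skew|)², sign-flipped for
left skews). Neither the estimator nor the exact cut-off is prescribed by
the source material; both are design decisions of this package, and the
threshold is configurable per variable
(`zscore_standardise(x, skew_threshold = ...)`, or `skew_threshold`
inside a mapping rule) because a single global rule is a deliberate
simplification.

```{r}
r <- zscore_standardise(rlnorm(1000, meanlog = 6.4, sdlog = 0.6))
r
```

## Mapping rules and their conventions

Each cohort has one JSON mapping file with at most one rule per
harmonised variable. Conventions, chosen once:

* **Unmapped categorical labels become missing**, never "other": coding
  an unrecognised label as "other" would fabricate data. "Other" is
  emitted only when the source itself says other. Unmapped labels are
  logged in provenance.
* **Partial dates** (`"2001"`, `"2001-05"`) are rejected to missing with
  a warning, not imputed to mid-year: the convention is truncation only.
  Two input dialects are supported (`yyyy-mm-dd` with optional time, and
  `dd/mm/yyyy`).
* **Income quantiles** are computed within cohort on non-missing values,
  splitting at order statistics ⌈n/4⌉, ⌈n/2⌉, ⌈3n/4⌉ with ties to the
  lower quantile. Banded incomes (annual pound bands, monthly euro
  bands) resolve to band midpoints first; an open-ended top band is
  valued at 1.5 × its lower bound. Fewer than 4 usable values yields
  all-missing with a warning rather than arbitrary codes.
* **Smoking** targets {0 never, 1 past, 2 current}. A cohort that asks
  "ever smoked?" plus "smoking now?" resolves ever-smokers through the
  second question; when it is missing, "past" is used (the conservative
  reading of an ever-smoker with unknown current status).
* **Alcohol** is numeric units/week where derivable, with the sentinel
  category `"other"` when consumption is present but not quantifiable —
  so the harmonised column is text, the one deliberate departure from
  numeric typing, recorded in the sidecar dictionary.
* **Exercise** is reduced to presence/absence: any positive
  frequency/duration field → 1, explicit none → 0, all-missing → missing.
* **APOE genotypes** are normalised order-insensitively over allele
  pairs from {e2, e3, e4} to the 6-level coding (so `"4/3"`, `"e3/e4"`
  and `"E4E3"` all map to code 5).
* **Unit conversions** are explicit factor/offset pairs declared in the
  mapping file (metres → cm, mmol/l → mg/dl); no unit inference.
* **Ethnicity in `memento`** carries a `not_collected` marker rule: the
  data may not legally be collected in France, so harmonisation logs a
  provenance entry ("not collected (legal restriction)", 100% missing)
  but emits no column, keeping the cohort's column count equal to its
  presence count.

## The pipeline and provenance

`harmonise_cohort()` executes a cohort's rule set in schema order. The
output table contains exactly the variables with a rule and a source
column (absent variables are omitted, not emitted as all-missing); rows
are never created or lost; every non-missing categorical cell must lie in
its codebook (`check_codebook_closure()` runs in the acceptance path).
The provenance log has one entry per processed variable with
`n_mapped + n_missing = nrow`, plus human-readable warnings (unmapped
labels, partial dates, unparseable scores, applied log transforms). A
missing source field degrades to an all-missing column with a warning; a
rule whose kind contradicts the variable's strategy is a configuration
error raised before any data is touched. `write_harmonised()` emits CSV
(missing = empty field) plus a JSON data-dictionary sidecar; the pair
round-trips and is byte-identical across reruns.

## Coverage analytics

`build_presence()` derives the binary variable × cohort grid (presence =
rule + source present); `theme_coverage()`, `overlap_distribution()`,
`strategy_tally()` and `correspondence_summary()` compute the evaluation
numbers, assembled by `coverage_report()`:

```{r}
coverage_report()
```

Percentages round half-up to whole percent (so 92.5% reports as 93, and
120/124 as 97), matching conventional reporting. Per-variable presence is
not published anywhere; the packaged `presence_matrix.csv` is *one*
matrix constructed to satisfy simultaneously the theme-by-cohort table,
the per-cohort totals (47/73/60/92), the overlap histogram
({4:34, 3:10, 2:30, 1:46, 0:4}), the four named absences and the
ELSA/Memento unique counts (13, 26). Any matrix meeting all those
constraints would be equally valid; the analytics are tested against this
one and against brute-force oracles on random matrices.

## What the synthetic cohorts do and do not establish

`generate_cohort()` emulates each cohort's *native* surface: Scottish
qualification labels, monthly euro income bands, French yes/no, two-field
smoking questions, diagnosis-date fields, datetime stamps, log-normal
reaction times (σ = 0.6 on the log scale, so sample skew exceeds 1
essentially surely at n = 500). Categorical fields are multinomial over
the native vocabulary, quantitative fields normal with plausible
location/scale, missingness 5% per field; one master seed drives
independent substreams keyed by cohort id, so adding a cohort never
shifts another's draws.

A green end-to-end run establishes that the rules execute, close over
their codebooks, conserve rows, reproduce the presence structure and are
deterministic. It does **not** establish semantic validity on real data:
the generator draws variables independently (no epidemiological
correlations), has no waves, no informative missingness, and its label
frequencies are uniform. The cohort-specific skew values quoted above
describe real data and are not reproduced by the generator — only the
threshold behaviour built from them is tested.

## Known limitations

* Free-text fields are handled by a small exact-match lookup (ICD-11
  chapter stub); real cause-of-death coding needs proper terminology
  services.
* The interpretive recode tables encode one defensible reading of
  ambiguous source material (which cohort asks which smoking question;
  where each qualification label lands); alternatives are configurable
  through the mapping files without code changes.
* Income quantiles from banded data inherit the band resolution: with
  four input bands the quantile split can only follow band boundaries.
* Wave-level metadata is carried nowhere; baseline-vs-wave decomposition
  is out of scope.
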