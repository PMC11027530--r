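---
title: "Screening infant causes of death for SIDS-like mortality patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening infant causes of death for SIDS-like mortality patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sidscreen)
```

## The scientific question

Sudden infant death syndrome (SIDS) is a diagnosis of exclusion for infants
younger than 12 months. Its mortality peaks around the third month of life —
the main statistical evidence for a "critical developmental period" in the
triple-risk framework (a vulnerable infant, a critical period, an exogenous
stressor). Two questions can be asked of routine vital-statistics data:

1. Is the third-month peak *unique* to SIDS, or do other causes of death
   share it (which would point to misdiagnosis or a shared trigger such as
   infection)?
2. Does age at death depend on gestational age at birth — do preterm SIDS
   victims die at an *older* postnatal age, as expected if death is tied to a
   developmental stage rather than a calendar age?

`sidscreen` implements both screens as a tested pipeline over linked
birth-infant death records, plus the data-engineering steps they require:
harmonizing ICD-9 and ICD-10 cause codes into comparable groups and
filtering ultra-rare causes.

## Cause-code harmonization

US mortality coding switched from ICD-9 to ICD-10 in 1999, and the two
vocabularies map many-to-many. The package treats every (code, ICD version)
pair observed in the cohort as a graph node and adds an undirected edge
whenever the General Equivalence Mappings (GEM) crosswalk lists the pair, in
either mapping direction. Connected components of this graph become the
harmonized *joined codes* on which all screens operate.

Three design choices matter:

* **Nodes are restricted to observed codes.** Building components over the
  full GEM universe would let unobserved bridge codes merge groups that the
  cohort never connects.
* **GEM flags are ignored for edge construction.** Any listed pair counts as
  an equivalence; callers who want flag-aware filtering can subset the parsed
  entry table before building the graph (the flags are retained verbatim).
* **Component ids are the lexicographically smallest member code** (C-locale
  radix ordering), which makes group labels deterministic across runs and
  platforms. Human-readable aliases are presentation, not algorithm.

Component extraction is delegated to `igraph`; an independent brute-force
union–find implementation lives in the test suite and must agree exactly on
hundreds of randomized instances.

## Record ETL

Records carry year, gestational age (completed weeks, support 17–47), age at
death in days (0–364) and a raw cause code. Conventions fixed package-wide:

* **Weeks are 0-based half-open**: age-at-death week $w$ covers days
  $[7w, 7w+7)$, i.e. `floor(days / 7)`, giving weeks 0–52.
* **ICD version is a pure function of year**: ICD-9 before 1999, ICD-10 from
  1999 on.
* **Eras** around the 1994 "Back to Sleep" safe-sleep campaign: before
  (1986–1991), during (1995–1999), after (2000–2005); everything else —
  including the 1992–1994 gap in the national linked files — is excluded.
* **Unknown-value sentinels** in fixed-width layouts cause the row to be
  dropped and counted, never imputed.
* **Rare-cause filter**: a cause enters the screens only if its mean annual
  count over the in-scope years strictly exceeds 20. The source criterion
  ("more than 20 cases per year") does not say whether it is a per-year
  minimum or an average; the mean is robust to single sparse years, and a
  `per_year = TRUE` variant is available for sensitivity analysis.

## The three screens

**Weekly-profile screen.** For each cause, deaths are tallied by
age-at-death week and normalized to frequencies (each week's count divided
by the cause's total). The screen computes the Pearson correlation between
each cause's 53-week frequency vector and the reference (SIDS) vector over
the *full* axis 0–52 — no windowing, which would build the answer into the
question — and flags causes with $r \ge 0.5$ (inclusive: "at least" 0.5).

**Annual-trend screen.** Deaths are counted per cause per in-scope year and
expressed as a percent of the cause's mean annual count (so every normalized
series has mean 100, making causes of different absolute frequency
comparable). A cause is flagged when its series has $r > 0$ with the
reference's and the two-sided p-value is below 0.005. P-values use the exact
t-transform of $r$ with $n - 2$ degrees of freedom, where $n$ is the number
of paired points — 53 weeks for the profile screen, 17 years for the default
trend scope — and $n$ is reported alongside every $r$. No multiple-testing
correction is applied across causes: the procedure applies fixed per-cause
thresholds. The intersection of the two flagged sets is the candidate list;
the reference cause itself is a member of both sets by construction
(self-correlation 1), so the non-reference members are the interesting ones.

**Gestational-age screen.** For each cause, ordinary least squares of
age-at-death weeks on gestational-age weeks at the *record* level, with the
two-sided slope t-test ($n - 2$ df). A cause passes when slope $< 0$ and
$p < 0.05$: preterm victims dying at an older postnatal age. The fit is on
record-level points rather than the per-gestational-week means used for
display; the mean/SD-per-week table is produced separately
(`per_gestweek_summary()`), and a count-weighted per-week-means fit is
available behind `weighted_means = TRUE` for sensitivity. The screen is
repeated on the era subsets (before/during/after) and the ICD-9/ICD-10
subsets; a robust signal must survive all of them. The regression uses the
full gestational-age span — truncating the axis where the relation visually
weakens would be data-dependent selection. A cause needs at least 3 records
spanning at least 2 distinct gestational weeks to be fit; below that it is
reported as unfit rather than silently dropped.

## The synthetic cohort generator

Real linked birth-infant death files are multi-gigabyte restricted
downloads, so the package ships a generator whose outputs have *known*
structure; every screen is verified against planted truth.

* **Counts are exact quotas**, not Poisson draws: the realized count per
  (cause, year) equals the configured count. This makes the rare-cause
  filter and the trend screen deterministic functions of the configuration
  and keeps the planted-truth tests sharp. (A Poisson mode would be a small
  extension but would turn several exact tests into statistical ones.)
* **Age at death** for a victim with gestational age $g$ is
  $\mathrm{round}(\text{peak} + \text{slope}\cdot(g - 40) + e)$ weeks, with
  $e \sim N(0, \sqrt{\text{spread}^2 + \text{noise}^2})$, clamped to
  $[0, 52]$, then placed uniformly on a day within that week (capped at day
  364). The two dispersion parameters describe the profile width and the
  regression residual; since both act on the same scale they combine into a
  single Gaussian draw. Clamping piles mass on the boundary weeks, so
  calibration cohorts place the peak mid-axis (week 26), where clamping is
  negligible and cannot bias a planted slope.
* **Gestational age** is drawn from a discrete mixture over weeks 17–47:
  90% near-term ($N(39, 1.8)$) plus a 10% preterm tail ($N(33, 3.5)$),
  overall SD about 2.7 weeks — a realistic stand-in, not an estimate of any
  particular cohort's distribution.
* **One seeded stream** drives all sampling in documented order, so every
  fixture is bit-reproducible.

The generator also emits GEM tables with known connected components
(`generate_gem_tables()`): within each specified component a spanning set of
cross-version edges is guaranteed and extra edges are added at random; no
edge ever crosses components, so the ground-truth partition is exact.

What the generator does *not* emulate: live-birth denominators, maternal
covariates, sleep-position exposure, coding drift within an ICD era, or the
real files' byte layouts beyond the documented pluggable fixed-width
dialect. Passing tests therefore demonstrate that the *procedure* is
implemented correctly and calibrated, not that any particular real-data
finding is true.

## The bundled demo and its planted truth

`demo_cohort_config()` (fixed seed 1983) defines an eight-cause cohort over
1986–2005 with the 1992–1994 gap: a SIDS-like reference (peak week 11, a
campaign-era drop in annual counts, planted gestational-age slope −0.6
weeks/week), two causes sharing both profile and trend, one profile-only,
one trend-only, two matching neither, and one too rare to survive the
filter. `demo_planted_truth()` states the expected screen outcomes in
joined-id terms; the pipeline recovers them exactly:

```{r demo, eval = FALSE}
cfg <- pipeline_config(
  mode = "synthetic", cohort = demo_cohort_config(),
  gem_components = demo_gem_components(), seed = 1983L,
  out_dir = "demo_out"
)
manifest <- run_pipeline(cfg)
manifest$screen_sets$intersection   # "4275" "4800" "7980"
manifest$gestage_pass_all           # "7980"
```

## Numerical and calibration choices

* Pearson and OLS inference go through `stats::cor.test()` and
  `stats::lm()`; tests check both against direct textbook formulas to
  1e-10 relative error.
* Constant frequency vectors or count series have undefined correlation;
  such causes are excluded from the affected screen and reported, never
  scored.
* Threshold semantics are literal: profile screen inclusive
  ($r \ge 0.5$), trend and regression screens strict ($r > 0$,
  $p < \alpha$). Because the regression verdict conjoins a two-sided
  $p < 0.05$ with a negative sign, the null pass rate is about 2.5%, and
  the test suite verifies this within 3 Monte-Carlo standard errors over
  1,000 null causes of 500 records each; power and bias are checked with
  200 replicates of a planted −0.6 slope (residual SD 8 weeks, n = 2000 per
  replicate), sizes chosen to keep the whole suite within a desk-scale run
  while leaving the Monte-Carlo error well below the tolerances tested.
* Reruns of the pipeline with the same configuration and seed produce
  byte-identical output tables (fixed column order, `readr` number
  formatting, relative paths and no timestamps in the manifest).

## Known limitations

* The harmonization treats ICD-10 (WHO mortality) and ICD-10-CM dialect
  differences only through string normalization (uppercase, strip periods).
* The trend screen assumes a shared year axis; it refuses fewer than three
  shared years rather than guessing.
* Group counts on real national data depend on the exact code inventory
  observed there and are not a verification surface for this package; the
  synthetic planted-truth recovery is.
* The screens are descriptive: no survival modelling, no adjustment of
  postnatal age for prematurity, and no multiple-testing correction by
  default (a Benjamini–Hochberg pass over the verdict table is a one-liner
  with `p.adjust` if wanted).
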