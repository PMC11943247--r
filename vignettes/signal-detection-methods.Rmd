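---
title: "Methods: disproportionality analysis and time-to-onset modelling on spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis and time-to-onset modelling on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

# The data model

A spontaneous-reporting database is a set of case reports, each joining
demographics (DEMO), drug rows with role codes (DRUG), reaction preferred
terms (REAC), therapy dates (THER) and outcome codes (OUTC), distributed
as quarterly `$`-delimited ASCII tables. Three properties of this format
drive the design of the ingestion layer:

* **Versioning.** A case (CASEID) may be re-reported in later quarters
  under new PRIMARYIDs. The deduplication rule keeps, per CASEID, the row
  with the latest FDA receipt date, breaking ties by the largest
  PRIMARYID. PRIMARYIDs are compared numerically when all ids parse as
  numbers, lexicographically (with a warning) otherwise — the ids in the
  wild are numeric, but the comparison domain must be defined for
  arbitrary input.
* **Retraction.** From 2019Q1 each quarterly package carries a deletion
  list of retracted CASEIDs. Lists are applied *after* deduplication, so
  a retraction removes the case entirely rather than reviving an older
  version.
* **Partial dates.** Dates may arrive as YYYYMMDD, YYYYMM or YYYY. For
  ordering (deduplication) a partial date is padded to its earliest
  completion (missing month/day → 01), which is deterministic and invents
  no precision. For interval arithmetic (time-to-onset) partial dates are
  never padded: those records are excluded as unreliable, with the reason
  recorded.

Parsing never drops rows silently: lines whose field count disagrees with
the header are counted and reported, and empty fields become `NA`.

# Contingency tables

For each event term the 2×2 table compares the suspect drug's reports
with the rest of the database:

|                | event        | other events |
|----------------|--------------|--------------|
| suspect drug   | a            | b            |
| all other drugs| c            | d            |

The counting unit is the distinct (report, term) pair: a report
mentioning the same PT twice counts once, and the margins are pair totals
— so the `a` cells over all terms sum exactly to the cohort's pair count,
which makes the funnel auditable. At SOC level the same rule applies to
(report, SOC) pairs, so no PT is counted in two SOCs (each PT has one
primary SOC in the dictionary schema). The suspect-drug margin is the
cohort selected by the PS role filter; the comparator is the full
deduplicated snapshot, i.e. a single-drug-versus-rest design.

# The four statistics

**ROR.** `ad/bc` with the Wald interval
`exp(log ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`. A zero cell leaves the
statistic undefined-with-reason rather than silently corrected; the
Haldane +0.5 correction is available behind a flag. Default positivity:
`a ≥ 3` and lower bound > 1.

**PRR.** `[a/(a+b)]/[c/(c+d)]` with
`exp(log PRR ± 1.96 √(1/a − 1/(a+b) + 1/c − 1/(c+d)))`. The accompanying
χ² uses the Yates continuity correction
`N(|ad − bc| − N/2)² / [(a+b)(c+d)(a+c)(b+d)]`, floored at zero inside
the continuity band; a flag disables the correction. Positivity is the
MHRA combined criterion: `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`.

**BCPNN information component.** The closed-form posterior moments of
`IC = log2 P(drug, event)/(P(drug) P(event))` under the standard Beta
prior structure (margin priors Beta(1,1), joint-cell prior weight 1, the
joint prior count chosen so the prior expectation sits at independence).
`IC025 = IC − 2 sd`. Two properties are worth stating because they
surprise users: the IC is finite for `a = 0` (the prior regularises the
empty cell), and for cells with a small independence expectation the IC
is *heavily* shrunk relative to the raw `log2(aN/((a+b)(a+c)))` — the
margin-adaptive prior weight grows like `N²/((a+b)(a+c))`, so a cell
expecting one report and observing ten reads well below the raw ratio.
This shrinkage is the method's defence against false positives in sparse
cells, and the test suite pins it against Monte-Carlo samples of the
model's own posterior rather than against the raw ratio. Positivity:
`IC025 > 0`.

**Gamma Poisson shrinker.** Cell counts are modelled as Poisson with mean
`λE`, `E = (a+b)(a+c)/N` the independence expectation, and `λ` drawn from
a two-component gamma mixture `π Gamma(α₁, β₁) + (1−π) Gamma(α₂, β₂)`.
The marginal likelihood of a cell is then a two-component
negative-binomial mixture (size `α`, probability `β/(β+E)`), maximised
over the five parameters by quasi-Newton iteration on log-transformed
shapes/rates and a logit-transformed weight, from the conventional start
`(0.2, 0.1, 2.0, 4.0, 1/3)`. The fit uses the cells with `n ≥ 1` under
the untruncated likelihood by default; a zero-truncation flag implements
the conditional-on-`n≥1` variant, since both appear in practice. The
posterior for one cell is again a two-gamma mixture; `EBGM =
2^{E[log2 λ]}` comes from the digamma identity
`E[ln λ] = ψ(shape) − ln(rate)` per component, and `EBGM05` is found by
monotone root-finding on the posterior mixture CDF (bracketed by the
component quantiles, tolerance well below 10⁻⁶). Positivity:
`EBGM05 ≥ 2`.

Because `EBGM` is a geometric-scale mean, the Jensen gap can push it
slightly below both the raw ratio and the prior mean on the low side;
the shrinkage property tested is therefore the one that matters for
detection — on elevated cells the estimate sits between the prior mean
and the observed `a/E`.

A term is a potential signal when **at least one** method exceeds its
threshold. All thresholds live in `signal_thresholds()` and are
configurable; the defaults are the canonical published values.

# Time-to-onset

Onset is the whole-day difference between the DEMO event date and the
earliest full THER start date linked to the target drug's sequence
number (earliest, because the first exposure is the conservative reading
of "start of treatment"). Records failing the date checks carry exactly
one exclusion reason (`missing date`, `partial date`, `negative
interval`), and `reliable + unreliable = linked` is asserted in tests.

The Weibull fit addresses a structural problem: for a bolus diagnostic
agent the onset distribution has a large point mass at day 0, which is
outside the Weibull support. The default adds a half-day offset
(`t = days + 0.5`), reading "day 0" as "within the first day"; the offset
is a parameter, and continuous positive data can be fitted with
`offset = 0`. Maximisation is on `(log shape, log scale)` with
confidence intervals from the observed-information normal approximation
on the log scale. The hazard profile is classified from the shape
interval: upper bound < 1 ⇒ early-failure (decreasing hazard), lower
bound > 1 ⇒ wear-out, otherwise random; fewer than 10 records, identical
values, or a failed/singular fit give `indeterminate` with a reason.
Note that with a dominant day-0 mass the fitted shape mostly reflects
the offset convention, not biology — the classification (decreasing
hazard, risk concentrated immediately after administration) is the
robust conclusion, the point estimate is not.

# The synthetic generator

`faers_sim_config()` fixes the study conditions a generated package
emulates; the defaults describe a realistic single-drug safety snapshot:

* 20,000 expected reports over three quarters, 25 drugs (drug 1 the
  target, reported under two synonyms), 80 PTs cycling through the 27
  SOCs;
* drug–event cell counts Poisson with mean `Eλ`, where `E` comes from
  mild power-law marginals and `λ` is 1, mixture-drawn (the same
  two-gamma family the shrinker fits, defaults `(0.2, 0.1, 2, 4, 1/3)`),
  or planted — default five pairs on the target drug at relative risks
  5–12;
* 10% of cases re-reported (same CASEID, incremented PRIMARYID, later or
  equal receipt date — equal dates exercise the PRIMARYID tie-break), 2%
  retracted via deletion lists;
* onset times: 99% exactly day 0, the rest a Weibull(shape 0.6, scale
  30 days) tail floored to whole days; therapy start and event dates are
  derived backwards from the receipt date so `start ≤ event ≤ receipt`
  always holds and the true onset is known per report;
* field-level missingness (35% event dates, 30% start dates, 25% ages,
  …) and 5% partial-date truncation; 2% of reaction rows written under
  an obsolete PT name that the emitted dictionary maps back.

What it deliberately does **not** emulate: free-text drug names and
misspellings, multi-reaction reports (each synthetic report carries one
PT, which keeps the pair-count margins exactly equal to the cell draws;
multi-PT counting is covered by hand-built unit fixtures), indication
fields, country-specific reporting behaviour, and secular trends.
Passing the recovery tests therefore shows the *statistics and plumbing*
are right; it says nothing about name normalisation or coding quality on
real FAERS extracts.

Planted-signal recovery is evaluated on an independence background
(`background_prior = NULL`, all non-planted relative risks exactly 1),
because the false-positive rate is defined against true nulls; with the
mixture background many non-planted pairs are genuinely elevated and
flagging them is correct behaviour, not error. Under those conditions
(seed-fixed, ~20,000 reports) all five planted pairs are flagged and no
true-null term with `a ≥ 3` is.

# Validation problem sizes

The test suite works at sizes chosen to keep each check sharp but cheap:
enumerated small tables for the closed forms (with `stats::chisq.test`
as the independent χ² route and `fitdistrplus` as the independent
Weibull route); 10⁵-draw Monte-Carlo posteriors for the information
component and 10⁶ for the shrinker posterior; 5,000 simulated cells for
prior recovery; 2,000 draws for Weibull shape recovery (±0.05); and one
20,000-report and one 5,000-report synthetic database shared across
files. The whole suite runs in well under a minute.

# Known limitations

* Expectations `E` are unstratified (no age/sex/year stratification);
  the hook exists but the default matches the single-stratum design.
* The legacy pre-2012 column layout and the XML dialect are not parsed.
* Severity is derived from the outcome-code vocabulary (DE, LT, HO, DS,
  CA, RI ⇒ serious); reports without outcome rows count as non-severe.
* The Weibull model is a single homogeneous distribution — no competing
  risks, censoring, or per-term onset models.
* Signal positivity is a screening statement about reporting
  disproportion, not causality; confounding by indication and reporting
  artefacts are out of scope.
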