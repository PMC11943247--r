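# faersignal

Pharmacovigilance signal detection on FAERS-style spontaneous adverse-event
reports.

Spontaneous reporting databases such as the FDA Adverse Event Reporting
System (FAERS) are the main post-marketing source of drug-safety signals.
`faersignal` implements the full analysis chain used in drug-safety studies
of a single suspect drug against the rest of the database:

1. **Ingestion** of the quarterly `$`-delimited ASCII packages
   (DEMO/DRUG/REAC/THER/OUTC), with the FDA-recommended case deduplication
   (per CASEID keep the latest FDA_DT, ties broken by the largest
   PRIMARYID) and the quarterly deletion lists distributed from 2019Q1 on.
2. **Event coding** of MedDRA preferred terms (PTs) to their primary system
   organ class (SOC) through a plain TSV dictionary (MedDRA itself is
   licensed and is not shipped).
3. **Cohort selection** of reports where the target drug is the primary
   suspect (PS role), with a descriptive summary (sex, age bands, reporter,
   severity from the FDA serious-outcome codes, reporting year, country).
4. **Disproportionality analysis** on 2×2 contingency tables
   (`a` = suspect-drug reports with the event, against the rest of the
   database; counting unit: distinct (report, term) pairs), with four
   statistics:
   - reporting odds ratio `ROR = ad/bc` with its Wald 95% interval,
   - proportional reporting ratio `PRR = [a/(a+b)]/[c/(c+d)]` with the
     MHRA combined criterion (PRR ≥ 2, Yates χ² ≥ 4, a ≥ 3),
   - the BCPNN information component
     `IC = log2 P(drug, event)/[P(drug)P(event)]` with its closed-form
     posterior bound IC025,
   - the multi-item gamma Poisson shrinker: an empirical-Bayes
     two-component gamma prior on the relative report rate fitted by
     marginal (negative-binomial mixture) maximum likelihood, giving
     `EBGM` (posterior geometric mean) and `EBGM05` (posterior 5th
     percentile).
   A term is a potential signal when at least one method exceeds its
   threshold; all thresholds are configurable.
5. **Time-to-onset**: days from the earliest target-drug therapy start to
   the event date, with explicit reliability accounting
   (missing/partial-date and negative-interval exclusions), a
   maximum-likelihood Weibull fit with hazard-profile classification
   (shape < 1 ⇒ decreasing hazard, "early failure"), and the empirical
   cumulative-incidence curve.

A synthetic FAERS generator (`faers_sim_config()`,
`generate_faers_package()`) emulates the structural features that matter
to this pipeline — case re-reporting across quarters, deletion lists,
partial dates, role-coded drug rows, a day-0-dominated onset distribution,
and drug–event counts drawn from a gamma-Poisson mixture with planted
elevated-risk pairs — so every stage is testable against known ground
truth without downloading anything.

## Worked example

```r
library(faersignal)

cfg   <- faers_sim_config(n_reports = 5000, background_prior = NULL, seed = 202)
dir   <- file.path(tempdir(), "demo_pkg")
truth <- generate_faers_package(cfg, dir)

store  <- ingest_faers(dir, cfg$quarters)
store
#> FAERS case store: 5967 retained reports
#>   raw 6721 | unique cases 6084 | deleted 117

cohort <- select_primary_suspect(store, c("REGADENOSON", "LEXISCAN"))
map    <- read_meddra(file.path(dir, "meddra.tsv"))
tabs   <- build_tables(cohort, store, level = "PT", map = map)
prior  <- fit_gps_prior(tabs$a, tabs$expected)
st     <- signal_stats(tabs, prior = prior)
rank_report(st, by = "frequency", top_n = 5)[,
  c("term", "a", "ror", "prr", "chi2", "ic", "ic025", "ebgm", "ebgm05", "positive")]
#>        term   a  ror  prr  chi2    ic ic025 ebgm ebgm05 positive
#>  EVENT_0005 266 6.77 5.94 313.8 1.216 0.983 2.25   2.05     TRUE
#>  EVENT_0004 245 4.51 4.04 210.2 1.044 0.807 2.04   1.85     TRUE
#>  EVENT_0003 231 3.83 3.48 167.6 0.963 0.722 1.95   1.77     TRUE
#>  EVENT_0001 230 2.21 2.06  69.7 0.625 0.393 1.61   1.46     TRUE
#>  EVENT_0002 222 2.80 2.58 105.6 0.783 0.543 1.76   1.59     TRUE
```

The five planted elevated-risk pairs (true relative risks 5–12 on the
target drug) all come back `positive`: each is flagged by at least one of
the four methods. The ingest banner shows the deduplication funnel — 6721
raw quarterly rows collapse to 6084 unique cases, of which 117 are
retracted by deletion lists.

```r
ons <- compute_onset(cohort)
ons
#> Time-to-onset: 747 reliable of 1858 linked reports
#>   median 0 days (IQR 0.00-0.00)
#>   0 days          737   98.66%
#>   ...
weibull_fit(ons$records$onset_days[ons$records$reliable])
#> Weibull fit on 747 records (offset 0.5 days)
#>   shape 0.747 (95% CI 0.720-0.774)
#>   scale 0.77 days (95% CI 0.69-0.85)
#>   hazard profile: early-failure
```

The onset summary reproduces the day-0-dominated profile the generator
was configured with (99% same-day events), and the Weibull shape below 1
classifies the hazard as early-failure: the risk is concentrated right
after administration.

`run_pipeline(run_config(dir, cfg$quarters))` executes the whole chain in
one call and writes `demographics.json`, ranked `signals_PT.tsv` /
`signals_SOC.tsv`, `onset.json`, `onset_cdf.tsv`, and a `manifest.json`
with input checksums and the record count at every filtering step.

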