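# ctrreport

Meta-analysis tools for **results deposition and outcome reporting in
clinical-trial registries** (the ClinicalTrials.gov public-XML dialect).

Public trial registries exist so that the scientific community and the
public can see what was studied and what came of it. In practice only a
minority of registered trials ever deposit summary results, even where
FDAAA Section 801 makes deposition mandatory. Whether a trial reports
turns out to depend strongly on *who sponsors it* — a pharmaceutical
company, a university, a hospital, a government body or a collaboration.
`ctrreport` implements the full analysis pipeline needed to quantify
that: registry XML ingestion, sponsor classification, the
results-deposition requirement cascade, reporting-efficiency tables, and
per-class odds ratios. A calibrated synthetic registry generator makes
every stage testable without downloading a registry snapshot.

The package is aimed at biostatisticians and health-policy researchers
studying registry compliance and reporting bias.

## What it computes

**Sponsor classification.** Each lead sponsor is assigned one of five
institutional classes — `edu` (research/educational), `com` (for-profit),
`gov` (national/government), `hos` (hospitals & clinics), `col`
(collaborations) — by prioritised multilingual keyword dictionaries
("University", "Università" → edu; "Hospital", "Hôpitaux", "Klinik" →
hos; "Inc.", "Corp." → com, ...) with hospital keywords outranking
university keywords ("University Hospital" is `hos`), and a fallback to
the registry's own agency class (Industry → com, NIH / U.S. Fed → gov)
for names matching no keyword.

**The requirement cascade.** Summary-results deposition is expected of
trials that are *completed* (by the snapshot cutoff), *FDA regulated* and
specifically *Section 801* covered, in an explicit *phase 2–4*, carrying
a *peer-reviewed publication* reference, and *interventional*. The
conjunction defines the "restrained pool". Per year and per class the
package tabulates trials with deposited results against totals.

**Association.** For class membership Y and reporting indicator X
(results deposited, or ≥ 1 outcome listed), association is measured by
the odds ratio of the joint distribution

    OR = (p11 · p00) / (p10 · p01) = (n11 · n00) / (n10 · n01)

with a Woolf confidence interval on the log scale,
`SE = sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)`, using a Student-t quantile
(df = n − 1; a normal-quantile switch is available).

## Worked example

```r
library(ctrreport)

# a 20,000-trial corpus calibrated to the 2012 registry composition
res <- run_registry_analysis(default_registry_config(20000),
                             out_dir = "results/run_all", seed = 20120101)
#> [..] classified: edu=5412 com=6477 gov=3342 hos=2860 col=1634 unclassified=275
#> [..] restrained cascade: corpus=20000 completed_by_cutoff=11141
#>      fda_regulated=3185 section_801=2259 phase_2_to_4=5190
#>      has_publication=774 interventional=9157 all_requirements=50

res$or_overall[res$or_overall$indicator == "results", c(1, 3:5)]
#> # A tibble: 4 × 4
#>   sponsor_class     or ci_low ci_high
#>   <chr>          <dbl>  <dbl>   <dbl>
#> 1 com           7.54   6.32     8.98
#> 2 gov           0.0929 0.0574   0.151
#> 3 hos           0.389  0.295    0.513
#> 4 edu           0.291  0.233    0.364
```

Reading: of 20,000 trials, 11,141 are completed by the 2011-12-31 cutoff
but only 50 satisfy every deposition requirement simultaneously — the
cascade is that selective on real registry data too. Company-sponsored
trials have about 7.5× the odds of depositing results relative to all
other classes pooled; government-sponsored trials about 0.09× — the same
ordering (com ≫ hos ≈ edu > gov) seen in the 2012 registry snapshot.

Classifier behaviour on real-looking names:

```r
dict <- load_sponsor_dictionary()
classify_sponsor(c("University Hospital Basel", "Hôpitaux de Paris",
                   "Acme Corp.", "Xyzzy Foundation"),
                 c("Other", "Other", "Industry", "NIH"), dict)
#> [1] "hos" "hos" "com" "gov"
```

The numbered scripts under `analysis/` run the same workflow as separate
narrated steps (simulate → ingest/classify → cascade tables → odds
ratios), writing their tables under `results/`.

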