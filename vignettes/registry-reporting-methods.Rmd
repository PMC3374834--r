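---
title: "Methods: sponsor classification, the deposition cascade, and reporting odds ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sponsor classification, the deposition cascade, and reporting odds ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrreport)
```

## The problem

A public trial registry accumulates one record per registered study:
who sponsors it, its design, status and dates, its pre-specified outcome
measures, and — for a minority of trials — a deposited summary-results
section. Regulation (FDAAA Section 801, 2007) makes results deposition
mandatory for a defined subset of trials, and the ICMJE makes
registration a precondition of journal publication; yet even among
trials meeting every condition simultaneously, only roughly a third had
deposited results by the start of 2012. `ctrreport` operationalises the
question *which institutions report, and under which obligations* as a
pipeline of five stages, each exposed as ordinary functions over a
tidy corpus tibble: XML ingestion, sponsor classification, the
requirement cascade, summary tables, and odds ratios.

## Sponsor classification

The registry's own sponsor label has four levels (Industry, NIH,
U.S. Fed, Other), which hides exactly the contrasts of interest:
universities, hospitals, collaborations and non-US governments are all
"Other". The classifier refines this into five classes using keyword
dictionaries over the lead-sponsor name.

Design choices, in decreasing order of consequence:

* **Priority is a total order, `hos > edu > com > gov > col`.** The one
  ordering that matters in practice is hospital-over-university:
  "University Hospital Basel" must be `hos`, because the operative
  institution is the hospital. The remaining order is our own
  assumption, chosen so that specific facility terms beat generic
  corporate or governmental terms; it is configurable in the dictionary
  file, which is data, not code.
* **Matching is word-boundary substring matching over a normalised
  name** (Unicode NFKC, case-folded, whitespace-collapsed). Boundary
  anchoring prevents "Include" from matching the corporate suffix
  "Inc." while still letting "Acme Corp" (no dot) match "corp." at the
  end of the name.
* **Diacritics are significant by default.** Sponsors are filed in many
  languages; "Hôpitaux", "Klinik" and "Università" are dictionary
  entries in their own right. A folding switch
  (`load_sponsor_dictionary(fold_diacritics = TRUE)`) exists for
  corpora known to contain transliterated names, off by default because
  folding can only create false positives, never remove one.
* **Fallback, then residue.** Names matching no keyword inherit the
  agency class mapping (Industry → com, NIH and U.S. Fed → gov); a
  keyword-free "Other" stays `unclassified`. Unclassified records are
  excluded from per-class tables but kept in corpus-wide denominators.
* **No manual pass.** Production registry analyses typically follow
  automatic classification with manual correction of residual errors;
  that step is irreproducible by definition and deliberately out of
  scope here. The shipped dictionaries are therefore a reconstruction,
  and users with a real corpus are expected to iterate on the YAML
  dictionary, not on code.

Ties within one class (a name matching several keywords of the same
class) cannot change the assignment; for reporting purposes the longest
keyword is considered the match, remaining ties broken lexicographically,
so output is deterministic.

## The requirement cascade

Five conditions jointly define the pool of trials for which results
deposition is expected (the *restrained pool*): completed by the
snapshot cutoff; FDA regulated; Section 801 covered; explicit phase
2–4; at least one publication reference; interventional design.
Semantics that required a decision:

* **Completion is conservative.** Registry dates are month-granular; a
  completion date counts as on-or-before the cutoff only if its *latest
  possible day* is. "December 2011" passes a 2011-12-31 cutoff; a bare
  "2011" passes; "2012" or "January 2012" do not. This avoids counting
  trials that may have completed after the snapshot. Only status
  `Completed` qualifies, whatever the date says.
* **Absent oversight flags are false.** Registry counts of "FDA
  regulated" trials count affirmative assignments; a record that is
  silent cannot be presumed covered.
* **Phase uses set intersection by default.** "Phase 1/Phase 2"
  qualifies as phase 2–4 because it names phase 2 explicitly; the
  stricter rule (minimum phase ≥ 2) is available via
  `compute_flags(phase_rule = "min")`. "N/A" and "Early Phase 1" are
  not explicit phases.
* **Publication is structural**: at least one attached reference of any
  kind. Verifying ICMJE membership of the venue would require external
  data and is out of scope.

Flags are pure functions of the record and cutoff; the restrained pool
is provably a subset of every single-requirement pool, and the tests
assert this on every generated corpus.

## Summary tables

All percentage columns are `100·k/n` rounded **half-up** (`percent()`),
because that is the rounding convention registry summary tables use;
base R's round-half-even would disagree on exact ties (55.555 → 55.56,
not 55.55). Zero denominators render "n/a" rather than erroring: whole
cells (e.g. a class with no device trials) can legitimately be empty. A
trial with several intervention types counts once per type, so
intervention columns need not sum to the interventional total; a
multi-phase trial counts once per phase. Enrollment summaries do *not*
filter anomalies — the unrestricted stratum deliberately shows how a
single sentinel value (99999999) dominates a class maximum and average,
which is itself a finding about registry data quality; the
results-deposited stratum shows how conditioning on reporting removes
them.

## Odds ratios

For Y = membership in a target class and X = a reporting indicator, the
odds ratio is the cross-product of the 2×2 joint distribution; the count
and probability forms are algebraically identical and the tests hold
them to machine precision. The OR was chosen (rather than a risk ratio)
because it is estimable from the registry's non-random sample — deposits
cluster heavily by sponsor.

The interval is Woolf's: `log OR ± q·SE`,
`SE = sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)`. For the quantile `q` we use
the two-sided Student-t value with `df = n − 1` by default and provide a
standard-normal switch; at any realistic corpus size the two differ by
well under 0.1% of interval width, and the coverage simulation in the
test suite (true OR 2, n = 500, 1000 tables) lands within [92%, 98%] for
both. The t default is a convention choice, not a small-sample claim:
log-OR standard errors at the cell counts involved dwarf the t-vs-normal
quantile difference.

Zero off-diagonal cells are a hard error by default — an infinite OR
estimate is never silently produced — with an opt-in Haldane–Anscombe
+0.5 correction. The pipeline orchestrator applies the correction for
its *restrained* OR report only, because the restrained pool is a
fraction of a percent of any corpus and zero cells there are routine at
moderate corpus sizes; module-level calls keep the strict default.

The `col` class is excluded from OR pools by default (configurable):
collaborations contain members of the other classes, so its indicator
is not a clean partition. `unclassified` is excluded for the same
reason. Published per-class OR values for the 2012 snapshot depend on an
analysis pool whose exact construction (precise restraint arithmetic,
handling of the unclassified residue) is not recoverable, and their
printed interval widths are far narrower than any Woolf-type interval at
those counts; we therefore treat only the qualitative structure — com
largest, gov smallest, by a wide margin in both cases — as the
reproducible signature, and the tests check exactly that on calibrated
synthetic corpora.

## The synthetic registry generator

`default_registry_config()` encodes the study conditions: every
parameter with a published counterpart in the 2012 snapshot's summary
statistics is set to it —

* class mix (27.2 / 32.1 / 16.4 / 14.5 / 8.4% plus a 1.4% unclassified
  residue), and the agency-class correspondence per class;
* completed share (65937/118602) and completion-year weights (the
  yearly completed totals, pre-2001 tail pooled at 2000);
* FDA marginal 29.8%, Section-801-given-FDA 25151/35344;
* phase-2–4, publication and interventional shares among completed
  trials (Table-level totals: 51.5%, 7.1%, 82.7%);
* per-class outcome-listing rates and restrained-pool results rates;
* per-class unrestricted results rates from deposited-results counts
  over class totals;
* enrollment log-normal scales matched to per-class averages of the
  outcome-reporting stratum (the least anomaly-contaminated published
  scale), with exact-rate injection of the documented anomalies
  (zero enrollment at 255/118602, sentinel 99999999 at 3/118602).

Where no published value exists (non-completed status mix, reference
count beyond the first, arms distribution, date granularity mixture,
keyword-free fraction of com/gov names at 15%), values were fixed once
at what a registry analyst would call realistic and are documented in
the config structure itself.

Two structural choices matter for interpretation:

* **Requirement flags are conditionally independent given class.** The
  restrained pool is therefore *emergent*, arising at roughly 0.3% of
  trials — the same order as the real snapshot's ~0.5%, where the
  requirements are positively correlated. Consequently a 20,000-trial
  corpus contains only tens of restrained trials per class, and
  restrained-pool rate estimates carry binomial standard errors of
  several percentage points. This is a property of the phenomenon, not
  of the generator: the real cascade is exactly this selective. Tests
  of restrained-pool recovery at this scale are expected to show
  multi-point deviations; the unrestricted rates (class mix, outcome
  rates, overall results rates), estimated on thousands of trials per
  class, recover to fractions of a point.
* **One seeded stream, fixed field order.** All randomness derives from
  a single `set.seed(seed)` with every field drawn for all trials in one
  vectorised call in a fixed order, so identical config + seed gives an
  identical corpus, and generation cannot be perturbed by insertion
  order. The caller's RNG state is restored on exit.

What the generator does *not* emulate: typographic errors and
transliteration noise in sponsor names (classifier accuracy on synthetic
corpora is 100% by construction — real-world accuracy is bounded by
dictionary coverage); temporal correlation beyond per-year weights;
correlation between enrollment and reporting; multi-sponsor records.
Passing recovery tests therefore demonstrates that the *pipeline* is
correct and calibrated, not that the shipped dictionaries would classify
an arbitrary real corpus without error.

## Problem sizes and numerical conventions

The test suite and the acceptance script use corpora of 20,000 trials
(three seeds) for rate-recovery checks, 10,000 for class-mix recovery,
1,000 records for exact XML round-tripping, and 1,000 replicate tables
for interval coverage; these sizes put binomial noise well inside the
asserted bounds for all unrestricted quantities while keeping a full run
in tens of seconds on a laptop. Rounding is half-up everywhere
percentages are displayed, at two decimals (tables compare at each
printed value's own precision). Partial dates are carried as ISO-like
strings and compared through their latest possible day. Determinism is
asserted byte-for-byte on the orchestrator's outputs.

## Known limitations

* The keyword dictionaries are a reconstruction and deliberately modest;
  per-class counts on real corpora will differ with dictionary edits,
  which is why the dictionary is a user-editable YAML file and the
  manifest records a content hash of the dictionary used.
* The restrained-pool OR at moderate corpus sizes is Haldane-corrected
  and wide; it stabilises only at registry scale (hundreds of restrained
  trials per class).
* `completed_by_cutoff` trusts the recorded status; trials completed but
  never updated (status "Unknown") are excluded by design.
* Enrollment totals use double precision (class totals exceed the
  32-bit integer range when sentinel values are present).
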