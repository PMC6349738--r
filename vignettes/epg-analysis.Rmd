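---
title: "Analysing whitefly EPG recordings: model, parameters and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing whitefly EPG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgtools)
```

## The measurement and its grammar

The electrical penetration graph (EPG) technique records voltage
fluctuations through a plant–insect circuit while a tethered sap-sucking
insect probes a leaf. Manual annotation of a 12-h recording yields an
ordered sequence of behavioural waveforms; for whiteflies the conventional
set is **np** (non-probing, stylet out of the plant), **C** (stylet pathway
through the tissue), **pd** (potential drop — a brief intracellular
puncture during pathway), **G** (xylem ingestion), **E1** (phloem
salivation), **E2** (phloem ingestion) and **F** (derailed stylet
mechanics). `epgtools` takes such annotation sequences as its input; it
does not classify raw voltage traces.

A recording is modelled as a contiguous tiling of half-open intervals
`[start, end)` over the window (default 43 200 s at a nominal 100 Hz
acquisition rate). Half-open intervals make the tiling exact — durations
sum to the window length with no double counting — and adjacent events with
equal codes are merged on read, since annotators routinely split a single
behavioural bout into several segments and event *counts* are only
meaningful under the merged convention.

The annotation grammar encodes biology: phloem ingestion is always entered
through salivation (every E2 directly follows E1 or E2), potential drops
occur only inside probes (never adjacent to np), and a probe normally opens
with pathway activity before any phloem phase. `validateGrammar()` reports
violations of these rules as data (rules R1–R4, with severities), so a
pipeline can quarantine corrupt files without aborting a batch.

## Probe structure and the early-G rule

A **probe** is a maximal run of non-np events; probes are delimited by np
periods or by the recording boundary, and a probe cut off by the end of the
window is kept and flagged censored (with a fixed-duration design this
truncation is unavoidable, and no censoring adjustment is applied to
durations — truncated events enter totals and means at their observed
length).

Whiteflies are considered unable to reach xylem vessels within the first
ten minutes of a probe, so a xylem-like (G) waveform that begins strictly
less than `earlyGThreshold = 600` s after the start of its probe is
relabelled F before any parameter is computed (`reclassifyEarlyG()`). The
boundary is strict (`<`), the relabelling conserves total time, and the
operation is idempotent. The threshold is exposed because annotators differ
in whether they already label this pattern F at source; on such files the
rule is a no-op.

Potential drops are treated as punctuations of pathway rather than as
interruptions that terminate it: a run `C pd C ... C` counts as **one** C
event whose duration is the summed C time, with the pds kept as their own
events (`effectiveEvents()`, `mergeCAcrossPd = TRUE`). This is the
convention under which published per-waveform counts, means and totals are
mutually consistent — with tens of pds per recording, splitting C at every
pd would inflate C counts several-fold while leaving totals unchanged. The
switch is exposed for comparison with tools that use the other convention;
totals are invariant to it by construction.

## The parameter battery

`computeInsectParameters()` produces one record per insect (all durations
stored in seconds; conversion to the conventional reporting units — minutes
generally, mean pd and E1 durations in seconds, the first-probe-to-first-E1
latency in hours — happens only in `parametersToTable(units = "display")`):

* per waveform: total duration, effective event count, mean event duration;
* probe measures: number of probes, mean probe duration, duration of the
  first and second probe, number of short C events (strictly shorter than
  `shortCThreshold = 180` s; the cutoff is a convention, exposed as
  configuration, since "short" has no universal definition);
* time-to-event measures: time to the first probe, to the first E1 ("first
  E" means phloem-phase entry, i.e. E1, which by grammar precedes any E2),
  from the first probe to the first E1, and within-probe latencies to the
  first E1 and first E2;
* sustained-event measures: counts of E2 and G events strictly longer than
  `sustainedThreshold = 600` s, the longest E2, and the duration of the E1
  bout immediately preceding the first sustained E2. The 10-min criterion
  for committed ingestion is applied to G as well as E2 — the G threshold is
  an assumption (no separate value is established for xylem), and both are
  one configuration field;
* the percent contribution of E1 to the phloem phase,
  $100 \cdot E1/(E1+E2)$ on total durations — a two-component share; G and
  pd are not part of the phloem phase.

A parameter whose triggering waveform never occurs is missing (`NA`) with a
censoring flag, and group statistics run on the non-missing values — the
share of insects that showed E2 at all is reported separately
(`computeCohort()`), which is why per-parameter sample sizes vary. The
alternative convention, scoring a never-observed event at the recording
length, is available as `censorPolicy = "max_time"` for time-to-event
parameters; it makes estimates conservative rather than conditional.

All of this is interval arithmetic on event tables. Its correctness is
checked against an independently written brute-force oracle that expands a
recording into 100 Hz ticks and recomputes every parameter by scanning the
tick sequence; the test suite requires exact agreement on counts and
agreement within $10^{-9}$ s on durations across hundreds of simulated
recordings.

## The synthetic-data generator

No public corpus of annotated whitefly recordings exists, so the package
carries a first-order semi-Markov simulator (`simulateRecording()`): an
embedded Markov chain over {np, C, G, E1, E2, F} with lognormal sojourn
times, and potential drops inserted inside C sojourns as a marked point
process (rate per minute of pathway, lognormal durations). The lognormal
was chosen because behavioural bout lengths are strictly positive and
right-skewed — the same feature that motivates power transformations in the
analysis. Transitions that would break the grammar (any entry into E2 other
than from E1, E1 exits other than to E2/C/np) carry probability zero by
validity check, so every simulated recording passes `validateGrammar()`
with no errors. Onsets are emitted on the 0.01-s grid, which keeps the
tick-expansion oracle exact.

Four built-in profiles (`builtinProfiles()`) emulate the contrast structure
of host-acceptance experiments: `host_adapted` (mean E2 bout 260 min, short
np, pd-rich pathway), `phloem_rejection` (rare, short E2 with mean 41 min,
repeated salivation and a high E1 share, elevated xylem ingestion),
`delayed_acceptance` (first probe delayed by about 99 min on average, via a
separate distribution for the initial np bout) and `thick_wire` (many short
probes, elevated F). The sojourn means are emulation targets taken from the
magnitudes such studies report; transition probabilities were set once so
that simulated cohorts land in those magnitude ranges (for example, total
E2 above 5 h per 12-h recording for `host_adapted` versus about 1 h for
`phloem_rejection`, and E1 shares near 1% versus tens of percent). No
attempt is made to reproduce exact published letter groupings — the
profiles exist so that group contrasts of realistic size exercise the full
pipeline.

Because a 260-min mean bout cannot fit many times into a 720-min window,
realized event durations are length-biased: long draws are
disproportionately truncated. Sojourn-recovery checks therefore run on the
generator's pre-truncation draw log, attached to each recording as
`attr(rec, "sojournDraws")` — that is the quantity the closed-form
lognormal mean describes. Tests verify recovery of every state's mean
within 10% using 200 recordings, and grammar soundness over 1 000
recordings across all profiles; these problem sizes keep the whole suite in
the low minutes on one core while leaving Monte-Carlo error well inside
the tolerances.

What the simulator does **not** emulate: higher-order dependence (refractory
behaviour after long ingestion), diurnal nonstationarity, annotator noise
such as mislabelled fragments, and oviposition waveforms. Passing tests on
synthetic cohorts therefore demonstrate the correctness of the bookkeeping
and statistics, not the realism of any biological conclusion.

## The statistical workflow

Group comparison (`groupCompare()`) follows the transformation-based
pipeline standard in EPG work:

1. **Transformation selection** (`selectTransform()`): proportion-typed
   parameters (the E1 share, and any parameter declared as a percentage)
   are first mapped by $\arcsin\sqrt{x/100}$; if zeros or non-positive
   values are present, a shift of half the smallest positive value is added
   (recorded in the output — scale-respecting and standard); then the
   Box-Cox exponent is selected from the grid $-3, -2.75, \ldots, 3$ by
   maximizing the profile log-likelihood, with $\lambda = 0$ meaning log.
   The conventional visual histogram/Q-Q inspection is replaced by this
   numeric criterion for reproducibility, and the Shapiro–Wilk statistic of
   the transformed sample is reported for audit. A quarter-step grid is as
   fine as the information in cohort-sized samples supports. For samples
   that are already normal with a small coefficient of variation the
   profile likelihood is nearly flat in $\lambda$ — any value in a wide
   range transforms the data almost affinely — so single-sample $\lambda$
   values should be read with that in mind; recovery tests average the
   selected $\lambda$ over replicates.
2. **Tukey–Kramer all-pairs tests** (`tukeyKramer()`): a one-way
   fixed-effects model on the transformed scale, studentized-range adjusted
   p-values with the Kramer unequal-$n$ correction, pooled error variance on
   $N-k$ degrees of freedom. With one fixed factor and one observation per
   insect, the general mixed-model formulation reduces exactly to this
   one-way analysis, which is what the package implements; no random-effect
   structure is supported. Tests verify the two-group case collapses to the
   pooled t-test and that unbalanced three-group results match an
   independent implementation.
3. **Compact letter display** (`piephoLetters()`): the insert-and-absorb
   algorithm — start from one column holding all groups, split every column
   containing a significant pair, absorb subset columns, assign letters in
   first-appearance order. The defining property (two groups share a letter
   **iff** their pair is not significant) holds for any significance
   pattern, including non-transitive ones where the classic line display
   fails; discontinuous strings like `"ac"` then appear, typically when
   group sizes (hence standard errors) differ strongly. The test suite
   verifies the property by brute force on every run with up to eight
   groups.

Group means are reported on the original scale next to the letters (the
convention that keeps tables interpretable), with transformed-scale means
and confidence intervals in a supplementary sheet. A parameter that cannot
be analysed — a whole group missing, fewer than two usable groups, or a
degenerate constant sample — is flagged and skipped, never thrown.

## Quality accounting and orchestration

Whether a recording is "bad" (noise, leaf detachment, a damaged insect) is
a human judgement; the pipeline takes it as the metadata status
`excluded_bad_recording` and never infers it. `qcSummary()` computes the
two standard efficiencies — recordings completed per insect wired, and
high-quality recordings retained per recording completed — rounding to
whole percent for the report while keeping exact values.

`runPipeline()` ties everything together: it parses and grammar-validates
every completed recording, quarantines failures in an error log while the
run continues, applies the early-G rule, computes the parameter battery,
summarizes cohorts and runs the statistics, and writes a deterministic set
of CSVs plus a YAML manifest. Reruns with the same configuration are
byte-identical. A thin command-line wrapper
(`inst/scripts/epgtool.R`, verbs `simulate`, `params`, `stats`, `qc`,
`run`) exposes the same functions to shell users; all logic lives in the
package.

## Known limitations

* The parameter battery covers the standard reported set, not the full
  ~100-parameter workbook tradition; extensions are straightforward on top
  of `effectiveEvents()`.
* Time-to-event parameters are analysed as plain durations conditional on
  occurrence (or clamped at the window under `max_time`); no survival
  analysis of censored latencies is attempted.
* The native binary layout of proprietary annotation exports is not parsed;
  the package defines an open two-column dialect that such tools can
  trivially emit.
* E2 sub-variants and oviposition waveforms are not distinguished.
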