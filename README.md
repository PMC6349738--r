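# epgtools

Analysis of electrical penetration graph (EPG) recordings of sap-sucking
insect feeding behaviour, built around the whitefly (*Bemisia tabaci*)
waveform repertoire.

EPG tethers an insect into a plant–insect electrical circuit and records
voltage fluctuations while it probes; manual annotation turns a 12-h
recording into an ordered sequence of behavioural waveforms — np
(non-probing), C (stylet pathway), pd (potential drop / intracellular
puncture), G (xylem ingestion), E1 (phloem salivation), E2 (phloem
ingestion) and F (derailed stylet mechanics). Researchers comparing host
plants, insect species or tethering methods need the same chain of steps
every time: validate the annotation grammar, segment probes, apply the
early-xylem reclassification rule, compute the per-insect EPG parameter
battery, and compare groups with transformation-based statistics.
`epgtools` packages that chain, end to end and tested.

## What it computes

* **Annotation I/O and grammar** — an open two-column dialect (waveform
  label, onset seconds, terminal `end` row); grammar validation (every E2
  preceded by E1; pd only inside probes; probes open with pathway).
* **Feeding model** — probe segmentation; relabelling of xylem-like G
  waveforms that start < 10 min into a probe as F; pathway runs merged
  across embedded potential drops so event counts are well defined.
* **Parameter battery** — per-waveform totals, counts and mean durations;
  probe measures; time-to-event latencies (first probe, first E1, first E2,
  within-probe versions); sustained (> 10 min) E2 and G counts; longest E2;
  the percent contribution of E1 to the phloem phase
  `100 * E1 / (E1 + E2)`. Insects lacking a waveform contribute missing
  values, with the share of insects showing E2 reported separately.
* **Statistics** — per parameter: optional arcsine pre-transformation for
  percentages, Box-Cox exponent selected from the grid −3 … 3 (step 0.25)
  by profile log-likelihood, Tukey-Kramer all-pairs comparisons with the
  unequal-*n* correction, and the Piepho insert-and-absorb compact letter
  display (two groups share a letter iff not significantly different;
  discontinuous strings such as `ac` are legitimate).
* **Synthetic cohorts** — a semi-Markov simulator with lognormal sojourn
  times and pd bursts inside pathway, plus four built-in feeding phenotypes
  (`host_adapted`, `phloem_rejection`, `delayed_acceptance`, `thick_wire`)
  so the whole pipeline can be exercised without data.
* **Orchestration** — `runPipeline()` turns an annotation directory plus a
  metadata table into parameter/cohort/statistics CSVs, a QC report and a
  manifest; `inst/scripts/epgtool.R` wraps it for the shell.

## Worked example

```r
library(epgtools)

rec <- readAnnotation(c("np\t0",  "C\t120", "pd\t300", "C\t306",
                        "E1\t900", "E2\t960", "np\t4000", "G\t4600",
                        "np\t7000", "end\t43200"))
rec
#> EpgRecording 'recording': 9 events over 12.0 h
#>   time budget (min): np=615.3  C=12.9  pd=0.1  G=40.0  E1=1.0  E2=50.7  F=0.0

rec <- reclassifyEarlyG(rec)          # early-probe G -> F (none here)
v <- computeInsectParameters(rec)$values
round(v[c("n_probes", "t_to_first_probe", "dur_total_E2", "dur_mean_C",
          "n_pd", "n_sustained_E2", "pct_E1_phloem")], 2)
#>         n_probes t_to_first_probe     dur_total_E2       dur_mean_C
#>             2.00           120.00          3040.00           774.00
#>             n_pd   n_sustained_E2    pct_E1_phloem
#>             1.00             1.00             1.94
```

Reading: this insect made 2 probes, the first starting 120 s into the
recording; it ingested phloem sap for 3 040 s in one sustained (> 10 min)
bout; the mean pathway event lasts 774 s because the two C segments around
the potential drop count as one event (120–900 s minus the 6-s pd); and
salivation contributed 1.94 % of the phloem phase — the signature of easy
phloem acceptance.

A full synthetic experiment:

```r
dir <- tempfile()
simulateToDir(builtinProfiles()[c("host_adapted", "phloem_rejection")],
              n = 15, seed = 7000, dir = dir)
bundle <- runPipeline(runConfig(factor = "group"), dir)
subset(bundle$stats, parameter == "dur_total_E2",
       c(group, n, mean_original, letters))
```

which assigns different letters to the two phenotypes for total phloem
ingestion (about 8 h vs about 1 h per 12-h recording).

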