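Package: epgtools
Title: Electrical Penetration Graph Feeding-Behavior Analysis for Whiteflies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing electrical penetration graph (EPG) recordings
    of sap-sucking insect feeding behaviour. Reads and validates waveform
    annotation files (non-probing, pathway, potential drop, xylem feeding,
    phloem salivation, phloem ingestion, derailed stylet mechanics), segments
    probes, applies the early-xylem-to-F reclassification rule, computes the
    standard per-insect EPG parameter battery (waveform totals, event counts
    and mean durations, time-to-event measures, sustained-event counts, the
    phloem-phase salivation share), and compares experimental groups with
    Box-Cox transformation selection, Tukey-Kramer all-pairs tests and the
    Piepho insert-and-absorb compact letter display. A semi-Markov feeding
    simulator generates grammar-valid synthetic 12-hour recordings for testing
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation-io.R'
    'feeding-model.R'
    'parameters.R'
    'simulate.R'
    'qc.R'
    'stats.R'
    'pipeline.R'
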