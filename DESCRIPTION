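Package: dimsMarkers
Title: Presence/Absence Metabolite Marker Discovery for Direct-Infusion
    Mass Spectrometry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering presence/absence metabolite markers
    from direct-infusion electrospray mass spectrometry (DIMS) cohort data.
    Covers profile-spectrum peak detection, internal lock-mass recalibration,
    intensity normalization against a spiked internal standard,
    technical-replicate consensus filtering, adduct-aware putative annotation
    of accurate masses against a compound library at a ppm tolerance,
    per-group detection frequencies, and threshold-based marker selection
    with an exact test for frequency differences. Includes a synthetic-cohort
    generator that emulates a multi-group clinical DIMS study design so that
    every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: MassSpectrometry, Metabolomics, BiomarkerDiscovery, Annotation
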