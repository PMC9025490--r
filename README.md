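# dimsMarkers

Presence/absence metabolite marker discovery for direct-infusion mass
spectrometry (DIMS) cohorts, in Bioconductor-style R.

## The problem

In untargeted DIMS metabolomics a sample is infused straight into the
ion source and each acquisition reduces to a list of (m/z, intensity)
ions in the 50–1000 Da range. For cohort studies — the motivating case
is blood plasma from pregnant women grouped by trimester and by whether
preeclampsia (PE) later developed (group sizes 25 / 3 / 20 / 31, two
technical replicates per sample) — the question is not differential
abundance but **detection frequency**: in what fraction of each group's
samples is a putative metabolite seen at all, and which metabolites are
(nearly) absent from controls yet frequent in cases?

`dimsMarkers` implements the complete workflow for that question:

* profile-spectrum **peak detection** (≥ 2 points per peak, SNR ≥ 1,
  relative/absolute intensity cutoffs 0.01 % and 100 counts);
* internal **lock-mass recalibration** (linear ppm-vs-m/z fit on
  characteristic high-intensity ions of known mass);
* intensity **normalization** against a spiked internal standard
  (losartan, C22H23ClN6O, [M+H]+ at m/z 423.169) or total ion current;
* the **technical-replicate consensus rule** — an ion counts only if its
  m/z is registered in *both* replicates (5 ppm matching, generalizes
  to R replicates);
* adduct-aware **putative annotation** of consensus ions against a
  compound library at **2 ppm**, for [M+H]+, [M+Na]+ and [M+K]+
  (`m/z = (M + s)/z` with electron-corrected cation masses);
* **per-group frequencies** (`detected count / group size`) and
  **marker selection**: frequency ≤ `maxControlFrequency` in every
  control group and ≥ `minCaseFrequency` in every case group, with an
  optional two-sided Fisher exact test (by hypergeometric enumeration)
  as a significance filter.

Because no raw spectra are publicly deposited for this design, the
package includes a first-class **synthetic cohort generator**
(`studyDesign()` / `generateCohort()`) whose defaults mirror the study:
group sizes, two replicates, 1 ppm mass error, H/Na/K adducts, spiked
losartan, noise peaks, replicate dropout, optional calibration drift,
and the published nine-metabolite PE panel at its published per-group
frequencies as prevalence. Every pipeline stage is tested against the
generator's planted truth.

## Worked example

```r
library(dimsMarkers)

# losartan internal standard: neutral mass and protonated m/z
adductMz(monoisotopicMass("C22H23ClN6O"), "[M+H]+")
#> [1] 423.1695

# simulate the four-group study and run the whole pipeline
res <- runDemo(outDir = "demo-run", seed = 11)
head(subset(as.data.frame(res$frequencies), group == "group2"))
#>    compound_id  group detected_count group_size frequency
#> 11 HMDB0002282 group2              3          3 1.0000000
#> 12 HMDB0003689 group2              3          3 1.0000000
#> 13 HMDB0013327 group2              1          3 0.3333333
#> 14 HMDB0006766 group2              2          3 0.6666667
#> ...
as.data.frame(res$markers)[, 1:3]
#>   compound_id frequency_group1 frequency_group2
#> 1 HMDB0002282             0.04        1.0000000
#> 2 HMDB0003689             0.08        1.0000000
#> 3 HMDB0004220             0.00        0.6666667
#> 4 HMDB0001445             0.00        1.0000000
#> 5 HMDB0006557             0.00        1.0000000
#> 6 HMDB0011764             0.00        1.0000000
#> 7 HMDB0000381             0.04        0.6666667
```

`runDemo()` writes `annotations.tsv`, `frequencies.tsv` (one row per
metabolite, per-group frequency to 2 dp plus detected counts and group
sizes), `markers.tsv`, the config and a provenance record into the run
directory; identical seeds give byte-identical reports. The marker rows
above are the metabolites that pass the demo rule — control (group 1)
frequency ≤ 0.15 and case (group 2) frequency ≥ 0.5. With only three
first-trimester PE samples the panel membership fluctuates between
seeds; the methods vignette discusses this power limitation.

File-based cohorts work the same way through a YAML config
(`pipelineConfig()`, `runPipeline()`) pointing at a replicate manifest
and two-column peak-list files.

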