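---
title: "Presence/absence marker discovery from direct-infusion MS cohorts"
author: "dimsMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence/absence marker discovery from direct-infusion MS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimsMarkers)
```

## The analytical problem

Direct-infusion electrospray mass spectrometry (DIMS) records a whole
metabolome snapshot without chromatographic separation: each acquisition
reduces to a list of (m/z, intensity) ions between 50 and 1000 Da. In a
cohort setting — here, blood plasma from pregnant women grouped by
trimester and by whether preeclampsia (PE) later developed — the
analysis is not quantitative comparison but *presence/absence*: which
putative metabolites are detected in which fraction of each clinical
group, and which are absent from controls yet common in cases.

`dimsMarkers` implements that workflow end to end:

1. **Peak detection** on profile spectra (points per peak ≥ 2, SNR ≥ 1,
   relative/absolute intensity cutoffs 0.01% and 100 counts).
2. **Internal recalibration** of the m/z axis against characteristic
   high-intensity ions of known mass.
3. **Normalization** of intensities against a spiked internal standard
   (losartan, C~22~H~23~ClN~6~O, [M+H]^+^ at m/z 423.169) or the total
   ion current.
4. **Technical-replicate consensus**: an ion counts as detected in a
   sample only if registered in *both* technical replicates.
5. **Putative annotation** of consensus ions against a compound library
   at a 2 ppm tolerance, considering [M+H]^+^, [M+Na]^+^ and [M+K]^+^
   adducts.
6. **Per-group detection frequencies** and **marker selection** by a
   thresholded presence/absence rule, with an optional exact test.

## Mass arithmetic

Annotation rests on three pieces of arithmetic, all in `mass-calc`:

* the neutral monoisotopic mass of a formula,
  $M = \sum_e n_e \, m_e$, with IUPAC most-abundant-isotope masses
  embedded to ≥ 6 decimals (a 2 ppm window at m/z 600 is 0.0012 Da, so
  table precision must not consume it);
* the adduct m/z, $(M + s)/z$, with *electron-corrected* cation masses
  (1.007276, 22.989218, 38.963158 Da for H^+^, Na^+^, K^+^ — the
  0.00055 Da electron matters at the ppm scale);
* the signed relative error
  $\mathrm{ppm} = (m_\mathrm{obs} - m_\mathrm{theo}) / m_\mathrm{theo}
  \times 10^6$.

```{r mass}
adductMz(monoisotopicMass("C22H23ClN6O"), "[M+H]+")   # losartan, 423.169
adductMz(595.59, "[M+Na]+")                           # sodiated ceramide
```

Only singly charged H/Na/K adducts are built in; `adductSpec()` extends
the registry. Isotope envelopes, multiple charging and neutral losses
are out of scope.

## The synthetic cohort generator

No raw spectra are publicly deposited for this study design, so the
package ships a generator whose defaults *are* the study conditions:
four groups of 25, 3, 20 and 31 samples, two technical replicates per
sample, m/z range 50–1000 Da, Gaussian mass error with SD 1 ppm (the
instrument class is specified to ≤ 3 ppm), H/Na/K adduct formation, a
spiked losartan internal standard in every spectrum, and the published
nine-metabolite panel at its published per-group detection frequencies
as prevalence. The adduct under which each panel compound is emitted is
inferred from its published observed m/z (nearest cation shift within
0.08 Da; rows whose observed mass fits no H/Na/K shift — a known
inconsistency of the printed table — default to [M+H]^+^ and are simply
not re-found by annotation, never special-cased).

Presence is drawn once per sample from the group prevalence; replicate
dropout is layered on top (each truly present ion is missed in any one
replicate with probability 0.1 by default). This two-level model is
what gives the both-replicates consensus rule something to do: sample
truth is fixed, replicate detection is noisy around it.

Where the study reports no value, defaults were chosen once as
plausible for plasma DIMS and documented here: log-normal intensities
(meanlog `log(1e4)`, sdlog 1) for analytes; noise-peak intensities from
the low tail of that model (meanlog shifted down by 3) so the relative
intensity cutoff is exercised; 200 uniform noise peaks per spectrum — a
deliberately desk-scale density, far below the ~14,000 ions of a real
acquisition; internal standard at meanlog `log(1e6)`, sdlog 0.2.
Optional linear calibration drift (ppm = intercept + slope × m/z) gives
the recalibration stage a realistic error to remove; default 0.

What the generator does *not* emulate: isotope envelopes, in-source
fragmentation, detector saturation, correlated (batch) mass drift and
intensity structure between co-eluting metabolites. Passing tests on
synthetic cohorts therefore demonstrate the correctness of the
pipeline's logic under the stated statistical model, not instrument
realism.

```{r cohort}
cohort <- generateCohort(studyDesign(seed = 1))
length(cohort$peakLists)      # 79 samples x 2 technical replicates
cohort$peakLists[[1]]
```

## Numerical and design choices

* **Peak detection** estimates noise as a scaled sliding-window median
  absolute deviation (robust to sparse peaks; the original vendor
  software does not document its estimator), requires the apex's
  contiguous above-noise run to span `minPointsPerPeak` points, and
  refines the apex by 3-point parabolic interpolation. Reported apex
  intensities never fall below either cutoff.
* **Recalibration** fits ppm error against m/z by least squares on the
  matched references (a constant shift with a single match) and only
  accepts a model that does not increase the mean absolute reference
  error — degenerate geometries fall back to the constant shift or to
  identity. Reference ions are restricted to the top intensity decile,
  the operational meaning of "characteristic high-intensity peaks".
* **Replicate matching tolerance** is not stated in the source
  workflow; the default is 5 ppm — above the 3 ppm instrument accuracy,
  far below typical peak spacing — and configurable. Pairing is greedy
  by increasing ppm difference with deterministic tie-breaks, which
  makes consensus symmetric in its arguments; the consensus m/z is the
  intensity-weighted mean, hence bracketed by its contributors. The
  rule generalizes to R replicates by requiring presence in all R.
* **Annotation** keeps *all* candidates within tolerance (identification
  is putative; collapsing to best-hit would discard real ambiguity) and
  uses an interval query over the sorted theoretical m/z grid that is
  provably equivalent to the all-pairs scan (tested against one).
* **The intensity cutoffs** "0.01% and 100" are mapped 0.01% → relative
  (fraction of base peak), 100 → absolute (counts); both are exposed as
  parameters since the pairing is ambiguous in the source description.
* **The selection rule** is parameterized. The literal "absent from the
  healthy group" is `maxControlFrequency = 0`; but the published panel
  itself shows control frequencies up to 0.12, so the demo
  configuration uses `maxControlFrequency = 0.15` with
  `minCaseFrequency = 0.5` (control group 1 vs case group 2 — the
  first-trimester prediction question), under which the printed
  nine-row frequency matrix is selected in full. Case and control group
  sets are free parameters, so group 2 alone or groups 2∪4 are both
  expressible. The exact test (`frequencyDifferenceTest()`, two-sided
  Fisher by hypergeometric enumeration) is an optional filter
  (`alpha`), off by default because the source workflow applies none;
  Benjamini–Hochberg adjustment is available but not silent.
* **Determinism**: every stochastic step draws from an RNG seeded
  explicitly; the generator restores the caller's RNG state. A pipeline
  run writes its config (with seed) and an md5 of it into
  `provenance.json`, and identical configs give byte-identical reports.

## Statistical power at the study's group sizes

With three first-trimester PE samples (group 2), presence/absence
frequencies are extremely coarse (0, 1/3, 2/3, 1), and a marker with
case prevalence 0.67 clears a 0.5 threshold only when at least 2 of 3
samples detect it — a run-to-run coin flip once replicate dropout is
added. The test suite documents this as a power property, not a
failure: recovery is asserted at ≥ 95% only for planted markers with
case probability 0.9 against the n = 31 case group, and null
metabolites (equal prevalence everywhere) are required to slip through
the thresholded rule plus exact-test filter in ≤ 5% of runs. At n = 3
the same assertions would not hold for any method.

Simulation sizes throughout the suite (100 seeded cohorts for the
recovery property, 200 for the generator's binomial calibration check,
100 random libraries for the annotation oracle) were chosen as the
smallest sizes at which the binomial assertions above are sharp.

## Degenerate inputs and edge behaviour

Empty peak-list files load as empty `PeakList`s with a warning; traces
shorter than the minimum peak width detect nothing, with a warning; a
recalibration with zero matched references returns its input unchanged,
with a warning. Library records lacking both formula and mass, duplicate
compound ids, negative intensities, unknown samples in annotations,
empty groups, overlapping control/case sets and unknown config keys are
all hard errors that name the offending record. A library record whose
stated mass disagrees with its formula by > 0.01 Da is flagged
`inconsistent` rather than dropped, because printed library masses are
routinely 2-decimal.

## Known limitations

Accurate-mass-only annotation cannot distinguish isomers or
near-isobars; everything downstream inherits that ambiguity, which is
why detection is compound-level ("any candidate annotation") rather
than ion-level. The replicate-consensus and annotation stages assume
centroid data of modest density; at very high peak density the greedy
5 ppm pairing would need a narrower tolerance. The real study's
cohort-level totals (14,087 ions, 1,234 putative metabolites) depend on
raw spectra that were never deposited and are out of reach of any
reimplementation; this package reproduces the workflow's arithmetic,
rules and statistical behaviour, not those counts.
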