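#' @importFrom stats rnorm runif rlnorm
NULL

#' CohortDesign: parameters of a synthetic DIMS cohort
#'
#' Describes a multi-group direct-infusion MS study design: group sizes, a
#' metabolite panel with per-group detection probabilities and the adduct
#' each metabolite is observed as, technical replication, instrument mass
#' error, replicate dropout, chemical-noise density, a log-normal intensity
#' model, a spiked internal standard, and an optional linear m/z-dependent
#' calibration drift. [generateCohort()] turns a design into peak lists
#' plus the generating truth.
#'
#' @slot groups named integer, samples per group.
#' @slot panel a [CompoundLibrary-class] of panel metabolites.
#' @slot panelAdduct named character, adduct name per panel compound.
#' @slot prevalence numeric matrix (compounds x groups) of per-sample
#'   detection probabilities.
#' @slot replicatesPerSample integer >= 2.
#' @slot massErrorPpmSd Gaussian m/z error SD in ppm (default 1).
#' @slot replicateDropoutProb probability a truly present ion is missed in
#'   any one technical replicate.
#' @slot noisePeaksPerSpectrum chemical-noise peaks drawn uniformly over
#'   the m/z range in every replicate spectrum.
#' @slot intensityMeanlog,intensitySdlog log-normal intensity model for
#'   panel ions (meanlog/sdlog of `rlnorm`).
#' @slot noiseIntensityMeanlog meanlog of noise-peak intensities (low tail
#'   of the intensity model).
#' @slot internalStandard list: `compound_id`, `name`, `formula`, `adduct`,
#'   `intensityMeanlog`, `intensitySdlog`.
#' @slot mzRange instrument m/z range, Da (default 50-1000).
#' @slot driftPpm length-2 numeric `c(intercept, slope)`: ppm offset applied
#'   to every spectrum as `intercept + slope * mz` (default no drift).
#' @slot seed integer RNG seed.
#'
#' @aliases CohortDesign-class
#' @exportClass CohortDesign
setClass("CohortDesign",
  representation(
    groups = "integer",
    panel = "CompoundLibrary",
    panelAdduct = "character",
    prevalence = "matrix",
    replicatesPerSample = "integer",
    massErrorPpmSd = "numeric",
    replicateDropoutProb = "numeric",
    noisePeaksPerSpectrum = "integer",
    intensityMeanlog = "numeric",
    intensitySdlog = "numeric",
    noiseIntensityMeanlog = "numeric",
    internalStandard = "list",
    mzRange = "numeric",
    driftPpm = "numeric",
    seed = "integer"
  )
)

setValidity("CohortDesign", function(object) {
  msg <- character(0)
  if (!length(object@groups) || is.null(names(object@groups)) ||
      any(object@groups < 1L))
    msg <- c(msg, "groups must be a named integer vector with n >= 1")
  if (object@replicatesPerSample < 2L)
    msg <- c(msg, "replicatesPerSample must be >= 2")
  p <- object@prevalence
  if (nrow(p) != nrow(object@panel) ||
      !identical(rownames(p), object@panel$compound_id))
    msg <- c(msg, "prevalence rows must match panel compound_ids")
  if (!identical(colnames(p), names(object@groups)))
    msg <- c(msg, "prevalence columns must match group labels")
  if (length(p) && (any(p < 0) || any(p > 1)))
    msg <- c(msg, "prevalence values must be probabilities in [0, 1]")
  if (object@replicateDropoutProb < 0 || object@replicateDropoutProb > 1)
    msg <- c(msg, "replicateDropoutProb must be in [0, 1]")
  if (object@massErrorPpmSd < 0)
    msg <- c(msg, "massErrorPpmSd must be >= 0")
  if (object@noisePeaksPerSpectrum < 0L)
    msg <- c(msg, "noisePeaksPerSpectrum must be >= 0")
  if (length(object@mzRange) != 2L || object@mzRange[1] >= object@mzRange[2])
    msg <- c(msg, "mzRange must be an increasing length-2 numeric")
  if (length(object@driftPpm) != 2L)
    msg <- c(msg, "driftPpm must be c(intercept, slope)")
  if (!identical(names(object@panelAdduct), object@panel$compound_id))
    msg <- c(msg, "panelAdduct must be named by panel compound_ids")
  if (nrow(object@panel)) {
    theo <- adductMz(object@panel$neutral_mass,
                     unname(object@panelAdduct))
    if (any(theo < object@mzRange[1] | theo > object@mzRange[2]))
      msg <- c(msg, "panel adduct m/z values must lie inside mzRange")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortDesign
#'
#' @param groups named integer vector of group sizes.
#' @param panel a [CompoundLibrary-class] (or data.frame coercible to one).
#' @param prevalence matrix of per-sample detection probabilities,
#'   compounds x groups (rownames = compound ids, colnames = group labels).
#' @param adduct adduct name per panel compound (recycled).
#' @param replicatesPerSample technical replicates per sample (default 2).
#' @param massErrorPpmSd Gaussian mass error SD, ppm (default 1; the
#'   instrument class is specified to <= 3 ppm accuracy).
#' @param replicateDropoutProb per-replicate miss probability for truly
#'   present ions (default 0.1).
#' @param noisePeaksPerSpectrum noise peaks per replicate spectrum
#'   (default 200).
#' @param intensityMeanlog,intensitySdlog log-normal intensity model
#'   (defaults `log(1e4)` and 1).
#' @param noiseIntensityMeanlog meanlog for noise intensities (default
#'   `log(1e4) - 3`, the low tail of the intensity model).
#' @param internalStandard list describing the spiked standard; defaults to
#'   losartan, `C22H23ClN6O`, observed as `[M+H]+` at high intensity.
#' @param mzRange instrument range (default `c(50, 1000)`).
#' @param driftPpm linear calibration drift `c(intercept, slope)` in ppm
#'   (default none).
#' @param seed integer RNG seed.
#' @return A validated [CohortDesign-class].
#' @export
cohortDesign <- function(groups, panel, prevalence,
                         adduct = "[M+H]+",
                         replicatesPerSample = 2L,
                         massErrorPpmSd = 1.0,
                         replicateDropoutProb = 0.1,
                         noisePeaksPerSpectrum = 200L,
                         intensityMeanlog = log(1e4),
                         intensitySdlog = 1.0,
                         noiseIntensityMeanlog = log(1e4) - 3,
                         internalStandard = list(
                           compound_id = "IS_LOSARTAN", name = "losartan",
                           formula = "C22H23ClN6O", adduct = "[M+H]+",
                           intensityMeanlog = log(1e6), intensitySdlog = 0.2),
                         mzRange = c(50, 1000),
                         driftPpm = c(0, 0),
                         seed = 1L) {
  if (!is(panel, "CompoundLibrary")) panel <- CompoundLibrary(panel)
  groups <- structure(as.integer(groups), names = names(groups))
  prevalence <- as.matrix(prevalence)
  if (is.null(rownames(prevalence))) rownames(prevalence) <- panel$compound_id
  if (is.null(colnames(prevalence))) colnames(prevalence) <- names(groups)
  prevalence <- prevalence[panel$compound_id, names(groups), drop = FALSE]
  panelAdduct <- structure(rep_len(adduct, nrow(panel)),
                           names = panel$compound_id)
  new("CohortDesign", groups = groups, panel = panel,
      panelAdduct = panelAdduct, prevalence = prevalence,
      replicatesPerSample = as.integer(replicatesPerSample),
      massErrorPpmSd = massErrorPpmSd,
      replicateDropoutProb = replicateDropoutProb,
      noisePeaksPerSpectrum = as.integer(noisePeaksPerSpectrum),
      intensityMeanlog = intensityMeanlog, intensitySdlog = intensitySdlog,
      noiseIntensityMeanlog = noiseIntensityMeanlog,
      internalStandard = internalStandard,
      mzRange = as.numeric(mzRange), driftPpm = as.numeric(driftPpm),
      seed = as.integer(seed))
}

# nearest built-in adduct whose shift explains observed - neutral, within
# tolDa; printed low-precision masses that fit no cation default to [M+H]+.
.inferAdduct <- function(neutralMass, observedMz, tolDa = 0.08) {
  ad <- defaultAdducts()
  vapply(seq_along(neutralMass), function(i) {
    d <- abs((observedMz[i] - neutralMass[i]) - ad$mass_shift)
    if (min(d) <= tolDa) ad$name[which.min(d)] else "[M+H]+"
  }, character(1))
}

#' The study-shaped cohort design
#'
#' A [CohortDesign-class] mirroring the preeclampsia DIMS study: four
#' groups of 25, 3, 20 and 31 samples (first-trimester control,
#' first-trimester pre-PE, third-trimester control, third-trimester PE),
#' two technical replicates per sample, m/z range 50-1000 Da, 1 ppm mass
#' error SD, H+/Na+/K+ adducts, losartan spiked as internal standard, and
#' the nine-metabolite panel at its published per-group detection
#' frequencies as prevalence. The adduct for each panel compound is
#' inferred from its published observed m/z.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [cohortDesign()].
#' @return A [CohortDesign-class].
#' @examples
#' d <- studyDesign(seed = 7)
#' d@groups
#' @export
studyDesign <- function(seed = 1L, ...) {
  panel <- pePanelLibrary()
  obs <- as.data.frame(pePanelFrequencies())
  prev <- matrix(0, nrow(panel), 4,
                 dimnames = list(panel$compound_id,
                                 c("group1", "group2", "group3", "group4")))
  for (g in colnames(prev)) {
    sub <- obs[obs$group == g, ]
    prev[sub$compound_id, g] <- sub$frequency
  }
  firstObs <- obs[match(panel$compound_id, obs$compound_id), ]
  adduct <- .inferAdduct(panel$neutral_mass, firstObs$observed_mz)
  cohortDesign(groups = c(group1 = 25L, group2 = 3L,
                          group3 = 20L, group4 = 31L),
               panel = panel, prevalence = prev, adduct = adduct,
               seed = seed, ...)
}

#' Generate a synthetic DIMS cohort
#'
#' Draws, for every sample, the true presence of each panel metabolite from
#' its group prevalence; a present metabolite emits one peak per technical
#' replicate (independently missed with the replicate dropout probability)
#' at its theoretical adduct m/z perturbed by Gaussian ppm error. Uniform
#' noise peaks are added, the internal standard appears in every replicate,
#' and the configured calibration drift is applied to every spectrum.
#' Identical designs (including seed) give identical output.
#'
#' @param design a [CohortDesign-class].
#' @return A list with elements
#' \describe{
#'   \item{peakLists}{named list of [PeakList-class], one per
#'     sample x replicate, names `"<sample>_<replicate>"`.}
#'   \item{manifest}{`DataFrame` with `sample_id`, `group`, `replicate_id`.}
#'   \item{truth}{list: `presence` (logical matrix samples x compounds),
#'     `peaks` (per-peak origin table: sample, replicate, m/z, source
#'     compound id or `"noise"`/the IS id, adduct), and `drift` (per
#'     spectrum, the applied ppm drift coefficients).}
#' }
#' @examples
#' cohort <- generateCohort(studyDesign(seed = 1))
#' length(cohort$peakLists)
#' @export
generateCohort <- function(design) {
  validObject(design)
  istd <- design@internalStandard
  isTheo <- adductMz(monoisotopicMass(istd$formula), istd$adduct)
  panelTheo <- adductMz(design@panel$neutral_mass, unname(design@panelAdduct))
  nComp <- nrow(design@panel)
  compIds <- design@panel$compound_id

  .withSeed(design@seed, {
    sampleGroups <- rep(names(design@groups), design@groups)
    sampleIds <- sprintf("S%03d", seq_along(sampleGroups))
    repIds <- sprintf("TR%d", seq_len(design@replicatesPerSample))

    presence <- matrix(FALSE, length(sampleIds), nComp,
                       dimnames = list(sampleIds, compIds))
    peakLists <- list()
    truthPeaks <- vector("list", length(sampleIds) * length(repIds))
    manifest <- data.frame(
      sample_id = rep(sampleIds, each = length(repIds)),
      group = rep(sampleGroups, each = length(repIds)),
      replicate_id = rep(repIds, times = length(sampleIds)),
      stringsAsFactors = FALSE)

    k <- 0L
    for (si in seq_along(sampleIds)) {
      prob <- design@prevalence[, sampleGroups[si]]
      present <- runif(nComp) < prob
      presence[si, ] <- present
      for (ri in seq_along(repIds)) {
        k <- k + 1L
        keep <- which(present &
                        runif(nComp) >= design@replicateDropoutProb)
        mzPanel <- panelTheo[keep] *
          (1 + rnorm(length(keep), 0, design@massErrorPpmSd) * 1e-6)
        intPanel <- rlnorm(length(keep), design@intensityMeanlog,
                           design@intensitySdlog)
        mzIS <- isTheo * (1 + rnorm(1, 0, design@massErrorPpmSd) * 1e-6)
        intIS <- rlnorm(1, istd$intensityMeanlog, istd$intensitySdlog)
        nN <- design@noisePeaksPerSpectrum
        mzNoise <- runif(nN, design@mzRange[1], design@mzRange[2])
        intNoise <- rlnorm(nN, design@noiseIntensityMeanlog,
                           design@intensitySdlog)
        mzAll <- c(mzPanel, mzIS, mzNoise)
        intAll <- c(intPanel, intIS, intNoise)
        source <- c(compIds[keep], istd$compound_id, rep("noise", nN))
        adduct <- c(unname(design@panelAdduct[keep]), istd$adduct,
                    rep(NA_character_, nN))
        # linear calibration drift, then clamp to the instrument range
        drift <- design@driftPpm[1] + design@driftPpm[2] * mzAll
        mzObs <- pmin(pmax(mzAll * (1 + drift * 1e-6), design@mzRange[1]),
                      design@mzRange[2])
        o <- order(mzObs)
        key <- paste(sampleIds[si], repIds[ri], sep = "_")
        peakLists[[key]] <- PeakList(mzObs[o], intAll[o],
                                     sampleIds[si], repIds[ri])
        truthPeaks[[k]] <- data.frame(
          sample_id = sampleIds[si], replicate_id = repIds[ri],
          mz = mzObs[o], source = source[o], adduct = adduct[o],
          stringsAsFactors = FALSE)
      }
    }
    list(peakLists = peakLists,
         manifest = DataFrame(manifest),
         truth = list(presence = presence,
                      peaks = do.call(rbind, truthPeaks),
                      drift = data.frame(
                        spectrum = names(peakLists),
                        intercept_ppm = design@driftPpm[1],
                        slope_ppm_per_da = design@driftPpm[2],
                        stringsAsFactors = FALSE)))
  })
}

#' Render a centroid peak list as a profile-mode trace
#'
#' Sums Gaussian peak shapes (FWHM = `peakWidth`, apex height = centroid
#' intensity) on a uniform m/z grid and adds white baseline noise. Used to
#' exercise the profile-mode peak-detection stage.
#'
#' @param peaks a [PeakList-class] (or two-column data.frame).
#' @param peakWidth full width at half maximum of each peak, Da.
#' @param baselineNoiseSd SD of additive Gaussian baseline noise.
#' @param gridStep grid spacing, Da; must be smaller than `peakWidth`.
#' @param mzRange grid range; defaults to the peak range padded by
#'   4 peak widths (50-1000 for an empty list).
#' @param seed RNG seed for the baseline noise.
#' @return A data.frame with columns `mz` and `intensity`.
#' @examples
#' tr <- generateProfileSpectrum(PeakList(400.2, 1e5), gridStep = 0.005)
#' tr$mz[which.max(tr$intensity)]
#' @export
generateProfileSpectrum <- function(peaks, peakWidth = 0.02,
                                    baselineNoiseSd = 0,
                                    gridStep = 0.005,
                                    mzRange = NULL, seed = 1L) {
  if (peakWidth <= 0 || gridStep <= 0)
    stop("peakWidth and gridStep must be positive")
  if (gridStep >= peakWidth)
    stop("gridStep must be smaller than peakWidth")
  if (is(peaks, "PeakList")) peaks <- as.data.frame(peaks)
  if (is.null(mzRange)) {
    mzRange <- if (nrow(peaks)) range(peaks$mz) + c(-4, 4) * peakWidth
               else c(50, 1000)
  }
  grid <- seq(mzRange[1], mzRange[2], by = gridStep)
  y <- numeric(length(grid))
  sigma <- peakWidth / (2 * sqrt(2 * log(2)))
  for (i in seq_len(nrow(peaks))) {
    lo <- max(1L, floor((peaks$mz[i] - 5 * sigma - mzRange[1]) / gridStep) + 1L)
    hi <- min(length(grid),
              ceiling((peaks$mz[i] + 5 * sigma - mzRange[1]) / gridStep) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    y[idx] <- y[idx] +
      peaks$intensity[i] * exp(-(grid[idx] - peaks$mz[i])^2 / (2 * sigma^2))
  }
  if (baselineNoiseSd > 0)
    y <- .withSeed(seed, y + rnorm(length(y), 0, baselineNoiseSd))
  data.frame(mz = grid, intensity = y)
}
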