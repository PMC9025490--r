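#' @importFrom utils packageVersion
NULL

.configSkeleton <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    write_peak_lists = FALSE,
    stages = list(simulate = TRUE, calibrate = TRUE, normalize = TRUE,
                  consensus = TRUE, annotate = TRUE, frequencies = TRUE,
                  select = TRUE),
    input = list(manifest = NULL, library = NULL,
                 internal_standard_mz = NULL),
    simulate = list(mass_error_ppm_sd = 1.0,
                    replicate_dropout_prob = 0.1,
                    noise_peaks_per_spectrum = 200L,
                    drift_intercept_ppm = 0,
                    drift_slope_ppm_per_da = 0),
    tolerances = list(replicate_match_ppm = 5,
                      annotation_ppm = 2,
                      calibration_match_ppm = 10,
                      internal_standard_ppm = 5),
    calibration = list(n_reference_ions = 5L),
    normalization = list(method = "internal_standard", fallback_tic = TRUE),
    adducts = c("[M+H]+", "[M+Na]+", "[M+K]+"),
    rule = list(control_groups = "group1", case_groups = "group2",
                max_control_frequency = 0.15, min_case_frequency = 0.5,
                alpha = NULL, level = "sample")
  )
}

.checkKeys <- function(config, skeleton, path = "") {
  extra <- setdiff(names(config), names(skeleton))
  if (length(extra))
    stop("unknown pipeline-config key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(config)) {
    if (is.list(skeleton[[k]]) && !is.null(names(skeleton[[k]])) &&
        !is.null(config[[k]])) {
      if (!is.list(config[[k]]))
        stop("config key '", path, k, "' must be a mapping")
      .checkKeys(config[[k]], skeleton[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

# fill missing keys from defaults, recursively
.mergeConfig <- function(config, defaults) {
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[k] <- defaults[k]
    } else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      config[[k]] <- .mergeConfig(config[[k]], defaults[[k]])
    }
  }
  config
}

#' Assemble a pipeline configuration
#'
#' All knobs of the end-to-end workflow in one validated, serializable
#' object: stage toggles, simulation parameters, every ppm tolerance
#' (annotation default 2 ppm, replicate matching 5 ppm), normalization
#' method, adduct set, and the marker-selection rule. Unknown keys are
#' rejected. The object round-trips unchanged through
#' [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param ... named overrides of top-level keys, nested lists for nested
#'   sections, e.g. `seed = 7, rule = list(alpha = 0.05)`.
#' @return A `dims_pipeline_config` list.
#' @examples
#' cfg <- pipelineConfig(seed = 7)
#' cfg$tolerances$annotation_ppm
#' @export
pipelineConfig <- function(...) {
  skel <- .configSkeleton()
  over <- list(...)
  .checkKeys(over, skel)
  cfg <- .mergeConfig(over, skel)
  cfg <- cfg[names(skel)]
  cfg$seed <- as.integer(cfg$seed)
  cfg$simulate$noise_peaks_per_spectrum <-
    as.integer(cfg$simulate$noise_peaks_per_spectrum)
  cfg$calibration$n_reference_ions <-
    as.integer(cfg$calibration$n_reference_ions)
  if (!cfg$rule$level %in% c("sample", "replicate"))
    stop("rule$level must be 'sample' or 'replicate'")
  class(cfg) <- "dims_pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipelineConfig()] object.
#' @param path YAML file.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` returns the validated config (unknown keys are
#'   rejected).
#' @export
writePipelineConfig <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

.designFromConfig <- function(config) {
  sim <- config$simulate
  studyDesign(seed = config$seed,
              massErrorPpmSd = sim$mass_error_ppm_sd,
              replicateDropoutProb = sim$replicate_dropout_prob,
              noisePeaksPerSpectrum = sim$noise_peaks_per_spectrum,
              driftPpm = c(sim$drift_intercept_ppm,
                           sim$drift_slope_ppm_per_da))
}

# theoretical m/z of high-intensity matched library/IS ions, for lock-mass
# recalibration: the k best matches ranked by observed intensity.
# "Characteristic high-intensity peaks" means exactly that: candidates are
# restricted to the top intensity decile so low-level chemical noise that
# happens to fall near a library mass cannot steer the mass-axis fit.
.calibrationRefs <- function(peaks, grid, matchTolPpm, k,
                             minIntensityQuantile = 0.9) {
  lo <- findInterval(mz(peaks) * (1 - 2 * matchTolPpm * 1e-6),
                     grid$theoretical_mz) + 1L
  hi <- findInterval(mz(peaks) * (1 + 2 * matchTolPpm * 1e-6),
                     grid$theoretical_mz)
  cand <- which(hi >= lo)
  if (length(peaks) >= 10L) {
    floorInt <- stats::quantile(intensity(peaks), minIntensityQuantile,
                                names = FALSE)
    cand <- cand[intensity(peaks)[cand] >= floorInt]
  }
  if (!length(cand)) return(numeric(0))
  refs <- vapply(cand, function(i) {
    th <- grid$theoretical_mz[lo[i]:hi[i]]
    th <- th[abs(ppmError(mz(peaks)[i], th)) <= matchTolPpm]
    if (length(th)) th[which.min(abs(th - mz(peaks)[i]))] else NA_real_
  }, numeric(1))
  ok <- !is.na(refs)
  refs <- refs[ok]; cand <- cand[ok]
  if (!length(refs)) return(numeric(0))
  o <- order(intensity(peaks)[cand], decreasing = TRUE)
  unique(refs[o])[seq_len(min(k, length(unique(refs[o]))))]
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end marker-discovery pipeline
#'
#' Executes the enabled stages in order -- simulate (or load) the cohort,
#' lock-mass recalibration, intensity normalization, technical-replicate
#' consensus, putative annotation, per-group frequencies, marker
#' selection -- and writes `annotations.tsv`, `frequencies.tsv`,
#' `markers.tsv`, a copy of the configuration and a provenance record
#' into the run directory. Identical configuration (including the seed)
#' produces byte-identical reports.
#'
#' @param config a [pipelineConfig()] object (or path to a YAML config).
#' @param outDir run directory; defaults to `config$output_dir`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`manifest`, `peakLists`, `consensus`, `annotations`, `frequencies`,
#'   `markers`) and `paths` to the written files.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(seed = 1), outDir = tempfile())
#' res$markers
#' }
#' @export
runPipeline <- function(config, outDir = config$output_dir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!inherits(config, "dims_pipeline_config"))
    config <- do.call(pipelineConfig, unclass(config))
  if (is.null(outDir)) stop("an output directory is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(config = file.path(outDir, "config.yaml"),
                provenance = file.path(outDir, "provenance.json"))
  writePipelineConfig(config, paths$config)

  st <- config$stages
  res <- list()
  library <- NULL
  isMz <- config$input$internal_standard_mz

  if (isTRUE(st$simulate)) {
    .stage("simulate", {
      design <- .designFromConfig(config)
      cohort <- generateCohort(design)
      res$manifest <- cohort$manifest
      res$peakLists <- cohort$peakLists
      res$truth <- cohort$truth
      istd <- design@internalStandard
      library <- CompoundLibrary(rbind(
        as.data.frame(design@panel)[, c("compound_id", "name", "formula",
                                        "neutral_mass")],
        data.frame(compound_id = istd$compound_id, name = istd$name,
                   formula = istd$formula, neutral_mass = NA_real_)))
      if (is.null(isMz))
        isMz <- adductMz(monoisotopicMass(istd$formula), istd$adduct)
      if (isTRUE(config$write_peak_lists)) {
        plDir <- file.path(outDir, "peaklists")
        dir.create(plDir, showWarnings = FALSE)
        for (nm in names(res$peakLists))
          writePeakList(res$peakLists[[nm]],
                        file.path(plDir, paste0(nm, ".tsv")))
      }
      res
    })
  } else if (any(unlist(st[c("calibrate", "normalize", "consensus",
                             "annotate", "frequencies", "select")]))) {
    .stage("load", {
      if (is.null(config$input$manifest) || is.null(config$input$library))
        stop("input$manifest and input$library are required when not simulating")
      res$manifest <- readCohortManifest(config$input$manifest)
      library <- readCompoundLibrary(config$input$library)
      mf <- as.data.frame(res$manifest)
      if (!"path" %in% colnames(mf))
        stop("manifest must carry a 'path' column for file-based input")
      res$peakLists <- lapply(seq_len(nrow(mf)), function(i)
        readPeakList(mf$path[i], sampleId = mf$sample_id[i],
                     replicateId = mf$replicate_id[i]))
      names(res$peakLists) <- paste(mf$sample_id, mf$replicate_id, sep = "_")
      if (is.null(isMz))
        isMz <- adductMz(monoisotopicMass("C22H23ClN6O"), "[M+H]+")
      res
    })
  }

  adducts <- .resolveAdducts(config$adducts)

  if (isTRUE(st$calibrate) && !is.null(res$peakLists)) {
    .stage("calibrate", {
      grid <- annotationGrid(library, adducts)
      res$peakLists <- lapply(res$peakLists, function(pl) {
        refs <- .calibrationRefs(pl, grid,
                                 config$tolerances$calibration_match_ppm,
                                 config$calibration$n_reference_ions)
        if (!length(refs)) return(pl)
        recalibrate(pl, refs, config$tolerances$calibration_match_ppm)
      })
      res
    })
  }

  if (isTRUE(st$normalize) && !is.null(res$peakLists)) {
    .stage("normalize", {
      res$peakLists <- lapply(res$peakLists, normalizeIntensities,
                              method = config$normalization$method,
                              isMz = isMz,
                              isTolPpm = config$tolerances$internal_standard_ppm,
                              fallback = isTRUE(config$normalization$fallback_tic))
      res
    })
  }

  if (isTRUE(st$consensus) && !is.null(res$peakLists)) {
    .stage("consensus", {
      mf <- as.data.frame(res$manifest)
      bySample <- split(seq_len(nrow(mf)), mf$sample_id)
      res$consensus <- lapply(bySample, function(idx) {
        keys <- paste(mf$sample_id[idx], mf$replicate_id[idx], sep = "_")
        replicateConsensus(res$peakLists[keys],
                           matchTolPpm = config$tolerances$replicate_match_ppm)
      })
      res
    })
  }

  if (isTRUE(st$annotate)) {
    .stage("annotate", {
      objects <- if (config$rule$level == "replicate" ||
                     is.null(res$consensus)) res$peakLists else res$consensus
      if (is.null(objects))
        stop("nothing to annotate: enable simulate (or provide inputs)")
      res$annotations <- annotateCohort(objects, library, adducts,
                                        tolPpm = config$tolerances$annotation_ppm)
      paths$annotations <- file.path(outDir, "annotations.tsv")
      write.table(as.data.frame(res$annotations), paths$annotations,
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  if (isTRUE(st$frequencies) && !is.null(res$annotations)) {
    .stage("frequencies", {
      if (config$rule$level == "replicate") {
        res$frequencies <- replicateLevelFrequency(res$annotations,
                                                   res$manifest)
      } else {
        det <- buildDetectionMatrix(res$annotations, res$manifest,
                                    compounds = library)
        res$detection <- det
        res$frequencies <- groupFrequency(det)
      }
      paths$frequencies <- file.path(outDir, "frequencies.tsv")
      writeFrequencyReport(res$frequencies, paths$frequencies)
      res
    })
  }

  if (isTRUE(st$select) && !is.null(res$frequencies)) {
    .stage("select", {
      r <- config$rule
      res$markers <- selectMarkers(res$frequencies,
                                   controlGroups = r$control_groups,
                                   caseGroups = r$case_groups,
                                   maxControlFrequency = r$max_control_frequency,
                                   minCaseFrequency = r$min_case_frequency,
                                   alpha = r$alpha)
      paths$markers <- file.path(outDir, "markers.tsv")
      write.table(as.data.frame(res$markers), paths$markers,
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  prov <- list(package = "dimsMarkers",
               version = as.character(packageVersion("dimsMarkers")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = config$seed,
               config_md5 = unname(tools::md5sum(paths$config)),
               n_samples = if (!is.null(res$manifest))
                 length(unique(res$manifest$sample_id)) else 0L,
               n_spectra = length(res$peakLists),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, pretty = TRUE)
  res$paths <- paths
  invisible(res)
}

#' One-command demonstration run
#'
#' Simulates the four-group study design (25/3/20/31 samples, two
#' technical replicates) and runs the full pipeline on it with default
#' tolerances and the first-trimester selection rule (control group 1 vs
#' case group 2).
#'
#' @param outDir run directory.
#' @param seed integer seed.
#' @param ... further [pipelineConfig()] overrides.
#' @return See [runPipeline()].
#' @export
runDemo <- function(outDir = file.path(tempdir(), "dims-demo"), seed = 1L,
                    ...) {
  runPipeline(pipelineConfig(seed = seed, ...), outDir = outDir)
}
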