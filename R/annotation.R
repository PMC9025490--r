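#' Adduct-aware putative annotation of accurate masses
#'
#' Matches observed ions against the theoretical adduct m/z of every
#' library compound within a ppm tolerance. Identification is by accurate
#' mass alone ("putative"): every (compound, adduct) candidate within the
#' window is emitted, sorted per ion by increasing absolute ppm error, and
#' the candidate search is an interval query over the precomputed, sorted
#' theoretical m/z grid -- equivalent to an exhaustive all-pairs scan.
#' Ions with no candidate are silently left unannotated.
#'
#' @param ions a [ConsensusIonTable-class], a [PeakList-class], or a bare
#'   numeric vector of m/z values.
#' @param library a [CompoundLibrary-class].
#' @param adducts adduct registry to search (default the built-in H+, Na+,
#'   K+ set, [defaultAdducts()]).
#' @param tolPpm annotation tolerance in ppm (default 2, the workflow's
#'   identification window).
#' @param sampleId,replicateId labels used when `ions` is a bare numeric
#'   vector; taken from the object otherwise.
#' @return A `DataFrame` with columns `sample_id`, `replicate_id`, `mz`,
#'   `compound_id`, `adduct`, `theoretical_mz`, `ppm_error`.
#' @examples
#' lib <- CompoundLibrary(data.frame(compound_id = "IS", name = "losartan",
#'                                   formula = "C22H23ClN6O"))
#' annotateIons(423.1695, lib)
#' @export
annotateIons <- function(ions, library, adducts = defaultAdducts(),
                         tolPpm = 2, sampleId = NA_character_,
                         replicateId = NA_character_) {
  stopifnot(is(library, "CompoundLibrary"))
  if (!nrow(library)) stop("compound library is empty")
  if (tolPpm <= 0) stop("tolPpm must be > 0")
  if (is(ions, "ConsensusIonTable")) {
    sampleId <- sampleId(ions); replicateId <- NA_character_
    mzv <- mz(ions)
  } else if (is(ions, "PeakList")) {
    sampleId <- sampleId(ions); replicateId <- replicateId(ions)
    mzv <- mz(ions)
  } else {
    mzv <- as.numeric(ions)
  }
  grid <- annotationGrid(library, adducts)
  # deliberately widened interval query (2x tol); the exact ppm filter
  # below restores the tolerance, so the result equals an all-pairs scan
  lo <- findInterval(mzv * (1 - 2 * tolPpm * 1e-6), grid$theoretical_mz) + 1L
  hi <- findInterval(mzv * (1 + 2 * tolPpm * 1e-6), grid$theoretical_mz)
  nCand <- pmax(0L, hi - lo + 1L)
  if (!sum(nCand))
    return(DataFrame(sample_id = character(0), replicate_id = character(0),
                     mz = numeric(0), compound_id = character(0),
                     adduct = character(0), theoretical_mz = numeric(0),
                     ppm_error = numeric(0)))
  ionIdx <- rep(seq_along(mzv), nCand)
  gIdx <- unlist(lapply(seq_along(mzv), function(i)
    if (nCand[i] > 0L) lo[i]:hi[i] else integer(0)), use.names = FALSE)
  err <- ppmError(mzv[ionIdx], grid$theoretical_mz[gIdx])
  keep <- abs(err) <= tolPpm
  ionIdx <- ionIdx[keep]; gIdx <- gIdx[keep]; err <- err[keep]
  o <- order(ionIdx, abs(err))
  DataFrame(sample_id = rep(sampleId, length(o)),
            replicate_id = rep(replicateId, length(o)),
            mz = mzv[ionIdx][o],
            compound_id = grid$compound_id[gIdx][o],
            adduct = grid$adduct[gIdx][o],
            theoretical_mz = grid$theoretical_mz[gIdx][o],
            ppm_error = err[o])
}

#' Theoretical m/z grid for a library and adduct set
#'
#' One row per (compound, adduct) pair, sorted by theoretical m/z; the
#' search structure behind [annotateIons()].
#'
#' @param library a [CompoundLibrary-class].
#' @param adducts adduct registry.
#' @return A data.frame with `compound_id`, `adduct`, `theoretical_mz`.
#' @export
annotationGrid <- function(library, adducts = defaultAdducts()) {
  g <- expand.grid(ci = seq_len(nrow(library)), ai = seq_len(nrow(adducts)))
  out <- data.frame(
    compound_id = library$compound_id[g$ci],
    adduct = adducts$name[g$ai],
    theoretical_mz = adductMz(library$neutral_mass[g$ci],
                              adducts[g$ai, , drop = FALSE]),
    stringsAsFactors = FALSE)
  out[order(out$theoretical_mz), , drop = FALSE]
}

#' Annotate every sample of a cohort
#'
#' Convenience loop over per-sample [ConsensusIonTable-class] objects (or
#' per-replicate [PeakList-class] objects for replicate-level analyses),
#' binding the per-sample annotation tables.
#'
#' @param objects list of `ConsensusIonTable` or `PeakList`.
#' @inheritParams annotateIons
#' @return A combined annotation `DataFrame`.
#' @export
annotateCohort <- function(objects, library, adducts = defaultAdducts(),
                           tolPpm = 2) {
  res <- lapply(objects, annotateIons, library = library,
                adducts = adducts, tolPpm = tolPpm)
  do.call(rbind, res)
}

#' Build the compound-by-sample detection matrix
#'
#' A cell is `TRUE` iff at least one annotation links that compound to
#' that sample; samples with no annotation at all still appear as
#' all-`FALSE` columns. Returned as a `SummarizedExperiment` with a
#' logical `detected` assay, sample groups in `colData` and compound ids
#' in `rowData`.
#'
#' @param annotations annotation table from [annotateIons()] /
#'   [annotateCohort()].
#' @param manifest cohort manifest (`sample_id`, `group`; replicate rows
#'   are collapsed).
#' @param compounds optional character vector (or [CompoundLibrary-class])
#'   fixing the row set; defaults to the annotated compounds.
#' @return A [SummarizedExperiment::SummarizedExperiment-class].
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @export
buildDetectionMatrix <- function(annotations, manifest, compounds = NULL) {
  samples <- .sampleTable(manifest)
  annotations <- as.data.frame(annotations)
  unknown <- setdiff(unique(annotations$sample_id), samples$sample_id)
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown))
    stop("annotation(s) reference unknown sample(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(compounds)) compounds <- sort(unique(annotations$compound_id))
  if (is(compounds, "CompoundLibrary")) compounds <- compounds$compound_id
  det <- matrix(FALSE, length(compounds), nrow(samples),
                dimnames = list(compounds, samples$sample_id))
  if (nrow(annotations)) {
    hit <- unique(annotations[annotations$compound_id %in% compounds,
                              c("compound_id", "sample_id")])
    det[cbind(hit$compound_id, hit$sample_id)] <- TRUE
  }
  SummarizedExperiment(
    assays = list(detected = det),
    colData = DataFrame(group = samples$group, row.names = samples$sample_id),
    rowData = DataFrame(compound_id = compounds, row.names = compounds))
}
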