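#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' PeakList: centroided ions for one sample and technical replicate
#'
#' A `PeakList` holds the centroided representation of one direct-infusion
#' mass spectrum: parallel vectors of m/z (Da) and intensity (arbitrary
#' units), sorted by m/z, together with the sample and technical-replicate
#' labels the spectrum belongs to.
#'
#' @slot sampleId character(1), sample label.
#' @slot replicateId character(1), technical-replicate label.
#' @slot mz numeric, ion m/z in Da, sorted increasing.
#' @slot intensity numeric, non-negative ion intensities.
#'
#' @aliases PeakList-class
#' @exportClass PeakList
setClass("PeakList",
  representation(
    sampleId   = "character",
    replicateId = "character",
    mz         = "numeric",
    intensity  = "numeric"
  ),
  prototype(sampleId = NA_character_, replicateId = NA_character_,
            mz = numeric(0), intensity = numeric(0))
)

setValidity("PeakList", function(object) {
  msg <- character(0)
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (anyNA(object@mz) || anyNA(object@intensity))
    msg <- c(msg, "mz and intensity must not contain NA")
  if (length(object@mz) && is.unsorted(object@mz))
    msg <- c(msg, "mz must be sorted in increasing order")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(object@sampleId) != 1L || length(object@replicateId) != 1L)
    msg <- c(msg, "sampleId and replicateId must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakList
#'
#' Peaks are sorted by m/z on construction.
#'
#' @param mz numeric vector of m/z values (Da).
#' @param intensity numeric vector of non-negative intensities.
#' @param sampleId,replicateId labels for the originating sample and
#'   technical replicate.
#' @return A [PeakList-class] object.
#' @examples
#' pl <- PeakList(c(423.169, 100.05), c(5e4, 2e3), "S1", "TR1")
#' mz(pl)
#' @export
PeakList <- function(mz = numeric(0), intensity = numeric(0),
                     sampleId = NA_character_, replicateId = NA_character_) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  new("PeakList", sampleId = as.character(sampleId),
      replicateId = as.character(replicateId),
      mz = mz, intensity = intensity)
}

#' ConsensusIonTable: per-sample ions surviving the replicate rule
#'
#' Holds, for one sample, the ions registered in every technical replicate
#' within the m/z matching tolerance. The consensus m/z is the
#' intensity-weighted mean of the contributing replicate m/z values and is
#' guaranteed to lie between their minimum and maximum.
#'
#' @slot sampleId character(1).
#' @slot mz numeric, consensus m/z, sorted increasing.
#' @slot intensities matrix, one row per consensus ion, one column per
#'   technical replicate (column names are replicate labels).
#' @slot sourceIndex integer matrix, same shape, the index of the
#'   contributing peak in each replicate's [PeakList-class].
#'
#' @aliases ConsensusIonTable-class
#' @exportClass ConsensusIonTable
setClass("ConsensusIonTable",
  representation(
    sampleId   = "character",
    mz         = "numeric",
    intensities = "matrix",
    sourceIndex = "matrix"
  ),
  prototype(sampleId = NA_character_, mz = numeric(0),
            intensities = matrix(numeric(0), 0, 0),
            sourceIndex = matrix(integer(0), 0, 0))
)

setValidity("ConsensusIonTable", function(object) {
  msg <- character(0)
  n <- length(object@mz)
  if (nrow(object@intensities) != n || nrow(object@sourceIndex) != n)
    msg <- c(msg, "intensities and sourceIndex must have one row per ion")
  if (ncol(object@intensities) != ncol(object@sourceIndex))
    msg <- c(msg, "intensities and sourceIndex must have equal column count")
  if (n && is.unsorted(object@mz))
    msg <- c(msg, "consensus mz must be sorted")
  if (length(object@intensities) && any(object@intensities < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CompoundLibrary: a table of reference metabolites
#'
#' A `CompoundLibrary` extends [S4Vectors::DataFrame] with the columns of a
#' compound record: `compound_id` (unique accession, e.g. HMDB-style),
#' `name`, optional `compound_class` and `kegg_id`, optional molecular
#' `formula` (Hill notation), and `neutral_mass` (monoisotopic, Da). When a
#' record carries a formula but no mass the mass is backfilled from the
#' formula; when it carries both and they disagree by more than 0.01 Da the
#' record is flagged in the logical `inconsistent` column rather than
#' rejected, since printed library masses are often low-precision.
#'
#' @aliases CompoundLibrary-class
#' @exportClass CompoundLibrary
setClass("CompoundLibrary", contains = "DFrame")

setValidity("CompoundLibrary", function(object) {
  msg <- character(0)
  need <- c("compound_id", "name", "neutral_mass")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing required column(s):", paste(miss, collapse = ", ")))
  if (anyNA(object$compound_id))
    msg <- c(msg, "compound_id must not contain NA")
  if (anyDuplicated(object$compound_id))
    msg <- c(msg, paste("duplicate compound_id:",
                        paste(unique(object$compound_id[duplicated(object$compound_id)]),
                              collapse = ", ")))
  if (!is.numeric(object$neutral_mass) || anyNA(object$neutral_mass) ||
      any(object$neutral_mass <= 0))
    msg <- c(msg, "neutral_mass must be positive and non-missing")
  if (length(msg)) msg else TRUE
})

#' Construct a CompoundLibrary
#'
#' @param records a `data.frame` or `DataFrame` with at least `compound_id`
#'   and `name`, plus `formula` and/or `neutral_mass` (one of the two is
#'   required per record).
#' @param massTolDa records carrying both a formula and a stated mass are
#'   flagged `inconsistent` when the two disagree by more than this (Da).
#' @return A [CompoundLibrary-class].
#' @examples
#' lib <- CompoundLibrary(data.frame(
#'   compound_id = "IS1", name = "losartan", formula = "C22H23ClN6O"))
#' lib$neutral_mass
#' @export
CompoundLibrary <- function(records, massTolDa = 0.01) {
  df <- DataFrame(records)
  for (col in c("compound_class", "kegg_id", "formula"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  if (is.null(df[["neutral_mass"]])) df$neutral_mass <- NA_real_
  df$neutral_mass <- as.numeric(df$neutral_mass)
  hasFormula <- !is.na(df$formula) & nzchar(df$formula)
  hasMass <- !is.na(df$neutral_mass)
  if (any(!hasFormula & !hasMass))
    stop("record(s) with neither formula nor neutral_mass: ",
         paste(df$compound_id[!hasFormula & !hasMass], collapse = ", "))
  computed <- rep(NA_real_, nrow(df))
  computed[hasFormula] <- vapply(df$formula[hasFormula],
                                 function(f) monoisotopicMass(parseFormula(f)),
                                 numeric(1))
  df$neutral_mass[!hasMass] <- computed[!hasMass]
  df$inconsistent <- hasFormula & hasMass &
    abs(computed - df$neutral_mass) > massTolDa
  df$inconsistent[is.na(df$inconsistent)] <- FALSE
  new("CompoundLibrary", df)
}

## ---- generics & accessors ----

#' @describeIn PeakList number of peaks
#' @param x a `PeakList`
#' @export
setMethod("length", "PeakList", function(x) length(x@mz))

#' @describeIn ConsensusIonTable number of consensus ions
#' @param x a `ConsensusIonTable`
#' @export
setMethod("length", "ConsensusIonTable", function(x) length(x@mz))

#' Accessors for peak containers
#'
#' `mz()` and `intensity()` return the m/z and intensity vectors of a
#' [PeakList-class]; for a [ConsensusIonTable-class], `mz()` returns the
#' consensus m/z and `intensity()` the replicate intensity matrix.
#' `sampleId()` and `replicateId()` return the labels.
#'
#' @param object a `PeakList` or `ConsensusIonTable`.
#' @return numeric vector (or matrix for consensus intensities) / character.
#' @name peak-accessors
NULL

#' @rdname peak-accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))
#' @rdname peak-accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname peak-accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname peak-accessors
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))

#' @rdname peak-accessors
setMethod("mz", "PeakList", function(object) object@mz)
#' @rdname peak-accessors
setMethod("intensity", "PeakList", function(object) object@intensity)
#' @rdname peak-accessors
setMethod("sampleId", "PeakList", function(object) object@sampleId)
#' @rdname peak-accessors
setMethod("replicateId", "PeakList", function(object) object@replicateId)
#' @rdname peak-accessors
setMethod("mz", "ConsensusIonTable", function(object) object@mz)
#' @rdname peak-accessors
setMethod("intensity", "ConsensusIonTable", function(object) object@intensities)
#' @rdname peak-accessors
setMethod("sampleId", "ConsensusIonTable", function(object) object@sampleId)

#' @export
#' @describeIn PeakList coerce to a two-column data.frame
#' @param row.names,optional,... passed on conventions of [as.data.frame]
setMethod("as.data.frame", "PeakList",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(mz = x@mz, intensity = x@intensity)
  })

#' @export
setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList: sample '%s' replicate '%s', %d peaks",
              object@sampleId, object@replicateId, length(object@mz)))
  if (length(object@mz))
    cat(sprintf(", m/z %.4f-%.4f", min(object@mz), max(object@mz)))
  cat("\n")
})

#' @export
setMethod("show", "ConsensusIonTable", function(object) {
  cat(sprintf(
    "ConsensusIonTable: sample '%s', %d consensus ions across %d replicates\n",
    object@sampleId, length(object@mz), ncol(object@intensities)))
})

#' @export
setMethod("show", "CompoundLibrary", function(object) {
  cat(sprintf("CompoundLibrary with %d compounds (%d flagged inconsistent)\n",
              nrow(object), sum(object$inconsistent)))
  callNextMethod()
})
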