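#' @importFrom utils read.table write.table
NULL

.detectSep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

.looksNumeric <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a peak list from disk
#'
#' The canonical peak-list dialect is two-column delimited text (m/z,
#' intensity), one file per sample and technical replicate; tab, comma or
#' whitespace separation is auto-detected, and a header line is detected by
#' its non-numeric first field. Centroided mzML is supported read-only via
#' the mzR package (the centroid arrays of the first spectrum in the file
#' are taken).
#'
#' @param path file to read.
#' @param dialect `"auto"` (default; mzML by file extension, else delimited
#'   text), `"delim"` or `"mzml"`.
#' @param sampleId,replicateId labels attached to the result.
#' @param mzRange optional length-2 numeric; peaks outside the instrument
#'   range raise an error.
#' @return A [PeakList-class], sorted by m/z. An empty file yields an empty
#'   `PeakList` with a warning.
#' @export
readPeakList <- function(path, dialect = c("auto", "delim", "mzml"),
                         sampleId = NA_character_, replicateId = NA_character_,
                         mzRange = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "delim"
  if (dialect == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    ms <- mzR::openMSfile(path)
    on.exit(mzR::close(ms))
    pk <- mzR::peaks(ms, 1L)
    return(PeakList(pk[, 1L], pk[, 2L], sampleId, replicateId))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty peak-list file: ", path)
    return(PeakList(sampleId = sampleId, replicateId = replicateId))
  }
  sep <- .detectSep(lines[[1]])
  first <- strsplit(trimws(lines[[1]]),
                    if (sep == "") "[[:space:]]+" else sep)[[1]]
  hasHeader <- !.looksNumeric(first[[1]])
  dataLines <- if (hasHeader) lines[-1] else lines
  if (!length(dataLines)) {
    warning("peak-list file has a header but no data rows: ", path)
    return(PeakList(sampleId = sampleId, replicateId = replicateId))
  }
  df <- tryCatch(
    read.table(text = dataLines, sep = sep, header = FALSE,
               colClasses = "character", quote = "\"",
               stringsAsFactors = FALSE, fill = TRUE),
    error = function(e) stop("cannot parse peak list ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 2L)
    stop("peak list ", path, " must have two columns (m/z, intensity)")
  mzv <- suppressWarnings(as.numeric(df[[1]]))
  iv <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(mzv) | is.na(iv))
  if (length(bad))
    stop(sprintf("unparseable row in %s at line %d: '%s'",
                 path, bad[1] + hasHeader, dataLines[bad[1]]))
  neg <- which(iv < 0)
  if (length(neg))
    stop(sprintf("negative intensity in %s at line %d (m/z %.4f)",
                 path, neg[1] + hasHeader, mzv[neg[1]]))
  if (!is.null(mzRange)) {
    out <- which(mzv < mzRange[1] | mzv > mzRange[2])
    if (length(out))
      stop(sprintf("%d peak(s) in %s outside the instrument m/z range [%g, %g]",
                   length(out), path, mzRange[1], mzRange[2]))
  }
  PeakList(mzv, iv, sampleId, replicateId)
}

#' Write a peak list as two-column delimited text
#'
#' @param x a [PeakList-class].
#' @param path output file.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writePeakList <- function(x, path, sep = "\t") {
  stopifnot(is(x, "PeakList"))
  df <- data.frame(mz = sprintf("%.6f", x@mz),
                   intensity = sprintf("%.10g", x@intensity))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compound library table
#'
#' Expects a delimited table (tab or comma, auto-detected) with a header
#' carrying at least `compound_id` and `name`, plus `formula` and/or
#' `neutral_mass`; optional `compound_class` and `kegg_id`. Records with a
#' formula but no mass get the mass backfilled from the formula; duplicate
#' ids are an error (see [CompoundLibrary()]).
#'
#' @param path file to read.
#' @return A [CompoundLibrary-class].
#' @export
readCompoundLibrary <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  firstLine <- readLines(path, n = 1L)
  sep <- .detectSep(firstLine)
  if (sep == "") sep <- "\t"
  df <- read.table(path, sep = sep, header = TRUE, quote = "",
                   stringsAsFactors = FALSE, comment.char = "",
                   na.strings = c("NA", ""))
  if (!all(c("compound_id", "name") %in% colnames(df)))
    stop("compound library must have 'compound_id' and 'name' columns")
  CompoundLibrary(df)
}

#' The nine-metabolite preeclampsia panel library
#'
#' The reference panel of nine endogenous blood-plasma metabolites whose
#' detection frequency separates uncomplicated pregnancies from pregnancies
#' that develop preeclampsia, with their published neutral monoisotopic
#' masses (printed to 2 decimal places). Shipped as a plain-text table in
#' `inst/extdata`.
#'
#' @return A [CompoundLibrary-class] of 9 compounds.
#' @examples
#' pePanelLibrary()
#' @export
pePanelLibrary <- function() {
  readCompoundLibrary(system.file("extdata", "pe_panel_library.tsv",
                                  package = "dimsMarkers", mustWork = TRUE))
}

#' Published detection counts for the preeclampsia panel
#'
#' Per-group detected-sample counts for the nine panel metabolites in the
#' four-group study design (group sizes 25, 3, 20, 31), together with the
#' observed (adduct) m/z each metabolite was detected at.
#'
#' @return A `DataFrame` with columns `compound_id`, `group`,
#'   `detected_count`, `group_size`, `frequency` (full precision) and
#'   `observed_mz`.
#' @examples
#' head(pePanelFrequencies())
#' @export
pePanelFrequencies <- function() {
  path <- system.file("extdata", "pe_panel_observations.tsv",
                      package = "dimsMarkers", mustWork = TRUE)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  sizes <- c(group1 = 25L, group2 = 3L, group3 = 20L, group4 = 31L)
  long <- do.call(rbind, lapply(names(sizes), function(g) {
    data.frame(compound_id = df$compound_id, group = g,
               detected_count = df[[paste0("count_", g)]],
               group_size = unname(sizes[g]),
               observed_mz = df$observed_mz,
               stringsAsFactors = FALSE)
  }))
  long$frequency <- long$detected_count / long$group_size
  DataFrame(long[, c("compound_id", "group", "detected_count",
                     "group_size", "frequency", "observed_mz")])
}

#' Read a cohort manifest
#'
#' A manifest assigns every sample to a group and lists its technical
#' replicates: a delimited table with columns `sample_id`, `group`,
#' `replicate_id` and (optionally) `path` pointing at per-replicate
#' peak-list files.
#'
#' @param path file to read.
#' @param minReplicates minimum technical replicates required per sample
#'   (default 2, matching the both-replicates consensus rule).
#' @param groups optional character vector of allowed group labels.
#' @return A `DataFrame` with one row per (sample, replicate).
#' @export
readCohortManifest <- function(path, minReplicates = 2L, groups = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .detectSep(readLines(path, n = 1L))
  if (sep == "") sep <- "\t"
  df <- read.table(path, sep = sep, header = TRUE, quote = "",
                   stringsAsFactors = FALSE, comment.char = "")
  need <- c("sample_id", "group", "replicate_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  validateManifest(df, minReplicates = minReplicates, groups = groups)
  DataFrame(df)
}

#' Validate a cohort manifest
#'
#' @param manifest data.frame with `sample_id`, `group` and (for
#'   replicate-resolved manifests) `replicate_id`.
#' @param minReplicates required replicates per sample; set 0 to skip.
#' @param groups optional allowed group labels.
#' @return The manifest, invisibly; errors describe the violation.
#' @export
validateManifest <- function(manifest, minReplicates = 2L, groups = NULL) {
  manifest <- as.data.frame(manifest)
  gPerSample <- tapply(manifest$group, manifest$sample_id,
                       function(g) length(unique(g)))
  if (any(gPerSample > 1L))
    stop("sample(s) assigned to more than one group: ",
         paste(names(gPerSample)[gPerSample > 1L], collapse = ", "))
  if (!is.null(groups)) {
    badg <- setdiff(unique(manifest$group), groups)
    if (length(badg))
      stop("undeclared group label(s): ", paste(badg, collapse = ", "))
  }
  if (minReplicates > 0L && "replicate_id" %in% colnames(manifest)) {
    reps <- tapply(manifest$replicate_id, manifest$sample_id,
                   function(r) length(unique(r)))
    low <- names(reps)[reps < minReplicates]
    if (length(low))
      stop("sample(s) with fewer than ", minReplicates,
           " technical replicates: ", paste(low, collapse = ", "))
  }
  invisible(manifest)
}

# one row per sample: sample_id, group
.sampleTable <- function(manifest) {
  manifest <- as.data.frame(manifest)
  unique(manifest[, c("sample_id", "group")])
}

#' Write a per-group frequency report
#'
#' One row per metabolite; for each group a frequency column rounded to two
#' decimal places (presentation only -- frequencies are held at full
#' precision internally), a detected-sample count column, and the group
#' size.
#'
#' @param freqs a frequency table as returned by [groupFrequency()]
#'   (columns `compound_id`, `group`, `detected_count`, `group_size`,
#'   `frequency`).
#' @param path output file (tab-delimited).
#' @return `path`, invisibly.
#' @export
writeFrequencyReport <- function(freqs, path) {
  freqs <- as.data.frame(freqs)
  if (!nrow(freqs)) {
    writeLines("compound_id", path)
    return(invisible(path))
  }
  grps <- unique(freqs$group)
  ids <- unique(freqs$compound_id)
  wide <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (g in grps) {
    sub <- freqs[freqs$group == g, ]
    idx <- match(ids, sub$compound_id)
    wide[[paste0("frequency_", g)]] <- sprintf("%.2f", sub$frequency[idx])
    wide[[paste0("detected_", g)]] <- sub$detected_count[idx]
    wide[[paste0("group_size_", g)]] <- sub$group_size[idx]
  }
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a frequency report
#'
#' Inverse of [writeFrequencyReport()]; counts are recovered exactly and
#' frequencies are recomputed at full precision from count / group size.
#'
#' @param path report written by [writeFrequencyReport()].
#' @return A `DataFrame` in the long frequency-table layout.
#' @export
readFrequencyReport <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  grps <- sub("^detected_", "", grep("^detected_", colnames(df), value = TRUE))
  if (!length(grps))
    return(DataFrame(compound_id = df$compound_id))
  long <- do.call(rbind, lapply(grps, function(g) {
    data.frame(compound_id = df$compound_id, group = g,
               detected_count = as.integer(df[[paste0("detected_", g)]]),
               group_size = as.integer(df[[paste0("group_size_", g)]]),
               stringsAsFactors = FALSE)
  }))
  long$frequency <- long$detected_count / long$group_size
  DataFrame(long)
}
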