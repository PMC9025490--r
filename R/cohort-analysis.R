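#' @importFrom stats dhyper p.adjust
NULL

#' Per-group detection frequencies
#'
#' For every compound and group, counts the group samples in which the
#' compound was detected and divides by the group size. Frequencies are
#' held at full precision; two-decimal rounding is applied only when a
#' report is written.
#'
#' @param detection a `SummarizedExperiment` from [buildDetectionMatrix()]
#'   (logical `detected` assay, `group` column in `colData`), or a logical
#'   matrix (compounds x samples) together with `manifest`.
#' @param manifest required when `detection` is a bare matrix: data.frame
#'   with `sample_id` and `group`.
#' @param groups optional expected group labels; an expected group with no
#'   samples is an error naming the group.
#' @return A `DataFrame` with `compound_id`, `group`, `detected_count`,
#'   `group_size`, `frequency`, ordered compounds within groups.
#' @export
groupFrequency <- function(detection, manifest = NULL, groups = NULL) {
  if (is(detection, "SummarizedExperiment")) {
    det <- SummarizedExperiment::assay(detection, "detected")
    sampleGroups <- as.character(SummarizedExperiment::colData(detection)$group)
  } else {
    det <- as.matrix(detection)
    if (is.null(manifest))
      stop("manifest is required when detection is a bare matrix")
    samples <- .sampleTable(manifest)
    sampleGroups <- samples$group[match(colnames(det), samples$sample_id)]
  }
  if (anyNA(sampleGroups)) stop("sample(s) without a group assignment")
  groupLevels <- if (is.null(groups)) unique(sampleGroups) else groups
  sizes <- vapply(groupLevels, function(g) sum(sampleGroups == g), integer(1))
  if (any(sizes == 0L))
    stop("empty group(s): ",
         paste(groupLevels[sizes == 0L], collapse = ", "))
  res <- do.call(rbind, lapply(groupLevels, function(g) {
    counts <- rowSums(det[, sampleGroups == g, drop = FALSE])
    data.frame(compound_id = rownames(det), group = g,
               detected_count = as.integer(counts),
               group_size = sum(sampleGroups == g),
               stringsAsFactors = FALSE)
  }))
  res$frequency <- res$detected_count / res$group_size
  DataFrame(res)
}

#' Two-sided exact test for a detection-frequency difference
#'
#' Fisher's exact test on the 2x2 table (detected / not detected in group
#' A vs group B), computed by exhaustive enumeration of the hypergeometric
#' distribution with fixed margins: the p-value is the sum of the
#' probabilities of all tables no more probable than the observed one
#' (with the customary `1 + 1e-7` relative tolerance on the probability
#' comparison).
#'
#' @param countA,nA detected count and group size in group A.
#' @param countB,nB detected count and group size in group B.
#' @return Two-sided exact p-value.
#' @examples
#' frequencyDifferenceTest(0, 25, 3, 3)  # < 0.05
#' @export
frequencyDifferenceTest <- function(countA, nA, countB, nB) {
  nA <- as.integer(nA); nB <- as.integer(nB)
  countA <- as.integer(countA); countB <- as.integer(countB)
  if (nA < 1L || nB < 1L) stop("group sizes must be >= 1")
  if (countA < 0L || countA > nA || countB < 0L || countB > nB)
    stop("counts must satisfy 0 <= count <= group size")
  m <- countA + countB
  support <- max(0L, m - nB):min(nA, m)
  probs <- dhyper(support, nA, nB, m)
  pObs <- dhyper(countA, nA, nB, m)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Select presence/absence markers
#'
#' A compound is selected iff its detection frequency is at most
#' `maxControlFrequency` in every control group and at least
#' `minCaseFrequency` in every case group; the strict literal rule
#' "absent from the healthy group" is `maxControlFrequency = 0`. An
#' optional exact-test filter keeps only compounds whose pooled
#' control-vs-case frequency difference is significant at `alpha`
#' (optionally after Benjamini-Hochberg adjustment across the tested
#' compounds). Selection is deterministic and order-independent.
#'
#' @param freqs frequency table from [groupFrequency()].
#' @param controlGroups,caseGroups disjoint sets of group labels.
#' @param maxControlFrequency maximum tolerated control frequency
#'   (default 0).
#' @param minCaseFrequency minimum required case frequency (default 0.5).
#' @param alpha if non-`NULL`, apply the exact-test filter at this level.
#' @param pAdjust `"none"` (default; the workflow applies no correction)
#'   or `"BH"`.
#' @return A `DataFrame` marker panel: one row per selected compound with
#'   per-group frequency columns and, when the test runs, `p_value` (and
#'   `p_adjusted`).
#' @examples
#' ft <- pePanelFrequencies()
#' selectMarkers(ft, "group1", "group2", maxControlFrequency = 0.15)
#' @export
selectMarkers <- function(freqs, controlGroups, caseGroups,
                          maxControlFrequency = 0,
                          minCaseFrequency = 0.5,
                          alpha = NULL, pAdjust = c("none", "BH")) {
  pAdjust <- match.arg(pAdjust)
  freqs <- as.data.frame(freqs)
  if (maxControlFrequency < 0 || maxControlFrequency > 1 ||
      minCaseFrequency < 0 || minCaseFrequency > 1)
    stop("frequency thresholds must be in [0, 1]")
  if (length(intersect(controlGroups, caseGroups)))
    stop("control and case groups must be disjoint")
  have <- unique(freqs$group)
  missing <- setdiff(c(controlGroups, caseGroups), have)
  if (length(missing))
    stop("group(s) not present in the frequency table: ",
         paste(missing, collapse = ", "))
  ids <- unique(freqs$compound_id)
  getF <- function(id, g) {
    row <- freqs[freqs$compound_id == id & freqs$group == g, ]
    if (!nrow(row)) 0 else row$frequency[1]
  }
  sel <- vapply(ids, function(id) {
    all(vapply(controlGroups, function(g) getF(id, g) <= maxControlFrequency,
               logical(1))) &&
      all(vapply(caseGroups, function(g) getF(id, g) >= minCaseFrequency,
                 logical(1)))
  }, logical(1))
  pool <- function(id, gs) {
    rows <- freqs[freqs$compound_id == id & freqs$group %in% gs, ]
    c(count = sum(rows$detected_count), n = sum(rows$group_size))
  }
  pv <- vapply(ids, function(id) {
    a <- pool(id, controlGroups); b <- pool(id, caseGroups)
    frequencyDifferenceTest(a["count"], a["n"], b["count"], b["n"])
  }, numeric(1))
  padj <- p.adjust(pv, method = if (pAdjust == "BH") "BH" else "none")
  if (!is.null(alpha)) sel <- sel & padj <= alpha
  out <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (g in have)
    out[[paste0("frequency_", g)]] <-
      vapply(ids, function(id) getF(id, g), numeric(1))
  out$p_value <- pv
  if (pAdjust == "BH") out$p_adjusted <- padj
  DataFrame(out[sel, , drop = FALSE])
}

#' Replicate-level detection frequencies
#'
#' Treats technical replicates as independent measurements (consensus
#' bypass): the unit of detection is the (sample, replicate) spectrum and
#' the denominator is group size times replicates per sample.
#'
#' @param annotations replicate-level annotation table (from
#'   [annotateCohort()] run on per-replicate [PeakList-class] objects),
#'   with non-missing `replicate_id`.
#' @param manifest manifest with `sample_id`, `group` and `replicate_id`
#'   rows for every acquired spectrum.
#' @return A `DataFrame` in the frequency-table layout; `group_size` is
#'   the number of replicate spectra in the group.
#' @export
replicateLevelFrequency <- function(annotations, manifest) {
  annotations <- as.data.frame(annotations)
  manifest <- as.data.frame(manifest)
  if (!"replicate_id" %in% colnames(manifest))
    stop("manifest must carry replicate_id rows for replicate-level analysis")
  specs <- unique(manifest[, c("sample_id", "replicate_id", "group")])
  specs$unit <- paste(specs$sample_id, specs$replicate_id, sep = "\r")
  annotations$unit <- paste(annotations$sample_id, annotations$replicate_id,
                            sep = "\r")
  unknown <- setdiff(unique(annotations$unit), specs$unit)
  if (length(unknown))
    stop("annotation(s) reference spectra absent from the manifest")
  ids <- sort(unique(annotations$compound_id))
  groupLevels <- unique(specs$group)
  res <- do.call(rbind, lapply(groupLevels, function(g) {
    units <- specs$unit[specs$group == g]
    sub <- annotations[annotations$unit %in% units, ]
    hits <- unique(sub[, c("compound_id", "unit")])
    counts <- table(factor(hits$compound_id, levels = ids))
    data.frame(compound_id = ids, group = g,
               detected_count = as.integer(counts),
               group_size = length(units),
               stringsAsFactors = FALSE)
  }))
  res$frequency <- res$detected_count / res$group_size
  DataFrame(res)
}
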