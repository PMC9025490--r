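#' @importFrom stats mad approx lm coef median
NULL

#' Peak-detection parameters
#'
#' Defaults follow the processing settings of the DIMS workflow this
#' package implements: at least 2 points per peak, signal-to-noise ratio 1,
#' a relative intensity cutoff of 0.01% of the base peak, and an absolute
#' intensity cutoff of 100 counts.
#'
#' @param minPointsPerPeak minimum contiguous profile points above local
#'   noise around an apex.
#' @param minSnr minimum apex signal-to-noise ratio (noise estimated as a
#'   scaled median absolute deviation over a sliding window).
#' @param relativeIntensityCutoff minimum apex intensity as a fraction of
#'   the base peak (default 1e-4, i.e. 0.01%).
#' @param absoluteIntensityCutoff minimum apex intensity in counts.
#' @param noiseWindowPoints width (profile points) of the sliding window
#'   used for the noise estimate.
#' @return A validated parameter list of class `PeakDetectionParams`.
#' @examples
#' peakDetectionParams()
#' @export
peakDetectionParams <- function(minPointsPerPeak = 2L, minSnr = 1,
                                relativeIntensityCutoff = 1e-4,
                                absoluteIntensityCutoff = 100,
                                noiseWindowPoints = 501L) {
  p <- list(minPointsPerPeak = as.integer(minPointsPerPeak),
            minSnr = as.numeric(minSnr),
            relativeIntensityCutoff = as.numeric(relativeIntensityCutoff),
            absoluteIntensityCutoff = as.numeric(absoluteIntensityCutoff),
            noiseWindowPoints = as.integer(noiseWindowPoints))
  if (p$minPointsPerPeak < 1L) stop("minPointsPerPeak must be >= 1")
  if (p$minSnr < 0 || p$relativeIntensityCutoff < 0 ||
      p$absoluteIntensityCutoff < 0)
    stop("thresholds must be >= 0")
  if (p$relativeIntensityCutoff > 1)
    stop("relativeIntensityCutoff is a fraction of the base peak (<= 1)")
  class(p) <- "PeakDetectionParams"
  p
}

# sliding-window noise estimate: scaled MAD computed on coarse chunks and
# linearly interpolated back onto the grid; robust to sparse peaks.
.localNoise <- function(y, windowPoints) {
  n <- length(y)
  w <- max(11L, min(windowPoints, n))
  starts <- seq(1L, n, by = max(1L, w %/% 2L))
  centers <- pmin(starts + w %/% 4L, n)
  est <- vapply(starts, function(s) {
    idx <- s:min(s + w - 1L, n)
    mad(y[idx], constant = 1.4826)
  }, numeric(1))
  if (length(est) == 1L) return(rep(est, n))
  approx(centers, est, xout = seq_len(n), rule = 2)$y
}

#' Detect peaks in a profile-mode spectrum
#'
#' Finds local maxima whose contiguous run of points above the local noise
#' level has at least `minPointsPerPeak` points, whose apex
#' signal-to-noise ratio (noise = scaled sliding-window median absolute
#' deviation) reaches `minSnr`, and whose apex intensity clears both the
#' absolute cutoff and the relative cutoff times the base-peak intensity.
#' The apex m/z is refined by 3-point parabolic interpolation.
#'
#' @param trace data.frame with columns `mz` (monotone grid) and
#'   `intensity`, as produced by [generateProfileSpectrum()].
#' @param params a [peakDetectionParams()] list.
#' @param sampleId,replicateId labels for the returned peak list.
#' @return A [PeakList-class] of centroided peaks. A trace shorter than
#'   `minPointsPerPeak` yields an empty list with a warning.
#' @export
detectPeaks <- function(trace, params = peakDetectionParams(),
                        sampleId = NA_character_,
                        replicateId = NA_character_) {
  stopifnot(is.data.frame(trace), all(c("mz", "intensity") %in% names(trace)))
  y <- trace$intensity
  x <- trace$mz
  n <- length(y)
  if (n < max(3L, params$minPointsPerPeak)) {
    warning("trace shorter than the minimum points per peak; no detection")
    return(PeakList(sampleId = sampleId, replicateId = replicateId))
  }
  if (is.unsorted(x)) stop("trace m/z grid must be monotone increasing")
  noise <- pmax(.localNoise(y, params$noiseWindowPoints),
                .Machine$double.eps)
  base <- max(y)
  minInt <- max(params$absoluteIntensityCutoff,
                params$relativeIntensityCutoff * base)
  apex <- which(y[-c(1L, n)] >= y[-c(n - 1L, n)] &
                  y[-c(1L, n)] > y[-c(1L, 2L)]) + 1L
  if (!length(apex))
    return(PeakList(sampleId = sampleId, replicateId = replicateId))
  above <- y > noise
  # length of the contiguous above-noise run each point belongs to
  r <- rle(above)
  runLen <- rep(r$lengths, r$lengths)
  keep <- above[apex] &
    runLen[apex] >= params$minPointsPerPeak &
    (y[apex] / noise[apex]) >= params$minSnr &
    y[apex] >= minInt
  apex <- apex[keep]
  if (!length(apex))
    return(PeakList(sampleId = sampleId, replicateId = replicateId))
  # 3-point parabolic apex refinement
  ym1 <- y[apex - 1L]; y0 <- y[apex]; yp1 <- y[apex + 1L]
  denom <- ym1 - 2 * y0 + yp1
  delta <- ifelse(abs(denom) > 0, 0.5 * (ym1 - yp1) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  step <- ifelse(delta >= 0,
                 x[pmin(apex + 1L, n)] - x[apex],
                 x[apex] - x[pmax(apex - 1L, 1L)])
  mzApex <- x[apex] + delta * step
  intApex <- y0 - 0.25 * (ym1 - yp1) * delta
  PeakList(mzApex, intApex, sampleId, replicateId)
}

# greedy matching of reference m/z values to the nearest peak within tol
.matchReferences <- function(peaks, referenceMz, matchTolPpm) {
  obsIdx <- integer(0); refIdx <- integer(0)
  for (i in seq_along(referenceMz)) {
    tolDa <- .ppmToDa(referenceMz[i], matchTolPpm)
    d <- abs(mz(peaks) - referenceMz[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tolDa) {
      obsIdx <- c(obsIdx, j); refIdx <- c(refIdx, i)
    }
  }
  list(obs = obsIdx, ref = refIdx)
}

#' Internal (lock-mass) recalibration of a peak list
#'
#' Matches reference m/z values (characteristic high-intensity ions of
#' known mass, e.g. the internal standard and confidently matched library
#' ions) to the observed peaks, fits the observed ppm error as a linear
#' function of m/z, and applies the inverse correction to every peak. With
#' a single matched reference a constant ppm shift is applied. The
#' correction is only accepted if it does not increase the mean absolute
#' ppm error on the matched references; otherwise the next simpler model
#' (constant shift, then identity) is used.
#'
#' @param peaks a [PeakList-class].
#' @param referenceMz numeric vector of reference m/z values (Da).
#' @param matchTolPpm matching tolerance for locating references among the
#'   observed peaks (default 5 ppm).
#' @return The recalibrated [PeakList-class]; the applied correction is
#'   attached as attribute `"correction"` (`c(intercept_ppm,
#'   slope_ppm_per_da)`). If no reference matches, the input is returned
#'   unchanged with a warning.
#' @export
recalibrate <- function(peaks, referenceMz, matchTolPpm = 5) {
  stopifnot(is(peaks, "PeakList"))
  if (!length(referenceMz) || !length(peaks)) {
    warning("no reference ions available; peaks returned unchanged")
    return(peaks)
  }
  m <- .matchReferences(peaks, referenceMz, matchTolPpm)
  if (!length(m$obs)) {
    warning("no reference ion matched within ", matchTolPpm,
            " ppm; peaks returned unchanged")
    return(peaks)
  }
  obs <- mz(peaks)[m$obs]
  ref <- referenceMz[m$ref]
  err <- ppmError(obs, ref)
  meanAbs <- function(coefs) {
    corrected <- obs / (1 + (coefs[1] + coefs[2] * obs) * 1e-6)
    mean(abs(ppmError(corrected, ref)))
  }
  candidates <- list(identity = c(0, 0),
                     constant = c(mean(err), 0))
  if (length(m$obs) >= 2L) {
    fit <- lm(err ~ obs)
    candidates$linear <- c(unname(coef(fit)[1]), unname(coef(fit)[2]))
  }
  scores <- vapply(candidates, meanAbs, numeric(1))
  # prefer the richest model among those not worse than doing nothing
  ok <- which(scores <= scores[["identity"]] + 1e-12)
  best <- candidates[[ok[length(ok)]]]
  corrected <- mz(peaks) / (1 + (best[1] + best[2] * mz(peaks)) * 1e-6)
  out <- PeakList(corrected, intensity(peaks), sampleId(peaks),
                  replicateId(peaks))
  attr(out, "correction") <- c(intercept_ppm = best[1],
                               slope_ppm_per_da = best[2])
  out
}

#' Normalize peak intensities
#'
#' Divides every intensity by a reference quantity: the intensity of the
#' spiked internal standard (located by its theoretical m/z within a ppm
#' tolerance) or the total ion current. m/z values are unchanged.
#'
#' @param peaks a [PeakList-class].
#' @param method `"internal_standard"` or `"total_ion_current"`.
#' @param isMz theoretical m/z of the internal standard ion (required for
#'   the internal-standard method).
#' @param isTolPpm matching tolerance for the internal standard (default 5
#'   ppm).
#' @param fallback if `TRUE` and the internal standard is not found, fall
#'   back to total-ion-current normalization with a warning instead of
#'   erroring.
#' @return The normalized [PeakList-class].
#' @export
normalizeIntensities <- function(peaks,
                                 method = c("internal_standard",
                                            "total_ion_current"),
                                 isMz = NULL, isTolPpm = 5,
                                 fallback = FALSE) {
  method <- match.arg(method)
  stopifnot(is(peaks, "PeakList"))
  if (!length(peaks)) return(peaks)
  if (method == "internal_standard") {
    if (is.null(isMz)) stop("isMz is required for internal-standard normalization")
    d <- abs(mz(peaks) - isMz)
    j <- which.min(d)
    if (d[j] > .ppmToDa(isMz, isTolPpm)) {
      if (!fallback)
        stop(sprintf("internal standard not found within %g ppm of m/z %.4f",
                     isTolPpm, isMz))
      warning("internal standard not found; falling back to total ion current")
      method <- "total_ion_current"
    } else {
      ref <- intensity(peaks)[j]
      if (ref <= 0) stop("internal standard has non-positive intensity")
      return(PeakList(mz(peaks), intensity(peaks) / ref,
                      sampleId(peaks), replicateId(peaks)))
    }
  }
  tic <- sum(intensity(peaks))
  if (tic <= 0) stop("total ion current is non-positive")
  PeakList(mz(peaks), intensity(peaks) / tic,
           sampleId(peaks), replicateId(peaks))
}

# greedy pairing of two sorted m/z vectors: candidate pairs within the ppm
# tolerance accepted in order of increasing |ppm difference| (ties broken
# by m/z), each ion pairing at most once. Symmetric in its two arguments.
.greedyPairs <- function(mzA, mzB, matchTolPpm) {
  if (!length(mzA) || !length(mzB))
    return(data.frame(a = integer(0), b = integer(0)))
  lo <- findInterval(mzA / (1 + matchTolPpm * 1e-6), mzB) + 1L
  hi <- findInterval(mzA * (1 + matchTolPpm * 1e-6), mzB)
  nCand <- pmax(0L, hi - lo + 1L)
  ai <- rep(seq_along(mzA), nCand)
  bi <- unlist(lapply(seq_along(mzA), function(i)
    if (nCand[i] > 0L) lo[i]:hi[i] else integer(0)), use.names = FALSE)
  if (!length(ai)) return(data.frame(a = integer(0), b = integer(0)))
  dppm <- abs(mzA[ai] - mzB[bi]) / pmax(mzA[ai], mzB[bi]) * 1e6
  keep <- dppm <= matchTolPpm
  ai <- ai[keep]; bi <- bi[keep]; dppm <- dppm[keep]
  o <- order(dppm, mzA[ai], mzB[bi])
  ai <- ai[o]; bi <- bi[o]
  usedA <- logical(length(mzA)); usedB <- logical(length(mzB))
  selA <- integer(0); selB <- integer(0)
  for (k in seq_along(ai)) {
    if (!usedA[ai[k]] && !usedB[bi[k]]) {
      usedA[ai[k]] <- TRUE; usedB[bi[k]] <- TRUE
      selA <- c(selA, ai[k]); selB <- c(selB, bi[k])
    }
  }
  data.frame(a = selA, b = selB)
}

#' Technical-replicate consensus filtering
#'
#' Implements the both-replicates detection rule: an ion is retained only
#' if its m/z is registered in every technical replicate within the
#' matching tolerance. Peaks are paired greedily by increasing ppm
#' difference (each peak pairs at most once); unpaired peaks are
#' discarded. The consensus m/z is the intensity-weighted mean of the
#' contributing peaks. With more than two replicates the rule generalizes
#' to presence in all of them.
#'
#' @param ... two or more [PeakList-class] objects, or a single list of
#'   them (all replicates of one sample).
#' @param matchTolPpm m/z agreement tolerance between replicates (default
#'   5 ppm; wider than the instrument accuracy of about 3 ppm, narrower
#'   than typical peak spacing).
#' @return A [ConsensusIonTable-class] for the sample.
#' @examples
#' a <- PeakList(c(100.0000, 200.0000), c(1, 1), "S1", "TR1")
#' b <- PeakList(c(100.0002, 300.0000), c(1, 1), "S1", "TR2")
#' length(replicateConsensus(a, b))  # only the 100 Da ion survives
#' @export
replicateConsensus <- function(..., matchTolPpm = 5) {
  reps <- list(...)
  if (length(reps) == 1L && is.list(reps[[1]]) && !is(reps[[1]], "PeakList"))
    reps <- reps[[1]]
  if (length(reps) < 2L) stop("at least two technical replicates are required")
  for (r in reps) stopifnot(is(r, "PeakList"))
  sid <- sampleId(reps[[1]])
  repNames <- vapply(seq_along(reps), function(i) {
    rid <- replicateId(reps[[i]])
    if (is.na(rid)) paste0("TR", i) else rid
  }, character(1))

  # state: consensus mz + per-replicate intensity/source columns so far
  consMz <- mz(reps[[1]])
  intMat <- matrix(intensity(reps[[1]]), ncol = 1)
  srcMat <- matrix(seq_along(consMz), ncol = 1)
  wSum <- intensity(reps[[1]])
  mzWSum <- consMz * intensity(reps[[1]])
  for (i in seq_along(reps)[-1]) {
    pr <- .greedyPairs(consMz, mz(reps[[i]]), matchTolPpm)
    iInt <- intensity(reps[[i]])[pr$b]
    intMat <- cbind(intMat[pr$a, , drop = FALSE], iInt)
    srcMat <- cbind(srcMat[pr$a, , drop = FALSE], pr$b)
    wSum <- wSum[pr$a] + iInt
    mzWSum <- mzWSum[pr$a] + mz(reps[[i]])[pr$b] * iInt
    consMz <- ifelse(wSum > 0, mzWSum / wSum,
                     rowMeans(cbind(consMz[pr$a], mz(reps[[i]])[pr$b])))
  }
  consMz <- as.numeric(consMz)   # ifelse() on zero ions yields logical(0)
  o <- order(consMz)
  intMat <- intMat[o, , drop = FALSE]
  srcMat <- srcMat[o, , drop = FALSE]
  colnames(intMat) <- repNames
  colnames(srcMat) <- repNames
  new("ConsensusIonTable", sampleId = sid, mz = consMz[o],
      intensities = intMat,
      sourceIndex = matrix(as.integer(srcMat), nrow = nrow(srcMat),
                           ncol = ncol(srcMat), dimnames = dimnames(srcMat)))
}
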