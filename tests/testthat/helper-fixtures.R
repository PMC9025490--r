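# Shared fixtures and independent oracles used across the suite.

# a minimal one-group design for degenerate-case tests
tinyDesign <- function(nSamples = 3L, prevalence = 1, noise = 0L,
                       dropout = 0, seed = 1L, ...) {
  panel <- data.frame(compound_id = "CMP1", name = "test compound",
                      neutral_mass = 400.1234, stringsAsFactors = FALSE)
  prev <- matrix(prevalence, 1, 1,
                 dimnames = list("CMP1", "grpA"))
  cohortDesign(groups = c(grpA = nSamples), panel = panel, prevalence = prev,
               noisePeaksPerSpectrum = noise, replicateDropoutProb = dropout,
               seed = seed, ...)
}

# brute-force all-pairs annotation oracle: every (ion, compound, adduct)
# with |ppm| <= tol, computed as a dense ions x candidates error matrix --
# independent of the sorted interval-query implementation
bruteForceAnnotate <- function(mzv, library, adducts = defaultAdducts(),
                               tolPpm = 2) {
  nL <- nrow(library); nA <- nrow(adducts)
  theo <- (rep(library$neutral_mass, times = nA) +
             rep(adducts$mass_shift, each = nL)) /
    rep(adducts$charge, each = nL)
  comp <- rep(library$compound_id, times = nA)
  addn <- rep(adducts$name, each = nL)
  err <- outer(mzv, theo, function(o, t) (o - t) / t * 1e6)
  hit <- which(abs(err) <= tolPpm, arr.ind = TRUE)
  out <- data.frame(ion = hit[, 1], compound_id = comp[hit[, 2]],
                    adduct = addn[hit[, 2]], stringsAsFactors = FALSE)
  out[order(out$ion, out$compound_id, out$adduct), , drop = FALSE]
}

# brute-force pairing oracle for replicate consensus on well-separated
# data: each peak's candidate set within tol must be unique, and the
# expected pairing is exactly the set of all-pairs matches
bruteForcePairs <- function(mzA, mzB, tolPpm) {
  pairs <- list()
  for (i in seq_along(mzA)) {
    for (j in seq_along(mzB)) {
      d <- abs(mzA[i] - mzB[j]) / max(mzA[i], mzB[j]) * 1e6
      if (d <= tolPpm)
        pairs[[length(pairs) + 1L]] <- c(a = i, b = j)
    }
  }
  if (!length(pairs)) return(data.frame(a = integer(0), b = integer(0)))
  as.data.frame(do.call(rbind, pairs))
}

# detection matrix with a fixed number of positives, for frequency
# worked examples: `count` detected samples out of `n`
countMatrix <- function(count, n, compound = "CMP", group = "g") {
  det <- matrix(seq_len(n) <= count, nrow = 1,
                dimnames = list(compound, sprintf("S%02d", seq_len(n))))
  manifest <- data.frame(sample_id = colnames(det), group = group,
                         stringsAsFactors = FALSE)
  list(det = det, manifest = manifest)
}

# the study-shaped design with planted presence/absence markers (control
# probability 0, case probability 0.9 in the n = 31 group) and planted
# null metabolites present everywhere at the same probability
recoveryDesign <- function(seed, caseProb = 0.9, nullProb = 0.5) {
  ids <- c(paste0("MARKER", 1:3), paste0("NULLMET", 1:3))
  panel <- data.frame(compound_id = ids, name = ids,
                      neutral_mass = c(310.1234, 455.2468, 610.9753,
                                       280.1111, 505.3333, 730.2222),
                      stringsAsFactors = FALSE)
  prev <- rbind(matrix(rep(c(0, 0, 0, caseProb), each = 3), 3),
                matrix(nullProb, 3, 4))
  dimnames(prev) <- list(ids, c("group1", "group2", "group3", "group4"))
  cohortDesign(groups = c(group1 = 25L, group2 = 3L,
                          group3 = 20L, group4 = 31L),
               panel = panel, prevalence = prev, seed = seed)
}

# consensus -> annotation -> frequencies -> selection on a generated
# cohort; returns the selected compound ids
runMarkerSelection <- function(design, controlGroups = "group1",
                               caseGroups = "group4",
                               maxControlFrequency = 0,
                               minCaseFrequency = 0.5, alpha = 0.05,
                               tolPpm = 2) {
  cohort <- generateCohort(design)
  mf <- as.data.frame(cohort$manifest)
  lib <- design@panel
  cons <- lapply(split(seq_len(nrow(mf)), mf$sample_id), function(idx) {
    keys <- paste(mf$sample_id[idx], mf$replicate_id[idx], sep = "_")
    replicateConsensus(cohort$peakLists[keys], matchTolPpm = 5)
  })
  ann <- annotateCohort(cons, lib, tolPpm = tolPpm)
  det <- buildDetectionMatrix(ann, cohort$manifest, compounds = lib)
  freqs <- groupFrequency(det)
  sel <- selectMarkers(freqs, controlGroups, caseGroups,
                       maxControlFrequency = maxControlFrequency,
                       minCaseFrequency = minCaseFrequency, alpha = alpha)
  sel$compound_id
}
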