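test_that("peak detection handles degenerate traces", {
  empty <- data.frame(mz = seq(100, 101, 0.01), intensity = 0)
  expect_length(detectPeaks(empty), 0)
  short <- data.frame(mz = c(100, 100.01), intensity = c(1, 2))
  expect_warning(res <- detectPeaks(short), "shorter")
  expect_length(res, 0)
})

test_that("a noise-free Gaussian is centroided onto its center", {
  tr <- generateProfileSpectrum(PeakList(423.169, 5e4), peakWidth = 0.02,
                                gridStep = 0.005)
  det <- detectPeaks(tr)
  expect_length(det, 1)
  expect_lt(abs(mz(det) - 423.169), 0.005)
  # parabolic refinement does better than the raw grid
  expect_lt(abs(mz(det) - 423.169), 0.002)
})

test_that("planted peaks above the cutoffs are found, those below are not", {
  strong <- seq(150, 600, by = 50)       # 10 peaks, intensity 1e5
  weak <- seq(650, 850, by = 50)         # 5 peaks below the relative cutoff
  pl <- PeakList(c(strong, weak), c(rep(1e5, 10), rep(5, 5)))
  tr <- generateProfileSpectrum(pl, peakWidth = 0.02, gridStep = 0.004)
  det <- detectPeaks(tr, peakDetectionParams(relativeIntensityCutoff = 1e-4,
                                             absoluteIntensityCutoff = 0))
  expect_length(det, 10)
  expect_true(all(vapply(strong, function(m) any(abs(mz(det) - m) < 0.02),
                         logical(1))))
  # invariant: no reported peak sits below either intensity cutoff
  expect_true(all(intensity(det) >= 1e-4 * max(tr$intensity)))
})

test_that("recalibration removes injected constant and linear drifts", {
  refs <- c(150.05, 423.169, 618.579, 850.3)
  others <- seq(100, 900, by = 37.7)
  clean <- sort(c(refs, others))
  intens <- rep(1e4, length(clean))

  # no drift: output identical to input
  pl0 <- PeakList(clean, intens)
  out0 <- recalibrate(pl0, refs, matchTolPpm = 5)
  expect_equal(mz(out0), clean, tolerance = 1e-12)

  # +5 ppm constant drift
  pl1 <- PeakList(clean * (1 + 5e-6), intens)
  out1 <- recalibrate(pl1, refs, matchTolPpm = 10)
  resid1 <- vapply(refs, function(r) min(abs(ppmError(mz(out1), r))), numeric(1))
  expect_lt(mean(resid1), 0.1)

  # linear drift: 0 ppm at m/z 50 rising to 6 ppm at m/z 1000
  drift <- function(m) (m - 50) / 950 * 6
  pl2 <- PeakList(clean * (1 + drift(clean) * 1e-6), intens)
  out2 <- recalibrate(pl2, refs, matchTolPpm = 10)
  resid2 <- vapply(refs, function(r) min(abs(ppmError(mz(out2), r))), numeric(1))
  expect_lt(max(resid2), 0.2)
})

test_that("recalibration never worsens the reference errors", {
  set.seed(21)
  refs <- c(150.05, 423.169, 618.579, 850.3)
  for (i in 1:20) {
    a <- runif(1, -6, 6); b <- runif(1, -0.005, 0.005)
    obs <- refs * (1 + (a + b * refs) * 1e-6) +
      rnorm(length(refs), 0, 1e-4)
    pl <- PeakList(sort(obs), rep(1, 4))
    before <- mean(abs(ppmError(sort(obs), sort(refs))))
    out <- recalibrate(pl, refs, matchTolPpm = 20)
    after <- mean(vapply(refs, function(r) min(abs(ppmError(mz(out), r))),
                         numeric(1)))
    expect_lte(after, before + 1e-9)
  }
})

test_that("no matched reference leaves peaks unchanged with a warning", {
  pl <- PeakList(c(100, 200), c(1, 1))
  expect_warning(out <- recalibrate(pl, 500.5, matchTolPpm = 5), "no reference")
  expect_identical(mz(out), mz(pl))
})

test_that("normalization divides by the reference quantity", {
  pl <- PeakList(c(300.1, 423.1695), c(4, 2), "S1", "TR1")
  out <- normalizeIntensities(pl, "internal_standard", isMz = 423.1695)
  expect_equal(intensity(out), c(2, 1))
  tic <- normalizeIntensities(pl, "total_ion_current")
  expect_equal(sum(intensity(tic)), 1)
  # scale invariance under both methods
  pl10 <- PeakList(mz(pl), intensity(pl) * 10, "S1", "TR1")
  expect_equal(intensity(normalizeIntensities(pl10, "internal_standard",
                                              isMz = 423.1695)),
               intensity(out))
  expect_equal(intensity(normalizeIntensities(pl10, "total_ion_current")),
               intensity(tic))
  # missing IS: error, or TIC fallback when allowed
  expect_error(normalizeIntensities(pl, "internal_standard", isMz = 800),
               "not found")
  expect_warning(fb <- normalizeIntensities(pl, "internal_standard",
                                            isMz = 800, fallback = TRUE),
                 "falling back")
  expect_equal(intensity(fb), intensity(tic))
})

test_that("consensus keeps only ions registered in both replicates", {
  a <- PeakList(c(100.0000, 200.0000, 300.0000), c(1, 2, 3), "S1", "TR1")
  cons <- replicateConsensus(a, a)
  expect_length(cons, 3)
  expect_equal(mz(cons), mz(a))
  b <- PeakList(c(100.0002, 400.0), c(1, 1), "S1", "TR2")
  cons2 <- replicateConsensus(a, b, matchTolPpm = 5)
  expect_length(cons2, 1)          # only the 100 Da ion is in both
  expect_gte(mz(cons2), 100.0000)
  expect_lte(mz(cons2), 100.0002)  # consensus m/z between contributors
  expect_length(replicateConsensus(PeakList(), PeakList()), 0)
})

test_that("consensus is symmetric in its replicate arguments", {
  set.seed(33)
  for (i in 1:10) {
    base <- sort(runif(15, 100, 900))
    a <- PeakList(base * (1 + rnorm(15, 0, 2) * 1e-6), runif(15), "S", "TR1")
    b <- PeakList(base * (1 + rnorm(15, 0, 2) * 1e-6), runif(15), "S", "TR2")
    ab <- replicateConsensus(a, b, matchTolPpm = 5)
    ba <- replicateConsensus(b, a, matchTolPpm = 5)
    expect_equal(sort(mz(ab)), sort(mz(ba)))
  }
})

test_that("greedy pairing equals exhaustive matching on well-separated ions", {
  set.seed(44)
  for (i in 1:30) {
    n <- sample(3:20, 1)
    base <- 100 + cumsum(runif(n, 0.5, 5))   # >> 5 ppm apart
    offs <- runif(n, -3e-6, 3e-6)            # within 3 ppm
    keepB <- runif(n) > 0.2
    a <- PeakList(base, rep(1, n), "S", "TR1")
    b <- PeakList(base[keepB] * (1 + offs[keepB]), rep(1, sum(keepB)),
                  "S", "TR2")
    cons <- replicateConsensus(a, b, matchTolPpm = 5)
    oracle <- bruteForcePairs(mz(a), mz(b), 5)
    # on separated data the oracle pairing is unique and must be matched
    expect_equal(length(cons), nrow(oracle))
    expect_equal(sort(unname(cons@sourceIndex[, 1])), sort(oracle$a))
  }
})

test_that("the consensus rule generalizes to three replicates", {
  a <- PeakList(c(100, 200, 300), c(1, 1, 1), "S1", "TR1")
  b <- PeakList(c(100.0001, 200.0002), c(1, 1), "S1", "TR2")
  c3 <- PeakList(c(100.0002, 300.0001), c(1, 1), "S1", "TR3")
  cons <- replicateConsensus(list(a, b, c3), matchTolPpm = 5)
  expect_length(cons, 1)  # only 100 Da is in all three
  expect_equal(ncol(intensity(cons)), 3)
})
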