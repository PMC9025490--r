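losartanLib <- CompoundLibrary(data.frame(
  compound_id = "IS_LOSARTAN", name = "losartan", formula = "C22H23ClN6O"))

test_that("accurate-mass annotation reproduces the worked examples", {
  ann <- annotateIons(423.1695, losartanLib, tolPpm = 2)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$adduct, "[M+H]+")
  expect_lte(abs(ann$ppm_error), 2)

  cer <- CompoundLibrary(data.frame(compound_id = "HMDB0011764",
                                    name = "Cer(d18:0/20:0)",
                                    neutral_mass = 595.59))
  ann2 <- annotateIons(618.580, cer, tolPpm = 5)
  expect_equal(ann2$adduct, "[M+Na]+")
  expect_equal(ann2$theoretical_mz, 618.579218, tolerance = 1e-6)

  # an m/z with no library neighbour inside the window
  expect_equal(nrow(annotateIons(500.000, pePanelLibrary(), tolPpm = 2)), 0)
})

test_that("candidates come back sorted by |ppm error| and are unique per ion", {
  lib <- CompoundLibrary(data.frame(
    compound_id = c("A", "B"), name = c("a", "b"),
    neutral_mass = c(499.0000, 499.0004)))
  ann <- annotateIons(500.0075, lib, tolPpm = 3)
  expect_equal(nrow(ann), 2)
  expect_true(all(diff(abs(ann$ppm_error)) >= 0))
  expect_false(any(duplicated(paste(ann$compound_id, ann$adduct))))
})

test_that("interval query equals the brute-force all-pairs scan", {
  set.seed(7)
  for (i in 1:15) {
    nLib <- sample(20:120, 1)
    lib <- CompoundLibrary(data.frame(
      compound_id = sprintf("C%03d", seq_len(nLib)),
      name = "x", neutral_mass = runif(nLib, 60, 950)))
    # half random ions, half planted on adduct masses with small errors
    planted <- adductMz(sample(lib$neutral_mass, 20, replace = TRUE),
                        sample(defaultAdducts()$name, 20, replace = TRUE)) *
      (1 + rnorm(20, 0, 1) * 1e-6)
    ions <- c(runif(20, 60, 990), planted)
    ann <- as.data.frame(annotateIons(ions, lib, tolPpm = 2))
    oracle <- bruteForceAnnotate(ions, lib, tolPpm = 2)
    got <- ann[order(match(ann$mz, ions), ann$compound_id, ann$adduct),
               c("compound_id", "adduct")]
    expect_equal(nrow(ann), nrow(oracle))
    expect_equal(got$compound_id, oracle$compound_id)
    expect_equal(got$adduct, oracle$adduct)
  }
})

test_that("tightening the tolerance never adds annotations", {
  set.seed(8)
  lib <- CompoundLibrary(data.frame(compound_id = sprintf("C%02d", 1:50),
                                    name = "x",
                                    neutral_mass = runif(50, 60, 950)))
  ions <- runif(300, 60, 990)
  for (tols in list(c(0.5, 2), c(1, 5), c(2, 10))) {
    tight <- as.data.frame(annotateIons(ions, lib, tolPpm = tols[1]))
    loose <- as.data.frame(annotateIons(ions, lib, tolPpm = tols[2]))
    keyT <- paste(tight$mz, tight$compound_id, tight$adduct)
    keyL <- paste(loose$mz, loose$compound_id, loose$adduct)
    expect_true(all(keyT %in% keyL))
  }
})

test_that("detection matrix cells reflect annotations exactly", {
  manifest <- data.frame(sample_id = c("S1", "S2", "S3"),
                         group = c("g1", "g1", "g2"))
  ann <- DataFrame(sample_id = "S2", replicate_id = NA_character_,
                   mz = 423.1694, compound_id = "X", adduct = "[M+H]+",
                   theoretical_mz = 423.1695, ppm_error = -0.2)
  se <- buildDetectionMatrix(ann, manifest)
  det <- SummarizedExperiment::assay(se, "detected")
  expect_equal(dim(det), c(1L, 3L))
  expect_true(det["X", "S2"])
  expect_equal(sum(det), 1)

  empty <- buildDetectionMatrix(ann[0, ], manifest, compounds = c("X", "Y"))
  expect_equal(dim(SummarizedExperiment::assay(empty)), c(2L, 3L))
  expect_false(any(SummarizedExperiment::assay(empty)))

  bad <- DataFrame(sample_id = "S9", compound_id = "X")
  expect_error(buildDetectionMatrix(bad, manifest), "unknown sample.*S9")
})

test_that("pipeline detections equal the planted truth without dropout", {
  d <- recoveryDesign(seed = 31)
  d@replicateDropoutProb <- 0
  # keep the mass error well inside the 2 ppm annotation window so the
  # detection matrix is an exact image of the planted presence
  d@massErrorPpmSd <- 0.2
  cohort <- generateCohort(d)
  mf <- as.data.frame(cohort$manifest)
  cons <- lapply(split(seq_len(nrow(mf)), mf$sample_id), function(idx) {
    keys <- paste(mf$sample_id[idx], mf$replicate_id[idx], sep = "_")
    replicateConsensus(cohort$peakLists[keys], matchTolPpm = 5)
  })
  ann <- annotateCohort(cons, d@panel, tolPpm = 2)
  se <- buildDetectionMatrix(ann, cohort$manifest, compounds = d@panel)
  det <- SummarizedExperiment::assay(se, "detected")
  truth <- t(cohort$truth$presence)[rownames(det), colnames(det)]
  expect_equal(det, truth)
})
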