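test_that("group frequencies are detected count over group size", {
  cm <- countMatrix(3, 25, group = "group1")
  ft <- groupFrequency(cm$det, cm$manifest)
  expect_equal(ft$detected_count, 3L)
  expect_equal(round(ft$frequency, 2), 0.12)

  cm0 <- countMatrix(0, 17)
  expect_equal(groupFrequency(cm0$det, cm0$manifest)$frequency, 0)

  # an expected group with no samples is a hard error, named
  det <- matrix(TRUE, 1, 2, dimnames = list("X", c("S1", "S2")))
  mf <- data.frame(sample_id = c("S1", "S2"), group = "g1")
  expect_error(groupFrequency(det, mf, groups = c("g1", "g2")),
               "empty group.*g2")
})

test_that("every published (count, size) pair rounds to its printed frequency", {
  pairs <- list(c(1, 25, 0.04), c(2, 25, 0.08), c(3, 25, 0.12),
                c(2, 3, 0.67), c(3, 3, 1.00), c(1, 20, 0.05),
                c(1, 31, 0.03), c(2, 31, 0.06), c(3, 31, 0.10))
  for (p in pairs) {
    cm <- countMatrix(p[1], p[2])
    ft <- groupFrequency(cm$det, cm$manifest)
    expect_equal(round(ft$frequency, 2), p[3],
                 info = sprintf("%d/%d", p[1], p[2]))
  }
})

test_that("frequency x group size recovers the count exactly", {
  ft <- pePanelFrequencies()
  expect_equal(ft$frequency * ft$group_size, as.numeric(ft$detected_count))
})

test_that("marker selection applies the presence/absence rule", {
  ft <- DataFrame(
    compound_id = rep(c("A", "B"), each = 2),
    group = rep(c("ctrl", "case"), 2),
    detected_count = c(0L, 2L, 5L, 5L),
    group_size = c(25L, 3L, 10L, 10L),
    frequency = c(0, 2 / 3, 0.5, 0.5))
  sel <- selectMarkers(ft, "ctrl", "case")
  expect_equal(sel$compound_id, "A")   # 0 vs 0.67 selected
  # equal frequencies 0.5 / 0.5 never qualify under the default rule
  expect_false("B" %in% sel$compound_id)
  expect_error(selectMarkers(ft, "ctrl", "ctrl"), "disjoint")
  expect_error(selectMarkers(ft, "ctrl", "nope"), "not present")
})

test_that("the published panel is selected whole under the study thresholds", {
  sel <- selectMarkers(pePanelFrequencies(), "group1", "group2",
                       maxControlFrequency = 0.15, minCaseFrequency = 0.5)
  expect_setequal(sel$compound_id, pePanelLibrary()$compound_id)
  expect_equal(nrow(sel), 9)
})

test_that("exact test agrees with Fisher and with the worked cases", {
  expect_equal(frequencyDifferenceTest(0, 10, 0, 10), 1.0)
  expect_lt(frequencyDifferenceTest(0, 25, 3, 3), 0.05)
  # independent route: stats::fisher.test on the same 2x2 table
  p1 <- frequencyDifferenceTest(0, 20, 3, 31)
  f1 <- fisher.test(matrix(c(0, 20, 3, 31 - 3), 2))$p.value
  expect_equal(p1, f1, tolerance = 1e-12)
  expect_error(frequencyDifferenceTest(0, 0, 1, 5), ">= 1")
  expect_error(frequencyDifferenceTest(6, 5, 1, 5), "<=")
})

test_that("the exact-test filter removes non-significant selections", {
  ft <- DataFrame(compound_id = rep("A", 2), group = c("ctrl", "case"),
                  detected_count = c(0L, 2L), group_size = c(3L, 3L),
                  frequency = c(0, 2 / 3))
  expect_equal(nrow(selectMarkers(ft, "ctrl", "case")), 1)
  # 0/3 vs 2/3 is not significant at alpha = 0.05
  expect_equal(nrow(selectMarkers(ft, "ctrl", "case", alpha = 0.05)), 0)
})

test_that("replicate-level frequencies use replicate spectra as units", {
  mf <- data.frame(sample_id = rep(c("S1", "S2", "S3"), each = 2),
                   group = "g1",
                   replicate_id = rep(c("TR1", "TR2"), 3))
  ann <- DataFrame(sample_id = c("S1", "S2"), replicate_id = c("TR1", "TR2"),
                   compound_id = "X")
  ft <- replicateLevelFrequency(ann, mf)
  expect_equal(ft$group_size, 6L)
  expect_equal(round(ft$frequency, 2), 0.33)
  annAll <- DataFrame(sample_id = mf$sample_id, replicate_id = mf$replicate_id,
                      compound_id = "X")
  expect_equal(replicateLevelFrequency(annAll, mf)$frequency, 1)
})

test_that("without dropout, replicate-level equals sample-level frequency", {
  d <- tinyDesign(nSamples = 20L, prevalence = 0.6, noise = 0, dropout = 0,
                  seed = 12)
  cohort <- generateCohort(d)
  lib <- d@panel
  ann <- annotateCohort(cohort$peakLists, lib, tolPpm = 5)
  repFt <- replicateLevelFrequency(ann, cohort$manifest)
  mf <- as.data.frame(cohort$manifest)
  cons <- lapply(split(seq_len(nrow(mf)), mf$sample_id), function(idx) {
    keys <- paste(mf$sample_id[idx], mf$replicate_id[idx], sep = "_")
    replicateConsensus(cohort$peakLists[keys], matchTolPpm = 5)
  })
  det <- buildDetectionMatrix(annotateCohort(cons, lib, tolPpm = 5),
                              cohort$manifest, compounds = lib)
  samFt <- groupFrequency(det)
  expect_equal(repFt$frequency[repFt$compound_id == "CMP1"],
               samFt$frequency[samFt$compound_id == "CMP1"])
})
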