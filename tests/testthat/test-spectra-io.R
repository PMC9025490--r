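test_that("delimited peak lists load sorted and validated", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("423.169,1000", "100.05,20", "250.1,5"), p)
  pl <- readPeakList(p, sampleId = "S1", replicateId = "TR1")
  expect_s4_class(pl, "PeakList")
  expect_length(pl, 3)
  expect_equal(mz(pl), c(100.05, 250.1, 423.169))
  expect_equal(sampleId(pl), "S1")
})

test_that("malformed rows and negative intensities are rejected with position", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "100.1,5", "oops,3"), p)
  expect_error(readPeakList(p), "line 3")
  writeLines(c("100.1,5", "200.2,-1"), p)
  expect_error(readPeakList(p), "negative intensity.*line 2")
  writeLines(c("100.1,5", "1500.0,3"), p)
  expect_error(readPeakList(p, mzRange = c(50, 1000)), "outside")
})

test_that("an empty peak-list file yields an empty PeakList with a warning", {
  p <- withr::local_tempfile(fileext = ".tsv")
  file.create(p)
  expect_warning(pl <- readPeakList(p), "empty")
  expect_length(pl, 0)
})

test_that("peak lists round-trip through write/read to 6 decimal places", {
  p <- withr::local_tempfile(fileext = ".tsv")
  pl <- PeakList(c(100.123456, 423.169459, 999.999999),
                 c(1.5, 2e5, 0.004), "S1", "TR2")
  writePeakList(pl, p)
  back <- readPeakList(p, sampleId = "S1", replicateId = "TR2")
  expect_equal(round(mz(back), 6), round(mz(pl), 6))
  expect_equal(intensity(back), intensity(pl), tolerance = 1e-6)
})

test_that("the panel library loads all nine records unflagged", {
  lib <- pePanelLibrary()
  expect_s4_class(lib, "CompoundLibrary")
  expect_equal(nrow(lib), 9)
  expect_false(any(lib$inconsistent))
  expect_true("HMDB0011764" %in% lib$compound_id)
  expect_equal(lib$neutral_mass[lib$compound_id == "HMDB0011764"], 595.59)
})

test_that("library masses are backfilled from formulas and duplicates rejected", {
  lib <- CompoundLibrary(data.frame(compound_id = "X1", name = "water",
                                    formula = "H2O"))
  expect_equal(lib$neutral_mass, monoisotopicMass("H2O"))
  expect_error(
    CompoundLibrary(data.frame(compound_id = c("A", "A"),
                               name = c("a", "a"),
                               neutral_mass = c(100, 200))),
    "duplicate compound_id.*A")
  expect_error(
    CompoundLibrary(data.frame(compound_id = "B", name = "b")),
    "neither formula nor neutral_mass.*B")
  # stated mass inconsistent with the formula is flagged, not rejected
  lib2 <- CompoundLibrary(data.frame(compound_id = "C1", name = "c",
                                     formula = "H2O", neutral_mass = 18.5))
  expect_true(lib2$inconsistent)
})

test_that("frequency reports print 2 dp and round-trip counts exactly", {
  ft <- DataFrame(compound_id = "HMDB0003689", group = "group1",
                  detected_count = 3L, group_size = 25L, frequency = 3 / 25)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeFrequencyReport(ft, p)
  txt <- readLines(p)
  expect_match(txt[2], "0\\.12")
  expect_match(txt[2], "\t3\t")
  back <- readFrequencyReport(p)
  expect_equal(back$detected_count, 3L)
  expect_equal(back$frequency, 0.12)

  # empty table: header-only file
  writeFrequencyReport(DataFrame(), p)
  expect_equal(readLines(p), "compound_id")

  # full-precision round trip on the published panel counts
  writeFrequencyReport(pePanelFrequencies(), p)
  back <- as.data.frame(readFrequencyReport(p))
  orig <- as.data.frame(pePanelFrequencies())
  back <- back[order(back$compound_id, back$group), ]
  orig <- orig[order(orig$compound_id, orig$group), ]
  expect_equal(back$detected_count, orig$detected_count)
  expect_equal(back$frequency, orig$frequency)
})

test_that("manifest validation enforces replicates and unique groups", {
  mf <- data.frame(sample_id = c("S1", "S1", "S2"),
                   group = c("g1", "g1", "g2"),
                   replicate_id = c("TR1", "TR2", "TR1"))
  expect_error(validateManifest(mf), "fewer than 2")
  mf2 <- data.frame(sample_id = c("S1", "S1"), group = c("g1", "g2"),
                    replicate_id = c("TR1", "TR2"))
  expect_error(validateManifest(mf2), "more than one group")
  p <- withr::local_tempfile(fileext = ".tsv")
  ok <- data.frame(sample_id = rep(c("S1", "S2"), each = 2),
                   group = rep(c("g1", "g2"), each = 2),
                   replicate_id = rep(c("TR1", "TR2"), 2))
  write.table(ok, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(mfr <- readCohortManifest(p))
  expect_equal(nrow(mfr), 4)
  expect_error(readCohortManifest(p, groups = "g1"), "undeclared group")
})
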