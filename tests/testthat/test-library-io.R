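test_that("canonical CSV parses into a valid library with a correct count index", {
  lib <- toyLibrary()
  p <- withr::local_tempfile(fileext = ".csv")
  writeShiftLibrary(lib, p, "csv")
  got <- readShiftLibrary(p, "csv")
  expect_s4_class(got, "ShiftLibrary")
  expect_identical(moleculeIds(got), c("m1", "m2"))
  idx <- countIndex(got)
  expect_identical(idx[["3_2"]], "m1")
  expect_identical(idx[["1_0"]], "m2")
  expect_identical(solventLabel(got), "water")
})

test_that("CSV and JSON serializations of the same data are equivalent", {
  lib <- toyLibrary()
  pc <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  writeShiftLibrary(lib, pc, "csv")
  writeShiftLibrary(lib, pj, "json")
  expect_library_equal(readShiftLibrary(pc, "csv"), readShiftLibrary(pj, "json"))
})

test_that("round-trips are bit-exact for both formats on arbitrary libraries", {
  for (seed in c(11, 12, 13, 14, 15)) {
    lib <- randomRecordsLibrary(10, seed)
    # irrational-looking doubles: ensure full-precision serialization
    lib@carbonShifts <- lapply(lib@carbonShifts, function(x) x + pi * 1e-8)
    for (fmt in c("csv", "json")) {
      p <- withr::local_tempfile(fileext = paste0(".", fmt))
      writeShiftLibrary(lib, p, fmt)
      got <- readShiftLibrary(p, fmt)
      expect_library_equal(got, lib)
      # determinism: a second read of the same file is identical
      expect_library_equal(got, readShiftLibrary(p, fmt))
    }
  }
})

test_that("zero-proton molecules survive the round-trip with an empty channel", {
  lib <- shiftLibrary(list(shiftRecord("noH", carbonShifts = c(5, 15))),
                      solvent = "water")
  for (fmt in c("csv", "json")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeShiftLibrary(lib, p, fmt)
    got <- readShiftLibrary(p, fmt)
    expect_identical(protonShifts(got, "noH"), numeric())
    expect_identical(carbonShifts(got, "noH"), c(5, 15))
  }
})

test_that("malformed inputs fail loudly with context", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,solvent,nucleus,shift_ppm",
               "m1,water,13C,12.5",
               "m1,water,13C,not_a_number"), p)
  expect_error(readShiftLibrary(p, "csv"), "non-numeric.*m1")

  writeLines("molecule_id,solvent,nucleus,shift_ppm", p)
  expect_error(readShiftLibrary(p, "csv"), "empty library")

  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(solvent = "w", molecules = list(
    list(molecule_id = "a", carbon_shifts = list(1)),
    list(molecule_id = "a", carbon_shifts = list(2)))), pj, auto_unbox = TRUE)
  expect_error(readShiftLibrary(pj, "json"), "duplicate molecule_id: a")

  expect_error(readShiftLibrary("/no/such/file.csv", "csv"), "no such path")
  expect_error(shiftLibrary(list()), "at least one molecule")
})

test_that("an affine converter re-references shifts at read time", {
  lib <- toyLibrary()
  p <- withr::local_tempfile(fileext = ".csv")
  writeShiftLibrary(lib, p, "csv")
  got <- readShiftLibrary(p, "csv",
    converter = list(carbon = c(slope = 2, intercept = 1)))
  expect_equal(carbonShifts(got, "m1"), 2 * c(10, 20, 30) + 1)
  expect_equal(protonShifts(got, "m1"), c(1.2, 3.4))  # untouched channel
})

test_that("MOL-directory format reads the tab-separated shift table", {
  d <- withr::local_tempdir()
  writeLines(c("molecule_id\tnucleus\tshift_ppm",
               "m1\t13C\t10", "m1\t13C\t20", "m1\t1H\t1.5",
               "m2\t13C\t99.5"),
             file.path(d, "shifts.tsv"))
  writeLines("dummy mol content", file.path(d, "m1.mol"))
  got <- readShiftLibrary(d, "moldir")
  expect_identical(moleculeIds(got), c("m1", "m2"))
  expect_equal(carbonShifts(got, "m1"), c(10, 20))
  expect_equal(protonShifts(got, "m2"), numeric())
})

test_that("summarize totals and histograms are consistent with the count index", {
  s <- summarizeLibrary(toyLibrary())
  expect_identical(s@nMolecules, 2L)
  expect_identical(s@nCarbonNuclei, 4L)
  expect_identical(s@nHydrogenNuclei, 2L)

  for (seed in c(21, 22, 23)) {
    lib <- randomRecordsLibrary(30, seed)
    s <- summarizeLibrary(lib)
    idx <- countIndex(lib)
    expect_identical(sum(lengths(idx)), s@nMolecules)
    counts <- nucleusCounts(lib)
    expect_identical(s@nCarbonNuclei, sum(counts$nC))
    expect_identical(s@nHydrogenNuclei, sum(counts$nH))
    # histogram mass equals molecule count; weighted sums equal nucleus totals
    expect_identical(sum(s@carbonHist), s@nMolecules)
    expect_equal(sum(as.integer(names(s@carbonHist)) * s@carbonHist),
                 s@nCarbonNuclei)
    # every record reachable from the index
    expect_setequal(unlist(idx, use.names = FALSE), moleculeIds(lib))
  }
})
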