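# Shared fixtures: tiny hand-built libraries and a random-library factory.

toyRecords <- function() {
  list(shiftRecord("m1", carbonShifts = c(10, 20, 30),
                   protonShifts = c(1.2, 3.4)),
       shiftRecord("m2", carbonShifts = c(100)))
}

toyLibrary <- function() shiftLibrary(toyRecords(), solvent = "water")

# library with count structure {m1:(3,2), m2:(1,4), m3:(4,6), m4:(2,3)}
countToyLibrary <- function() {
  shiftLibrary(list(
    shiftRecord("m1", c(10, 20, 30), c(1, 2)),
    shiftRecord("m2", c(50), c(3, 4, 5, 6)),
    shiftRecord("m3", c(60, 70, 80, 90), c(7, 8, 9, 10, 11, 0.5)),
    shiftRecord("m4", c(110, 120), c(1.5, 2.5, 3.5))),
    solvent = "toy")
}

randomLibrary <- function(n, seed, ...) {
  generateLibrary(librarySpec(n, seed = seed, ...))
}

# random valid library built record by record (exercises IO independently of
# the generator's cluster structure)
randomRecordsLibrary <- function(n, seed) {
  withr::with_seed(seed, {
    recs <- lapply(seq_len(n), function(i) {
      nc <- sample(0:6, 1)
      nh <- if (nc == 0) sample(1:8, 1) else sample(0:8, 1)
      shiftRecord(sprintf("mol%03d", i),
                  carbonShifts = round(runif(nc, 0, 220), 6),
                  protonShifts = round(runif(nh, 0, 12), 6),
                  smiles = if (i %% 2) "C1=CC=CC=C1" else NA_character_)
    })
    shiftLibrary(recs, solvent = "water")
  })
}

expect_library_equal <- function(a, b) {
  expect_identical(moleculeIds(a), moleculeIds(b))
  expect_identical(solventLabel(a), solventLabel(b))
  expect_identical(unname(carbonShifts(a)), unname(carbonShifts(b)))
  expect_identical(unname(protonShifts(a)), unname(protonShifts(b)))
}
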