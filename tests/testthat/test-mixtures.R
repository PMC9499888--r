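test_that("tuple enumeration finds exactly the count-sum combinations", {
  lib <- countToyLibrary()   # counts m1:(3,2) m2:(1,4) m3:(4,6) m4:(2,3)
  pairs <- enumerateTuples(lib, 4, 6, n = 2)
  expect_identical(pairs, list(c("m1", "m2")))
  both <- enumerateTuples(lib, 4, 6, n = "unknown", maxN = 2)
  expect_setequal(lapply(both, paste, collapse = "+"), c("m3", "m1+m2"))
  # n = 1 reduces to the pure-sample candidate filter
  expect_identical(unlist(enumerateTuples(lib, 4, 6, n = 1)),
                   filterCandidates(lib, 4, 6, "CH"))
  # infeasible totals give an empty (valid) result
  expect_identical(enumerateTuples(lib, 1, 1, n = 2), list())
  expect_error(enumerateTuples(lib, 4, 6, n = 4, maxN = 3), "exceeds maxN")
})

test_that("tuple enumeration agrees with brute force over all subsets", {
  lib <- randomLibrary(25, seed = 55)
  counts <- nucleusCounts(lib)
  set.seed(66)
  for (n in 2:3) {
    all_subsets <- combn(moleculeIds(lib), n, simplify = FALSE)
    for (trial in 1:5) {
      pick <- sample(moleculeIds(lib), n)
      tc <- sum(counts$nC[counts$molecule_id %in% pick])
      th <- sum(counts$nH[counts$molecule_id %in% pick])
      fast <- enumerateTuples(lib, tc, th, n = n)
      slow <- Filter(function(s) {
        sum(counts$nC[counts$molecule_id %in% s]) == tc &&
          sum(counts$nH[counts$molecule_id %in% s]) == th
      }, all_subsets)
      expect_setequal(vapply(fast, paste, "", collapse = "+"),
                      vapply(lapply(slow, sort), paste, "", collapse = "+"))
    }
  }
})

test_that("tuple scores follow pooled assignment and member-order invariance", {
  lib <- shiftLibrary(list(shiftRecord("A", c(10)), shiftRecord("B", c(20))),
                      solvent = "toy")
  q <- new("QuerySpectrum", carbonShifts = c(10, 21), protonShifts = numeric(),
           trueIds = c("A", "B"), nConstituents = 2L)
  s1 <- scoreTuple(q, c("A", "B"), lib, "C")
  expect_equal(s1$rmse_C, sqrt(1 / 2), tolerance = 1e-12)
  s2 <- scoreTuple(q, c("B", "A"), lib, "C")
  expect_equal(s1$combined, s2$combined, tolerance = 1e-12)
  expect_error(scoreTuple(q, c("A"), lib, "C"), "does not match")

  # true tuple at zero noise scores exactly 0
  lib2 <- randomLibrary(15, seed = 70)
  ids <- moleculeIds(lib2)[c(2, 9)]
  q2 <- makeMixture(lapply(ids, getRecord, lib = lib2), noiseModel(0, 0))
  expect_equal(scoreTuple(q2, ids, lib2, "CH")$combined, 0)
})

test_that("n = 1 mixture identification is bit-identical to the pure-sample path", {
  lib <- randomLibrary(40, seed = 81)
  for (id in moleculeIds(lib)[c(1, 13, 27)]) {
    q <- makeMixture(list(getRecord(lib, id)), noiseModel(2, 0.3, seed = 12L))
    mr <- identifyMixture(lib, q, "known", maxN = 3, mode = "CH")
    counts <- nucleusCounts(lib)
    i <- counts$molecule_id == id
    rr <- scoreAndRank(q, filterCandidates(lib, counts$nC[i], counts$nH[i], "CH"),
                       lib, "CH")
    expect_identical(mr@rankOfTruth, rr@rankOfTruth)
    expect_identical(unlist(mr@ranked$ids), rr@ranked$candidate_id)
    expect_equal(mr@ranked$combined, rr@ranked$combined, tolerance = 0)
  }
})

test_that("known-n candidates are a subset of unknown-n, and ranks order accordingly", {
  lib <- randomLibrary(20, seed = 90)
  set.seed(91)
  for (trial in 1:6) {
    ids <- sample(moleculeIds(lib), 2)
    q <- makeMixture(lapply(ids, getRecord, lib = lib),
                     noiseModel(4.41, 0.6, seed = 100L + trial))
    known <- identifyMixture(lib, q, "known", maxN = 3)
    unknown <- identifyMixture(lib, q, "unknown", maxN = 3)
    keyify <- function(mr) vapply(mr@ranked$ids, paste, "", collapse = "+")
    expect_true(all(keyify(known) %in% keyify(unknown)))
    expect_gte(unknown@rankOfTruth, known@rankOfTruth)
  }
})

test_that("zero-noise pairs and triplets are always identified first (known n)", {
  lib <- randomLibrary(20, seed = 101)
  set.seed(102)
  for (n in 2:3) {
    for (trial in 1:10) {
      ids <- sample(moleculeIds(lib), n)
      q <- makeMixture(lapply(ids, getRecord, lib = lib), noiseModel(0, 0))
      mr <- identifyMixture(lib, q, "known", maxN = 3)
      expect_identical(mr@rankOfTruth, 1L)
    }
  }
})

test_that("a count-matched singleton can outrank the true pair when n is unknown", {
  # impostor's counts equal the pair's totals and its shifts approximate the
  # pooled spectrum better than noise allows the pair to match
  lib <- shiftLibrary(list(
    shiftRecord("p1", c(10, 20), c(1)),
    shiftRecord("p2", c(100), c(5)),
    shiftRecord("impostor", c(10.05, 20.05, 100.05), c(1.02, 5.02)),
    shiftRecord("decoy", c(150, 160), c(8))), solvent = "toy")
  # the observed spectrum happens to land exactly on the impostor: a noise
  # draw closer to the count-matched singleton than to the true pair
  q <- new("QuerySpectrum", carbonShifts = c(10.05, 20.05, 100.05),
           protonShifts = c(1.02, 5.02), trueIds = c("p1", "p2"),
           nConstituents = 2L)
  unknown <- identifyMixture(lib, q, "unknown", maxN = 2)
  keys <- vapply(unknown@ranked$ids, paste, "", collapse = "+")
  expect_true("impostor" %in% keys)
  expect_identical(keys[1], "impostor")       # singleton wins
  expect_gt(unknown@rankOfTruth, 1L)
  # with the constituent count known, the impostor is excluded outright
  known <- identifyMixture(lib, q, "known", maxN = 2)
  expect_false("impostor" %in% vapply(known@ranked$ids, paste, "", collapse = "+"))
  expect_identical(known@rankOfTruth, 1L)
})

test_that("the enumeration budget aborts rather than silently truncating", {
  lib <- randomLibrary(30, seed = 111)
  counts <- nucleusCounts(lib)
  ids <- moleculeIds(lib)[1:2]
  tc <- sum(counts$nC[counts$molecule_id %in% ids])
  th <- sum(counts$nH[counts$molecule_id %in% ids])
  expect_error(enumerateTuples(lib, tc, th, n = 2, budget = 0), "budget")
})

test_that("the mixture experiment is reproducible and perfect at zero noise", {
  lib <- randomLibrary(15, seed = 120)
  pt <- data.frame(sigma_C = 0, sigma_H = 0)
  r1 <- mixtureExperiment(lib, 2, pt, replicates = 2, nMode = "known",
                          mixturesPerReplicate = 5, seed = 13)
  expect_equal(r1$mean_top1_pct, 100)
  expect_equal(r1$mean_rank, 1)
  r2 <- mixtureExperiment(lib, 2, pt, replicates = 2, nMode = "known",
                          mixturesPerReplicate = 5, seed = 13)
  expect_identical(r1, r2)
})
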