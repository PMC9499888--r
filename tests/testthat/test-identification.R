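test_that("candidate filtering matches exact counts per nuclei mode", {
  lib <- shiftLibrary(list(
    shiftRecord("m1", c(1, 2, 3), c(0.1, 0.2)),
    shiftRecord("m2", c(4)),
    shiftRecord("m3", c(5, 6, 7), c(0.3, 0.4))), solvent = "toy")
  expect_setequal(filterCandidates(lib, 3, 2, "CH"), c("m1", "m3"))
  expect_setequal(filterCandidates(lib, 3, 99, "C"), c("m1", "m3"))
  expect_identical(filterCandidates(lib, 1, 0, "H"), character())  # no-proton mode
  expect_identical(filterCandidates(lib, 17, 2, "CH"), character())
})

test_that("ranking follows hand-computed RMSEs and the pessimistic tie policy", {
  lib <- shiftLibrary(list(
    shiftRecord("m1", c(10, 20)),
    shiftRecord("m2", c(11, 19)),
    shiftRecord("m3", c(50, 60))), solvent = "toy")
  q <- new("QuerySpectrum", carbonShifts = c(10.4, 19.6),
           protonShifts = numeric(), trueIds = "m1", nConstituents = 1L)
  rr <- scoreAndRank(q, moleculeIds(lib), lib, "C")
  expect_identical(rr@ranked$candidate_id, c("m1", "m2", "m3"))
  expect_equal(rr@ranked$combined[1:2], c(0.4, 0.6), tolerance = 1e-12)
  expect_identical(rr@rankOfTruth, 1L)
  expect_true(all(rr@topK))

  # duplicate-shift candidates tied with the truth at score 0: pessimistic
  dup <- shiftLibrary(list(
    shiftRecord("t", c(10, 20)), shiftRecord("d1", c(10, 20)),
    shiftRecord("d2", c(20, 10))), solvent = "toy")
  q2 <- new("QuerySpectrum", carbonShifts = c(10, 20), protonShifts = numeric(),
            trueIds = "t", nConstituents = 1L)
  rr2 <- scoreAndRank(q2, moleculeIds(dup), dup, "C")
  expect_identical(rr2@rankOfTruth, 3L)   # all three tied at 0

  # empty candidate set is a distinguished outcome, not a crash
  rr3 <- scoreAndRank(q2, character(), dup, "C")
  expect_identical(rr3@status, "unidentifiable")
  expect_true(is.na(rr3@rankOfTruth))
})

test_that("ranks are invariant under permutation of library record order", {
  lib <- randomLibrary(40, seed = 8)
  q <- makeMixture(list(getRecord(lib, "SYN000007")),
                   noiseModel(2, 0.2, seed = 5L))
  perm <- withr::with_seed(1, sample(nMolecules(lib)))
  shuf <- new("ShiftLibrary", ids = lib@ids[perm], smiles = lib@smiles[perm],
              carbonShifts = lib@carbonShifts[perm],
              protonShifts = lib@protonShifts[perm], solvent = lib@solvent)
  counts <- nucleusCounts(lib)
  nc <- counts$nC[counts$molecule_id == "SYN000007"]
  nh <- counts$nH[counts$molecule_id == "SYN000007"]
  r1 <- scoreAndRank(q, filterCandidates(lib, nc, nh, "CH"), lib, "CH")
  r2 <- scoreAndRank(q, filterCandidates(shuf, nc, nh, "CH"), shuf, "CH")
  expect_identical(r1@rankOfTruth, r2@rankOfTruth)
})

test_that("zero noise gives perfect identification; same seed reproduces ranks", {
  lib <- randomLibrary(80, seed = 17)
  for (mode in c("C", "H", "CH")) {
    r <- runReplicate(lib, noiseModel(0, 0), mode, replicateSeed = 1L)
    expect_true(all(r == 1L))
  }
  nm <- noiseModel(3, 0.4)
  r1 <- runReplicate(lib, nm, "CH", replicateSeed = 21L)
  r2 <- runReplicate(lib, nm, "CH", replicateSeed = 21L)
  expect_identical(r1, r2)
  expect_error(runReplicate(lib, nm, "H",  replicateSeed = 1L), NA)
})

test_that("huge noise collapses Top-1 toward the random-guessing baseline", {
  lib <- randomLibrary(50, seed = 29)
  # baseline: truth picked uniformly among its exact-count candidate list
  counts <- nucleusCounts(lib)
  key <- paste(counts$nC, counts$nH)
  listSizes <- as.vector(table(key)[key])
  baseline <- mean(1 / listSizes) * 100
  top1 <- vapply(1:8, function(r) {
    100 * mean(runReplicate(lib, noiseModel(1e4, 1e4), "CH", r) == 1L)
  }, numeric(1))
  # statistically indistinguishable from guessing within the candidate lists
  se <- sd(top1) / sqrt(length(top1))
  expect_lt(abs(mean(top1) - baseline), max(4 * se, 5))
})

test_that("sweep percentages are nested in k and stored consistently", {
  lib <- randomLibrary(60, seed = 41)
  sw <- sweepSigma(lib, c(0, 2, 20), replicates = 4, mode = "C", seed = 6)
  st <- sw@stats
  expect_true(all(st$mean_pct >= 0 & st$mean_pct <= 100))
  # Top-k non-decreasing in k at every sigma
  for (s in unique(st$sigma_C)) {
    cur <- st[st$sigma_C == s, ]
    expect_true(all(diff(cur$mean_pct[order(cur$k)]) >= 0))
  }
  # sigma = 0 point is exact on a duplicate-free library
  expect_true(all(st$mean_pct[st$sigma_C == 0] == 100))
  # stored per-replicate values reproduce the means
  agg <- aggregate(pct ~ sigma_C + k, sw@perReplicate, mean)
  m <- merge(agg, st, by = c("sigma_C", "k"))
  expect_equal(m$pct, m$mean_pct, tolerance = 1e-12)
})

test_that("threshold extraction interpolates and flags boundary cases", {
  mk_sweep <- function(sig, pct) {
    st <- data.frame(sigma_C = sig, sigma_H = 0, k = 1L, mean_pct = pct,
                     sd_pct = 0)
    new("SweepResult", mode = "C",
        sigmaGrid = data.frame(sigma_C = sig, sigma_H = 0),
        replicates = 1L, stats = st, perReplicate = st[0, ])
  }
  th <- thresholdSigma(mk_sweep(c(1, 2), c(95, 85)), 90, 1)
  expect_equal(th$sigma, 1.5)
  expect_identical(th$status, "ok")

  th0 <- thresholdSigma(mk_sweep(c(0, 1, 2), c(100, 90, 70)), 100, 1)
  expect_equal(th0$sigma, 0)

  the <- thresholdSigma(mk_sweep(c(1, 2, 3), c(99, 95, 91)), 50, 1)
  expect_identical(the$status, "everywhere")
  expect_equal(the$sigma, 3)

  thu <- thresholdSigma(mk_sweep(c(1, 2), c(40, 20)), 90, 1)
  expect_identical(thu$status, "unattainable")
  expect_true(is.na(thu$sigma))
})
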