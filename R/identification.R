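# Pure-sample (single compound) identification: exact-count candidate
# filtering, Munkres scoring and ranking, Monte-Carlo replicates over noise
# levels, and Top-k threshold extraction.

.MODES <- c("C", "H", "CH")
.TOPK <- c(1L, 2L, 5L, 10L)

.checkMode <- function(nuclei_mode) match.arg(nuclei_mode, .MODES)

#' Filter library candidates by exact nucleus counts
#'
#' Candidate molecules are those with exactly the query's number of carbon
#' and/or proton shifts, depending on the nuclei mode. Molecules lacking the
#' active nucleus can never produce a defined score and are never candidates,
#' so a zero count for an active nucleus yields an empty set.
#'
#' @param lib a [ShiftLibrary-class].
#' @param nC,nH query nucleus counts.
#' @param mode "C", "H" or "CH".
#' @return character vector of candidate molecule ids (possibly empty).
#' @export
filterCandidates <- function(lib, nC, nH, mode = "CH") {
  mode <- .checkMode(mode)
  lib@ids[.candidateIdx(lib, nC, nH, mode)]
}

.candidateIdx <- function(lib, nC, nH, mode) {
  ncs <- lengths(lib@carbonShifts); nhs <- lengths(lib@protonShifts)
  switch(mode,
    C = if (nC < 1L) integer() else which(ncs == nC),
    H = if (nH < 1L) integer() else which(nhs == nH),
    CH = {
      if (nC < 1L && nH < 1L) integer()
      else which(ncs == nC & nhs == nH)
    })
}

# Per-candidate RMSE vectors for one query against pre-extracted candidate
# shift lists. A channel is NA when the query (hence, by exact-count
# filtering, every candidate) lacks that nucleus or the mode excludes it.
.scoreAgainst <- function(qc, qh, cand_c, cand_h, mode) {
  k <- length(cand_c)
  rc <- rep(NA_real_, k); rh <- rep(NA_real_, k)
  if (mode %in% c("C", "CH") && length(qc) > 0L)
    rc <- .assignment_rmse_cpp(qc, cand_c)
  if (mode %in% c("H", "CH") && length(qh) > 0L)
    rh <- .assignment_rmse_cpp(qh, cand_h)
  list(rmse_C = rc, rmse_H = rh, combined = geomCombine(rc, rh))
}

#' Score and rank candidates for a pure-sample query
#'
#' Each candidate's shift lists are matched one-to-one onto the query's by
#' minimum-cost assignment (squared differences), per-nucleus RMSE is
#' computed over the assigned pairs, the per-nucleus RMSEs are combined as a
#' geometric mean, and candidates are sorted ascending by the combined
#' score. The rank of the true molecule uses the pessimistic tie policy:
#' 1 + number strictly better + number of equally scored other candidates.
#'
#' @param query a [QuerySpectrum-class] (with `trueIds` of length 1 for a
#'   rank to be reported).
#' @param candidates character vector of candidate ids (e.g. from
#'   [filterCandidates()]); in pure-sample use these have the query's exact
#'   counts so each per-nucleus assignment is square.
#' @param lib a [ShiftLibrary-class].
#' @param mode "C", "H" or "CH".
#' @return A [RankingResult-class]; with an empty candidate set, a result
#'   with `status = "unidentifiable"`.
#' @export
scoreAndRank <- function(query, candidates, lib, mode = "CH") {
  mode <- .checkMode(mode)
  validObject(query)
  truth <- if (length(query@trueIds) == 1L) query@trueIds else NA_character_
  if (length(candidates) == 0L) {
    return(new("RankingResult", queryId = truth,
               ranked = data.frame(candidate_id = character(),
                                   rmse_C = numeric(), rmse_H = numeric(),
                                   combined = numeric()),
               rankOfTruth = NA_integer_,
               topK = setNames(rep(FALSE, length(.TOPK)), .TOPK),
               status = "unidentifiable"))
  }
  idx <- .lookupIdx(lib, candidates)
  sc <- .scoreAgainst(query@carbonShifts, query@protonShifts,
                      lib@carbonShifts[idx], lib@protonShifts[idx], mode)
  ord <- order(sc$combined, candidates)
  ranked <- data.frame(candidate_id = candidates[ord],
                       rmse_C = sc$rmse_C[ord], rmse_H = sc$rmse_H[ord],
                       combined = sc$combined[ord], row.names = NULL)
  rk <- if (is.na(truth)) NA_integer_
        else pessimisticRank(sc$combined, candidates, truth)
  new("RankingResult", queryId = truth, ranked = ranked,
      rankOfTruth = rk,
      topK = setNames(!is.na(rk) & rk <= .TOPK, .TOPK),
      status = "ok")
}

#' Identify one library molecule under noise
#'
#' Convenience wrapper reproducing a single pure-sample trial: perturb the
#' molecule's own shifts with the noise model, filter candidates by its
#' exact counts, then [scoreAndRank()].
#'
#' @param lib a [ShiftLibrary-class].
#' @param id molecule id of the (known) truth.
#' @param noise a [NoiseModel-class].
#' @param mode "C", "H" or "CH".
#' @return A [RankingResult-class].
#' @export
identifyMolecule <- function(lib, id, noise, mode = "CH") {
  mode <- .checkMode(mode)
  rec <- getRecord(lib, id)
  q <- makeMixture(list(rec), noise)
  cand <- filterCandidates(lib, length(rec@carbonShifts),
                           length(rec@protonShifts), mode)
  scoreAndRank(q, cand, lib, mode)
}

#' Run one replicate of the pure-sample experiment
#'
#' For every eligible molecule in the library (closed world: every query
#' molecule is itself in the library), perturbs its shifts with the
#' replicate's noise stream, filters candidates by exact counts and records
#' the pessimistic-tie rank of the truth. Fully reproducible from
#' `replicateSeed`.
#'
#' @param lib a [ShiftLibrary-class].
#' @param noise a [NoiseModel-class] (its own seed slot is ignored here).
#' @param mode "C", "H" or "CH".
#' @param replicateSeed integer seed for this replicate's noise stream.
#' @return named integer vector of ranks, one per eligible molecule.
#' @export
runReplicate <- function(lib, noise, mode = "CH", replicateSeed = 1L) {
  mode <- .checkMode(mode)
  validObject(lib); validObject(noise)
  ncs <- lengths(lib@carbonShifts); nhs <- lengths(lib@protonShifts)
  eligible <- switch(mode, C = ncs > 0L, H = nhs > 0L, CH = ncs > 0L | nhs > 0L)
  if (!any(eligible))
    stop("library has no eligible molecules for mode ", mode)
  key <- switch(mode, C = as.character(ncs), H = as.character(nhs),
                CH = countKey(ncs, nhs))
  groups <- split(seq_along(lib@ids), key)
  use_c <- mode %in% c("C", "CH"); use_h <- mode %in% c("H", "CH")
  ranks <- rep(NA_integer_, length(lib@ids))
  withSeed(replicateSeed, {
    for (i in which(eligible)) {
      cand <- groups[[key[i]]]
      qc <- lib@carbonShifts[[i]]; qh <- lib@protonShifts[[i]]
      if (use_c && length(qc)) qc <- addNoise(qc, noise@sigmaC, noise@mu)
      if (use_h && length(qh)) qh <- addNoise(qh, noise@sigmaH, noise@mu)
      sc <- .scoreAgainst(qc, qh, lib@carbonShifts[cand],
                          lib@protonShifts[cand], mode)
      ranks[i] <- pessimisticRank(sc$combined, lib@ids[cand], lib@ids[i])
    }
  })
  setNames(ranks[eligible], lib@ids[eligible])
}

.normalizeSigmaGrid <- function(sigmas, mode) {
  if (is.matrix(sigmas)) sigmas <- as.data.frame(sigmas)
  if (is.data.frame(sigmas)) {
    if (!all(c("sigma_C", "sigma_H") %in% names(sigmas)))
      stop("sigma grid data frames need columns sigma_C and sigma_H")
    return(data.frame(sigma_C = as.numeric(sigmas$sigma_C),
                      sigma_H = as.numeric(sigmas$sigma_H)))
  }
  if (mode == "CH")
    stop("CH mode needs (sigma_C, sigma_H) pairs: pass a two-column ",
         "data.frame with columns sigma_C and sigma_H")
  if (mode == "C") data.frame(sigma_C = as.numeric(sigmas), sigma_H = 0)
  else data.frame(sigma_C = 0, sigma_H = as.numeric(sigmas))
}

#' Sweep identification rate over a noise grid
#'
#' Runs `replicates` Monte-Carlo replicates of the pure-sample experiment at
#' each noise level and tabulates the mean and SD over replicates of the
#' Top-k identification percentage (fraction of eligible molecules with
#' rank <= k, times 100) for k in 1, 2, 5, 10.
#'
#' @param lib a [ShiftLibrary-class].
#' @param sigmas numeric vector of ppm sigma values for the active nucleus
#'   ("C"/"H" modes) or a data.frame with columns `sigma_C`, `sigma_H`
#'   ("CH" mode).
#' @param replicates number of replicates per noise level (default 16).
#' @param mode "C", "H" or "CH".
#' @param seed master seed; replicate r at grid point g uses the derived
#'   sub-stream seed for (g, r), so any replicate is reproducible alone.
#' @param mu noise mean (default 0).
#' @return A [SweepResult-class].
#' @export
sweepSigma <- function(lib, sigmas, replicates = 16L, mode = "C", seed = 1L,
                       mu = 0) {
  mode <- .checkMode(mode)
  grid <- .normalizeSigmaGrid(sigmas, mode)
  if (nrow(grid) < 1L) stop("need at least one sigma value")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("need at least one replicate")
  per <- vector("list", nrow(grid) * replicates)
  row <- 0L
  for (g in seq_len(nrow(grid))) {
    nm <- noiseModel(sigmaC = grid$sigma_C[g], sigmaH = grid$sigma_H[g],
                     mu = mu)
    for (r in seq_len(replicates)) {
      rs <- deriveSeed(seed, (g - 1L) * replicates + r)
      ranks <- runReplicate(lib, nm, mode, rs)
      row <- row + 1L
      per[[row]] <- data.frame(sigma_C = grid$sigma_C[g],
                               sigma_H = grid$sigma_H[g],
                               replicate = r, k = .TOPK,
                               pct = vapply(.TOPK, function(k)
                                 100 * mean(ranks <= k), numeric(1)))
    }
  }
  per <- do.call(rbind, per)
  agg_mean <- aggregate(pct ~ sigma_C + sigma_H + k, per, mean)
  agg_sd <- aggregate(pct ~ sigma_C + sigma_H + k, per,
                      function(x) if (length(x) > 1L) sd(x) else 0)
  stats <- merge(agg_mean, agg_sd, by = c("sigma_C", "sigma_H", "k"),
                 suffixes = c("_mean", "_sd"))
  names(stats)[names(stats) == "pct_mean"] <- "mean_pct"
  names(stats)[names(stats) == "pct_sd"] <- "sd_pct"
  # preserve the grid's own order
  stats <- stats[order(match(countKey(stats$sigma_C, stats$sigma_H),
                             countKey(grid$sigma_C, grid$sigma_H)),
                       stats$k), ]
  rownames(stats) <- NULL
  new("SweepResult", mode = mode, sigmaGrid = grid, replicates = replicates,
      stats = stats, perReplicate = per)
}

#' Largest tolerable sigma for a target identification rate
#'
#' From a single-nucleus sweep, the largest noise level at which the mean
#' Top-k curve still reaches `targetPct`, linearly interpolated between
#' adjacent grid points.
#'
#' @param sweep a [SweepResult-class] from a "C" or "H" mode sweep.
#' @param targetPct target identification percentage (e.g. 90).
#' @param k Top-k level (1, 2, 5 or 10).
#' @return list with elements `sigma` (ppm, NA when unattainable) and
#'   `status`: "ok", "unattainable" (curve never reaches the target) or
#'   "everywhere" (target met at the grid maximum, so the true threshold
#'   lies beyond the sweep).
#' @export
thresholdSigma <- function(sweep, targetPct, k = 1L) {
  stopifnot(is(sweep, "SweepResult"))
  if (!k %in% .TOPK) stop("k must be one of ", paste(.TOPK, collapse = ", "))
  st <- sweep@stats[sweep@stats$k == k, ]
  sig <- if (sweep@mode == "H") st$sigma_H else st$sigma_C
  if (sweep@mode == "CH") {
    varying <- vapply(st[c("sigma_C", "sigma_H")],
                      function(v) length(unique(v)) > 1L, logical(1))
    if (sum(varying) != 1L)
      stop("thresholdSigma on a CH sweep needs exactly one varying sigma axis")
    sig <- st[[names(varying)[varying]]]
  }
  o <- order(sig)
  sig <- sig[o]; pct <- st$mean_pct[o]
  above <- which(pct >= targetPct)
  if (length(above) == 0L)
    return(list(sigma = NA_real_, status = "unattainable"))
  i <- max(above)
  if (i == length(sig))
    return(list(sigma = sig[i], status = "everywhere"))
  # interpolate between the last grid point at/above target and the next below
  frac <- (pct[i] - targetPct) / (pct[i] - pct[i + 1L])
  list(sigma = sig[i] + frac * (sig[i + 1L] - sig[i]), status = "ok")
}

setMethod("show", "RankingResult", function(object) {
  cat(sprintf("RankingResult for query '%s' (%s): %d candidates, rank of truth = %s\n",
              object@queryId, object@status, nrow(object@ranked),
              ifelse(is.na(object@rankOfTruth), "NA", object@rankOfTruth)))
  if (nrow(object@ranked)) print(head(object@ranked, 5L))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult (%s mode): %d noise levels x %d replicates\n",
              object@mode, nrow(object@sigmaGrid), object@replicates))
})
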