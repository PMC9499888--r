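# Mixture (2-3 compound) identification: enumerate candidate tuples of
# distinct molecules whose nucleus counts sum to the query's, score pooled
# shift lists by one-to-one assignment (each observed shift can belong to
# only one constituent), and rank tuples.

#' Enumerate candidate tuples by count-sum lookup
#'
#' A size-n candidate tuple is an unordered combination of n distinct
#' library molecules whose carbon and hydrogen counts sum exactly to the
#' query totals. With `n = "unknown"`, all sizes 1..`maxN` are pooled.
#' Enumeration probes the count index for the complement of the counts
#' accumulated so far (never brute force over all tuples).
#'
#' @param lib a [ShiftLibrary-class].
#' @param totalNC,totalNH pooled query nucleus counts.
#' @param n tuple size (integer) or "unknown".
#' @param maxN maximum tuple size when `n = "unknown"` (default 3).
#' @param budget abort (hard error) if more than this many tuples would be
#'   enumerated; guards against combinatorial explosion on large libraries.
#' @return list of character id vectors (each sorted), possibly empty.
#' @export
enumerateTuples <- function(lib, totalNC, totalNH, n = 2L, maxN = 3L,
                            budget = 5e6) {
  validObject(lib)
  if (totalNC < 0L || totalNH < 0L || (totalNC == 0L && totalNH == 0L))
    stop("query totals must be non-negative and not both zero")
  sizes <- if (identical(n, "unknown")) seq_len(maxN) else {
    n <- as.integer(n)
    if (n < 1L) stop("tuple size must be >= 1")
    if (n > maxN) stop("tuple size ", n, " exceeds maxN = ", maxN)
    n
  }
  ncs <- lengths(lib@carbonShifts); nhs <- lengths(lib@protonShifts)
  key_map <- split(seq_along(lib@ids), countKey(ncs, nhs))
  out <- vector("list", 0L)
  count <- 0L
  emit <- function(idx) {
    count <<- count + 1L
    if (count > budget)
      stop("tuple enumeration budget (", format(budget, scientific = FALSE),
           ") exceeded; reduce the library size or maxN")
    out[[count]] <<- sort(lib@ids[idx])
  }
  # pick members in increasing library index so each combination appears once
  recurse <- function(prefix, start, remC, remH, slots) {
    if (slots == 1L) {
      hit <- key_map[[countKey(remC, remH)]]
      if (!is.null(hit)) for (j in hit[hit >= start]) emit(c(prefix, j))
      return(invisible())
    }
    if (start > length(lib@ids)) return(invisible())
    max_rem_c <- (slots - 1L) * max(ncs); max_rem_h <- (slots - 1L) * max(nhs)
    for (j in seq(start, length(lib@ids))) {
      cj <- ncs[j]; hj <- nhs[j]
      if (cj > remC || hj > remH) next
      if (remC - cj > max_rem_c || remH - hj > max_rem_h) next
      recurse(c(prefix, j), j + 1L, remC - cj, remH - hj, slots - 1L)
    }
  }
  for (s in sizes) recurse(integer(), 1L, totalNC, totalNH, s)
  out
}

#' Score one candidate tuple against a mixture query
#'
#' Concatenates the tuple members' shift lists per nucleus and assigns the
#' pooled query list onto the pooled candidate list one-to-one (square
#' minimum-cost assignment: every observed shift is explained by exactly one
#' candidate nucleus), then combines per-nucleus RMSEs as a geometric mean.
#' Invariant under permutation of the tuple members.
#'
#' @param query a [QuerySpectrum-class].
#' @param ids character vector of tuple member ids.
#' @param lib a [ShiftLibrary-class].
#' @param mode "C", "H" or "CH".
#' @return list with `rmse_C`, `rmse_H`, `combined` (ppm; NA for inactive or
#'   empty channels).
#' @export
scoreTuple <- function(query, ids, lib, mode = "CH") {
  mode <- .checkMode(mode)
  idx <- .lookupIdx(lib, ids)
  pc <- unlist(lib@carbonShifts[idx], use.names = FALSE)
  ph <- unlist(lib@protonShifts[idx], use.names = FALSE)
  if (mode %in% c("C", "CH") && length(pc) != length(query@carbonShifts))
    stop("pooled carbon count (", length(pc), ") does not match the query (",
         length(query@carbonShifts), "); tuple enumeration bug")
  if (mode %in% c("H", "CH") && length(ph) != length(query@protonShifts))
    stop("pooled proton count (", length(ph), ") does not match the query (",
         length(query@protonShifts), "); tuple enumeration bug")
  sc <- .scoreAgainst(query@carbonShifts, query@protonShifts,
                      list(pc), list(ph), mode)
  list(rmse_C = sc$rmse_C[1L], rmse_H = sc$rmse_H[1L],
       combined = sc$combined[1L])
}

#' Identify the constituents of a mixture
#'
#' Enumerates candidate tuples (known constituent count, or all sizes up to
#' `maxN` pooled into one list when unknown), scores each by pooled
#' assignment and ranks ascending. The truth's rank is by set equality with
#' the pessimistic tie policy.
#'
#' @param lib a [ShiftLibrary-class].
#' @param query a [QuerySpectrum-class]; with `nMode = "known"`,
#'   `query@nConstituents` must be set.
#' @param nMode "known" or "unknown".
#' @param maxN maximum tuple size (default 3).
#' @param mode "C", "H" or "CH".
#' @param budget tuple enumeration budget (hard error beyond it).
#' @return A [MixtureRanking-class]; `status = "unidentifiable"` when no
#'   tuple can be enumerated.
#' @export
identifyMixture <- function(lib, query, nMode = c("known", "unknown"),
                            maxN = 3L, mode = "CH", budget = 5e6) {
  nMode <- match.arg(nMode)
  mode <- .checkMode(mode)
  validObject(query)
  n_arg <- if (nMode == "known") {
    if (is.na(query@nConstituents))
      stop("nMode = 'known' requires query@nConstituents")
    query@nConstituents
  } else "unknown"
  tuples <- enumerateTuples(lib, length(query@carbonShifts),
                            length(query@protonShifts), n_arg, maxN, budget)
  if (length(tuples) == 0L) {
    return(new("MixtureRanking",
               ranked = data.frame(ids = I(list()), n = integer(),
                                   rmse_C = numeric(), rmse_H = numeric(),
                                   combined = numeric()),
               rankOfTruth = NA_integer_, nMode = nMode,
               status = "unidentifiable"))
  }
  sc <- lapply(tuples, function(t) scoreTuple(query, t, lib, mode))
  combined <- vapply(sc, `[[`, numeric(1), "combined")
  keys <- vapply(tuples, paste, character(1), collapse = "|")
  ord <- order(combined, keys)
  ranked <- data.frame(n = lengths(tuples)[ord],
                       rmse_C = vapply(sc, `[[`, numeric(1), "rmse_C")[ord],
                       rmse_H = vapply(sc, `[[`, numeric(1), "rmse_H")[ord],
                       combined = combined[ord])
  ranked$ids <- I(tuples[ord])
  ranked <- ranked[c("ids", "n", "rmse_C", "rmse_H", "combined")]
  truth_key <- paste(sort(query@trueIds), collapse = "|")
  rk <- if (length(query@trueIds) == 0L) NA_integer_
        else pessimisticRank(combined, keys, truth_key)
  new("MixtureRanking", ranked = ranked, rankOfTruth = rk,
      nMode = nMode, status = "ok")
}

#' Monte-Carlo mixture identification experiment
#'
#' At each noise level, draws `mixturesPerReplicate` random mixtures of `n`
#' distinct molecules per replicate, builds the pooled noisy query, runs
#' [identifyMixture()], and averages the Top-1 percentage and the mean rank
#' of the true tuple.
#'
#' @param lib a [ShiftLibrary-class].
#' @param n constituents per mixture (2 or 3).
#' @param noisePoints data.frame with columns `sigma_C`, `sigma_H` (ppm).
#' @param replicates Monte-Carlo replicates per noise point.
#' @param nMode "known" or "unknown".
#' @param mixturesPerReplicate sampled mixtures per replicate (default 200).
#' @param maxN maximum tuple size for the unknown-count search.
#' @param mode "C", "H" or "CH".
#' @param seed master seed (sub-streams derived per noise point/replicate).
#' @param budget tuple enumeration budget per query.
#' @return tidy data.frame: `n`, `n_mode`, `sigma_C`, `sigma_H`,
#'   `mean_top1_pct`, `sd_top1_pct`, `mean_rank`, `replicates`,
#'   `mixtures_per_replicate`.
#' @export
mixtureExperiment <- function(lib, n = 2L, noisePoints, replicates = 16L,
                              nMode = c("known", "unknown"),
                              mixturesPerReplicate = 200L, maxN = 3L,
                              mode = "CH", seed = 1L, budget = 5e6) {
  nMode <- match.arg(nMode)
  mode <- .checkMode(mode)
  n <- as.integer(n)
  if (!all(c("sigma_C", "sigma_H") %in% names(noisePoints)))
    stop("noisePoints needs columns sigma_C and sigma_H")
  res <- vector("list", nrow(noisePoints))
  for (p in seq_len(nrow(noisePoints))) {
    top1 <- numeric(replicates); mean_rank <- numeric(replicates)
    for (r in seq_len(replicates)) {
      rs <- deriveSeed(seed, (p - 1L) * replicates + r)
      stats <- withSeed(rs, {
        ranks <- integer(mixturesPerReplicate)
        for (m in seq_len(mixturesPerReplicate)) {
          ids <- sample(lib@ids, n)   # distinct constituents
          q <- makeMixture(lapply(ids, getRecord, lib = lib),
                           noiseModel(sigmaC = noisePoints$sigma_C[p],
                                      sigmaH = noisePoints$sigma_H[p]))
          mr <- identifyMixture(lib, q, nMode, maxN, mode, budget)
          ranks[m] <- mr@rankOfTruth
        }
        c(top1 = 100 * mean(ranks == 1L, na.rm = TRUE),
          mean_rank = mean(ranks, na.rm = TRUE))
      })
      top1[r] <- stats[["top1"]]; mean_rank[r] <- stats[["mean_rank"]]
    }
    res[[p]] <- data.frame(n = n, n_mode = nMode,
                           sigma_C = noisePoints$sigma_C[p],
                           sigma_H = noisePoints$sigma_H[p],
                           mean_top1_pct = mean(top1),
                           sd_top1_pct = if (replicates > 1L) sd(top1) else 0,
                           mean_rank = mean(mean_rank),
                           replicates = replicates,
                           mixtures_per_replicate = mixturesPerReplicate)
  }
  do.call(rbind, res)
}

setMethod("show", "MixtureRanking", function(object) {
  cat(sprintf("MixtureRanking (%s n, %s): %d tuples, rank of truth = %s\n",
              object@nMode, object@status, nrow(object@ranked),
              ifelse(is.na(object@rankOfTruth), "NA", object@rankOfTruth)))
})
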