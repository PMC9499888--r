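# Internal helpers: seed scoping, sub-stream seed derivation, tie-aware ranks.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream seed below 2^31, so replicate r of run s is
# reproducible in isolation.
deriveSeed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer(((abs(master) %% 1000003) * 2011 +
                (abs(stream) %% 100000) * 7919 + 17) %% 2147483647)
}

# Pessimistic competition rank of the truth among scores: 1 + strictly better
# + equally scored non-truth candidates. Deterministic under any input order.
pessimisticRank <- function(scores, ids, truth_id) {
  truth_score <- scores[match(truth_id, ids)]
  if (is.na(truth_score)) return(NA_integer_)
  as.integer(1L + sum(scores < truth_score) +
               sum(scores == truth_score & ids != truth_id))
}

# Geometric-mean combination of per-nucleus RMSEs; NA marks an undefined
# channel (molecule without that nucleus) and drops out of the combination.
geomCombine <- function(rmse_c, rmse_h) {
  both <- !is.na(rmse_c) & !is.na(rmse_h)
  out <- ifelse(both, sqrt(rmse_c * rmse_h),
                ifelse(is.na(rmse_c), rmse_h, rmse_c))
  if (any(is.na(out)))
    stop("combined score undefined: both nucleus channels missing")
  out
}

countKey <- function(nC, nH) paste(nC, nH, sep = "_")
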