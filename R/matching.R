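# Core scoring machinery: squared-difference cost matrices, minimum-cost
# one-to-one assignment (Hungarian algorithm, compiled), a brute-force
# oracle for small instances, and the MAE/RMSE/CMAE error statistics.

#' Squared-difference cost matrix between two shift lists
#'
#' Entry (i, j) is `(query[i] - candidate[j])^2` in ppm^2, rows indexed by
#' the query ("experimental") list and columns by the candidate ("computed")
#' list.
#'
#' @param query,candidate non-empty finite numeric ppm vectors (lengths M, N).
#' @return M x N numeric matrix.
#' @examples
#' costMatrix(c(1, 5), c(4, 6))  # rbind(c(9, 25), c(1, 1))
#' @export
costMatrix <- function(query, candidate) {
  if (length(query) == 0L || length(candidate) == 0L)
    stop("both shift lists must be non-empty")
  if (any(!is.finite(query)) || any(!is.finite(candidate)))
    stop("shift lists must be finite")
  outer(query, candidate, function(q, c) (q - c)^2)
}

.asAssignment <- function(cols, total) {
  new("Assignment",
      pairs = cbind(query_index = seq_along(cols),
                    candidate_index = as.integer(cols)),
      totalCost = total)
}

#' Minimum-cost assignment by the Hungarian (Munkres) algorithm
#'
#' Assigns each of the M rows of `cost` to a distinct column so that the sum
#' of selected entries is globally minimal. Requires M <= N; when the query
#' list is longer than the candidate list, transpose the cost matrix (i.e.
#' swap the roles) and re-orient the resulting pairs.
#'
#' Optimal assignments may be non-unique under cost ties; `totalCost` is
#' always the unique minimum.
#'
#' @param cost M x N matrix of finite costs, M <= N.
#' @return An [Assignment-class] with min(M, N) = M pairs.
#' @examples
#' a <- munkresAssign(costMatrix(c(1, 5), c(4, 6)))
#' a@totalCost  # 10: (1-4)^2 + (5-6)^2
#' @export
munkresAssign <- function(cost) {
  if (!is.matrix(cost) || !is.numeric(cost))
    stop("cost must be a numeric matrix")
  if (nrow(cost) > ncol(cost))
    stop("cost has more rows than columns (M > N): swap the query and ",
         "candidate roles (transpose the matrix) and retry")
  res <- .hungarian_cpp(cost)
  .asAssignment(res$cols, res$total_cost)
}

# all ordered selections of m items out of 1:n (n!/(n-m)! rows)
.orderedSelections <- function(n, m) {
  if (m == 1L) return(matrix(seq_len(n), ncol = 1L))
  sub <- .orderedSelections(n, m - 1L)
  out <- vector("list", n)
  for (j in seq_len(n)) {
    keep <- rowSums(sub == j) == 0L
    block <- sub[keep, , drop = FALSE]
    out[[j]] <- cbind(j, block)
  }
  do.call(rbind, out)
}

#' Exhaustive assignment oracle for small instances
#'
#' Enumerates every one-to-one assignment of the M rows into the N columns
#' (M <= N <= 8) and returns one attaining the minimal total cost. Intended
#' as an independent check of [munkresAssign()].
#'
#' @param cost M x N matrix, M <= N <= 8.
#' @return An [Assignment-class].
#' @export
bruteForceAssign <- function(cost) {
  if (!is.matrix(cost) || !is.numeric(cost))
    stop("cost must be a numeric matrix")
  M <- nrow(cost); N <- ncol(cost)
  if (M > N) stop("cost has more rows than columns (M > N): swap the inputs")
  if (N > 8L) stop("instance too large for exhaustive enumeration (N > 8)")
  sel <- .orderedSelections(N, M)
  tot <- numeric(nrow(sel))
  for (i in seq_len(M)) tot <- tot + cost[i, sel[, i]]
  best <- which.min(tot)
  .asAssignment(sel[best, ], tot[best])
}

.checkPairs <- function(exp_shifts, calc_shifts) {
  if (length(exp_shifts) == 0L) stop("need at least one assigned pair")
  if (length(exp_shifts) != length(calc_shifts))
    stop("experimental and calculated shift vectors must have equal length")
  if (any(!is.finite(exp_shifts)) || any(!is.finite(calc_shifts)))
    stop("shifts must be finite")
}

#' Mean absolute error of assigned shift pairs
#'
#' `MAE = sum(|exp - calc|) / N` over the N assigned pairs.
#'
#' @param exp_shifts,calc_shifts equal-length numeric ppm vectors, paired as
#'   assigned.
#' @return ppm scalar.
#' @export
mae <- function(exp_shifts, calc_shifts) {
  .checkPairs(exp_shifts, calc_shifts)
  mean(abs(exp_shifts - calc_shifts))
}

#' Root-mean-square error of assigned shift pairs
#'
#' `RMSE = sqrt(sum((exp - calc)^2) / N)`. Always >= [mae()] on the same
#' pairs (power-mean inequality).
#'
#' @inheritParams mae
#' @return ppm scalar.
#' @export
rmse <- function(exp_shifts, calc_shifts) {
  .checkPairs(exp_shifts, calc_shifts)
  sqrt(mean((exp_shifts - calc_shifts)^2))
}

#' Fit the affine scaling of calculated onto experimental shifts
#'
#' Ordinary least squares of `calc ~ exp`, giving the slope m and intercept
#' b used by the corrected MAE ([cmae()]).
#'
#' @inheritParams mae
#' @return A [ScalingFit-class].
#' @export
fitScaling <- function(exp_shifts, calc_shifts) {
  .checkPairs(exp_shifts, calc_shifts)
  if (length(unique(exp_shifts)) < 2L)
    stop("degenerate fit: need at least 2 distinct experimental shifts")
  co <- coef(lm(calc_shifts ~ exp_shifts))
  new("ScalingFit", m = unname(co[2L]), b = unname(co[1L]))
}

#' Corrected mean absolute error
#'
#' MAE after removing the fitted affine systematic distortion:
#' `CMAE = sum(|exp - (calc - b)/m|) / N`. Zero whenever `calc` is an exact
#' affine image of `exp`.
#'
#' @inheritParams mae
#' @param fit a [ScalingFit-class] (defaults to fitting on these pairs).
#' @return ppm scalar.
#' @export
cmae <- function(exp_shifts, calc_shifts, fit = fitScaling(exp_shifts, calc_shifts)) {
  .checkPairs(exp_shifts, calc_shifts)
  if (!is(fit, "ScalingFit")) stop("fit must be a ScalingFit")
  if (!is.finite(fit@m) || fit@m == 0) stop("invalid scaling fit: slope is 0")
  mean(abs(exp_shifts - (calc_shifts - fit@b) / fit@m))
}

#' Geometric-mean combination of per-nucleus RMSEs
#'
#' `sqrt(rmseC * rmseH)` when both channels are defined; the single defined
#' channel otherwise. The geometric mean normalizes the very different error
#' scales of the two nuclei so neither dominates. NA marks an undefined
#' channel (molecule without that nucleus).
#'
#' @param rmseC,rmseH non-negative ppm scalars or NA.
#' @return ppm scalar.
#' @export
combinedScore <- function(rmseC = NA_real_, rmseH = NA_real_) {
  if (is.na(rmseC) && is.na(rmseH))
    stop("combined score undefined: both nucleus channels missing")
  if (!is.na(rmseC) && rmseC < 0 || !is.na(rmseH) && rmseH < 0)
    stop("RMSE components must be non-negative")
  geomCombine(rmseC, rmseH)
}

setMethod("show", "Assignment", function(object) {
  cat(sprintf("Assignment of %d pairs, total cost %g ppm^2\n",
              nrow(object@pairs), object@totalCost))
})

setMethod("show", "ScalingFit", function(object) {
  cat(sprintf("ScalingFit: slope m = %g, intercept b = %g ppm\n",
              object@m, object@b))
})
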