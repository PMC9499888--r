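# Two-dimensional (sigmaC, sigmaH) identification surface, iso-identification
# contour extraction, reciprocal trade-off curve fitting and the optimum
# (minimum normalized cumulative error) point.

#' Top-1 identification surface over a (sigmaC, sigmaH) grid
#'
#' Runs the pure-sample experiment in CH mode at every grid cell and records
#' the mean and SD (over replicates) of the Top-1 identification percentage.
#'
#' @param lib a [ShiftLibrary-class].
#' @param sigmaCGrid,sigmaHGrid ppm grid vectors.
#' @param replicates replicates per cell (default 16).
#' @param seed master seed (per-cell/replicate sub-streams derived from it).
#' @param mu noise mean (default 0).
#' @return A [SweepSurface-class] (rows = sigmaC, cols = sigmaH).
#' @export
gridSweep <- function(lib, sigmaCGrid, sigmaHGrid, replicates = 16L,
                      seed = 1L, mu = 0) {
  if (length(sigmaCGrid) == 0L || length(sigmaHGrid) == 0L)
    stop("both sigma grids must be non-empty")
  sigmaCGrid <- as.numeric(sigmaCGrid); sigmaHGrid <- as.numeric(sigmaHGrid)
  replicates <- as.integer(replicates)
  pct <- matrix(NA_real_, length(sigmaCGrid), length(sigmaHGrid),
                dimnames = list(sigmaCGrid, sigmaHGrid))
  sdm <- pct
  cell <- 0L
  for (i in seq_along(sigmaCGrid)) {
    for (j in seq_along(sigmaHGrid)) {
      cell <- cell + 1L
      nm <- noiseModel(sigmaC = sigmaCGrid[i], sigmaH = sigmaHGrid[j], mu = mu)
      top1 <- vapply(seq_len(replicates), function(r) {
        ranks <- runReplicate(lib, nm, "CH",
                              deriveSeed(seed, (cell - 1L) * replicates + r))
        100 * mean(ranks == 1L)
      }, numeric(1))
      pct[i, j] <- mean(top1)
      sdm[i, j] <- if (replicates > 1L) sd(top1) else 0
    }
  }
  new("SweepSurface", sigmaCGrid = sigmaCGrid, sigmaHGrid = sigmaHGrid,
      top1Pct = pct, top1Sd = sdm, replicates = replicates)
}

#' Extract an iso-identification contour from a sweep surface
#'
#' For each sigmaH column, finds by linear interpolation the largest sigmaC
#' at which the Top-1 curve still reaches `level`. Columns whose curve never
#' reaches the level are omitted, as are columns still at/above the level at
#' the largest sigmaC of the grid (there the contour lies beyond the surveyed
#' range and the grid edge would understate it).
#'
#' @param surface a [SweepSurface-class].
#' @param level identification percentage of the contour (e.g. 90).
#' @return data.frame with columns `sigma_H`, `sigma_C`; zero rows with
#'   attribute `status = "unattainable"` when the level exceeds the whole
#'   surface.
#' @export
extractContour <- function(surface, level) {
  stopifnot(is(surface, "SweepSurface"))
  pts <- lapply(seq_along(surface@sigmaHGrid), function(j) {
    sig <- surface@sigmaCGrid
    pct <- surface@top1Pct[, j]
    o <- order(sig)
    sig <- sig[o]; pct <- pct[o]
    above <- which(pct >= level)
    if (length(above) == 0L) return(NULL)
    i <- max(above)
    if (i == length(sig) && pct[i] > level) return(NULL)  # saturated column
    sc <- if (i == length(sig)) sig[i] else
      sig[i] + (pct[i] - level) / (pct[i] - pct[i + 1L]) * (sig[i + 1L] - sig[i])
    data.frame(sigma_H = surface@sigmaHGrid[j], sigma_C = sc)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts)) {
    pts <- data.frame(sigma_H = numeric(), sigma_C = numeric())
    attr(pts, "status") <- "unattainable"
  } else {
    attr(pts, "status") <- "ok"
  }
  pts
}

#' Fit the reciprocal trade-off curve to contour points
#'
#' Nonlinear least squares of the trade-off relation between the tolerable
#' carbon and proton errors along an iso-identification contour,
#' `sigma_C = a / (sigma_H - b) + c`, via Levenberg-Marquardt. Starting
#' values keep the singularity just left of the data: `b = 0.9 min(sigma_H)`,
#' `c = 0.9 min(sigma_C)`, and `a` from the first point.
#'
#' @param points data.frame with columns `sigma_H`, `sigma_C` (>= 4 points,
#'   distinct `sigma_H`).
#' @param level contour level carried into the result (informational).
#' @return A [ContourFit-class].
#' @export
fitReciprocal <- function(points, level = NA_real_) {
  if (!all(c("sigma_H", "sigma_C") %in% names(points)))
    stop("points needs columns sigma_H and sigma_C")
  points <- points[order(points$sigma_H), , drop = FALSE]
  if (nrow(points) < 4L)
    stop("underdetermined: need at least 4 contour points to fit 3 parameters")
  if (anyDuplicated(points$sigma_H))
    stop("sigma_H values must be distinct")
  b0 <- 0.9 * min(points$sigma_H)
  c0 <- 0.9 * min(points$sigma_C)
  a0 <- (points$sigma_C[1L] - c0) * (points$sigma_H[1L] - b0)
  fit <- tryCatch(
    minpack.lm::nlsLM(sigma_C ~ a / (sigma_H - b) + c, data = points,
                      start = list(a = a0, b = b0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("reciprocal fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- coef(fit)
  on_singularity <- abs(points$sigma_H - co[["b"]]) < 1e-12
  if (any(on_singularity)) {
    warning("dropping ", sum(on_singularity),
            " contour point(s) on the sigma_H = b singularity")
    points <- points[!on_singularity, , drop = FALSE]
  }
  resid <- points$sigma_C - (co[["a"]] / (points$sigma_H - co[["b"]]) + co[["c"]])
  new("ContourFit", level = as.numeric(level), points = points,
      a = co[["a"]], b = co[["b"]], c = co[["c"]],
      residual = sqrt(mean(resid^2)))
}

#' Manually construct a ContourFit
#'
#' @param a,b,c reciprocal curve parameters.
#' @param level contour level (informational).
#' @param points optional data.frame of contour points (`sigma_H`, `sigma_C`);
#'   when present, [optimumPoint()] clips the optimum to their span.
#' @return A [ContourFit-class].
#' @export
contourFit <- function(a, b, c, level = NA_real_,
                       points = data.frame(sigma_H = numeric(),
                                           sigma_C = numeric())) {
  new("ContourFit", level = as.numeric(level), points = points,
      a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      residual = NA_real_)
}

#' Optimum trade-off point on a fitted contour
#'
#' Minimizes the normalized cumulative error `sigma_C/normC + sigma_H/normH`
#' subject to the contour `sigma_C = a/(sigma_H - b) + c`. Closed form:
#' `sigma_H* = b + sqrt(a normH / normC)`, `sigma_C* = c + sqrt(a normC / normH)`.
#' The default norms are the spans of the noise grids studied (50 ppm carbon,
#' 10 ppm proton). When the fit carries contour points, the optimum is
#' clipped to their observed sigma_H span (and sigma_C recomputed on the
#' curve).
#'
#' @param fit a [ContourFit-class] with `a > 0`.
#' @param normC,normH positive normalization constants (ppm).
#' @return A [TradeoffOptimum-class].
#' @export
optimumPoint <- function(fit, normC = 50, normH = 10) {
  stopifnot(is(fit, "ContourFit"))
  if (!is.finite(fit@a) || fit@a <= 0)
    stop("optimum requires a > 0 (a decreasing trade-off contour)")
  if (normC <= 0 || normH <= 0) stop("norms must be positive")
  sh <- fit@b + sqrt(fit@a * normH / normC)
  if (nrow(fit@points) > 0L)
    sh <- min(max(sh, min(fit@points$sigma_H)), max(fit@points$sigma_H))
  sc <- fit@a / (sh - fit@b) + fit@c
  new("TradeoffOptimum", sigmaCStar = sc, sigmaHStar = sh,
      normalizedCost = sc / normC + sh / normH,
      normC = as.numeric(normC), normH = as.numeric(normH))
}

setMethod("show", "SweepSurface", function(object) {
  cat(sprintf("SweepSurface: %d x %d (sigmaC x sigmaH) grid, %d replicates\n",
              length(object@sigmaCGrid), length(object@sigmaHGrid),
              object@replicates))
})

setMethod("show", "ContourFit", function(object) {
  cat(sprintf(
    "ContourFit (level %s%%): sigma_C = %.4g/(sigma_H - %.4g) + %.4g, RMS resid %.3g\n",
    ifelse(is.na(object@level), "?", object@level),
    object@a, object@b, object@c, object@residual))
})

setMethod("show", "TradeoffOptimum", function(object) {
  cat(sprintf(
    "TradeoffOptimum: sigma_C* = %.4g ppm, sigma_H* = %.4g ppm (cost %.4g; norms %g/%g)\n",
    object@sigmaCStar, object@sigmaHStar, object@normalizedCost,
    object@normC, object@normH))
})
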