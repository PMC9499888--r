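#' ShiftRecord: one molecule's chemical shift lists
#'
#' Holds a molecule identifier, an optional SMILES string, and the full
#' per-nucleus lists of \eqn{^{13}}C and \eqn{^1}H chemical shifts in ppm.
#' Every nucleus is listed individually (chemically equivalent nuclei are not
#' collapsed), so the list lengths equal the molecule's carbon and hydrogen
#' counts.
#'
#' @slot moleculeId character(1), unique within a library.
#' @slot smiles character(1) or NA; structure notation, informational only.
#' @slot carbonShifts numeric vector of 13C shifts (ppm), possibly empty.
#' @slot protonShifts numeric vector of 1H shifts (ppm), possibly empty.
#' @exportClass ShiftRecord
setClass("ShiftRecord",
  slots = c(moleculeId = "character", smiles = "character",
            carbonShifts = "numeric", protonShifts = "numeric"),
  prototype = prototype(smiles = NA_character_,
                        carbonShifts = numeric(), protonShifts = numeric()))

setValidity("ShiftRecord", function(object) {
  msg <- character()
  if (length(object@moleculeId) != 1L || is.na(object@moleculeId) ||
      !nzchar(object@moleculeId))
    msg <- c(msg, "moleculeId must be a single non-empty string")
  if (length(object@smiles) != 1L)
    msg <- c(msg, "smiles must be a single string (possibly NA)")
  if (length(object@carbonShifts) == 0L && length(object@protonShifts) == 0L)
    msg <- c(msg, "at least one of carbonShifts/protonShifts must be non-empty")
  if (any(!is.finite(object@carbonShifts)) || any(!is.finite(object@protonShifts)))
    msg <- c(msg, "all shift values must be finite")
  if (length(msg)) msg else TRUE
})

#' ShiftLibrary: a reference library of chemical shift lists
#'
#' Column-oriented container for a collection of [ShiftRecord]-equivalent
#' entries: parallel vectors/lists indexed by molecule. A count index keyed by
#' the (carbon count, hydrogen count) pair supports the exact-count candidate
#' filtering that the identification pipeline relies on; it is derived from
#' the shift lists on demand (see [countIndex()]) so it can never fall out of
#' step with the records.
#'
#' @slot ids character vector of unique molecule identifiers (input order).
#' @slot smiles character vector parallel to `ids` (NA when unknown).
#' @slot carbonShifts list of numeric vectors, one per molecule (ppm).
#' @slot protonShifts list of numeric vectors, one per molecule (ppm).
#' @slot solvent character(1) label, e.g. "water" or "chloroform".
#' @exportClass ShiftLibrary
setClass("ShiftLibrary",
  slots = c(ids = "character", smiles = "character",
            carbonShifts = "list", protonShifts = "list",
            solvent = "character"))

setValidity("ShiftLibrary", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (n == 0L) msg <- c(msg, "library must contain at least one molecule")
  if (anyDuplicated(object@ids))
    msg <- c(msg, paste0("duplicate molecule_id: ",
                         paste(unique(object@ids[duplicated(object@ids)]),
                               collapse = ", ")))
  if (length(object@smiles) != n || length(object@carbonShifts) != n ||
      length(object@protonShifts) != n)
    msg <- c(msg, "parallel slots must all have one entry per molecule")
  if (length(object@solvent) != 1L)
    msg <- c(msg, "solvent must be a single label")
  for (i in seq_len(n)) {
    cs <- object@carbonShifts[[i]]; hs <- object@protonShifts[[i]]
    if (!is.numeric(cs) || !is.numeric(hs) ||
        any(!is.finite(cs)) || any(!is.finite(hs))) {
      msg <- c(msg, paste0("non-finite or non-numeric shifts for molecule ",
                           object@ids[i]))
      break
    }
    if (length(cs) == 0L && length(hs) == 0L) {
      msg <- c(msg, paste0("molecule ", object@ids[i], " has no shifts at all"))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' LibrarySummary: totals and per-molecule count histograms
#'
#' @slot nMolecules integer(1).
#' @slot nCarbonNuclei integer(1), total carbon nuclei across all molecules.
#' @slot nHydrogenNuclei integer(1), total hydrogen nuclei.
#' @slot carbonHist named integer vector: molecules per carbon count.
#' @slot protonHist named integer vector: molecules per hydrogen count.
#' @exportClass LibrarySummary
setClass("LibrarySummary",
  slots = c(nMolecules = "integer", nCarbonNuclei = "integer",
            nHydrogenNuclei = "integer", carbonHist = "integer",
            protonHist = "integer"))

#' NoiseModel: Gaussian error specification for surrogate spectra
#'
#' Zero-mean (by default) Gaussian noise added independently to every shift,
#' with separate standard deviations for the two nuclei, emulating the error
#' of calculated shifts relative to experiment.
#'
#' @slot mu ppm, noise mean (default 0).
#' @slot sigmaC ppm, 13C noise standard deviation (>= 0).
#' @slot sigmaH ppm, 1H noise standard deviation (>= 0).
#' @slot seed integer RNG seed, or NA to draw from the current RNG state.
#' @exportClass NoiseModel
setClass("NoiseModel",
  slots = c(mu = "numeric", sigmaC = "numeric", sigmaH = "numeric",
            seed = "integer"),
  prototype = prototype(mu = 0, sigmaC = 0, sigmaH = 0, seed = NA_integer_))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (length(object@mu) != 1L || !is.finite(object@mu))
    msg <- c(msg, "mu must be a single finite value")
  for (s in c("sigmaC", "sigmaH")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, paste(s, "must be a single finite non-negative value"))
  }
  if (length(msg)) msg else TRUE
})

#' LibrarySpec: recipe for a synthetic shift library
#'
#' Describes the statistical structure of a generated library: how many
#' molecules, the per-molecule carbon/hydrogen count distributions
#' (right-skewed truncated negative binomials by default), the ppm ranges of
#' the two nuclei, and how strongly shifts clump into functional-group-like
#' clusters.
#'
#' @slot nMolecules integer(1) > 0.
#' @slot carbonSampler,hydrogenSampler lists with elements `size`, `mu`,
#'   `min`, `max` parameterising a truncated negative binomial count
#'   distribution on `min:max` (see [sampleCounts()]).
#' @slot carbonRange,protonRange length-2 ppm intervals.
#' @slot clusterSpread ppm; within-cluster standard deviation on the carbon
#'   scale (the proton spread is scaled by the range ratio).
#' @slot countCorrelation Gaussian-copula correlation between a molecule's
#'   carbon and hydrogen counts (marginals are preserved exactly); real
#'   molecules have strongly coupled C and H counts.
#' @slot seed integer(1) RNG seed.
#' @exportClass LibrarySpec
setClass("LibrarySpec",
  slots = c(nMolecules = "integer", carbonSampler = "list",
            hydrogenSampler = "list", carbonRange = "numeric",
            protonRange = "numeric", clusterSpread = "numeric",
            countCorrelation = "numeric", seed = "integer"))

setValidity("LibrarySpec", function(object) {
  msg <- character()
  if (length(object@nMolecules) != 1L || object@nMolecules < 1L)
    msg <- c(msg, "nMolecules must be a positive integer")
  for (s in c("carbonRange", "protonRange")) {
    r <- slot(object, s)
    if (length(r) != 2L || !all(is.finite(r)) || diff(r) <= 0)
      msg <- c(msg, paste(s, "must be a non-degenerate finite interval"))
  }
  for (s in c("carbonSampler", "hydrogenSampler")) {
    sp <- slot(object, s)
    if (!all(c("size", "mu", "min", "max") %in% names(sp)))
      msg <- c(msg, paste(s, "must have elements size, mu, min, max"))
    else if (sp$min < 0 || sp$max < sp$min)
      msg <- c(msg, paste(s, "support must satisfy 0 <= min <= max"))
  }
  if (length(object@clusterSpread) != 1L || object@clusterSpread <= 0)
    msg <- c(msg, "clusterSpread must be a single positive ppm value")
  if (length(object@countCorrelation) != 1L ||
      abs(object@countCorrelation) > 1)
    msg <- c(msg, "countCorrelation must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' QuerySpectrum: a (possibly mixed) shift list to be identified
#'
#' The pooled carbon and proton shift lists of a sample, the ground-truth
#' constituent molecule ids when known, and the number of constituents
#' (NA when unknown).
#'
#' @slot carbonShifts,protonShifts numeric ppm vectors.
#' @slot trueIds character vector of ground-truth ids (may be empty).
#' @slot nConstituents integer(1) >= 1, or NA for "unknown".
#' @exportClass QuerySpectrum
setClass("QuerySpectrum",
  slots = c(carbonShifts = "numeric", protonShifts = "numeric",
            trueIds = "character", nConstituents = "integer"),
  prototype = prototype(trueIds = character(), nConstituents = NA_integer_))

setValidity("QuerySpectrum", function(object) {
  msg <- character()
  if (length(object@carbonShifts) == 0L && length(object@protonShifts) == 0L)
    msg <- c(msg, "query must carry at least one shift")
  if (any(!is.finite(object@carbonShifts)) ||
      any(!is.finite(object@protonShifts)))
    msg <- c(msg, "query shifts must be finite")
  if (!is.na(object@nConstituents) && object@nConstituents < 1L)
    msg <- c(msg, "nConstituents must be >= 1 or NA (unknown)")
  if (length(msg)) msg else TRUE
})

#' Assignment: a minimum-cost one-to-one matching of two shift lists
#'
#' @slot pairs integer matrix with columns `query_index`, `candidate_index`,
#'   one row per assigned pair (min(M, N) rows).
#' @slot totalCost numeric(1), summed squared differences (ppm^2).
#' @exportClass Assignment
setClass("Assignment",
  slots = c(pairs = "matrix", totalCost = "numeric"))

#' ScalingFit: affine relation of calculated to experimental shifts
#'
#' @slot m slope (dimensionless), @slot b intercept (ppm).
#' @exportClass ScalingFit
setClass("ScalingFit", slots = c(m = "numeric", b = "numeric"))

#' RankingResult: scored candidate ranking for one pure-sample query
#'
#' @slot queryId character(1) id of the query molecule.
#' @slot ranked data.frame with columns `candidate_id`, `rmse_C`, `rmse_H`,
#'   `combined`, sorted ascending by `combined`.
#' @slot rankOfTruth integer(1), pessimistic-tie competition rank.
#' @slot topK named logical vector, indicator of rank <= k for k in 1,2,5,10.
#' @slot status character(1): "ok" or "unidentifiable" (empty candidate set).
#' @exportClass RankingResult
setClass("RankingResult",
  slots = c(queryId = "character", ranked = "data.frame",
            rankOfTruth = "integer", topK = "logical", status = "character"))

#' SweepResult: Top-k identification percentage across a noise grid
#'
#' @slot mode "C", "H" or "CH".
#' @slot sigmaGrid data.frame with columns `sigma_C`, `sigma_H` (the inactive
#'   one fixed at 0 in single-nucleus modes).
#' @slot replicates integer(1).
#' @slot stats data.frame: `sigma_C`, `sigma_H`, `k`, `mean_pct`, `sd_pct`.
#' @slot perReplicate data.frame: `sigma_C`, `sigma_H`, `replicate`, `k`, `pct`.
#' @exportClass SweepResult
setClass("SweepResult",
  slots = c(mode = "character", sigmaGrid = "data.frame",
            replicates = "integer", stats = "data.frame",
            perReplicate = "data.frame"))

#' SweepSurface: Top-1 identification over a (sigmaC, sigmaH) grid
#'
#' @slot sigmaCGrid,sigmaHGrid ppm grid vectors.
#' @slot top1Pct matrix (rows = sigmaC, cols = sigmaH) of mean Top-1 %.
#' @slot top1Sd matching replicate standard deviations.
#' @slot replicates integer(1).
#' @exportClass SweepSurface
setClass("SweepSurface",
  slots = c(sigmaCGrid = "numeric", sigmaHGrid = "numeric",
            top1Pct = "matrix", top1Sd = "matrix", replicates = "integer"))

setValidity("SweepSurface", function(object) {
  msg <- character()
  if (!identical(dim(object@top1Pct),
                 c(length(object@sigmaCGrid), length(object@sigmaHGrid))))
    msg <- c(msg, "top1Pct dimensions must match the sigma grids")
  p <- object@top1Pct
  if (any(p < -1e-9 | p > 100 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "percentages must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' ContourFit: reciprocal fit of an iso-identification contour
#'
#' Parameters of the reciprocal trade-off curve
#' \deqn{\sigma_C = a / (\sigma_H - b) + c}
#' fitted to contour points extracted from a [SweepSurface].
#'
#' @slot level identification percentage of the contour.
#' @slot points data.frame with columns `sigma_H`, `sigma_C`.
#' @slot a ppm^2, @slot b ppm, @slot c ppm: curve parameters.
#' @slot residual RMS of fit residuals (ppm).
#' @exportClass ContourFit
setClass("ContourFit",
  slots = c(level = "numeric", points = "data.frame",
            a = "numeric", b = "numeric", c = "numeric", residual = "numeric"))

#' TradeoffOptimum: minimum normalized-cost point on a trade-off contour
#'
#' @slot sigmaCStar,sigmaHStar ppm coordinates of the optimum.
#' @slot normalizedCost sigmaC/normC + sigmaH/normH at the optimum.
#' @slot normC,normH the normalization constants used (ppm).
#' @exportClass TradeoffOptimum
setClass("TradeoffOptimum",
  slots = c(sigmaCStar = "numeric", sigmaHStar = "numeric",
            normalizedCost = "numeric", normC = "numeric", normH = "numeric"))

#' MixtureRanking: scored tuple ranking for a mixture query
#'
#' @slot ranked data.frame with columns `ids` (list column of member id
#'   vectors), `n`, `rmse_C`, `rmse_H`, `combined`, ascending by `combined`.
#' @slot rankOfTruth integer(1), set-equality pessimistic-tie rank (NA when
#'   the true tuple is not among the candidates).
#' @slot nMode "known" or "unknown".
#' @slot status "ok" or "unidentifiable".
#' @exportClass MixtureRanking
setClass("MixtureRanking",
  slots = c(ranked = "data.frame", rankOfTruth = "integer",
            nMode = "character", status = "character"))
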