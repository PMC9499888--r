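#' Construct a NoiseModel
#'
#' Gaussian error specification for surrogate experimental spectra: every
#' shift receives an independent Normal(mu, sigma) perturbation, with
#' separate sigmas for the carbon and proton channels.
#'
#' @param sigmaC,sigmaH ppm standard deviations (>= 0).
#' @param mu ppm mean (default 0: calculated-shift errors are taken as
#'   equally likely positive or negative).
#' @param seed integer seed; NA draws from the current RNG state.
#' @return A [NoiseModel-class].
#' @export
noiseModel <- function(sigmaC, sigmaH = 0, mu = 0, seed = NA_integer_) {
  new("NoiseModel", mu = as.numeric(mu), sigmaC = as.numeric(sigmaC),
      sigmaH = as.numeric(sigmaH), seed = as.integer(seed))
}

#' Truncated negative-binomial count sampler specification
#'
#' Per-molecule nucleus counts are drawn from a negative binomial shifted to
#' start at `min` and truncated at `max`, giving the right-skewed count
#' histograms typical of metabolite libraries.
#'
#' @param size,mu negative binomial shape and mean (of the untruncated,
#'   unshifted distribution; the sampled counts are `min + NB`).
#' @param min,max integer support bounds.
#' @return list spec consumed by [librarySpec()] and [sampleCounts()].
#' @export
countSampler <- function(size, mu, min = 1L, max) {
  list(size = size, mu = mu, min = as.integer(min), max = as.integer(max))
}

#' Analytic pmf of a count sampler
#'
#' @param sampler a [countSampler()] spec.
#' @return data.frame with columns `count` and `prob` over the support.
#' @export
samplerPmf <- function(sampler) {
  support <- sampler$min:sampler$max
  p <- dnbinom(support - sampler$min, size = sampler$size, mu = sampler$mu)
  data.frame(count = support, prob = p / sum(p))
}

#' Draw per-molecule nucleus counts
#'
#' @param sampler a [countSampler()] spec.
#' @param n number of draws (uses the current RNG state).
#' @return integer vector of counts in `[min, max]`.
#' @export
sampleCounts <- function(sampler, n) {
  pmf <- samplerPmf(sampler)
  as.integer(sample(pmf$count, n, replace = TRUE, prob = pmf$prob))
}

#' Construct a LibrarySpec
#'
#' Defaults emulate the structure of water/chloroform-soluble metabolite
#' sets: carbon counts 1-40 peaking near 8-12, hydrogen counts 1-60 peaking
#' near 12-18 (both right-skewed), carbon shifts spanning 0-220 ppm and
#' proton shifts 0-12 ppm, with per-molecule shifts clumped into a few
#' functional-group-like Gaussian clusters.
#'
#' @param nMolecules number of molecules to generate.
#' @param carbonSampler,hydrogenSampler [countSampler()] specs.
#' @param carbonRange,protonRange ppm intervals.
#' @param clusterSpread ppm; within-cluster SD on the carbon scale (proton
#'   clusters use `clusterSpread * diff(protonRange) / diff(carbonRange)`).
#' @param countCorrelation Gaussian-copula correlation between a molecule's
#'   carbon and hydrogen counts (default 0.8). Both count marginals are
#'   preserved exactly; the coupling reflects that larger molecules carry
#'   more of both nuclei, which is what populates the joint (nC, nH)
#'   candidate classes that exact-count filtering relies on.
#' @param seed integer RNG seed.
#' @return A [LibrarySpec-class].
#' @export
librarySpec <- function(nMolecules,
                        carbonSampler = countSampler(5, 10, 1L, 40L),
                        hydrogenSampler = countSampler(5, 14, 1L, 60L),
                        carbonRange = c(0, 220),
                        protonRange = c(0, 12),
                        clusterSpread = 6,
                        countCorrelation = 0.8,
                        seed = 1L) {
  new("LibrarySpec", nMolecules = as.integer(nMolecules),
      carbonSampler = carbonSampler, hydrogenSampler = hydrogenSampler,
      carbonRange = as.numeric(carbonRange),
      protonRange = as.numeric(protonRange),
      clusterSpread = as.numeric(clusterSpread),
      countCorrelation = as.numeric(countCorrelation),
      seed = as.integer(seed))
}

# inverse-cdf lookup on a sampler's truncated pmf; u in (0, 1)
.countQuantile <- function(sampler, u) {
  pmf <- samplerPmf(sampler)
  cdf <- cumsum(pmf$prob)
  pmf$count[findInterval(u, cdf, left.open = TRUE) + 1L]
}

# Draw one molecule's shifts: counts nuclei land in 1..4 Gaussian clusters
# placed uniformly in range, then clip. Clustering makes between-molecule
# shift collisions realistically frequent; iid-uniform shifts would make
# identification artificially easy.
.drawShifts <- function(count, range, spread) {
  if (count == 0L) return(numeric())
  k <- min(count, sample.int(4L, 1L))
  centers <- runif(k, range[1], range[2])
  assign_to <- sample.int(k, count, replace = TRUE)
  x <- centers[assign_to] + rnorm(count, 0, spread)
  pmin(pmax(x, range[1]), range[2])
}

#' Generate a synthetic shift library
#'
#' Fully reproducible from `spec@seed`: the same spec yields a bit-identical
#' library on any platform using R's default Mersenne-Twister RNG.
#'
#' @param spec a [LibrarySpec-class].
#' @return A [ShiftLibrary-class] with ids `SYN000001, ...` and solvent
#'   `"synthetic"`.
#' @export
generateLibrary <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    n <- spec@nMolecules
    # correlated count draws through a Gaussian copula: marginals follow the
    # samplers exactly, the coupling mimics molecule size driving both counts
    rho <- spec@countCorrelation
    draw_counts <- function(m) {
      z1 <- rnorm(m)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
      list(nc = as.integer(.countQuantile(spec@carbonSampler, pnorm(z1))),
           nh = as.integer(.countQuantile(spec@hydrogenSampler, pnorm(z2))))
    }
    cts <- draw_counts(n)
    nc <- cts$nc; nh <- cts$nh
    # guard the not-both-zero invariant (possible only if a sampler's min is 0)
    both0 <- nc == 0L & nh == 0L
    while (any(both0)) {
      redraw <- draw_counts(sum(both0))
      nc[both0] <- redraw$nc; nh[both0] <- redraw$nh
      both0 <- nc == 0L & nh == 0L
    }
    h_spread <- spec@clusterSpread * diff(spec@protonRange) / diff(spec@carbonRange)
    cs <- vector("list", n); hs <- vector("list", n)
    for (i in seq_len(n)) {
      cs[[i]] <- .drawShifts(nc[i], spec@carbonRange, spec@clusterSpread)
      hs[[i]] <- .drawShifts(nh[i], spec@protonRange, h_spread)
    }
    new("ShiftLibrary",
        ids = sprintf("SYN%06d", seq_len(n)),
        smiles = rep(NA_character_, n),
        carbonShifts = cs, protonShifts = hs,
        solvent = "synthetic")
  })
}

#' Add Gaussian noise to a shift list
#'
#' Creates a surrogate "experimental" shift list from a calculated one by
#' adding an independent Normal(mu, sigma) draw to every element. Length and
#' order are preserved; the current RNG state is consumed (seed it with
#' [set.seed()] or use the seeded wrappers for reproducibility).
#'
#' @param shifts numeric ppm vector.
#' @param sigma ppm standard deviation (>= 0; 0 returns `shifts + mu`).
#' @param mu ppm mean (default 0).
#' @return numeric vector, same length as `shifts`.
#' @export
addNoise <- function(shifts, sigma, mu = 0) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("sigma must be a single finite non-negative value")
  if (length(shifts) == 0L) return(shifts)
  shifts + rnorm(length(shifts), mean = mu, sd = sigma)
}

#' Construct a QuerySpectrum
#'
#' Wraps an observed (or simulated) pooled shift list for identification.
#' [makeMixture()] builds these from library records; use this constructor
#' for externally supplied shift lists.
#'
#' @param carbonShifts,protonShifts numeric ppm vectors (not both empty).
#' @param trueIds ground-truth constituent ids, if known (may be empty).
#' @param nConstituents number of constituents, or NA when unknown.
#' @return A [QuerySpectrum-class].
#' @export
querySpectrum <- function(carbonShifts = numeric(), protonShifts = numeric(),
                          trueIds = character(),
                          nConstituents = NA_integer_) {
  new("QuerySpectrum", carbonShifts = as.numeric(carbonShifts),
      protonShifts = as.numeric(protonShifts),
      trueIds = as.character(trueIds),
      nConstituents = as.integer(nConstituents))
}

#' Compose a mixture query spectrum
#'
#' Pools the constituents' shift lists (concatenation in input order) and
#' perturbs them with the noise model, emulating a sample spectrum that is
#' the sum of its constituents' pure spectra.
#'
#' @param records list of [ShiftRecord-class] constituents (1 to `maxN`).
#' @param noise a [NoiseModel-class]; if `noise@seed` is not NA the RNG is
#'   seeded (and restored) so the query is reproducible in isolation.
#' @param maxN maximum allowed number of constituents (default 3).
#' @return A [QuerySpectrum-class] with `trueIds` in input order.
#' @export
makeMixture <- function(records, noise, maxN = 3L) {
  if (length(records) == 0L) stop("mixture needs at least one constituent")
  if (length(records) > maxN)
    stop("mixture has ", length(records), " constituents; maximum is ", maxN)
  ok <- vapply(records, is, logical(1), class2 = "ShiftRecord")
  if (!all(ok)) stop("all records must be ShiftRecord objects")
  validObject(noise)
  cs <- unlist(lapply(records, slot, name = "carbonShifts"), use.names = FALSE)
  hs <- unlist(lapply(records, slot, name = "protonShifts"), use.names = FALSE)
  perturb <- function() {
    new("QuerySpectrum",
        carbonShifts = addNoise(if (is.null(cs)) numeric() else cs,
                                noise@sigmaC, noise@mu),
        protonShifts = addNoise(if (is.null(hs)) numeric() else hs,
                                noise@sigmaH, noise@mu),
        trueIds = vapply(records, slot, character(1), name = "moleculeId"),
        nConstituents = length(records))
  }
  if (!is.na(noise@seed)) withSeed(noise@seed, perturb()) else perturb()
}
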