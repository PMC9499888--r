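---
title: "Identifying small molecules from noisy NMR chemical shift lists: methods and design"
author: "NMRShiftID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying small molecules from noisy NMR chemical shift lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NMRShiftID)
```

## The problem

In silico NMR reference libraries — per-molecule lists of calculated
\(^{13}\)C and \(^1\)H chemical shifts — promise metabolite identification
without authentic chemical standards. Their usefulness hinges on one
question: **how much prediction error can a shift list carry before
identification against the library breaks down?** NMRShiftID implements a
Monte-Carlo framework to answer it. Calculated shift lists serve as
surrogate "experimental" spectra after zero-mean Gaussian noise of known
standard deviation \(\sigma\) is added per nucleus; the noisy list is then
searched back against the library, and identification success is measured
as a function of \(\sigma\).

Two sample types are covered:

* **pure samples** — the query is a single molecule's shift list; candidates
  are the library molecules with exactly the query's number of carbon and/or
  proton shifts;
* **mixtures of 2–3 compounds** — the query is the pooled (concatenated)
  shift list of its constituents; candidates are *tuples* of distinct
  library molecules whose nucleus counts sum exactly to the query's.

## Scoring model

Given a query list and a candidate list of equal length \(N\) (guaranteed by
the exact-count filtering), the pairing of observed to reference shifts is
unknown. We resolve it as a minimum-cost one-to-one assignment over the
\(M \times N\) matrix of squared differences \((s_i - b_j)^2\) (Hungarian /
Munkres algorithm; compiled, \(O(M^2N)\)). Over the assigned pairs we report

\[
\mathrm{MAE} = \frac{1}{N}\sum |\delta_{\exp} - \delta_{\mathrm{calc}}|,
\qquad
\mathrm{RMSE} = \sqrt{\frac{1}{N}\sum (\delta_{\exp} - \delta_{\mathrm{calc}})^2},
\]

and, for library reuse, the corrected MAE
\(\mathrm{CMAE} = \frac1N \sum |\delta_{\exp} - (\delta_{\mathrm{calc}} - b)/m|\)
where \(m, b\) are the least-squares slope/intercept of calculated on
experimental shifts. The identification pipeline scores candidates by
**RMSE on raw shifts**; CMAE and the scaling fit are available but not
applied inside the pipeline (de-scaling before matching is an explicit
opt-in, since the surrogate spectra are generated without systematic
distortion).

When both nuclei are used, each channel's RMSE is computed separately and
combined as a geometric mean \(\sqrt{\mathrm{RMSE}_C \cdot \mathrm{RMSE}_H}\),
which keeps the ppm scale of carbon (0–220 ppm) from dominating that of
proton (0–12 ppm). Candidates are sorted ascending; rank 1 is a positive
identification. Note one consequence of the formula as written: a perfect
single-channel match (RMSE 0) annihilates the product regardless of the
other channel. We follow the formula and flag rather than "fix" this edge.

**Tie policy.** The truth's rank is pessimistic:
\(1 + \#\{\text{strictly better}\} + \#\{\text{equal non-truth}\}\).
This makes reported identification rates conservative and — importantly —
deterministic under permutation of library record order.

## The synthetic library generator

The paper-scale reference sets (thousands of water/chloroform-solvated
metabolites) are distributed on request only, so the package ships a
generator whose defaults emulate their statistical structure:

* **counts**: per-molecule carbon and hydrogen counts follow shifted,
  truncated negative binomials on \([1,40]\) and \([1,60]\), peaking near
  8–12 C and 12–18 H (right-skewed, as in metabolite libraries). The two
  counts are coupled through a Gaussian copula (default correlation 0.8,
  marginals preserved exactly): real molecules gain carbons and hydrogens
  together with size, and it is precisely this coupling that populates the
  joint \((n_C, n_H)\) candidate classes on which exact-count filtering
  operates. Independent draws would leave almost every joint class a
  singleton and make combined-nuclei identification trivially easy.
* **shifts**: each molecule's shifts are drawn from 1–4 Gaussian clusters
  placed uniformly in the nucleus range (cluster SD 6 ppm for carbon, scaled
  by the range ratio for proton), then clipped to range. Clustering mimics
  functional-group clumping and produces realistic between-molecule shift
  collisions; i.i.d. uniform shifts would make matching unrealistically
  discriminative.
* **noise**: `addNoise()` adds independent \(\mathcal N(\mu, \sigma^2)\)
  per shift, \(\mu = 0\) by default (calculated-shift errors are equally
  likely positive or negative). Student-t errors, pH/temperature effects,
  peak overlap, missing/extra peaks and lineshape are *not* modelled.

What passing tests on synthetic libraries do **not** show: absolute
identification rates transfer to real libraries. Rates depend strongly on
library size and on how densely count classes and shift space are occupied;
a 300-molecule synthetic library is far more forgiving than a 2,723-molecule
metabolite set, and the thresholds reported by `scripts/acceptance.R` are
accordingly larger than those of paper-scale sets. What does transfer is the
qualitative structure: monotone decay of Top-k rates in \(\sigma\), a much
larger tolerable carbon error than proton error, the gain from combining
nuclei, and the known-vs-unknown constituent-count ordering in mixtures.

Reproducibility: every experiment takes a master seed and derives one
sub-stream seed per (grid point, replicate), so any replicate can be rerun
in isolation; `generateLibrary()` is bit-reproducible from its spec seed
under R's default Mersenne-Twister RNG.

## Case I: sweeps and tolerance thresholds

`runReplicate()` perturbs every eligible library molecule, filters
candidates by exact counts, and records ranks (the truth is always present:
closed-world, as when every query molecule exists in the library).
`sweepSigma()` averages Top-k percentages (k = 1, 2, 5, 10) over replicates
(default 16, the study's design), and `thresholdSigma()` returns the largest
\(\sigma\) at which the mean Top-k curve still reaches a target percentage,
linearly interpolated between grid points; targets never attained or
attained everywhere return distinguished statuses rather than numbers
pretending precision.

```{r caseI, eval = FALSE}
lib <- generateLibrary(librarySpec(300, seed = 1))
sw <- sweepSigma(lib, c(0.5, 1, 2, 4, 7, 12, 20, 35, 50),
                 replicates = 16, mode = "C", seed = 1)
thresholdSigma(sw, 90, k = 1)
```

A note on units: study reports sometimes label tolerances as MAE where the
swept quantity is the Gaussian \(\sigma\). For zero-mean Gaussian error
\(\mathrm{MAE} = \sigma\sqrt{2/\pi} \approx 0.798\,\sigma\); this package
consistently treats all thresholds as \(\sigma\) values.

## The carbon/proton trade-off

`gridSweep()` maps mean Top-1 over a \((\sigma_C, \sigma_H)\) grid in
combined mode. `extractContour()` pulls an iso-identification contour
(per \(\sigma_H\) column, the interpolated \(\sigma_C\) crossing); columns
that never reach the level, or are still at/above it at the grid edge, are
omitted — the latter because the grid edge would understate the true
contour. The contour is fitted by Levenberg–Marquardt to the reciprocal law

\[ \sigma_C = \frac{a}{\sigma_H - b} + c, \]

with starting values placing the singularity just left of the data
(\(b_0 = 0.9\min\sigma_H\), \(c_0 = 0.9\min\sigma_C\), \(a_0\) from the
first point). The trade-off optimum minimizes the normalized cumulative
error \(\sigma_C/\mathrm{norm}_C + \sigma_H/\mathrm{norm}_H\) on the curve;
the closed form is \(\sigma_H^\* = b + \sqrt{a\,\mathrm{norm}_H/\mathrm{norm}_C}\),
\(\sigma_C^\* = c + \sqrt{a\,\mathrm{norm}_C/\mathrm{norm}_H}\), clipped to
the observed contour span. The default norms 50 and 10 ppm are the spans of
the studied noise grids — the only "ranges" the design defines; both are
configurable.

## Case II: mixtures

A mixture query pools its constituents' shifts; candidate tuples are
unordered combinations of *distinct* molecules (a compound cannot appear
twice in one sample) whose count sums match the query exactly. Enumeration
probes the library's count index with the complement of the counts
accumulated so far — never brute force over all tuples — and a hard budget
(default \(5\times10^6\) tuples per query) aborts rather than silently
truncating. Scoring assigns the pooled query list onto the pooled candidate
list one-to-one, so each observed shift is explained by exactly one
candidate nucleus.

With the constituent count **unknown**, all tuple sizes \(1..\mathrm{maxN}\)
(default 3) compete in one ranking, still under exact count sums per size;
scoring incomplete tuples whose counts fall short of the query's is left
unimplemented by design. This pooled ranking reproduces the characteristic
failure mode: a single molecule whose counts happen to equal a pair's totals
and whose shifts resemble the pooled spectrum can outrank the true pair —
knowing the constituent count excludes such impostors outright (demonstrated
deterministically in the test suite). On desk-scale synthetic libraries
(\(\le\) 300 molecules) tuple competition is sparse enough that both modes
typically still identify the truth first; the collapse becomes a rate
phenomenon only at reference-library scale, which is why the packaged
experiments report it qualitatively (known-n ranks \(\le\) unknown-n ranks,
provably, since known-n candidates are a subset).

## Numerical and design choices

* Cost-matrix orientation is pinned: rows = query ("experimental"), columns
  = candidate ("computed"); `munkresAssign()` requires \(M \le N\) and
  instructs the caller to swap otherwise.
* RMSE is computed over the \(\min(M,N)\) assigned pairs only; unassigned
  larger-side shifts contribute nothing (Case II relies on this when a
  molecule's list is matched into a pooled query by the general matcher).
* Assignment ties are harmless: only the (unique) minimal total cost feeds
  the score.
* The compiled solver accumulates the total in row order of the assigned
  pairs so that it is bit-identical to an enumeration oracle's sum — the
  test suite demands exact, not approximate, agreement.
* Molecules lacking the active nucleus are retained in libraries but are
  neither queries nor candidates in that mode (they can never produce a
  defined score).
* Canonical CSV/JSON serialize doubles at 17 significant digits; write/read
  cycles reproduce libraries bit-exactly.
* Contours are extracted from the replicate-averaged surface, not per
  replicate, matching how averaged identification percentages are reported.

## Problem sizes

The packaged experiments are sized for a desk machine: the default study
library is 300 molecules (grids of 9 \(\sigma\) values per nucleus, 8–16
replicates), trade-off surfaces 9 × 11 cells at 4 replicates, and mixture
experiments run 100 sampled mixtures per configuration on a 150-molecule
library. Full-scale runs (thousands of molecules, 190+ noise levels,
exhaustive pair enumeration) use the same code paths; only the budgets and
grids change.

## Known limitations

* No modelling of missing/extra peaks, overlap, lineshape, pH/temperature
  effects, or concentration/stoichiometry in mixtures.
* No computation of shifts from structure (no quantum chemistry); ingestion
  expects referenced ppm values, with an optional user-supplied affine
  converter applied at read time (referencing constants are never guessed).
* The geometric-mean zero-annihilation edge case described above.
* Absolute rates on synthetic libraries understate the difficulty of
  paper-scale reference sets; treat them as protocol demonstrations, not
  transferable constants.
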