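# NMRShiftID

How accurate do predicted NMR chemical shifts have to be before you can
trust them to identify a small molecule? In silico reference libraries —
per-molecule lists of quantum-chemically calculated ¹³C and ¹H chemical
shifts — could free metabolomics from its dependence on authentic chemical
standards, but only if the prediction error stays below the level at which
library search starts returning the wrong molecule. NMRShiftID is an R
package for quantifying that tolerance by simulation, for both pure samples
and small (2–3 compound) mixtures.

It is aimed at researchers building or evaluating calculated-shift
libraries who want, for their own library and error model, curves of
identification rate versus noise, tolerable-error thresholds, the
carbon/proton error trade-off, and mixture-identification behaviour.

## Method

A query shift list (per nucleus) is matched to each candidate's list by a
minimum-cost one-to-one assignment over squared differences
(Hungarian/Munkres algorithm), resolving the unknown pairing of observed to
reference shifts. Agreement over the assigned pairs is scored as

    MAE  = Σ|δ_exp − δ_calc| / N
    RMSE = sqrt( Σ(δ_exp − δ_calc)² / N )
    CMAE = Σ|δ_exp − (δ_calc − b)/m| / N     (m, b: fitted slope/intercept)

The pipeline ranks candidates by RMSE; when ¹³C and ¹H are used together
the two RMSEs are combined as a geometric mean `sqrt(RMSE_C · RMSE_H)` so
neither ppm scale dominates. Rank 1 in the ascending score list is a
positive identification (ties are counted pessimistically).

Monte-Carlo experiments perturb every library molecule with zero-mean
Gaussian noise (σ_C, σ_H), giving Top-k identification percentages as a
function of noise; from these come tolerance thresholds (largest σ still
reaching, say, 90% Top-1), the iso-identification contour in the
(σ_H, σ_C) plane with its reciprocal fit `σ_C = a/(σ_H − b) + c` and
trade-off optimum, and mixture experiments in which candidate *tuples* of
distinct molecules are enumerated by exact nucleus-count sums — with the
constituent count known or unknown.

A synthetic library generator (right-skewed, copula-coupled carbon/hydrogen
count distributions; cluster-structured shifts over 0–220 ppm ¹³C and
0–12 ppm ¹H) stands in for request-only reference sets; real libraries are
ingested from canonical CSV/JSON or a MOL-directory-plus-shift-table
layout. See `vignettes/shift-matching-methods.Rmd` for the full model and
design rationale.

## Worked example

```r
library(NMRShiftID)

lib <- readShiftLibrary(system.file("extdata", "example_library.csv",
                                    package = "NMRShiftID"), "csv")
lib
#> ShiftLibrary: 6 molecules, solvent 'water'
#>   53 carbon and 99 hydrogen nuclei in total

# one identification trial: perturb a molecule's own shifts and search back
identifyMolecule(lib, "SYN000003",
                 noiseModel(sigmaC = 2, sigmaH = 0.2, seed = 42L), mode = "CH")
#> RankingResult for query 'SYN000003' (ok): 1 candidates, rank of truth = 1
#>   candidate_id   rmse_C    rmse_H  combined
#> 1    SYN000003 2.034963 0.1044291 0.4609874
```

The per-nucleus RMSEs (2.03 ppm carbon, 0.10 ppm proton) sit near the
injected σ values, and their geometric mean 0.46 ppm is the candidate's
score; with rank 1 the molecule is identified. At study scale:

```r
biglib <- generateLibrary(librarySpec(300, seed = 1))
sw <- sweepSigma(biglib, c(1, 4, 12, 35), replicates = 8, mode = "C", seed = 7)
sw@stats[sw@stats$k == 1, ]
#>    sigma_C sigma_H k  mean_pct    sd_pct
#> 1        1       0 1 100.00000 0.0000000
#> 5        4       0 1  98.37500 0.5175492
#> 9       12       0 1  89.83333 1.0389250
#> 13      35       0 1  53.50000 2.5448360

thresholdSigma(sw, 90, k = 1)
#> $sigma
#> [1] 11.8439
#> $status
#> [1] "ok"
```

Top-1 identification on this 300-molecule synthetic library stays above 90%
up to σ_C ≈ 11.8 ppm when carbon shifts are used alone. (Thresholds shrink
as libraries grow: more molecules share a candidate list.)

A thin command-line front end over the same functions ships in
`inst/scripts/nmrmatch.R` (subcommands `gen-lib`, `summarize`, `identify`,
`sweep`, `mix`, `tradeoff`).

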