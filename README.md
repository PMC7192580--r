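# dascr

Classification of clathrin-coated structure (CS) trajectories from
single-channel live-cell fluorescence imaging. Given per-trace intensity
time series (1 frame/s) and per-movie metadata, `dascr` separates
*abortive coats* (ACs) from *bona fide clathrin-coated pits* (CCPs) and
*outlier traces* (OTs) without user-defined lifetime or intensity
thresholds, and computes the downstream stage-resolved endocytosis
metrics and statistics that such classifications feed: initiation and
stabilization rates, lifetime/intensity distributions with bootstrap
confidence bands, 2D feature density ("DAS") maps and difference maps,
cross-day pooled bootstrap phenotype comparisons, permutation robustness
tests, and an epifluorescence/TIRF ratiometric invagination-depth
estimator. A labeled synthetic trace simulator makes the entire pipeline
testable without microscopy data.

## The method

Each trace is quantized into a chain of integer intensity states
`(i, t=1) → (j, t=2) → … → (k, t=τ)`. From the whole control population,
the conditional probabilities `W_t(i⁻|i)` of a drop from state `i` to any
lower state between frames `t` and `t+1`, and `W_t(i|i⁻)` of a gain into
`i` from any lower state, define the **disassembly risk function**

    D(i,t) = ln Σ_{i⁻<i} W_t(i⁻|i) − ln Σ_{i⁻<i} W_t(i|i⁻)

— negative while assembly dominates, ≈ 0 for plateau fluctuation,
positive where loss dominates. Projecting a trace through `D` yields a
risk series summarized by three features: the time average `d1`, the log
range rate `d2 = ln{[max(D) − min(D)]/τ}`, and a 1/τ-weighted skewness
`d3`. After normalization by control statistics, k-medoids clustering
(k = 3, Euclidean distance) separates ACs (`d1 < 0`), CCPs (`d1 ≈ 0`)
and OTs (high `d3`); the control model's boundaries are then applied to
every experimental condition of the same day.

## Worked example

```r
library(dascr)

# a control condition plus a stabilization-defective condition
# (CCP fraction reduced by 0.12) of synthetic traces
sim <- simulateTwoConditions(dascSimConfig(n_traces = 4000, seed = 7),
                             ccp_fraction_shift = 0.12)
res <- runDasc(sim$control$traces,
               list(perturbed = sim$perturbed$traces), seed = 7)
res$model
#> DasModel: k = 3 | total distance = 3488.42 | provenance: control
#>      label d1n    d2n    d3n
#> [1,] AC    -0.756  0.128  0.596
#> [2,] CCP    0.600 -0.659 -1.189
#> [3,] OT     1.801  1.953  0.972

sapply(res$movie_metrics, function(m) mean(m$ccp_pct))
#>   control perturbed
#>  37.59684  28.72421

compareConditions(res$movie_metrics$perturbed, res$movie_metrics$control)
#>              variable    delta_r            p
#> 1        cs_init_rate   0.000000 8.603077e-01
#> 2             ccp_pct -23.599409 3.411263e-07
#> 3              ac_pct  15.919168 3.286408e-07
#> 4            ccp_rate -23.375754 1.341998e-06
#> 5 median_ccp_lifetime  -2.272727 1.345645e-01
```

The fitted medoids carry the semantic labels (OT = highest mean `d3n`,
then AC = lower mean `d1n`). The planted relative CCP deficit shows up as
a −24% change in CCP% with a highly significant rank-sum p, while the
initiation rate and CCP lifetime are unaffected — the signature of a pure
stabilization defect (at this small demonstration size, n = 4,000 traces,
classification leakage attenuates the planted −30% somewhat; the test
suite checks recovery at full study size).

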