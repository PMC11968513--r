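# relkin — release kinetics modelling for sustained-release microparticles

`relkin` analyses in vitro drug-release studies of biodegradable polymeric
microparticles (PLGA microspheres and kin) run under the standard
**sample-and-replace** dissolution design: a known mass of particles is
suspended in a fixed volume of medium, and at each sampling time the whole
medium is removed, assayed, and replaced. It is written for formulation
scientists who need to turn replicate-level supernatant concentrations into
cumulative release profiles, quantify burst release, identify the release
mechanism by fitting and ranking kinetic models, and compare formulations
with the regulatory f2 similarity factor.

## The models

Released fraction vs time `Y(t)` is described by a catalog of classical
models — zero order (`kt`), first order (`1 − e^(−kt)`), Higuchi (`k√t`),
Korsmeyer–Peppas (`kt^n`), Baker–Lonsdale (implicit,
`(3/2)[1 − (1 − m)^(2/3)] − m = kt`), Weibull (`1 − e^(−t^β/α)`) — and, as
the headline model for degradable matrices, the biphasic
**Gallagher–Corrigan** equation with the **Gorrasi** burst correction:

```
Y(t) = b + Y1 (1 − e^(−k1 t)) + Y2 · e^(−k2 (t2 − t)) / (1 + e^(−k2 (t2 − t)))
```

where `b` is the 24-h burst fraction, `Y1`/`k1` describe the first-order
dissolution stage of non-bonded drug, and `Y2`/`k2`/`t2` describe the
sigmoidal polymer-erosion stage centred at `t2` (days). With `b = 0` the
original two-stage model is recovered. Fits are ranked by the adjusted
coefficient of determination `R²adj = 1 − ((n−1)/(n−p))(1−R²)`.

Profiles are compared with `f2 = 50·log10(100/√(1 + Σ(R_t − T_t)²/n))` on
mean percent released, truncated at the first point where either profile
reaches 85%; `50 ≤ f2 ≤ 100` means "similar".

## Worked example

A small synthetic triplicate assay (dexamethasone + ursodeoxycholic acid
co-loaded microspheres, 5 mg in 2 mL, sampled at 24 h then weekly to day
91) ships with the package:

```r
library(relkin)
csv  <- system.file("extdata", "synthetic_dx_udca_assay.csv", package = "relkin")
meta <- system.file("extdata", "synthetic_dx_udca_meta.json", package = "relkin")
assay <- read_assay(csv, meta)

prof <- cumulative_from_samples(assay, "DX")
prof
#> <cumulative_profile> DX: 14 times (1..91 d), 3 replicate(s)
#>   final mean release: 68.13 ug/mg (fraction 0.7112)

experimental_burst(prof)
#> <burst_summary> DX: 18.35 per mg (fraction 0.1915) at 1 d

interval_release_rate(prof, 7, 42)   # ug/mg/day over the erosion onset
#> [1] 0.585

fit_model(prof, "gallagher_corrigan_gorrasi", fit_config(seed = 1))
#> <fit_result> gallagher_corrigan_gorrasi: sse = 1.53e-06, R2 = 1.00000, adj R2 = 0.99999 (n = 14, p = 6)
#>    b = 0.14566, Y1 = 0.22158, k1 = 0.22971, Y2 = 0.34408, k2 = 0.16504, t2 = 42.194

compare_models(prof, c("higuchi", "first_order", "korsmeyer_peppas",
                       "gallagher_corrigan", "gallagher_corrigan_gorrasi"),
               fit_config(seed = 1))
#> <model_comparison> selected: gallagher_corrigan_gorrasi
#>                       model p r2_adjusted converged
#>  gallagher_corrigan_gorrasi 6   0.9999942      TRUE
#>          gallagher_corrigan 5   0.9971663      TRUE
#>            korsmeyer_peppas 2   0.9242422      TRUE
#>                     higuchi 1   0.8923224      TRUE
#>                 first_order 1   0.7305254      TRUE

compute_f2(prof, cumulative_from_samples(assay, "UDCA"))
#> <similarity_result> f2 = 48.31 over 14 point(s) -> not-similar
```

The assay was simulated (noise CV 2%) from the burst-corrected biphasic
parameters `b = 0.1436, Y1 = 0.2225, k1 = 0.2284, Y2 = 0.3442, k2 = 0.1661,
t2 = 42.25`; the fit recovers them to the precision the noise permits, the
24-h burst (0.1915) sits next to the fitted `b`, and the single-mechanism
classical models lose the ranking — the motivating observation for
segmented fitting via `fit_segmented()`.

The whole chain (profiles → burst table → model ranking → biphasic
parameter table → pairwise f2) is available as `characterize()`, and as a
command-line tool in `exec/relkin`
(`simulate`, `cumulate`, `fit`, `f2`, `characterize` subcommands).

## Package layout

- `R/assay.R` — assay container, CSV/JSON I/O
- `R/cumulate.R` — mass balance, burst, interval rates
- `R/kinetics.R` — model catalog and predictors
- `R/fitting.R` — bounded multistart least squares, segmentation, ranking
- `R/similarity.R` — f2 with the 85% truncation rule
- `R/synthetic.R` — seeded assay generator + reference parameter sets
- `R/pipeline.R` — `characterize()` report bundle
- `vignettes/release-kinetics.Rmd` — methods notes and design rationale
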