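---
title: "Release kinetics of sustained-release microspheres: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Release kinetics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relkin)
```

## The measurement model

A sample-and-replace release assay suspends a mass $m$ (mg) of drug-loaded
microspheres in a volume $V$ (mL) of buffer. At each sampling time $t_k$
the vial is centrifuged, the **entire** supernatant is removed and assayed,
and fresh medium is added. Because the whole medium is exchanged, the
supernatant concentration $C_k$ (amount/mL) measures exactly the amount
released in the interval $(t_{k-1}, t_k]$, and the cumulative amount per mg
of particles is the running sum

$$Q(t_k) = \frac{1}{m}\sum_{i \le k} C_i V .$$

`cumulative_from_samples()` implements this mass balance with no
carry-over or sink-saturation correction — the simplest balance consistent
with a full-replacement protocol. Partial-replacement designs are out of
scope. Dividing $Q$ by the analyte loading $L$ (amount/mg, from the
encapsulation-efficiency assay) gives the released fraction. Fractions
above 1 are possible — loadings carry measurement error — and are flagged
rather than clipped.

Replicates are accumulated independently and summarised as mean ± SD in
amount units; the fraction is computed from the replicate mean
(mean-then-fraction), matching how release curves are reported. A lost
sample leaves a hole in that replicate's running sum, so its cumulative
series is `NA` from that time onward and the remaining replicates carry the
mean; nothing is imputed.

Two model-free summaries are provided: `experimental_burst()` (the value at
the sampling time nearest 24 h, tolerance ±0.5 d — a definition, not an
extrapolation, so schedules with no sampling near day 1 have no burst) and
`interval_release_rate()` (the chord slope in amount/mg/day, linearly
interpolated at the endpoints).

## The kinetic models

`predict_release()` exposes the canonical single-mechanism models (zero and
first order, Higuchi, Korsmeyer–Peppas, Baker–Lonsdale, Weibull) and the
two biphasic forms. The headline model is the Gallagher–Corrigan equation
with the Gorrasi burst term:

$$Y(t) = b + Y_1\!\left(1 - e^{-k_1 t}\right)
       + Y_2\,\frac{e^{-k_2 (t_2 - t)}}{1 + e^{-k_2 (t_2 - t)}}$$

| parameter | meaning | unit | typical magnitude |
|---|---|---|---|
| $b$ | 24-h burst fraction | – | 0.03–0.30 |
| $Y_1$ | fraction released by dissolution of non-bonded drug | – | 0.05–0.40 |
| $k_1$ | stage-1 first-order rate | day$^{-1}$ | 0.01–0.45 |
| $Y_2$ | fraction released by matrix erosion | – | 0.25–0.95 |
| $k_2$ | steepness of the erosion sigmoid | day$^{-1}$ | 0.09–0.40 |
| $t_2$ | centre of the erosion stage | day | 30–81 |

$b + Y_1 + Y_2$ is the asymptotic released fraction; the constructor
enforces a soft bound of 1.2 on the sum, because loading-normalised
published parameter sets can exceed 1 (the single-loaded UDCA reference row
sums to 1.0958 — encapsulation-efficiency uncertainty propagates into the
normalisation). We normalise fractions to the measured loading, not to the
final released amount; the two conventions differ exactly by such excesses.
The printed source of the reference rows describes the equation as having
seven unknown parameters while printing six; the six printed parameters are
what `relkin` fits.

Numerical choices worth knowing:

* the logistic term is evaluated as `plogis(k2 * (t - t2))`, which is
  algebraically identical to the printed form and overflow-safe for
  arbitrarily large $|k_2(t_2 - t)|$;
* Baker–Lonsdale is implicit in the fraction; it is inverted per time point
  with `uniroot()` at tolerance 1e-13, with the saturated branch
  ($kt \ge 1/2$, the maximum of the left-hand side) returning 1;
* the Weibull form is the minimal two-parameter one (no lag time): a lag is
  representable by segmentation instead.

## Fitting

`fit_model()` minimises $\sum_i (y_i - Y(t_i))^2$ on the mean fraction
series under box constraints with `stats::nlminb`, restarted from 32
Latin-hypercube points (log-uniform for parameters spanning ≥ 3 decades,
i.e. the rate constants) plus one data-driven start (burst from the first
point, $t_2$ from the steepest late interval, amplitudes from the plateau).
Bounds default to $b, Y_1, Y_2 \in [0, 1.2]$,
$k_1, k_2 \in [10^{-4}, 10]$ day$^{-1}$, $t_2 \in [1, t_{\max}]$ —
generous envelopes around the magnitudes in the table above. The incumbent
is polished until the SSE change drops below $10^{-10}$. One parameter set
is reported per profile (replicate means), matching how release-parameter
tables are published; fitting is deterministic given `fit_config(seed)`
because the only randomness is the start draw. A fit in which no start
converges is returned with `converged = FALSE`, never as a silent
best-effort value. The sigmoid term does create local minima — the
multistart is not decorative — but on noiseless 14-point schedules the
global minimum (SSE $\approx 0$) pins all six parameters to ~$10^{-8}$
relative error, and the suite verifies this for all seven reference rows.

$R^2$ is computed against the mean-fraction null and ranked after the
$p$-penalty: $R^2_{adj} = 1 - \frac{n-1}{n-p}(1 - R^2)$. Model selection
uses adjusted $R^2$ only (no AIC/BIC); ties — which occur exactly, e.g.
zero-order vs Korsmeyer–Peppas with $n \to 1$ on a perfect line — go to
the model with fewer parameters, then to alphabetical order, with adjusted
$R^2$ compared at 12 decimals so floating-point dust cannot reorder exact
ties. No artificial $(0,0)$ point is prepended to the data: the
burst-corrected model intentionally has $Y(0) = b + \text{(sigmoid tail)} > 0$.

Single-mechanism models generally cannot track a multiphasic profile in one
piece; `fit_segmented()` implements the classical remedy of splitting the
profile into 2–3 steps at user-chosen breakpoints. Each segment is rebased
to its own origin (the last point of the preceding segment), so the
per-segment model describes incremental release; per-segment and pooled
goodness of fit are both reported. Breakpoint *selection* is left to the
user — the tool fits given breakpoints, it does not search for them.

## Similarity

`compute_f2()` works on mean percent released (profiles in fraction units
are converted internally — the statistic is meaningless on the fraction
scale). The comparison window follows the regulatory 85% rule: all points
strictly before the first time either profile reaches 85% dissolved, plus
that first point, are retained. The wording of the rule is ambiguous about
the boundary point; we keep it, which preserves the plateau onset in the
comparison. Useful closed forms (both verified in the suite): identical
profiles give $f_2 = 100$, and a uniform offset of $\sqrt{99} \approx 9.95$
percentage points gives exactly 50, the similarity boundary. Replicate
variability is out of $f_2$'s scope (no bootstrap intervals).

## What the synthetic generator does and does not emulate

`generate_assay()` simulates the stated assay design: 5 mg of microspheres
in 2 mL, triplicate vials, sampling at 24 h, day 7, then weekly
(`release_schedule()`), with analytes carried in their own units (the
protein reference loading is 19.83 ng/mg, three orders of magnitude below
the small molecules, deliberately exercising unit handling). True
per-interval released amounts are computed from the generating curve and
perturbed **multiplicatively** with a configurable CV, floored at zero,
then expressed as supernatant concentrations. Noise on increments (rather
than on cumulative values) matches the physical measurement — each
supernatant is assayed independently — and keeps every replicate's
cumulative series non-decreasing, so `cumulative_from_samples()` inverts
the generator exactly at zero noise. That round trip is the pipeline's
master oracle.

The default `noise_cv = 0.02` is a statement about a well-behaved LC-MS/
ELISA assay, not an estimate of any particular study's error (none is
published for the reference data). The generator does not emulate:
inter-batch loading variability, systematic drift, medium saturation,
particle loss at sampling, or correlated replicate errors. A green
recovery test therefore establishes that the estimator inverts the model
under the stated noise — not that any real assay satisfies the model.

## Degenerate inputs and edge behaviour

Duplicate measurement cells, negative concentrations, unknown analytes,
non-positive or non-increasing times, and zero mass/volume are hard errors
at construction; missing cells are completed and flagged. Schedules whose
first sampling is after 1.5 d have no burst (error, not 0). `adjusted_r2`
refuses $n \le p$. A constant fraction series has $SS_{tot} = 0$; $R^2$ is
1 for a perfect fit and undefined otherwise. `characterize()` records
stage failures per analyte in the bundle and keeps going.

## Known limitations

* Breakpoints for segmented fits are not optimised.
* `f2` has no confidence interval.
* The fitter offers no per-replicate (mixed-effects) mode beyond fitting
  each replicate separately by hand.
* The burst offset $b$ is always fitted freely; the experimental 24-h value
  is reported alongside for comparison (whether published tables fixed it
  is not stated — both columns are printed there, which is what we mirror).
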