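# nixdry

Kinetic analysis of isothermal dehydration of nixtamalized corn grains
(NCG) as a function of steeping time.

Nixtamalization — alkaline cooking of corn in lime water followed by
steeping — leaves the grain hydrated; before milling into masa or flour it
is dried at constant temperature (below starch gelatinization, ~50 °C).
`nixdry` is for food-process engineers and researchers who need to model
that drying step: how fast moisture leaves the grain, how the steeping time
(ST, hours) changes the kinetics, and which (steeping time, drying time)
combinations deliver a product at a target moisture.

## The model

Moisture loss is first order in the excess moisture above equilibrium:

    dM/dt = -k [M(t) - ME]   =>   M(t) = (M0 - ME) e^{-kt} + ME

with `M0` the initial moisture (%), `ME` the equilibrium moisture (%) and
`k` the rate constant (per minute). Derived quantities:

- moisture ratio `MR(t) = (M - ME)/(M0 - ME) = e^{-kt}`;
- dehydration rate `vI(t) = -k (M0 - ME) e^{-kt}` (negative: moisture is
  lost), with initial rate `v0 = -k (M0 - ME)`;
- inverse time `t = (1/k) ln[(M0 - ME)/(M - ME)]`;
- the Crank sphere solution of Fick's second law,
  `MR = (6/π²) Σ (1/n²) exp(-Deff n² π² t / a²)`, whose one-term reduction
  identifies `k` with the effective diffusivity through
  `Deff = k a² / π²` (grain radius `a = 0.0049` m by default);
- the diffusivity rate `vk(t) = -t (M0 - ME) e^{-kt}`, the sensitivity of
  the moisture curve to `k`, whose magnitude peaks at exactly `t = 1/k`.

The package recovers `(M0, ME, k)` from drying trajectories by bounded
Levenberg–Marquardt least squares (and by the log-linear slope method),
builds moisture and rate isoline surfaces over the (ST, drying-time)
plane, and ships a seeded generator that emulates the standard experiment:
ST ∈ {0, 2, 4, 6, 8} h, weighings every 15 min over 0–120 min plus an
equilibrium point at 2600 min, five replicates, with measurement noise
shrinking from ±0.993 to ±0.181 percentage points over log time.

## Worked example

```r
library(nixdry)

p <- kinetic_params(m0 = 47, me = 5.792, k = 0.0158)  # ST = 4 h condition
moisture_at_time(p, 60)   # 21.761 % — moisture after 1 h of drying
time_for_moisture(p, 15)  # 94.8 min — drying time to reach 15 % moisture
deff_from_k(p$k)
#> <diffusivity_result> Deff = 3.844e-08 m^2/min (2.31e-06 m^2/h),
#>                      k = 0.0158 /min, a = 0.0049 m
vk_peak_time(p)           # 63.3 min — fastest diffusivity-driven loss

# simulate the full five-ST campaign and refit every condition
d <- generate_trajectories(experiment_design(seed = 42))
fit_all_st(d)
#>   st_h    m0    me       k      v0 r_squared
#> 1    0 38.57 5.045 0.01892 -0.6344    0.9994
#> 2    2 45.16 5.392 0.01606 -0.6387    0.9996
#> 3    4 47.32 5.904 0.01621 -0.6714    0.9996
#> 4    6 46.33 5.646 0.01467 -0.5970    0.9998
#> 5    8 45.86 5.963 0.01405 -0.5605    0.9998
```

Each row is one steeping-time condition: the fitted initial and
equilibrium moistures, rate constant, initial dehydration rate and
coefficient of determination. With the default noise the generating rate
constants (0.0185, 0.0161, 0.0158, 0.0147, 0.0140 /min) are recovered to a
few percent and every fit sits in the R² ≥ 0.994 band typical of this
assay.

`run_pipeline(run_config(seed = 1, output_dir = "out"))` chains
simulate → fit → diffusivity → surfaces and writes a JSON report plus CSV
grids and isolines; `inst/cli/nixdry.R` is a command-line wrapper over the
same functions.

## Package layout

- `R/kinetics.R` — the closed-form model and its inverse
- `R/fick.R` — sphere-diffusion series, the k ↔ Deff bridge, vk
- `R/fitting.R` — per-condition and per-campaign parameter recovery
- `R/isolines.R` — parameter surfaces, moisture/rate grids, isolines
- `R/synthetic.R` — experiment design, noise model, trajectory generator
- `R/io.R` — CSV/JSON I/O and the end-to-end pipeline
- `vignettes/dehydration-kinetics.Rmd` — the methods vignette
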