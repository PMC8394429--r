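---
title: "Modelling isothermal dehydration of nixtamalized corn grains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling isothermal dehydration of nixtamalized corn grains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nixdry)
```

## The process and the model

After nixtamalization (alkaline cooking in lime water) and a steeping
period of ST hours, corn grains are dried at a constant temperature low
enough to avoid starch gelatinization. `nixdry` models that drying stage
as first-order relaxation towards an equilibrium moisture:

$$\frac{dM}{dt} = -k\,[M(t) - M_E], \qquad
  M(t) = (M_0 - M_E)\,e^{-kt} + M_E,$$

with $M_0$ the moisture at the start of drying (percent), $M_E$ the
asymptotic equilibrium moisture (percent) and $k$ the rate constant (per
minute). The assumptions behind this single-exponential ("thin-layer" or
Newton/Lewis-type) description are: constant drying temperature, a
driving force proportional to the excess moisture above equilibrium, and
parameters that are constant over one drying run (steeping changes the
grain, so each ST gets its own triple). Moisture is treated as a
percentage on whatever basis the data were recorded — wet or dry basis —
because the model form is invariant to that choice; users should simply be
consistent.

Derived quantities follow in closed form: the moisture ratio
$MR = e^{-kt}$, the dehydration rate $v_I = -k(M_0 - M_E)e^{-kt}$ with
initial value $v_0 = -k(M_0 - M_E)$, and the inverse time
$t = (1/k)\ln[(M_0 - M_E)/(M - M_E)]$. Because equilibrium is approached
only asymptotically, `time_for_moisture()` treats a target at or below
$M_E$ as an error rather than returning `Inf`: a finite answer does not
exist, and silently returning infinity invites unit mistakes downstream.

## The diffusion link

Treating the grain as a homogeneous sphere of radius $a$ (default
$0.0049$ m, an average corn-grain radius), the Fick's-second-law solution
for desorption is the Crank series

$$MR(t) = \frac{6}{\pi^2}\sum_{n\ge 1}\frac{1}{n^2}
  \exp\!\left(-\frac{D_{eff}\,n^2\pi^2 t}{a^2}\right),$$

which is 1 at $t = 0$ (Basel sum) and decays monotonically. Published
statements of this series sometimes carry an alternating $(-1)^n$ factor
and a leading $1-$; that variant evaluates to $1.5$ at $t=0$ and is
inconsistent with $MR(0)=1$ and with the one-term logic below, so the
package implements the standard Crank form. Keeping only $n = 1$ gives
$MR \approx (6/\pi^2)\exp(-D_{eff}\pi^2 t/a^2)$, whose logarithm is affine
in $t$ with slope $-D_{eff}\pi^2/a^2$. Matching that slope to the
exponential model's $-k$ yields the bridge

$$D_{eff} = \frac{k\,a^2}{\pi^2},$$

implemented by `deff_from_k()` / `k_from_deff()` (stored per minute,
reported per hour, the customary unit for grain drying). For the five
reference rate constants this maps to $2.04$–$2.70 \times 10^{-6}$ m²/h;
note that only the interior steeping times fall inside the
$2.26$–$2.56\times 10^{-6}$ m²/h band quoted for this assay, so the
package reports the computed values and does not force agreement at the
extreme STs.

`diffusivity_rate_vk()` implements the sensitivity
$v_k(t) = \partial M/\partial k = -t\,(M_0 - M_E)\,e^{-kt}$, taken at its
final closed form (the chain-rule route by which it is sometimes derived
is not needed to define it). Its magnitude peaks at exactly $t = 1/k$
(54–72 min for the reference conditions, i.e. within the first 100 min of
drying), which is when the moisture curve is most informative about $k$ —
useful both for interpreting where the drying is diffusivity-limited and
for placing measurements.

### Numerical choices in the series

- Truncation defaults to 200 terms with an early exit once a term falls
  below $10^{-12}$; for any positive Fourier number met in practice the
  terms decay like $e^{-n^2}$ and far fewer terms are summed.
- At $t = 0$ (or $D_{eff} = 0$) the truncated direct sum converges only
  like $1/N$ — 200 terms still leave a $3\times10^{-3}$ deficit — while
  the analytic value of the full series is exactly 1. The implementation
  therefore returns the analytic limit there and uses the direct sum only
  for positive exponents; this keeps both the normalization and the
  large-$t$ accuracy (agreement with a 10,000-term sum to $10^{-10}$).
- The one-term reduction is accurate to 1.2% relative at
  $D_{eff}\pi^2t/a^2 = 1$, 0.06% at 2, and is essentially exact beyond 5;
  tests pin these oracle-tabulated errors rather than a blanket bound.

## Parameter recovery

`fit_exponential()` estimates $(M_0, M_E, k)$ by Levenberg–Marquardt
least squares (via `minpack.lm::nlsLM`) with box bounds that keep the
optimizer physical: $k \in (10^{-6}, 1)$ per minute, $M_E \in [0, M_0]$,
$M_0 \le 100$. Starting values are deterministic and data-driven — $M_0$
from the first observation, $M_E$ from the last, $k$ from the log-linear
slope — so fits are reproducible without a seed; up to three restarts with
deterministically jittered starts guard against a stray local minimum
before non-convergence is reported. The cost tolerance is $10^{-10}$.
Replicates are averaged per time point before fitting (matching how such
data are usually summarized); `use_replicates = TRUE` fits the raw
observations instead — with equal replicate counts per time the two
minimizers coincide, and both paths are provided because which one a given
laboratory used is rarely stated. $R^2$ is the conventional coefficient of
determination $1 - SS_{res}/SS_{tot}$ about the observed mean.

`fit_loglinear()` is the classical slope method: with $M_E$ assumed
known, $\ln[M - M_E]$ is affine in $t$ with slope $-k$. It is exact on
noiseless model data and serves as an independent cross-check on the
nonlinear fit; it requires every observation to exceed the assumed $M_E$
and names the first offending time point otherwise. Its intercept is
reported on the moisture-ratio scale (anchored at the first observation),
so it is zero for noiseless data.

## Surfaces and isolines

`build_param_surface()` interpolates the fitted $(M_0, M_E, k)$
component-wise across steeping time. Linear interpolation is the default:
it is transparent, exact at the nodes, and keeps interpolated values
inside the convex hull of the fitted ones; a monotone (Fritsch–Carlson)
cubic is available when smoother surfaces are wanted. Extrapolation
beyond the fitted ST range is refused — the five steeping times carry no
information about behaviour outside $[0, 8]$ h.

`moisture_grid()` and `rate_grid()` evaluate $M$ and $v_I$ on a
rectangular (ST, drying-time) grid — by default $0.1$ h × $10$ min over
$[0,8]$ h × $[0,2600]$ min (81 × 261 nodes) with 14 contour levels, a
resolution at which the linear in-cell error is far below measurement
noise. `extract_isoline()` traces level sets by linear interpolation along
cell edges (the marching-squares construction, delegated to
`grDevices::contourLines`); every crossing it returns agrees with the
closed-form inverse time at the interpolated parameters to within one
grid cell. A requested level outside the grid's value range yields an
empty result with a warning rather than an error, since scanning a level
ladder past the range is routine; a constant grid is flagged as
degenerate. `time_to_target_moisture()` answers the practical scheduling
question (e.g. drying into the 15–19% band used for shelf-stable corn
flour) directly from the inverse formula, without touching the grid.

## The synthetic generator

`generate_trajectories()` emulates the standard campaign: steeping times
0, 2, 4, 6, 8 h; weighings every 15 min over the first 120 min plus one
long-time point at 2600 min that pins down $M_E$; five replicates;
$5\times10\times5 = 250$ rows. The generating $(M_E, k)$ pairs are the
fitted per-ST values of the emulated assay; $M_0$ is **synthetic** — no
measured initial moistures exist to anchor it — and defaults to
$(38, 45, 47, 46.5, 46)$ %, rising steeply from the unsteeped condition
towards a ceiling of about 47% and easing slightly beyond 4 h, the
qualitative pattern steeping produces. The `m0_synthetic` flag in
`default_params_table()` marks this provenance.

Noise is Gaussian with a standard deviation that shrinks from 0.993 at
$t=0$ to 0.181 percentage points at 2600 min, interpolated linearly in
$\log(1+t)$: the measured uncertainty band for this assay gives only the
endpoints and the observation that scatter stabilizes at long times, and
log-time interpolation is the simplest schedule with that shape (most of
the decline happens early, as observed). Draws are clipped at zero —
moisture cannot be negative — and clipped cells are flagged. Generation
uses a private seeded RNG stream and leaves the caller's RNG state
untouched, so identical seeds give byte-identical CSV output.

What the generator does **not** emulate: the hydration (uptake) phase and
the cooling-water temperature profile during steeping, replicate-level
systematic offsets, drift or autocorrelation in the balance readings, and
any departure of a real grain from single-exponential kinetics. Passing
round-trip tests therefore demonstrates that the estimator recovers the
truth *when the model family is correct and errors are independent
Gaussians* — they validate the software and the identification strategy,
not the physics of any particular grain lot.

## Numerical limits and test sizes

In double precision $M(t) - M_E$ underflows below the representable
resolution of $M$ once $kt \gtrsim 20$ (for the reference rate constants,
beyond roughly 1100–1400 min). Past that point the inverse-time round
trip cannot meet a $10^{-9}$ relative target for purely floating-point
reasons, so the property tests assert it on $kt \le 20$ and strict
monotonicity on $kt \le 25$; the fitting code is unaffected (the 2600 min
equilibrium point carries information through its level, not its slope).

The test suite exercises: the five-condition noiseless round trip
(parameter recovery to better than $10^{-6}$ relative); 200 seeded
Monte-Carlo noisy campaigns at ST = 0 (median $|\hat k - k|/k$ about
1.4%, bias below 0.1%, asserted at < 5% and < 1%); a 10,000-replicate
check that the sample noise sd matches the schedule to 3%; and grid
identities on 33 × 53 to 81 × 261 surfaces. These sizes were chosen so
the estimator's sampling behaviour is measured with comfortable margin
while the whole suite stays fast.

## Known limitations

- A single exponential cannot represent falling-rate/constant-rate
  transitions or case hardening; grains departing from first-order
  behaviour will show structured residuals (inspect `fit_result$residuals`).
- $D_{eff}$ inherits the sphere idealization and the fitted $k$; it is an
  effective, not a mechanistic, diffusivity.
- Interpolated parameters between measured steeping times are a
  convenience for contouring and scheduling, not evidence about
  intermediate STs; this is why extrapolation is disabled outright.
- The log-linear method needs $M_E$ supplied and degrades quickly as
  observations approach it; prefer the nonlinear fit except as a check.
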