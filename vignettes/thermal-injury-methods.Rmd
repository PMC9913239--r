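---
title: "Modelling heat-induced cell death: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat-induced cell death: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodose)
```

## The problem

Thermal therapies — ablation and mild hyperthermia — kill cells as a
function of the whole time–temperature history they deliver, and the
dose–response differs across cell types. The standard experimental route
to cell-line-specific injury kinetics is water-bath heating of monolayer
cultures in 96-well plates (setpoints in the 42.5–50 °C range, exposures
of minutes to an hour, n = 6 wells per condition), with viability read
out by MTT absorbance normalized to unheated 37 °C control plates.
`thermodose` implements the forward models that map a time–temperature
profile to predicted survival, the inverse procedures that estimate each
model's coefficients from such viability tables, and a simulator of the
experiment itself, so the whole analysis chain can be exercised and
tested without access to any particular laboratory's raw data.

## Forward models

**Arrhenius damage integral.** Cell death is treated as a first-order
reaction with rate $k(T) = A e^{-E_a / (R T)}$ ($A$ in s$^{-1}$, $E_a$
in J mol$^{-1}$, $T$ in kelvin). Damage accumulates as
$\Omega(t) = \int_0^t k(T(\tau))\, d\tau$; the surviving fraction is
$e^{-\Omega}$ and the injury probability $100(1 - e^{-\Omega})$.
`damage_integral()` evaluates $\Omega$ by the trapezoidal rule on the
profile's own samples, which is exact for constant temperature and
second-order accurate otherwise.

**Time-delayed Arrhenius.** Many cell lines show a *shoulder*: viability
stays near 100 % until a threshold exposure is reached, then decays
exponentially. The delayed model adds a temperature-dependent latency
$t_d(T) = b - m T$ before the integral starts. $t_d$ goes negative above
$T = b/m$; a negative delay has no physical meaning and the piecewise
definition only distinguishes $t < t_d$ from $t \ge t_d$, so
`time_delay()` clamps it at zero.

The piecewise definition is stated for isothermal exposures only. For
time-varying profiles `damage_integral_delayed()` uses a normalized
delay accumulator $\xi(t) = \int_0^t d\tau / t_d(T(\tau))$: damage
integration starts when $\xi$ reaches 1, and any instant with
$t_d(T) = 0$ completes the delay immediately. This is, to our knowledge,
the only extension that is continuous in the profile and reduces
*exactly* to the piecewise definition at constant temperature (there,
$\xi(t) = t / t_d$ crosses 1 at $t = t_d$). The crossing time is located
by linear interpolation of $\xi$ within the bracketing interval and
inserted as an integration node, so the reduction holds at every sample,
not just asymptotically.

**Two-state logistic model.** The viable fraction is
$C(\tau, T) = \mathrm{logistic}(\gamma T - \beta - \alpha \tau)$: the
log-odds of being in the viable state are bilinear in temperature and
exposure time. It is fit by ordinary least squares on the logit scale
(`fit_two_state()`), which is the model's standard estimation route and
has a closed-form normal-equations solution that the test suite uses as
an independent oracle. The model is defined for isothermal exposures;
when the pipeline must apply it to a non-isothermal profile it uses the
profile's duration and time-averaged temperature, the natural summary
for a surface linear in $T$. This is an extrapolation convention, not
part of the model, and is the weakest link of the three models on
transient profiles.

**CEM43.** The thermal isoeffective dose converts a profile into
equivalent minutes at 43 °C:
$t_{43} = \sum_i \Delta t_i \, R^{(43 - T_i)}$ with $\Delta t_i$ in
minutes, $T_i$ in °C, and $R = 0.5$ strictly above the 43 °C break,
$0.25$ at or below (both configurable via `dose_params()`). On
non-uniform grids each interval contributes at its midpoint temperature,
consistent with the trapezoidal treatment of the damage integral. At
exactly 43 °C the exponent is zero, so the break-side choice is
irrelevant there.

## Inverse procedures

The estimation chain mirrors how such data are conventionally analysed:

1. **Per-temperature decay rates** (`fit_decay_rate()`): linear
   regression of $\ln S$ on exposure time; the slope gives $-k$. Two
   modes: `through_origin` forces $S(0) = 1$ (the "simple Arrhenius"
   arm), while `free_intercept` lets the intercept float and reports
   the positive x-intercept as the shoulder delay at that temperature.
2. **Arrhenius line** (`fit_arrhenius()`): OLS of $\ln k$ on $1/T$;
   slope $= -E_a/R$, intercept $= \ln A$.
3. **Delay line** (`fit_time_delay()`): OLS of the per-temperature
   shoulder delays on $T$, giving $b$ and $m$.
4. **Isoeffect factor** (`fit_rcem()`): under first-order kinetics the
   time to a fixed isoeffect is $\propto 1/k(T)$, so $R$ is
   $\exp(\text{slope})$ of $\ln(1/k)$ against $T$ in °C, using
   temperatures above the break. For pure Arrhenius rates this has the
   closed form $R(T) = e^{-E_a / (R_{gas} T (T+1))}$, used as a
   cross-check.

### Censoring and clipping rules

These small rules matter more than they look; each encodes a statement
about what an observation can and cannot tell us.

- **Survival clipping.** Control normalization can push measured
  survival slightly above 1; such points are retained, clipped at 1.5,
  because discarding them would bias early time points. Below, survival
  is clipped at $\varepsilon = 10^{-4}$ for log transforms.
- **Floor censoring.** A well at the clip floor is below the assay's
  resolvable range; its exact value is unknown. Floor-clipped points
  are excluded from the rate regressions rather than fitted at the
  floor, which would flatten the slope arbitrarily.
- **Shoulder trimming.** In `free_intercept` mode, observations inside
  the fitted shoulder carry delay information but no rate information.
  The fit is iterated: fit, compute the implied delay, refit on points
  at or beyond it, until the retained set stabilizes. On noiseless
  shoulder data this converges to the exact generating line. If a
  trimming step ever leaves a subset with a non-negative slope, the
  previous iterate stands — trimming is never allowed to destroy
  identifiability.
- **Sub-resolution delays.** A fitted delay shorter than the earliest
  measured exposure is indistinguishable from zero and is censored to
  zero. Without this rule, rounding-level intercepts at high
  temperatures masquerade as tiny shoulders and contaminate the delay
  line.
- **Censored delays constrain the delay line.** Setpoints whose
  estimated delay is zero do not enter the delay regression as data
  (their true delay is merely known to be $\le 0$), but they bound it:
  if the unconstrained line predicts a positive delay at such a
  setpoint — or has the unphysical sign — the line is refit anchored at
  zero delay for the coolest censored setpoint, the steepest line
  consistent with the censoring. This prevents a pathology where noisy
  shoulder estimates at two cool setpoints imply long delays at
  temperatures where none was observed.

### Model comparison

`evaluate_fit()` predicts survival (in percent) for every condition
from the forward model at that condition's setpoint and duration, and
reports root-mean-square error in percentage points, pooled across
conditions and cell lines, with a per-cell-line breakdown. Fits are run
separately per recovery time; the 24 h fits are treated as the kinetic
reference, since late-manifesting death means earlier readouts
understate the eventual kill.

## The synthetic experiment

`generate_viability_dataset()` emulates the study design: for each cell
line, setpoint, duration and recovery time, the true surviving fraction
is $S = \exp(-r\,k(T')\max(0, t - t_d(T')))$ where:

- $T'$ is the setpoint plus a per-plate jitter
  (`temperature_jitter_sd`, default 0.2 K — the scale of reported bath
  accuracy; drawn once per plate and shared across its wells, matching
  how bath error is characterized at plate level);
- $r$ is a recovery-time multiplier on log-kill (default 0.7 at 6 h,
  1.0 at 24 h). This is deliberately phenomenological: it encodes only
  the qualitative observation that death continues to progress between
  6 h and 24 h, not any measured kinetics, and it is excluded from the
  package's quantitative checks;
- wells receive multiplicative lognormal noise (`well_cv`, default
  0.05, mean-one so the noiseless limit is unbiased) — absorbance
  noise is scale-proportional and survival must stay non-negative —
  plus a shared lognormal control-normalization factor per plate
  (`control_cv`, default 0.02).

All randomness flows from the single seed in `noise_spec()`; the
caller's RNG stream is saved and restored, so generation has no hidden
global state.

Defaults reproduce the emulated design: setpoints 42.5/44/46/50 °C,
durations 3–60 min (3, 5, 10, 15, 20, 30, 45, 60), n = 6 wells. The
bundled registry `cell_line_params()` carries published coefficients
for two murine pancreatic cancer lines (KPC, Pan02) and a fibroblast
line (STO), used as generating truths.

What the generator does **not** emulate: MTT chemistry and its
saturation artefacts, thermotolerance induction under repeated or slow
heating, cell-cycle-dependent sensitivity, edge effects across a
plate, and any real 6 h → 24 h death kinetics. A passing test
therefore demonstrates that the estimation chain is correct *under the
model's own assumptions and this noise structure* — it cannot certify
behaviour on real assay pathologies the generator does not contain.

`make_transient_profile()` builds water-bath transients as a linear
ramp to the setpoint, an exact hold, and an exponential cool-down with
time constant one third of the stated cool-down duration (so the
profile is within 5 % of baseline by its end). The true functional
forms of laboratory ramp and cool-down curves are generally not
published; the linear/exponential choice is a stand-in with the right
qualitative shape, and the two-step heat-up sometimes used in practice
(a hotter transfer bath) is collapsed into the single stated ramp time,
since only the delivered $T(t)$ matters to the models.
`generate_ablation_periphery_profile()` produces the
saturating-exponential heating seen at the edge of an ablation zone,
for non-isothermal validation.

## Numerical choices

- Kelvin everywhere internally; Celsius only at file/CLI boundaries
  (`K = C + 273.15`, exact). Gas constant 8.314 J K⁻¹ mol⁻¹ by
  default, configurable (some published fits used 8.31; exact
  reproduction of such arithmetic needs the same constant).
- Sampling grids always include the exact endpoint: when a duration is
  not a multiple of the step, the endpoint is appended, so integrals
  cover the full exposure.
- Trapezoidal integration throughout; the delayed integrator inserts
  the delay-completion time as a node so the constant-temperature
  reduction is exact at every sample.
- Ties and degeneracies: all-equal survival raises a degenerate-fit
  error; rank-deficient two-state designs raise one too; a dataset
  whose shoulders appear at fewer than two setpoints degrades the
  pipeline's delay model to null (delayed arm = free-intercept
  Arrhenius) instead of failing the run.
- Report JSON is serialized with stable key order and full precision:
  identical inputs give byte-identical files.

## Problem sizes

The package's own checks run the full pipeline on the emulated design
(3 cell lines × 4 setpoints × 8 durations × 6 wells). Stochastic
properties (coefficient recovery under noise; the delayed-vs-simple
RMSE ordering) use 100 seeded replicates of the single-line design,
which the pipeline processes in well under a minute; the
law-of-large-numbers check uses one condition at 500 wells. These sizes
were chosen as the smallest at which the medians and orderings of
interest are stable across seeds.

## Known limitations

- The shoulder delay is estimated from the free-intercept line, so its
  variance is dominated by the coolest setpoint, where few exposures
  outlast the shoulder; with the standard design grid, the 42.5 °C
  delay rests on two to three informative durations.
- The delay-accumulator extension for time-varying profiles is a
  modelling choice; published work rarely states how the delayed model
  was applied to non-isothermal histories, and alternatives (e.g.
  piecewise-isothermal approximation) would differ during fast
  transients.
- The two-state model extrapolates poorly outside its fitted
  temperature range (its logit surface has no kinetic zero at body
  temperature), and its non-isothermal evaluation via time-averaged
  temperature is a convention.
- R_CEM estimation from rate-derived isoeffect times is one defensible
  reading of a procedure that is usually left unspecified; with pure
  Arrhenius kinetics it agrees with the closed-form per-degree ratio to
  within a few percent over the 44–50 °C range.
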