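# thermodose

Thermal-injury kinetics and dosimetry for in vitro hyperthermia data.

Researchers developing thermal therapies (ablation, mild hyperthermia)
need cell-line-specific models that map an arbitrary time–temperature
history to expected cell survival. The standard experiment heats
monolayer cultures in 96-well plates in temperature-controlled water
baths (42.5–50 °C, 3–60 min, n = 6 wells per condition) and reads
viability by MTT assay normalized to 37 °C controls. `thermodose`
provides every stage of the analysis of such data:

- **Forward models** on arbitrary temperature profiles:
  - the Arrhenius damage integral
    Ω(t) = ∫₀ᵗ A·exp(−Eₐ/RT(τ)) dτ, with survival e^(−Ω) and injury
    probability 100(1 − e^(−Ω));
  - the time-delayed Arrhenius model, which adds a shoulder latency
    t_d(T) = b − mT before injury begins (with a delay-accumulator
    rule for non-isothermal profiles that reduces exactly to the
    piecewise definition at constant temperature);
  - the two-state logistic model,
    C(τ,T) = logistic(γT − β − ατ);
  - the CEM43 thermal isoeffective dose,
    t₄₃ = Σ Δtᵢ·R^(43−Tᵢ), R = 0.5 above 43 °C and 0.25 at or below.
- **Inverse procedures**: per-temperature decay rates (through-origin
  or free-intercept with shoulder detection), the ln k vs 1/T
  Arrhenius regression for Eₐ and ln A, the delay line for b and m,
  bilinear least squares for (α, β, γ), R_CEM estimation from
  isoeffect times, and pooled RMSE model comparison.
- **A synthetic experiment generator** reproducing the plate design and
  its noise structure (per-plate setpoint jitter, lognormal well noise,
  shared control-normalization error), plus water-bath transient and
  ablation-periphery profile builders.
- **A pipeline** (`run_analysis()`) that fits all three models per cell
  line and recovery time, compares them by RMSE, and serializes a
  deterministic JSON report (schema shipped under `inst/schema/`).

A registry of published coefficients for murine pancreatic cancer
(KPC, Pan02) and fibroblast (STO) cell lines ships with the package
(`cell_line_params()`).

## Worked example

Predict survival of KPC cells after 10 minutes at 50 °C, then recover
the kinetics from a simulated plate experiment:

```r
library(thermodose)

kpc  <- cell_line_params("KPC")
prof <- make_constant_profile(celsius_to_kelvin(50), 600, 1)

damage_integral_delayed(prof, kpc$arrhenius, kpc$delay)
#> damage_result: 601 samples, final omega = 4.17678, final survival = 1.535%
cem43(prof)
#> [1] 1280
```

So a 10-minute, 50 °C exposure accumulates Ω ≈ 4.18 — about 1.5 %
of cells survive — and is isoeffective with 1280 minutes at 43 °C
(each of the 10 minutes counts 0.5⁻⁷ = 128).

```r
ds  <- generate_viability_dataset(list(KPC = kpc),
                                  noise = noise_spec(seed = 7),
                                  recovery_scale = c("24" = 1))
rep <- run_analysis(ds)
rep
#> analysis_report: 1 cell line(s) [KPC], recovery 24 h
#> model comparison (pooled RMSE, percentage points):
#>  recovery_h             model  rmse_pct
#>          24         arrhenius 10.820294
#>          24 arrhenius_delayed  3.974326
#>          24         two_state 14.071340
```

The delayed model fits shoulder-bearing data far better than the
simple Arrhenius model (3.97 vs 10.82 RMSE percentage points here),
and the two-state surface trails both — the ordering such experiments
typically report. The fitted coefficient block
(`rep$fits[["24"]][["KPC"]]`) carries Eₐ, ln A, the delay line, the
two-state coefficients, R_CEM, and the per-temperature decay table.

A thin command-line front end over the same functions is installed at
`system.file("cli", "thermodose.R", package = "thermodose")` with verbs
`synth-profile`, `simulate`, `dose`, `predict` and `run-all`.

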