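# thermoramp

Activation thermodynamics of enzyme catalysis from a **single
temperature-gradient steady-state experiment**.

Classically, measuring an enzyme's Arrhenius activation energy needs a full
Michaelis–Menten experiment at each of several constant temperatures —
close to fifty cuvettes. `thermoramp` implements the gradient alternative:
one run in which a temperature-controlled cuvette changer ramps the
temperature slowly (1–2 K/min) across a substrate dilution series, so that
every short window of every progress curve reports a velocity at its own
temperature. Twelve cuvettes replace the whole temperature series.

The analysis chain:

1. parse the long-form instrument CSV (sample, time, temperature,
   absorbance) and convert to concentrations by Beer–Lambert,
   `[P] = (A - A₀)/(εl)`;
2. rolling ordinary-least-squares slopes (default window: 4 points) give
   velocities with window-mean temperatures and substrate concentrations;
3. velocities are binned by temperature and each bin is fit to
   `v = kcat·[E]₀·[S]/(KM + [S])` by Levenberg–Marquardt nonlinear least
   squares;
4. `ln(kcat)` is regressed on `1/T`, weighted by `1/SE(kcat)²`; the slope is
   `−Ea/R`, the intercept `ln A`;
5. transition-state theory (κ = 1) gives, at a reference temperature,
   `ΔG‡ = RT·ln(k_B T / (h·kcat))`, `ΔH‡ = Ea − RT`,
   `TΔS‡ = ΔH‡ − ΔG‡`, with errors propagated from the regression
   covariance.

An AICc module (`compare_global_vs_separate()`) tests whether a gradient run
and a classical stepwise run are described by one Arrhenius line, and a
seeded simulator (`simulate_ramp()`, `simulate_stepwise()`) integrates
Michaelis–Menten depletion under an Arrhenius-dependent `kcat` with
fixed-step RK4 to produce instrument-format datasets with known ground
truth.

## Worked example

```r
library(thermoramp)

sim <- simulate_ramp(simulation_spec(noise_sd = 0.01, rng_seed = 1))
res <- analyze_ramp(sim$readings, sim$design, n_bins = 10)
res$activation
#> Activation parameters at T_ref = 287.65 K (kappa = 1):
#>   Ea   =  15.23 +/- 0.51 kcal/mol
#>   dG++ =  13.81 +/- 0.01 kcal/mol
#>   dH++ =  14.66 +/- 0.51 kcal/mol
#>   TdS++=   0.84 +/- 0.51 kcal/mol
#>   A    = 7.11e+13 s^-1, kcat(T_ref) = 191.6 s^-1
```

The simulation's generating values are Ea = 15.325 kcal/mol and
kcat(287.5 K) ≈ 188 s⁻¹: from one noisy 21-kelvin ramp over twelve cuvettes
the pipeline recovers the activation energy within ~1% and the barrier free
energy to 0.01 kcal/mol. `res$mm_table` holds the per-bin kcat and KM with
standard errors; `write_analysis(res, dir)` exports the table as CSV and the
thermodynamics as JSON.

Published regression lines can be evaluated directly:

```r
activation_parameters(arrhenius_line(-7712, 32.06), T_ref = 287.5)
#>   Ea   =  15.33, dG++ = 13.82, dH++ = 14.75, TdS++ = 0.94 (kcal/mol)
eyring_kcat(dH = 16.3, TdS = -0.5, T_quoted = 294.5, temperature = 303.15)
#> [1] 4.769742
```

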