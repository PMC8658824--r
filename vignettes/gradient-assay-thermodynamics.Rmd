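---
title: "Activation thermodynamics from a single temperature-gradient assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation thermodynamics from a single temperature-gradient assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoramp)
```

## The problem and the model

Determining how an enzyme's catalysis depends on temperature classically
requires a full Michaelis–Menten experiment at each of several constant
temperatures — six or more substrate concentrations, replicated, at four or
more temperatures. The activation parameters are then read off an Arrhenius
plot. `thermoramp` implements a much cheaper design: a *single* run in which a
temperature-controlled cuvette changer ramps the temperature slowly (1–2
K/min) while cycling through a substrate dilution series. Each short time
window of each progress curve then reports a velocity at a slightly different
temperature, and one run yields the whole Arrhenius relation.

Two laws underpin the analysis. Steady-state velocities follow
Michaelis–Menten kinetics,

$$ v = \frac{V_{max}[S]}{K_M + [S]} = \frac{k_{cat} [E]_0 [S]}{K_M + [S]}, $$

and the turnover number follows the Arrhenius law,

$$ k_{cat}(T) = A \, e^{-E_a / RT}, $$

so $\ln k_{cat}$ is linear in $1/T$ with slope $-E_a/R$ and intercept
$\ln A$. Transition-state theory (Eyring, transmission coefficient
$\kappa = 1$) converts a rate at a reference temperature into a barrier free
energy,

$$ \Delta G^\ddagger = R T \ln\!\frac{k_B T}{h \, k_{cat}(T)}, \qquad
   \Delta H^\ddagger = E_a - RT, \qquad
   T\Delta S^\ddagger = \Delta H^\ddagger - \Delta G^\ddagger. $$

$R$ is used in kcal units ($1.9872 \times 10^{-3}$ kcal/mol/K) so all
energies are reported in kcal/mol.

## The pipeline

`analyze_ramp()` chains the stages; each is exported on its own.

1. **`parse_instrument_csv()`** reads the long-form CSV (one row per
   reading: sample, time, temperature, absorbance), normalises time to
   seconds and temperature to kelvin. Temperatures below 150 K are taken as
   Celsius — no biological assay runs below 150 K — unless overridden.
2. **`to_concentrations()`** applies Beer–Lambert,
   $[P] = (A - A_0)/(\varepsilon \ell)$, and $[S] = S_0 - [P]$. The baseline
   $A_0$ defaults to each cuvette's first reading, so product starts at
   zero. Readings outside $[0, S_0]$ beyond a tolerance are flagged, never
   silently dropped: exclusion is the analyst's explicit decision via
   temperature cut-offs.
3. **`rolling_velocity()`** slides a window (default 4 points, stride 1)
   along each trace and takes the OLS slope of product versus time as the
   velocity, with the window-mean temperature and window-mean substrate
   concentration attached. The mean (rather than midpoint) is used for both:
   the slope is a window-average rate, and the mean is more robust to uneven
   sampling. The first window − 1 positions yield no point, so the extreme
   ends of the gradient are not represented.
4. **`bin_by_temperature()`** partitions velocities into equal-width
   temperature bins (user-selected count; equal width keeps the within-bin
   temperature spread uniform across the gradient). `fit_michaelis_menten()`
   then fits ($k_{cat}$, $K_M$) per bin by unweighted Levenberg–Marquardt
   nonlinear least squares (via `minpack.lm`), with standard errors from the
   linearised covariance. Bins are fit independently — no parameter sharing
   across temperatures. Defaults: start values $k_{cat,0} = \max(v)/[E]_0$,
   $K_{M,0} = \mathrm{median}(S)$; bins with fewer than 4 points are skipped;
   fits with non-positive parameters are flagged invalid and excluded rather
   than clamped.
5. **`apply_temperature_cutoffs()`** and **`weighted_arrhenius_fit()`**: the
   surviving ($T$, $k_{cat}$, $SE$) triples are regressed as $\ln k_{cat}$
   on $1/T$ with weights $1/SE(k_{cat})^2$. Weighting by the *untransformed*
   kcat error is the published convention for this method and is the
   default; `weights = "delta-log"` gives the delta-method-consistent
   $(k_{cat}/SE)^2$ for users who prefer it. The solve is a weighted QR with
   a tight rank tolerance, so a bin whose weight dominates by many orders of
   magnitude still yields the correct limiting line.
6. **`activation_parameters()`** converts slope and intercept into $E_a$,
   $A$, $\Delta G^\ddagger$, $\Delta H^\ddagger$, $T\Delta S^\ddagger$ at a
   reference temperature $T_{ref}$ (default: mean of the fitted bin
   temperatures, i.e. mid-range of the experiment, since the quantity the
   experiment pins down best is the rate at mid-range). Errors are
   propagated from the coefficient covariance by the delta method; the
   $\Delta G^\ddagger$ error uses the standard error of the fitted mean
   $\ln k_{cat}$ at $1/T_{ref}$, and the slope contribution to
   $T\Delta S^\ddagger$ cancels exactly, leaving
   $R\,T_{ref}\,SE(\mathrm{intercept})$. Confidence intervals use the $t$
   distribution with $n - 2$ degrees of freedom.

```{r example}
sim <- simulate_ramp(simulation_spec(noise_sd = 0.01, rng_seed = 1))
res <- suppressWarnings(suppressMessages(
  analyze_ramp(sim$readings, sim$design, n_bins = 10)))
res$activation
```

## Model comparison

`compare_global_vs_separate()` asks whether two or more Arrhenius datasets
(say, a gradient run and a classical stepwise run) are statistically one
line. It fits a pooled "global" line ($k = 3$: two coefficients plus the
residual variance) and a "separate" model with one line per dataset
($k = 2d + 1$), computes AICc on the pooled weighted residual sum of squares
on the $\ln k_{cat}$ scale — the same scale and weights as the Arrhenius fit
— and reports Akaike weights. Counting the residual variance as a parameter
matches the convention of the common graphing packages, making the values
comparable with published ones. Each dataset's own line is also reported
with an AICc computed on its own $n$; those values are informative for a
three-way table but are not likelihood-comparable to the pooled models
(different data), so the evidence weights are taken over the global and
separate models only.

## The ramp simulator

`simulate_ramp()` provides ground-truth datasets for validation: it
integrates $dS/dt = -k_{cat}(T(t))\,[E]_0\,S/(K_M + S)$ with
$T(t) = T_{start} + rt$ per cuvette using classical fixed-step 4th-order
Runge–Kutta (substeps capped at 1 s, landing exactly on sample times; fixed
stepping keeps runs bit-identical across platforms), converts product to
absorbance by Beer–Lambert and adds seeded Gaussian noise on the absorbance
— instrument noise lives on the detector, not on concentration. A step that
would consume more than 20% of the substrate raises a stability error
instead of integrating on. `simulate_stepwise()` produces the matching
constant-temperature design.

The defaults are a realistic psychrotolerant esterase experiment: $E_a$ =
15.325 kcal/mol, $\ln A$ = 32.06 (so $k_{cat} \approx 190\,s^{-1}$
mid-range), $K_M$ = 200 µM (temperature-constant by default; an optional
van 't Hoff dependence is available for robustness studies), 1 nM enzyme, a
1:1 dilution series from 1 mM in two replicates (12 cuvettes — six
concentrations twice), a 2 K/min ramp over 277.15–298.15 K sampled once per
cuvette per kelvin, $\varepsilon = 17800$ M$^{-1}$cm$^{-1}$, and 0.01 AU
additive noise (1% of a 1 AU absorbance scale). The simulator does *not*
model enzyme inactivation or unfolding, interfacial activation, buffer pKa
drift, or multiplicative/drifting instrument error — so parameter-recovery
results bound what the method achieves on a well-behaved enzyme inside its
stable temperature range, not on a marginal system.

## Numerical and design notes

- Window temperature/substrate are arithmetic means over the window; window
  stride is 1.
- Binning is equal-width in temperature; empty bins are dropped with a
  notice; the top edge is inclusive.
- At zero noise a perfectly linear system would make every Arrhenius weight
  infinite; weights stay finite because the within-bin temperature spread
  leaves systematic residuals, which is also why the method's accuracy
  improves with more bins until counts per bin become limiting.
- Validation problem sizes in the test suite: the end-to-end recovery runs
  the default 12-cuvette, 21 K ramp — about 260 readings per replicate —
  once noise-free (recovering $E_a$ within 2%) and over 200 seeded noisy
  replicates (median error within 5% at 0.01 AU noise). Michaelis–Menten
  fits are cross-checked against an iteratively refined exhaustive grid
  search, rolling slopes against a two-pass textbook OLS formula, and the
  constant-temperature integrator against the implicit integrated
  Michaelis–Menten relation $K_M \ln(S_0/S) + (S_0 - S) = k_{cat}[E]_0 t$
  solved by root bracketing.
- Known limitations: the Arrhenius line is assumed straight (no heat
  capacity of activation $\Delta C_p^\ddagger$, no equilibrium model of
  activity loss); velocities are treated as exchangeable within a bin even
  though consecutive windows share points and are therefore correlated —
  the per-bin standard errors absorb this only approximately.
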