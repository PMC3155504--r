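---
title: "Modelling relapsing-remitting autoimmunity with the Teff-Treg loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling relapsing-remitting autoimmunity with the Teff-Treg loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relapsim)
```

## The model

relapsim simulates a population-level model of the adaptive immune system
built around the cross-regulation of activated effector T cells (Teff, `E`)
and activated regulatory T cells (Treg, `R`). The loop is a prey-predator
negative feedback: Treg inhibit Teff proliferation and raise Teff clearance,
while Teff stimulate Treg expansion. Six state variables evolve in continuous
time (days): resting Teff and Treg (`E_r`, `R_r`), activated Teff and Treg
(`E`, `R`) and two tissue-damage compartments (`l` reversible, `L`
irreversible).

The governing equations, with all rates per day:

* `dE_r/dt = I_E - (delta + beta) E_r + eta E`
* `dR_r/dt = I_R - (delta + beta) R_r + eta R`
* `dE/dt = delta E_r + alpha_E E hd(R) - gamma_E E (1 + hu(R)) - eta E`
* `dR/dt = delta R_r + alpha_R R hu(E) - gamma_R R - eta R`
* `dl/dt = d1 (E/a)^2 - (r + d2) l`
* `dL/dt = d2 l`

where `hu(x) = x^h / (k^h + x^h)` and `hd = 1 - hu` are Hill responses
(`hill_up()`, `hill_down()`). Resting cells are produced by stochastic
impulse trains `I_E`, `I_R` (thymic export and sporadic activation events),
become activated at rate `delta` = 1/day, or die/anergise at `beta`.
Activated cells return to the resting (memory) pool at `eta`. Treg presence
raises the Teff loss rate from its 5-day-expectancy baseline `gamma_E` up to
twice that value through `1 + hu(R, k_R, h)`; Treg clearance `gamma_R` is
constant. Damage is driven one-way by the second-order term `(E/a)^2` --
the T cells do not sense the damage. Two structurally plausible
transcriptions of the damage recovery exist in the literature this model
descends from; this package follows the parameter-table labels (recovery at
`r`, irreversible conversion at `d2`), recorded in `model_form()`.

Reference parameters (see `model_parameters()`, `damage_parameters()`):
`delta` = 1, `beta` = `eta` = 0.01, `gamma_E` = `gamma_R` = 0.2/day,
`k_E` = 1000 and `k_R` = 200 cells, `h` = 5, `d1` = 1, `d2` = 0.02,
`r` = 0.1/day, `a` = 22,800 cells. Runs start from 0 resting cells, 1,000
activated Teff, 200 activated Treg and no damage, and last 1,825 days
(5 years) on a fixed grid of `dt` = 0.05 days.

Two presets differ only in the Treg arm of the loop:

```{r presets}
healthy_config()$params$alpha_R     # homeostasis
autoimmune_config()$params$alpha_R  # weakened cross-regulation
```

## Stochastic forcing and its calibration

The forcing is deliberately not Gaussian noise: thymic escape of
self-reactive clones is a sparse sequence of discrete events. Each resting
pool receives a train of 100 impulses per year at independent uniform random
times (`generate_pulse_train()`); a train is realised with exactly the
nominal count per span (a Poisson-count option exists for robustness
studies). An impulse is applied as a state jump at the first grid point at
or after its drawn time. The Teff and Treg trains use independent streams
derived from one master seed, so every run is reproducible bit for bit.

The impulse *amplitude* (cells per impulse) is not fixed by the published
parameter table, so it is a convention of this package, chosen once on three
grounds and then frozen at **400 resting Teff / 40 resting Treg cells per
impulse**:

1. *Smallness.* The forcing must be a small perturbation of the loop. Teff
   kicks comparable to `k_E` = 1000 cells hold the time-averaged Treg
   stimulus `hu(E)` above the Treg loss rate `gamma_R + eta`, and the
   healthy Treg pool then grows without bound -- a hypersensitive-Treg
   artefact, not homeostasis.
2. *Output composition.* Treg make up roughly 10% of peripheral CD4 T-cell
   output, hence the 10:1 amplitude ratio.
3. *Regime dichotomy.* At this scale the healthy preset fluctuates at a few
   thousand activated Teff with negligible damage, while the autoimmune
   preset produces threshold-crossing Teff bursts in over 80% of 5-year
   realisations -- the qualitative dichotomy the model is known for.

The reduced deterministic model replaces the trains by their expected values
`Lambda = rate x amplitude / 365` (`expected_inflow()`): 109.6 and 11.0
cells/day at the defaults, so the full and reduced models describe the same
average forcing.

## Regimes, relapses and damage

```{r regimes}
h <- simulate_model(healthy_config(master_seed = 1, record_stride = 20L))
a <- simulate_model(autoimmune_config(master_seed = 1, record_stride = 20L))
c(healthy_peak_E = h$peak_E, autoimmune_peak_E = a$peak_E)
detect_relapses(a)[, c("start", "peak_E")]
```

A relapse is operationalised as a maximal interval with `E` at or above a
threshold; the default threshold is the damage parameter `a` = 22,800 cells,
the only population-scale constant the model provides. In the healthy regime
the loop damps every excursion; weakening `alpha_R` to 0.25 lets Teff bursts
escape transiently before the slow Treg response recaptures them, which is
why the process is relapsing rather than chronic-progressive. Relapse timing
is driven by the random forcing and differs across seeds with identical
parameters (clinical heterogeneity).

## The reduced model and the phase plane

`find_equilibrium()` solves the two-variable reduction by damped Newton
iteration (numerical Jacobian by central differences, relative step 1e-6),
with a long-horizon integration restart if Newton stalls, to a residual
below 1e-8 cells/day. Across `alpha_R` in [0.25, 2] the equilibrium is a
stable spiral whose Teff coordinate rises as the Treg arm weakens while the
Treg coordinate barely moves:

```{r equilibria}
infl <- expected_inflow(pulse_spec())
rbind(healthy = unlist(find_equilibrium(model_parameters(alpha_R = 1),
                                        infl)[c("E_star", "R_star")]),
      autoimmune = unlist(find_equilibrium(model_parameters(alpha_R = 0.25),
                                           infl)[c("E_star", "R_star")]))
```

Trajectories spiral clockwise in the (R, E) plane with successively smaller
Teff maxima; the spirals elongate along the Teff axis as `alpha_R`
decreases. For forcings stronger than the default the Treg balance can fail
to close at large `alpha_R` (the hypersensitive regime); `find_equilibrium()`
then reports non-convergence rather than inventing a root. Phase-plane
sectors are the sign quadrants of the two growth rates (`classify_sector()`):
I both growing, II Teff shrinking/Treg growing, III both shrinking, IV Teff
growing/Treg shrinking. States on a nullcline (including the equilibrium)
are deliberately not assigned. The printed legend this convention descends
from describes two sectors identically; the quadrant rule used here treats
that as the evident typo and is applied uniformly.

## Perturbation experiments

`therapy_experiment()` mimics cell-based immunotherapy: a single impulse
added to one pool at a fixed day or on first entry into a phase-plane
sector, with both arms sharing the identical pulse-train realisation
(common random numbers), so any difference is attributable to the dose. The
same Treg dose barely moves the healthy regime yet is followed by
order-of-magnitude larger Teff rebounds and visible damage under the
autoimmune regime: suppressing Teff deepens the subsequent Treg trough, and
with `alpha_R` = 0.25 the recapture is slow. Timing matters: small doses
from sector I land on nearby spirals, large ones overshoot the Treg
nullcline onto wider loops.

## Sensitivity sweep

`sensitivity_sweep()` scans `alpha_E` in [1, 2] and `alpha_R` in [0.25, 1]
(reference grid 21 x 16 at step 0.05, 200 seeds per cell, retaining the
maximum activated-Teff value per run). Per-seed peaks are *not* monotone in
`alpha_E` -- the interaction between loop dynamics and impulse timing can
make a weaker Teff arm produce a worse relapse for a given seed -- so the
suite asserts only distribution-level trends: median peaks grow as
`alpha_R` falls. `convergence_check()` implements the seed-convergence rule
(trailing-window spread below 1e-5, applied to the running statistic
normalised by its current value because peaks span orders of magnitude;
window 50 seeds). Tests and the acceptance script use a 4 x 4 x 20 sub-grid;
the full grid is a few minutes of compute.

## Clinical comparison pipeline

Monthly contrast-enhancing-lesion (CEL) counts are the clinical counterpart
of the model's reversible damage. The pipeline (`monthly_series()`,
`evolution_series()`, `best_sliding_correlation()`,
`correlation_distribution()`): discretise `l` to one instantaneous sample
per month (month = 365/12 days, so 120 months = 10 years; a monthly-mean
mode exists behind a flag), first-difference both series so that zero means
no change and positive means exacerbation, then slide the 48-month patient
series along each 120-month simulated series and keep the best Pearson
correlation (73 alignments; ties go to the earliest offset; zero-variance
simulated windows are skipped and counted, a zero-variance patient series is
a hard error). One bank of simulations is shared across all patients of a
cohort. The distribution summary reports the median and the modal 0.05-wide
histogram bin, since "centre" admits either reading.

Because the real 9-patient dataset cannot ship with the package, validation
is closed-loop: `plant_signal()` returns a synthetic patient together with
its generating trajectory, and the pipeline must (a) recover the generating
trajectory at offset 0 with best-r near 1 in the zero-noise variant, and
(b) rank the generating trajectory above an independent one in the large
majority of paired draws. A selection-maximum null (two independent white
noise series) centres near 0.34, well below the clinically reported centres,
so best-r values in the 0.5-0.8 range are not an artefact of taking a
maximum over 73 alignments.

## Synthetic cohorts

`synthesize_cohort()` emulates the structure of a monthly-MRI natural
history study: 9 patients, 48 months, one autoimmune simulation per patient
(per-patient `alpha_R` and seed), CEL counts drawn Poisson with mean
`scale x l` (negative-binomial and noiseless options exist). The default
`scale` = 10 CELs per damage unit makes the typical patient average 1-3
lesions/month, the clinically usual order for active disease -- a
convention, not a claim of the source model. A month is flagged as a relapse
month when the underlying activated-Teff population crossed the relapse
threshold within it.

What the generator does *not* emulate: scanner and reader noise, lesion
spatial structure, EDSS dynamics (carried through I/O only), treatment
effects, and the long negative tail of patient heterogeneity. Passing tests
on synthetic cohorts therefore demonstrate pipeline correctness and the
model's internal consistency, not clinical validity; the damage process is
far burstier than real CEL series, with occasional extremely active
synthetic patients.

## Numerical choices

* **Integrator.** Explicit Euler at `dt` = 0.05 days is the reference
  scheme because impulses are state jumps on that grid and the model's
  published behaviour was produced on it. Any component pushed below zero by
  a step is clipped to exactly 0 and the event counted; non-finite states
  abort with the step index.
* **Grid adequacy.** Halving `dt` moves no sample of the deterministic
  constant-inflow run by more than 0.05 log10 units (measured worst case
  ~0.03, concentrated in the resting pools, whose ~1/day rates are the
  fastest in the system). Under impulse forcing, pointwise agreement decays
  with horizon (phase drift of a weakly damped oscillation), so the
  trajectory-level refinement check runs on a 30-day forced window (within
  0.15 log10) while long-horizon claims are made at the distribution level
  (peaks, relapse fractions). An adaptive high-accuracy solver (deSolve) is
  used as an independent reference in the test suite only.
* **Hill evaluation.** `x^h` overflows double precision during Teff bursts;
  both Hill forms are evaluated as `1 / (1 + (k/x)^h)` style ratios that
  saturate gracefully at either extreme.
* **Seeds.** All child streams (trains, sweep cells, banks, patients) derive
  from one master seed via an order-insensitive integer mix
  (`derive_seed()`), so sub-experiments are reproducible in isolation.
* **Huge Poisson means.** Damage bursts can imply Poisson means beyond
  integer range; above 1e8 the generator switches to a clamped normal
  approximation.

## Problem sizes used by tests and the acceptance script

Regime checks use 20 five-year runs per preset; the sweep runs a 4 x 4 grid
with 20 seeds (full scale: 21 x 16 x 200); the correlation pipeline uses a
200-simulation bank (reference scale: 2,000) and 50 paired closed-loop
draws. These sizes give stable qualitative results while keeping the whole
suite in the minutes range on one core.

## Known limitations

* No spatial or CNS-compartment structure, no innate immunity, no TCR
  repertoire diversity; the populations are antigen-specific pools.
* Parameters are literature-anchored conventions, not fits to patient data;
  no fitting code is provided by design.
* The impulse amplitude and the CEL scale are package conventions (above);
  conclusions that depend on them are flagged as such in the documentation.
* The perturbation experiments reproduce the direction and the
  orders-of-magnitude asymmetry of regime sensitivity, but absolute rebound
  sizes depend strongly on the unpublished forcing amplitude; with the
  calibrated small forcing the autoimmune rebound after a maximal Treg dose
  reaches ~1e5-1e7 cells, not arbitrarily large values.
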