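---
title: "Growth kinetics from batch respirograms: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth kinetics from batch respirograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respirokin)
```

## The measurement

Respirometry characterizes the aerobic metabolism of a heterotrophic
culture by watching dissolved oxygen (DO) in a stirred, aerated batch
reactor. A small pulse of substrate drives DO down as the cells oxidize it;
once the substrate is exhausted, aeration pulls DO back to its pre-pulse
baseline. One experiment doses a substrate at several strengths in
sequence — here three pulses at 35, 70 and 100% of a stock, each 10 mL
into an initial 1.010 L, the next pulse added only after DO has
restabilized (the sign that the previous dose is fully consumed). Substrate
is accounted in oxygen-equivalent units (COD, mg O~2~ L^-1^), biomass as
total suspended solids (TSS, mg L^-1^) via a linear OD~600~ calibration.

From each drop-and-recovery event the pipeline extracts:

* the **dynamic oxygen uptake rate** `R_S(t)` (mg O~2~ L^-1^ h^-1^),
* the **oxygen consumption** `OC = ∫ R_S dt` over the event,
* yield coefficients from the COD balance,
  `Y_O2 = (S - OC)/S` and `Y_TSS = Y_O2 / f_cv` with
  `f_cv = 1.48` mg COD per mg TSS, and
* the **empirical specific growth rate**
  `mu = Y_TSS · R_S / ((1 - Y_O2) · X_T)`.

The (S, mu) points are then fitted by four unstructured growth laws —
Monod `mu_m S/(K_S+S)`, Moser `mu_m S^n/(K_S+S^n)` with `n = 2`, Contois
`mu_m S/(K_C X_T + S)` and Tessier `mu_m (1 - e^{-S/K_S})` — by minimizing
the least-squared error `LSE = Σ (mu_theoretical - mu_empirical)^2`; the
model with the lowest LSE is selected per substrate. Reported rate curves
are the substrate degradation rate `r_su = mu · X_T / Y_TSS` (a magnitude;
the substrate balance carries the minus sign) and the cell growth rate
`r_x = mu · X_T`.

## Two readings of R_S

A derivative of DO alone (`R_S = -dDO/dt`, floored at zero) is the
textbook definition, but over a full drop-and-recovery cycle it integrates
to roughly zero, because reaeration resupplies what respiration consumed.
The package therefore offers two modes:

* **mass-balance** (default): `R_S = kLa · (DO_baseline - DO) - dDO/dt`,
  the exogenous uptake relative to the pre-addition steady state. Its
  integral is a true oxygen consumption, which makes the COD balance in
  `Y_O2` meaningful.
* **derivative**: the literal reading, retained for comparison, with the
  OC integral terminated at the DO minimum (beyond it the raw derivative
  measures reaeration, not uptake). On any aerated event its OC is a lower
  bound on the mass-balance OC.

Mass-balance mode needs the volumetric oxygen-transfer coefficient `kLa`.
`estimate_kla()` fits the exponential reaeration law
`DO(t) = B - (B - DO_0) e^{-kLa t}` to a recovery tail; this is accurate on
a clean reaeration test but biased low when residual substrate oxidation
overlaps the tail, which is common in sequential-addition runs. We
therefore treat `kLa` as a reactor constant to be measured once by a
dedicated reaeration experiment and supplied in `reactor_constants()`;
automatic estimation remains available and is logged when used.

## Extracting points for fitting

Differentiating a noisy probe signal is the numerically fragile step.
Defaults, chosen for probe noise of a few hundredths of a mg O~2~ L^-1^ at
sampling intervals of ~20 s: a Savitzky–Golay filter (order 2, 21 samples)
for the DO signal, centered finite differences with one-sided end
stencils, R_S floored at zero, baseline averaged over six samples ending
half a smoothing window before the pulse (samples closer to the pulse
already feel the drop through the filter support).

Two further choices matter:

* **Peak statistic.** A single `mu` per event can be read at the R_S peak,
  which occurs just after the pulse while S is still at its dosed value.
  The raw maximum of a differentiated noisy series is badly upward-biased,
  so `rs_peak` is taken from the R_S series after an 11-sample moving
  average.
* **Resolved points (default for fitting).** The event start is also where
  smoothing is least trustworthy: the filter spans the pulse discontinuity
  and attenuates a sharp peak, which on fast events biases the peak-based
  `mu` low by ~10%. The resolved mode sidesteps the edge entirely: the
  substrate remaining at interior time t is reconstructed from the
  cumulative-uptake fraction, `S(t) = S_dosed (1 - U(t)/OC)`, and paired
  with the locally smoothed R_S(t), yielding several interior (S, mu)
  points per event. These are unbiased to within the noise and also widen
  the S coverage of the fit. The per-event peak summary is still reported
  in the events table.

## Fitting and selection

The LSE objective is minimized over positive `(mu_m, k)` in log-parameter
space with bounded quasi-Newton searches started from a 5×5 log-spaced
grid over `mu_m ∈ [10^-3, 10]` h^-1^ and `k ∈ [10^-4, 10^3]`
(objective tolerance 10^-12), so the result can never be worse than the
best grid start. The Moser exponent is fixed at `n = 2`, not estimated.
Weights default to one; the tests cross-check the optimizer against an
independent 200×200 grid-search oracle. Exact LSE ties are broken toward
the simpler model, in the order Monod, Tessier, Moser, Contois. With
replicate traces, models are fitted per replicate and parameters reported
as mean ± SD, alongside a pooled fit.

## What the simulator emulates

`simulate_respirogram()` integrates the batch balances

    dX/dt  = mu(S, X) · X
    dS/dt  = -mu · X / Y_TSS
    dDO/dt = kLa (DO_sat - DO) - (1 - f_cv Y_TSS) mu X / Y_TSS - b X

with a fixed-step classical Runge–Kutta scheme at one tenth of the
sampling interval (halving the step moves the final state by < 10^-6^
relative). Pulses add their dose over the post-addition volume and dilute
X and DO by the volume ratio, the same bookkeeping `in_reactor_substrate()`
uses, so S has a single source of truth. The simulated operator triggers
the next pulse from the true DO (substrate below 2% of the dose and DO
within 0.02 mg L^-1^ of the endogenous baseline for six samples, then a
0.15 h plateau, mirroring an operator waiting for a visibly flat trace);
probe noise — i.i.d. Gaussian, SD 0.05 mg O~2~ L^-1^ — is added only to
the sampled observation, so pulse timing and ground truth are
deterministic given the scenario, and the seed affects nothing but the
noise.

Default reactor conditions: 20 °C, `DO_sat = 9.08` mg O~2~ L^-1^ (clean
fresh water at 20 °C; the experiment never reports the conversion
constant, and every concentration-scale quantity simply scales with it),
`kLa = 10` h^-1^ (typical of a 1 L stirred tank aerated at ~1 vvm),
endogenous respiration `b = 0.002` mg O~2~ mg TSS^-1^ h^-1^ folded into
the baseline, sampling every 0.005 h. The four built-in substrate
scenarios carry the reference stocks (1800, 3400, 1100, 2400 mg O~2~
L^-1^ as COD), the 35/70/100% pulse series, starting biomass at the
measured pre-addition levels, and true kinetics of the magnitudes reported
for a cold-adapted marine heterotroph (Monod for sodium acetate and tween
80, Contois for glucose and peptone).

The **true biomass yield is 0.47 mg TSS per mg COD** (oxygen yield ≈ 0.7,
typical of aerobic heterotrophs). Published yield tables for this kind of
assay sometimes imply `Y_O2 ≈ 0.99`, i.e. an oxygen footprint of ~1% of
the dosed COD; such a culture would leave no measurable respirogram above
probe noise, and we do not attempt to emulate it. Printed parameter sets
of that provenance are used in this package only as desk-scale worked
examples, consumed as printed.

Deliberately not modeled: probe response time, pH and temperature
dynamics, spatial gradients, multi-substrate diauxie, and the trace
nutrient supplement (0.1 mL corn steep liquor, ~0.01% of volume and
unknown COD) used in such assays — its omission is the main known gap
between simulated and real traces. Passing the recovery tests therefore
demonstrates correctness of the estimators under idealized probe physics,
not robustness to every artifact of a real sensor.

## Problem sizes and reproducibility

The validation suite runs each built-in scenario (three pulses, ~500–700
samples per trace) over dozens of seeds: parameter recovery uses 100
seeded replicates per model at 5% multiplicative noise, model-selection
accuracy 100 seeds of a 3-level × 3-replicate design, and the end-to-end
check 50 seeds of all four substrates — sizes at which the medians are
stable while a laptop run stays comfortable. Every stochastic entry point
takes an explicit seed and restores the caller's RNG state; rerunning a
pipeline configuration with the same seed reproduces the JSON report byte
for byte.

## Known limitations

* Peak-mode `mu` is biased low on events whose consumption time is
  comparable to the smoothing support; prefer resolved mode (the default)
  or sample faster.
* Tail-based `kLa` estimation underestimates when oxidation overlaps the
  recovery; supply an independently measured value where possible.
* Monod, Tessier and Moser are near-indistinguishable from three
  substrate levels at realistic noise unless biomass varies enough for
  Contois-type dependence to show; treat single-dataset model selection
  accordingly (the selection-accuracy test quantifies this on a
  well-separated regime).
* The COD balance assumes complete consumption between pulses; partially
  consumed pulses violate `in_reactor_substrate()`'s bookkeeping.
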