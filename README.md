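# respirokin

Growth kinetics of heterotrophic bacteria from batch respirometry.

A respirometric assay watches dissolved oxygen (DO) in an aerated stirred
batch reactor while small pulses of an organic substrate are added in
sequence. Each pulse leaves a drop-and-recovery excursion (a *respirogram*)
whose shape encodes how fast the culture oxidizes that substrate.
`respirokin` turns such traces into growth kinetics:

1. **Process** — segment the trace into addition events, extract the
   dynamic oxygen uptake rate `R_S(t)` (reaeration-corrected by default,
   `R_S = kLa (DO_b - DO) - dDO/dt`) and the oxygen consumption
   `OC = ∫ R_S dt` per event.
2. **Balance** — convert to yields and empirical specific growth rates via
   the COD balance:
   `Y_O2 = (S - OC)/S`, `Y_TSS = Y_O2 / f_cv` (with `f_cv = 1.48` mg COD
   per mg TSS), `mu = Y_TSS R_S / ((1 - Y_O2) X_T)`.
3. **Fit** — fit the unstructured growth models of Monod
   `mu_m S/(K_S + S)`, Moser `mu_m S^n/(K_S + S^n)` (n = 2), Contois
   `mu_m S/(K_C X_T + S)` and Tessier `mu_m (1 - e^{-S/K_S})` by
   least-squared-error minimization `LSE = Σ (mu_theo - mu_emp)^2`, and
   select the best model per substrate by lowest LSE.
4. **Report** — a substrate × model parameter table (mu_m, K with
   model-specific units, Y_TSS, LSE) and rate curves: substrate
   degradation `r_su = mu X_T / Y_TSS` and cell growth `r_x = mu X_T`.

A mechanistic simulator (`simulate_respirogram()`) reproduces the whole
experiment — oxygen transfer, endogenous respiration, pulsed additions,
probe noise — with known ground truth, and backs every validation test.
The methods vignette (`vignettes/respirometric-kinetics.Rmd`) documents
the models, estimators and numerical choices.

## Worked example

Substrate bookkeeping for sequential additions (10 mL pulses of a
2400 mg O₂ L⁻¹ peptone stock, diluted to 35/70/100%, into 1.010 L):

```r
library(respirokin)
sched <- addition_schedule(2400, c(0.35, 0.70, 1.00),
                           substrate_label = "peptone")
events_table(sched)
#>   substrate dilution  cod         s x_t
#> 1   peptone       S1  840  8.235294  NA
#> 2   peptone       S2 1680 16.310680  NA
#> 3   peptone       S3 2400 23.076923  NA
```

`s` is the in-reactor substrate concentration each pulse sees (dose over
post-addition volume, earlier pulses fully consumed). Evaluating the
reported Contois kinetics of a cold-adapted marine heterotroph on peptone
(`mu_m = 0.2062 h⁻¹`, `K_C = 0.0039 mg O₂ mg TSS⁻¹`, `Y_TSS = 0.6687`,
`X_T = 284.8 mg TSS L⁻¹`) at the highest tested concentration:

```r
fit <- structure(list(model_name = "contois", mu_m = 0.2062, k = 0.0039,
                      n = NA_real_), class = "kinetic_fit")
rate_curves(fit, x_t = 284.8, y_tss = 0.6687,
            s_grid = in_reactor_substrate(sched, 3))
#>          s        mu     r_su      r_x
#> 1 23.07692 0.1967311 83.78797 56.02902
```

so peptone is degraded at ~84 mg O₂ L⁻¹ h⁻¹ — above the 60 mg O₂ L⁻¹ h⁻¹
mark that distinguishes fast proteolytic metabolism, while the culture
grows at 56 mg TSS L⁻¹ h⁻¹ (`r_x / r_su = Y_TSS`).

End to end on simulated data (two substrates, known ground truth, kLa
measured at 10 h⁻¹):

```r
cfg <- run_config(
  substrates = list(sodium_acetate = substrate_scenario("sodium_acetate"),
                    peptone = substrate_scenario("peptone")),
  constants = reactor_constants(kla = 10), seed = 7L)
rep <- run_pipeline(cfg)
render_kinetics_table(rep)
#>        substrate   model  mu_m_h        K        K_units  y_tss     lse_h2
#> 1 sodium_acetate   monod  0.1232    5.480      mg O2 L-1 0.4715 1.8222e-04
#> 2 sodium_acetate tessier 0.08952    4.507      mg O2 L-1 0.4715 2.2191e-04
#> 3 sodium_acetate   moser 0.08104    6.443  (mg O2 L-1)^2 0.4715 7.4580e-04
#> 4 sodium_acetate contois  0.1236  0.01812 mg O2 mg TSS-1 0.4715 1.8094e-04
#> 5        peptone   monod  0.2228    1.506      mg O2 L-1 0.4637 1.1859e-03
#> 6        peptone tessier  0.1947    1.951      mg O2 L-1 0.4637 4.3268e-04
#> 7        peptone   moser  0.1949    2.064  (mg O2 L-1)^2 0.4637 7.6967e-04
#> 8        peptone contois  0.2236 0.008650 mg O2 mg TSS-1 0.4637 1.3078e-03
```

The acetate trace was generated under Monod kinetics with
`mu_m = 0.1163 h⁻¹`; the fitted 0.1232 h⁻¹ recovers it within 6%, and the
measured yield (0.47 mg TSS per mg COD) matches the simulator's truth.
Note the Monod/Contois LSE near-tie on acetate: with little biomass
variation across events the two models coincide, which is why single-run
model selection should be read together with the LSE margins.

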