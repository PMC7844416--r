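# coronabiophys

Biophysical analysis of nanocarrier protein coronas in R.

When a nanocarrier (here, a polymersome — a self-assembled polymer vesicle)
enters blood, serum albumin adsorbs to its surface within milliseconds. The
biological fate of the carrier then depends not just on *whether* albumin is
there but on its **folding state**: macrophage class A1 scavenger receptors
recognize structurally altered albumin, so surface chemistries that denature
the adsorbed protein are cleared while chemistries that stabilize it evade
recognition. Characterizing that axis requires a chain of quantitative
analyses, and this package implements all of them as tested, reusable
functions, each paired with a seeded synthetic-data generator of known
ground truth:

* **SAXS** — spherical vesicle form factor
  `P(q) = (φ/V_shell)[3V_c(ρ_solv−ρ_shell)j₁(qr_c)/(qr_c) +
  3V_t(ρ_shell−ρ_solv)j₁(qr_t)/(qr_t)]² + b` with Levenberg–Marquardt
  fitting (fringe-aware multi-start, reduced χ² reporting), Guinier
  estimation of the radius of gyration from
  `I(q) ≈ I₀·exp(−q²Rg²/3)`, and the dimensionless Kratky diagnostic
  `(qRg)²·I(q)/I₀` vs `qRg`, whose peak sits at `(√3, 3/e ≈ 1.104)` for
  any compact globule and degrades toward a plateau of 2 for unfolded
  chains.
* **CD spectroscopy** — mean residue ellipticity
  `MRE = W_r·θ_obs/(10·d·c)` (θ in mdeg), α-helicity from the 208 nm
  estimator `%α = (−[θ]₂₀₈ − 4000)/(33000 − 4000)·100`, and difference
  spectra against the folded reference.
* **Tryptophan quenching** — background-subtracted emission AUC (300–400
  nm) normalized to a folded control.
* **Kinetics** — plateau-offset one-phase decay
  `y = y_p + (y₀−y_p)·e^(−kt)` for limited-proteolysis time courses,
  one-phase association for zeta-vs-adsorption curves, linear calibration
  with inverse prediction, encapsulation efficiency
  `EE = (M_i − M_u)/M_i·100`, and supernatant-subtraction adsorption
  bookkeeping.
* **Uptake & biodistribution** — false-positive-rate gating (threshold =
  the (1−FPR) quantile of a null sample), percent-positive,
  background-subtracted median fluorescence intensity, adjusted radiant
  efficiency over organ ROIs, organ fractions, and t₀-proxy blood
  clearance.
* **Cross-assay statistics** — Pearson correlation with OLS lines and 95%
  CIs, and a structure-panel driver that assembles all metrics per
  condition.

## Worked example

```r
library(coronabiophys)

# --- SAXS: generate a noisy vesicle profile and refit it -------------
truth   <- vesicle_params(phi = 1e-4, r_c = 302, shell_thickness = 80,
                          background = 0.01)           # 76.4 nm vesicle
profile <- gen_vesicle_profile(truth, seed = 42, noise_rel = 0.01,
                               uncertainty_rel = 0.02) # 2x-stated errors
init    <- vesicle_params(phi = 1.2e-4, r_c = 250, shell_thickness = 95,
                          background = 0.012)          # deliberately off
fit <- fit_vesicle_model(profile, init)
fit
#> <vesicle_fit> reduced chi^2 = 0.2399 (200 points, 4 free), converged
#> <vesicle_params>
#>   core radius      302.0 A
#>   shell thickness  80.0 A
#>   total diameter   76.4 nm
#>   ...

# --- CD: helicity of a partially denatured albumin corona ------------
cd <- gen_cd_spectrum(34.9, seed = 1, noise_mdeg = 0)
helicity_from_mre208(mre_spectrum(cd))
#> <helicity_result> 34.9% alpha helix (theta_208 = -14121)

# --- proteolysis: rate of a strongly denaturing surface --------------
tc <- gen_proteolysis_timecourse(k = 0.31, y_plateau = 0.1, seed = 1,
                                 noise_rel = 0)
fit_decay(tc)
#> <decay_fit> k = 0.31 /min, y0 = 1, plateau = 0.1, r2 = 1.0000

# --- cytometry: FPR gating of a synthetic uptake mixture -------------
ev  <- gen_flow_events(n_null = 10000, n_sample = 10000,
                       uptake_shift = 1.5, positive_fraction = 0.6,
                       seed = 7)
thr <- gate_threshold(ev$null, fpr = 0.015)
percent_positive(ev$sample, thr)
#> [1] 47.9
```

Reading the numbers: the fit recovers the generating 76.4 nm diameter from
a start ~17% off, and its reduced χ² of 0.24 is the expected (1/2)² ≈ 0.25
when recorded uncertainties double the true noise; the CD chain returns the
generating helicity exactly at zero noise; the decay fit returns the
generating rate with r² = 1; and the gated percent-positive (47.9%) matches
the closed-form mixture tail above the threshold (`lognormal_mixture_tail`)
to within binomial error — by construction a 60% positive fraction is only
partially resolved at this shift, so the gate recovers the exceedance mass,
not the mixing weight.

## Package layout

```
R/                 analysis modules (SAXS, CD/fluorescence, kinetics,
                   uptake, synthetic generators, pipeline statistics)
tests/testthat/    unit, property and acceptance suites
scripts/           acceptance.R
vignettes/         methods vignette (models, assumptions, limitations)
```
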