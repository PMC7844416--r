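---
title: "Methods: quantifying adsorbed-protein folding state on nanocarrier surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying adsorbed-protein folding state on nanocarrier surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coronabiophys)
```

## Scope

When a nanocarrier enters a protein-rich fluid, serum albumin adsorbs within
milliseconds and the surface the immune system actually sees is the adsorbed
protein layer — and, crucially, its *folding state*: macrophage class A1
scavenger receptors (SR-A1) recognize structurally altered albumin, so a
surface chemistry that denatures its albumin corona is marked for clearance
while one that stabilizes it evades recognition. `coronabiophys` implements
the quantitative chain needed to characterize that axis for a vesicular
nanocarrier (a polymersome): small-angle x-ray scattering (SAXS) morphology
and flexibility analysis, circular dichroism (CD) secondary-structure
metrics, tryptophan-quench fluorescence, limited-proteolysis and
adsorption kinetics, and the flow-cytometry / organ-imaging arithmetic used
to quantify uptake and biodistribution. Each analysis has a paired seeded
generator producing synthetic inputs with known ground truth, so every
estimator in the package is validated by round-trip rather than by fiat.

## SAXS: the spherical vesicle model

A vesicle is modeled as a solvent-filled core of radius $r_c$ inside a
shell of thickness $r_{st}$, total radius $r_t = r_c + r_{st}$. With shell
volume fraction $\phi$, core/total volumes $V_c, V_t$
($V_{shell} = V_t - V_c$), and scattering length densities
$\rho_{shell}, \rho_{solv}$, the scattered intensity at momentum transfer
$q = 4\pi\sin(\theta)/\lambda$ is

$$P(q) = \frac{\phi}{V_{shell}}\left[
  \frac{3V_c(\rho_{solv}-\rho_{shell})\,j_1(qr_c)}{qr_c} +
  \frac{3V_t(\rho_{shell}-\rho_{solv})\,j_1(qr_t)}{qr_t}
  \right]^2 + b,$$

with $j_1(x) = (\sin x - x\cos x)/x^2$ the first-order spherical Bessel
function (evaluated by Taylor series below $|x| < 0.05$ to avoid
catastrophic cancellation; the $j_1(x)/x \to 1/3$ limit is then exact).

Numerical choices that matter:

* **Intensity scale is arbitrary.** Reduced synchrotron curves are in
  arbitrary units, so only the squared contrast
  $(\rho_{shell}-\rho_{solv})^2$ is identifiable and $\phi$ absorbs the
  overall scale. Both SLDs are therefore *fixed by default* during fitting
  (defaults 10.8 and 9.4 in units of $10^{-6}\,\text{Å}^{-2}$, i.e. a 1.4
  contrast); they are configuration, not science.
* **Reduced $\chi^2$.** Goodness of fit is reported per degree of freedom,
  $\chi^2/(N-p)$ — the only convention under which "below 1 indicates a
  reasonable fit" is meaningful.
* **Constraints by reparameterization.** Positivity of $r_c$, $r_{st}$,
  $b$ and $\phi \in (0,1]$ are enforced by fitting $\log r_c$,
  $\log r_{st}$, $\log b$ and $\mathrm{logit}\,\phi$, which keeps the
  Levenberg–Marquardt (LM) step well-behaved and guarantees $r_t > r_c$
  structurally.
* **Multi-start over the fringe landscape.** The form factor has
  interference fringes, so $\chi^2$ over $(r_c, r_{st})$ has local minima
  spaced about $\pi/q_{max}$ apart and a single LM descent from a start
  20% off simply polishes the nearest wrong fringe. `fit_vesicle_model`
  therefore scans a deterministic grid over the free radii at half-fringe
  spacing; at each node the model is *linear* in $(\phi, b)$, so those are
  eliminated exactly by weighted linear least squares, making the node
  value the true profile $\chi^2$. The best nodes seed LM polishing and
  the lowest-$\chi^2$ solution wins. A final restart from the
  re-canonicalized incumbent (which lifts a background collapsed to zero
  back onto its transform floor, where its log-coordinate is no longer
  flat) rescues stalled descents. On noiseless self-generated profiles
  this recovers all free parameters to $10^{-4}$ relative error from
  ±20%-perturbed starts.
* **No instrumental smearing or polydispersity.** The target data carry no
  resolution function, and a monodisperse model is the stated analysis
  convention; both are out of scope.

The default analysis grid is 200 log-spaced points over
0.001–0.5 Å$^{-1}$, matching the measurement range of the 10 keV
($\lambda = 1.24$ Å) synchrotron configuration these analyses assume.

## Guinier analysis and the dimensionless Kratky plot

The low-$q$ Guinier law $I(q) \approx I_0 e^{-q^2 R_g^2/3}$ is fitted in
log space with an iteratively selected window: starting from the lowest-$q$
fifth of the curve, the window is recomputed as all points with
$qR_g \le$ `qmax_Rg` until stable. The default bound 1.3 is the standard
compact-globule convention. Because the Guinier law is an *approximation*
for any real shape, the window bound sets a small systematic bias that is a
property of the mathematics, not of the implementation: on exact noiseless
curves a homogeneous sphere ($R_g/R = \sqrt{3/5}$) is recovered to 1.5% at
the 1.3 bound and 0.9% at 1.0, while a Debye chain is biased low by 5.5%
at 1.3, 3.2% at 1.0 and 2.0% at 0.8. For flexible or elongated particles
a tighter window (`qmax_Rg` of 0.8–1.0) should be used, and the test suite
pins exactly those figures.

The dimensionless Kratky transform plots $v = (qR_g)^2 I(q)/I_0$ against
$u = qR_g$. Its value is diagnostic and size-independent: any particle
obeying the Guinier law peaks at $u = \sqrt 3$ with
$v = 3e^{-1} \approx 1.104$, while a flexible Gaussian chain
($I/I_0 = 2(e^{-x}+x-1)/x^2$, $x = q^2R_g^2$) shows no such peak and
plateaus at $v \to 2$. Departures from the $(\sqrt 3, 1.104)$ waveform
flag asymmetry or flexibility — e.g. denatured protein. The peak is
located by parabolic interpolation through the grid maximum and its two
neighbours, giving $|\Delta u| < 10^{-3}$ on a 500-point grid.

## CD: mean residue ellipticity and the 208 nm helicity estimator

Observed ellipticity $\theta_{obs}$ (in millidegrees, the usual
spectrometer export) is normalized per residue and per molar
concentration:

$$\mathrm{MRE}(\lambda) = \frac{W_r\,\theta_{obs}(\lambda)}
  {10\,d\,c \times 1000},\qquad W_r = \mathrm{MW}/n_{res},$$

with $d$ the path length (cm) and $c$ the protein concentration (g/mL);
units deg·cm²/dmol. The factor 1000 converts mdeg to degrees and is folded
into the constant — the source convention does not state mdeg vs deg, so
the mdeg default is recorded here as configuration. For BSA the defaults
are 583 residues and 66 430.3 Da ($W_r \approx 113.95$).

Helix content uses the single-wavelength estimator at 208 nm:

$$\%\alpha = \frac{-[\theta]_{208} - 4000}{33000 - 4000} \times 100,$$

with $[\theta]_{208}$ extracted by *linear interpolation* at exactly
208 nm (robust to grid pitch; at the standard 0.5 nm pitch nearest-point
and interpolation differ measurably). Values outside $[0, 100]$ are
reported as-is with an `out_of_range` flag — clamping would destroy the
diagnostic value of a bad input. No basis-set deconvolution is attempted:
the 208 nm estimator is the entire secondary-structure model here.

Difference spectra (sample − folded reference) require identical
wavelength grids; there is deliberately no implicit resampling.

## Tryptophan quenching

Intrinsic tryptophan emission (300–400 nm, excitation 280 nm) diminishes
as the fold opens. The analysis is: subtract the matched protein-free
blank pointwise, integrate by the trapezoid rule (no integration rule is
canonical for these bands; trapezoid is the assumption-free choice), and
normalize to a folded-protein control AUC. The result is invariant to any
common offset in sample and blank.

## Kinetics

Limited proteolysis time courses ($t_0$-normalized intact-protein peak
areas at 0, 10, 20, 30, 60, 120 min) are fitted with the plateau-offset
one-phase decay

$$y(t) = y_p + (y_0 - y_p)\,e^{-kt}.$$

The literal no-offset variant $(y_0-y_p)e^{-kt}$ — which decays to zero
and therefore has no plateau asymptote consistent with the definition of
$y_p$ — is retained behind `form = "literal"` for auditing. Fitting uses
LM with a seeded multi-start (five rate initializations spanning a
16-fold range, best SSE kept); the model is linear in
$(y_p,\, y_0 - y_p)$ given $k$, which the test suite exploits as a
profiled grid-search oracle. Two identifiability guards are flagged, not
silenced: a constant series (no decay) and a rate so fast the decay
completes before the first positive timepoint ($k\,t_1 > 20$) or so slow
it is invisible over the span. The six-timepoint schedule resolves rates
in roughly the 0.01–0.3 min$^{-1}$ decade; at the top of that range a
*noisy* series carries little rate information (the curve is ~96% decayed
by 10 min), which is why the noisy-recovery validation uses a mid-range
rate (0.15 min$^{-1}$: 500-seed mean bias 1.3%) while the fast rate is
validated noiselessly.

Zeta-potential-versus-adsorption curves use the same engine in
association form $y = y_{start} + (y_{plateau}-y_{start})(1-e^{-kx})$.
Calibration curves are ordinary least squares with closed-form inversion
$x = (y-a)/b$; below-intercept readings invert to negative concentrations
and are flagged as extrapolation. Encapsulation efficiency and
supernatant-subtraction adsorption are exact arithmetic with negative
results flagged rather than raised.

## Cytometry gating and biodistribution

* **Gate threshold**: the $(1-\mathrm{FPR})$ empirical quantile of a
  designated null (negative-control) sample, with the linear-interpolation
  (type 7) quantile definition fixed so gates are bit-reproducible.
  Typical FPR: 1.5% in vitro, 2% in vivo.
* **Percent positive**: events *strictly* above threshold; ties count
  negative (deterministic tie-breaking; the source convention is
  unstated, so one side had to be chosen and recorded).
* **MFI**: median fluorescence minus the untreated-control median;
  negative values are reported as-is.
* **Organ imaging**: adjusted radiant efficiency is the organ ROI total
  minus the background *average* converted to a total over the ROI area
  (circular ROIs, e.g. 1.9 cm diameter for spleen/kidney/lung/heart,
  3.0 cm for liver). The literal instrument-manual phrasing is
  dimensionally circular and survives only behind `literal = TRUE`.
  Organ shares are percentages of the summed adjusted radiant efficiency.
* **Blood clearance**: the $t_0$ proxy is the input formulation diluted
  by the dose-to-blood-volume ratio (100 µL into ~1.5 mL gives 1:15);
  percent change of the measured plasma fluorescence against that proxy
  estimates the fraction cleared.

## What the generators emulate — and what they do not

Each generator is a bijection from (seed, truth) to output and leaves the
global RNG untouched. Noise families are the simplest matching each
assay's support: multiplicative Gaussian for scattering (counting-dominated
relative error), additive Gaussian for spectra and time courses, and
log-normal event distributions for cytometry (mixture shift on the log
scale, with a closed-form exceedance tail for exact gate truths).

The CD basis templates are Gaussian sums shaped only to *look* like
helix/coil far-UV spectra; their science is anchored solely at 208 nm,
where $B_{helix}(208) = -33000$ and $B_{coil}(208) = -4000$ exactly, so
helicity round-trips are exact by construction at that wavelength and the
rest of the waveform is cosmetic. Real spectra carry correlated baseline
drift, high-tension-voltage artifacts and concentration errors that the
generator does not model — passing round-trips therefore validate the
estimator arithmetic, not robustness to every instrumental pathology.
Similarly, the scattering generators are monodisperse and unsmeared, the
proteolysis generator has no MALDI peak-integration noise structure, and
the cytometry generator is a single-channel intensity model without
compensation or doublet artifacts. Those upstream steps are explicit
non-goals.

## Problem sizes and runtime envelope

The validation suite runs at deliberately modest sizes — 200-point
scattering profiles (500 for Kratky peak localization), 20-draw parameter
recovery, 200-replicate $\chi^2$ coverage, 100-seed gating calibration,
500-seed rate recovery, 5 000–20 000-event cytometry samples — chosen so
the full suite completes in well under a minute while every estimate's
Monte-Carlo error stays far below the tolerance it is tested against.

## Known limitations

* The vesicle model is monodisperse, unsmeared, and structure-factor-free;
  it is not suitable for concentrated or interacting suspensions.
* The Guinier/Kratky normalization inherits the window-bias discussed
  above; cross-shape comparisons should hold the window fixed.
* The 208 nm estimator is a one-parameter summary of secondary structure;
  it cannot separate β-sheet from coil rearrangements.
* Gating assumes singly-labeled intensity vectors per population —
  hierarchical multi-marker gating trees and compensation live upstream.
* The decay/association fits report $r^2$ on the scale fitted
  (normalized, for time courses); raw-scale $r^2$ can be obtained by
  fitting unnormalized series with `time_course(..., normalize = FALSE)`.
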