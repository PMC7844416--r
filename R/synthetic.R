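#' @importFrom withr with_seed
NULL

#' Generate a synthetic vesicle scattering profile
#'
#' Evaluates the spherical vesicle form factor on a log-spaced q grid and
#' adds multiplicative Gaussian noise: sd(q) = noise_rel * I(q), the
#' simplest noise family matching the counting-dominated relative error
#' of a synchrotron measurement at these intensities. The recorded
#' uncertainty column is `uncertainty_rel * I(q)`, which by default
#' matches the generating noise but can be inflated deliberately to
#' emulate conservative error estimates (reduced chi-square then scales
#' as (noise_rel / uncertainty_rel)^2).
#'
#' @param params A [vesicle_params] ground truth.
#' @param seed Integer seed; identical seeds reproduce identical
#'   profiles.
#' @param noise_rel Relative noise level (fraction of I(q)).
#' @param uncertainty_rel Relative uncertainty recorded in the profile;
#'   `NULL` omits the column (also omitted when zero).
#' @param n_points,q_min,q_max q-grid specification (defaults: 200
#'   log-spaced points over 0.001-0.5 1/Angstrom, the measurement range).
#' @return A [scattering_profile] with the generating [vesicle_params]
#'   attached as attribute `truth`.
#' @export
gen_vesicle_profile <- function(params, seed, noise_rel = 0.01,
                                uncertainty_rel = noise_rel,
                                n_points = 200, q_min = 0.001,
                                q_max = 0.5) {
  stopifnot(inherits(params, "vesicle_params"))
  q <- default_q_grid(n_points, q_min, q_max)
  ideal <- vesicle_intensity(params, q)
  intensity <- if (noise_rel > 0) {
    withr::with_seed(seed, ideal + stats::rnorm(n_points, sd = noise_rel * ideal))
  } else {
    ideal
  }
  unc <- NULL
  if (!is.null(uncertainty_rel) && uncertainty_rel > 0) {
    unc <- uncertainty_rel * ideal
  }
  prof <- scattering_profile(q, intensity, uncertainty = unc)
  attr(prof, "truth") <- params
  prof
}

#' Generate a globular / chain-like scattering profile
#'
#' Three analytic single-particle models with a known radius of gyration:
#' * `guinier`: I = I0 exp(-q^2 Rg^2 / 3), the idealized compact particle
#'   (dimensionless Kratky peak exactly at (sqrt(3), 3/e));
#' * `sphere`: squared homogeneous-sphere form factor with
#'   R = Rg * sqrt(5/3) (so the sphere's Rg equals the request);
#' * `debye_chain`: the Debye Gaussian-chain function
#'   I = I0 * 2 (exp(-x) + x - 1) / x^2 with x = (q Rg)^2, whose
#'   dimensionless Kratky curve plateaus at 2 -- the flexible-chain
#'   (denatured) limit.
#'
#' @param Rg Radius of gyration, Angstrom, > 0.
#' @param kind One of `"guinier"`, `"sphere"`, `"debye_chain"`.
#' @param seed Integer seed (used only when `noise_rel > 0`).
#' @param noise_rel Relative multiplicative Gaussian noise.
#' @param I0 Forward intensity.
#' @param n_points,q_min,q_max q-grid specification.
#' @return A [scattering_profile] with attribute `truth` (list with `Rg`,
#'   `kind`, `I0`).
#' @export
gen_globule_profile <- function(Rg, kind = c("guinier", "sphere",
                                             "debye_chain"),
                                seed = 1, noise_rel = 0, I0 = 1,
                                n_points = 200, q_min = 0.001,
                                q_max = 0.5) {
  kind <- match.arg(kind)
  if (!is.finite(Rg) || Rg <= 0) {
    stop("`Rg` must be positive", call. = FALSE)
  }
  q <- default_q_grid(n_points, q_min, q_max)
  ideal <- switch(kind,
    guinier = I0 * exp(-q^2 * Rg^2 / 3),
    sphere = {
      R <- Rg * sqrt(5 / 3)
      x <- q * R
      I0 * (3 * spherical_bessel_j1(x) / x)^2
    },
    debye_chain = I0 * debye_function(q^2 * Rg^2)
  )
  intensity <- if (noise_rel > 0) {
    withr::with_seed(seed, ideal + stats::rnorm(n_points, sd = noise_rel * ideal))
  } else {
    ideal
  }
  unc <- if (noise_rel > 0) noise_rel * ideal else NULL
  prof <- scattering_profile(q, intensity, uncertainty = unc)
  attr(prof, "truth") <- list(Rg = Rg, kind = kind, I0 = I0)
  prof
}

#' Debye function for a Gaussian chain
#'
#' 2 (exp(-x) + x - 1) / x^2, with a series branch near the origin so the
#' x -> 0 limit of 1 is preserved.
#'
#' @param x Non-negative values of (q Rg)^2.
#' @return The Debye function evaluated elementwise.
#' @export
debye_function <- function(x) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  small <- x < 1e-3
  xs <- x[small]
  out[small] <- 1 - xs / 3 + xs^2 / 12 - xs^3 / 60
  xl <- x[!small]
  out[!small] <- 2 * (exp(-xl) + xl - 1) / xl^2
  out
}

#' Generate a synthetic CD spectrum of known helicity
#'
#' Builds the mean residue ellipticity as a two-state mixture
#' MRE(lambda) = (h/100) B_helix(lambda) + (1 - h/100) B_coil(lambda),
#' with smooth Gaussian-sum basis templates rescaled so that
#' B_helix(208) = -33000 and B_coil(208) = -4000 deg cm^2/dmol -- the
#' anchor points of the 208 nm helicity estimator. The template shapes
#' away from 208 nm are cosmetic (minima near 208/222 nm for helix and
#' 198 nm for coil) and carry no additional science. The MRE is converted
#' back to observed ellipticity (mdeg) through the declared path length,
#' concentration and mean residue weight, and additive Gaussian noise is
#' applied on the mdeg scale.
#'
#' @param helicity Ground-truth alpha-helix content, percent, in
#'   \[0, 100\].
#' @param seed Integer seed (used only when `noise_mdeg > 0`).
#' @param noise_mdeg Additive Gaussian noise on the observed ellipticity,
#'   mdeg (default 0.05, a typical far-UV spectrometer noise floor).
#' @param pitch Wavelength pitch, nm (default 0.5).
#' @param path_cm,conc_g_per_ml,n_residues,mw_da Acquisition metadata
#'   (defaults: 0.1 cm cuvette, 2e-4 g/mL BSA, 583 residues, 66430.3 Da).
#' @return A [cd_spectrum] with attribute `truth` (list with `helicity`).
#' @export
#' @examples
#' s <- gen_cd_spectrum(55.9, seed = 1, noise_mdeg = 0)
#' helicity_from_mre208(mre_spectrum(s))$percent # 55.9
gen_cd_spectrum <- function(helicity, seed = 1, noise_mdeg = 0.05,
                            pitch = 0.5, path_cm = 0.1,
                            conc_g_per_ml = 2e-4, n_residues = 583,
                            mw_da = 66430.3) {
  if (!is.finite(helicity) || helicity < 0 || helicity > 100) {
    stop("`helicity` must lie in [0, 100]", call. = FALSE)
  }
  wl <- seq(190, 260, by = pitch)
  h <- helicity / 100
  mre <- h * cd_basis_helix(wl) + (1 - h) * cd_basis_coil(wl)
  w_r <- mw_da / n_residues
  theta <- mre * (10 * path_cm * conc_g_per_ml * 1000) / w_r
  if (noise_mdeg > 0) {
    theta <- withr::with_seed(
      seed, theta + stats::rnorm(length(theta), sd = noise_mdeg))
  }
  s <- cd_spectrum(wl, theta, path_cm = path_cm,
                   conc_g_per_ml = conc_g_per_ml,
                   n_residues = n_residues, mw_da = mw_da)
  attr(s, "truth") <- list(helicity = helicity)
  s
}

# smooth spectrum-like basis templates, exactly anchored at 208 nm
cd_basis_helix <- function(wl) {
  shape <- function(l) {
    -exp(-(l - 208)^2 / (2 * 6.5^2)) -
      0.95 * exp(-(l - 222)^2 / (2 * 8^2)) +
      1.9 * exp(-(l - 192)^2 / (2 * 5.5^2))
  }
  -33000 / shape(208) * shape(wl)
}

cd_basis_coil <- function(wl) {
  shape <- function(l) {
    -exp(-(l - 198)^2 / (2 * 7^2)) +
      0.15 * exp(-(l - 220)^2 / (2 * 10^2))
  }
  -4000 / shape(208) * shape(wl)
}

#' Generate a quenched tryptophan emission spectrum with matching blank
#'
#' A Gaussian emission band centered at 340 nm over the 300-400 nm
#' acquisition window, scaled by (1 - quench_factor), on a flat buffer
#' baseline, with additive Gaussian noise. At zero noise the
#' background-subtracted AUC normalized to the unquenched control is
#' exactly 1 - quench_factor.
#'
#' @param quench_factor Fraction of intrinsic fluorescence lost, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @param amplitude Peak band height above baseline at zero quench, a.u.
#' @param center,width Band center and Gaussian sd, nm.
#' @param baseline Flat buffer background, a.u.
#' @param noise_sd Additive Gaussian noise, a.u.
#' @return List with `spectrum` and `blank` ([emission_spectrum]
#'   objects) and `quench_factor` (the ground truth).
#' @export
gen_trp_spectrum <- function(quench_factor, seed = 1, amplitude = 1000,
                             center = 340, width = 15, baseline = 20,
                             noise_sd = 2) {
  if (!is.finite(quench_factor) || quench_factor < 0 ||
      quench_factor > 1) {
    stop("`quench_factor` must lie in [0, 1]", call. = FALSE)
  }
  wl <- 300:400
  band <- amplitude * (1 - quench_factor) *
    exp(-(wl - center)^2 / (2 * width^2))
  spec_f <- baseline + band
  blank_f <- rep(baseline, length(wl))
  if (noise_sd > 0) {
    noise <- withr::with_seed(
      seed, stats::rnorm(2 * length(wl), sd = noise_sd))
    spec_f <- spec_f + noise[seq_along(wl)]
    blank_f <- blank_f + noise[length(wl) + seq_along(wl)]
  }
  list(
    spectrum = emission_spectrum(wl, spec_f),
    blank = emission_spectrum(wl, blank_f),
    quench_factor = quench_factor
  )
}

#' Generate a proteolysis time course
#'
#' Samples the plateau-offset one-phase decay (y0 = 1) at the standard
#' quench schedule of six timepoints (0, 10, 20, 30, 60, 120 min), adds
#' additive Gaussian noise, and t0-normalizes the result the way
#' measured peak-area series are (dividing by the observed t0 value).
#'
#' @param k Proteolysis rate, 1/min, > 0.
#' @param y_plateau Plateau of the normalized AUC.
#' @param seed Integer seed.
#' @param noise_rel Additive Gaussian noise sd on the normalized scale.
#' @param t Quench timepoints, minutes.
#' @return A [time_course] with attribute `truth` (list with `k`,
#'   `y_plateau`, `y0 = 1`).
#' @export
gen_proteolysis_timecourse <- function(k, y_plateau = 0.1, seed = 1,
                                       noise_rel = 0.03,
                                       t = c(0, 10, 20, 30, 60, 120)) {
  if (!is.finite(k) || k <= 0) {
    stop("`k` must be positive", call. = FALSE)
  }
  y <- one_phase_decay(t, y0 = 1, y_plateau = y_plateau, k = k)
  if (noise_rel > 0) {
    y <- withr::with_seed(
      seed, y + stats::rnorm(length(t), sd = noise_rel))
  }
  tc <- time_course(t, y, normalize = TRUE)
  attr(tc, "truth") <- list(k = k, y_plateau = y_plateau, y0 = 1)
  tc
}

#' Generate paired null / treated cytometry event tables
#'
#' Null (negative-control) events are log-normal; treated events are a
#' two-component mixture in which a fraction `positive_fraction` of cells
#' is shifted by `uptake_shift` on the log scale. The exceedance mass of
#' the mixture above any threshold has the closed form implemented by
#' [lognormal_mixture_tail], giving every gate an exact ground truth.
#'
#' @param n_null,n_sample Event counts (>= 100 each).
#' @param uptake_shift Log-scale shift of the positive component.
#' @param positive_fraction Fraction of treated cells in the positive
#'   component, in \[0, 1\].
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters of the null population
#'   (defaults 4 and 0.5: autofluorescence around 55 a.u.).
#' @return List with `null` and `sample` ([event_table] objects) and
#'   `truth` (list with the generating parameters).
#' @export
gen_flow_events <- function(n_null, n_sample, uptake_shift = 0,
                            positive_fraction = 0, seed = 1,
                            meanlog = 4, sdlog = 0.5) {
  if (n_null < 100 || n_sample < 100) {
    stop("event counts must be at least 100", call. = FALSE)
  }
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop("`positive_fraction` must lie in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    null_i <- stats::rlnorm(n_null, meanlog, sdlog)
    pos <- stats::rbinom(n_sample, 1, positive_fraction) == 1
    sample_i <- stats::rlnorm(n_sample, meanlog + uptake_shift * pos,
                              sdlog)
    list(
      null = event_table(null_i, "null"),
      sample = event_table(sample_i, "treated"),
      truth = list(meanlog = meanlog, sdlog = sdlog,
                   uptake_shift = uptake_shift,
                   positive_fraction = positive_fraction)
    )
  })
}

#' Exceedance mass of a two-component log-normal mixture
#'
#' P(X > threshold) for the mixture generated by [gen_flow_events]:
#' (1 - p) * S0(threshold) + p * S1(threshold), with S0 and S1 the
#' log-normal survival functions of the null and shifted components.
#'
#' @param threshold Intensity threshold.
#' @param meanlog,sdlog Null-component parameters.
#' @param uptake_shift Log-scale shift of the positive component.
#' @param positive_fraction Mixture weight of the positive component.
#' @return Probability of exceeding `threshold`.
#' @export
lognormal_mixture_tail <- function(threshold, meanlog, sdlog,
                                   uptake_shift, positive_fraction) {
  (1 - positive_fraction) *
    stats::plnorm(threshold, meanlog, sdlog, lower.tail = FALSE) +
    positive_fraction *
    stats::plnorm(threshold, meanlog + uptake_shift, sdlog,
                  lower.tail = FALSE)
}

#' Generate a zeta-potential versus adsorbed-protein curve
#'
#' One-phase association from the pristine-surface zeta potential toward
#' the adsorption plateau, evaluated on a grid of adsorbed protein
#' concentrations, with additive Gaussian noise. Defaults reproduce the
#' charge-shielding behaviour of a strongly anionic phosphate surface:
#' -59.3 mV pristine rising to a -39.1 mV plateau as albumin saturates
#' the surface.
#'
#' @param start_mv Zeta potential at zero adsorbed protein, mV.
#' @param plateau_mv Zeta potential at saturating adsorption, mV.
#' @param k Association constant, (ug/mL)^-1, > 0.
#' @param adsorbed_grid Adsorbed protein concentrations, ug/mL.
#' @param seed Integer seed.
#' @param noise_sd Additive Gaussian noise, mV.
#' @return Data frame with columns `adsorbed` and `zeta`, attribute
#'   `truth` (generating parameters).
#' @export
gen_zeta_adsorption <- function(start_mv = -59.3, plateau_mv = -39.1,
                                k = 0.3,
                                adsorbed_grid = seq(0, 16, by = 2),
                                seed = 1, noise_sd = 1.5) {
  if (!is.finite(k) || k <= 0) {
    stop("`k` must be positive", call. = FALSE)
  }
  zeta <- one_phase_association(adsorbed_grid, y_start = start_mv,
                                y_plateau = plateau_mv, k = k)
  if (noise_sd > 0) {
    zeta <- withr::with_seed(
      seed, zeta + stats::rnorm(length(zeta), sd = noise_sd))
  }
  df <- data.frame(adsorbed = adsorbed_grid, zeta = zeta)
  attr(df, "truth") <- list(start_mv = start_mv, plateau_mv = plateau_mv,
                            k = k)
  df
}
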