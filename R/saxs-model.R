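#' Momentum transfer from scattering angle
#'
#' q = 4 pi sin(theta) / lambda, the reciprocal-space coordinate of
#' small-angle scattering.
#'
#' @param theta Scattering angle in radians.
#' @param wavelength X-ray wavelength in Angstrom (e.g. 1.24 A for a
#'   10 keV beam).
#' @return Momentum transfer in inverse Angstrom.
#' @export
#' @examples
#' q_from_angle(pi / 2, 1.24) # 4*pi/1.24
q_from_angle <- function(theta, wavelength) {
  if (!is.numeric(wavelength) || any(!is.finite(wavelength)) ||
      any(wavelength <= 0)) {
    stop("`wavelength` must be a positive finite number", call. = FALSE)
  }
  4 * pi * sin(theta) / wavelength
}

#' First-order spherical Bessel function
#'
#' j1(x) = (sin x - x cos x) / x^2. Near the origin the closed form loses
#' all significant digits to cancellation, so |x| < 0.05 is evaluated with
#' the Taylor series x/3 - x^3/30 + x^5/840, which preserves the limit
#' j1(x)/x -> 1/3 (and j1(0) = 0) exactly.
#'
#' @param x Numeric vector.
#' @return j1 evaluated elementwise.
#' @export
spherical_bessel_j1 <- function(x) {
  x <- as.numeric(x)
  out <- numeric(length(x))
  small <- abs(x) < 0.05
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 30 + xs^5 / 840
  xl <- x[!small]
  out[!small] <- (sin(xl) - xl * cos(xl)) / xl^2
  out
}

#' Spherical vesicle model parameters
#'
#' Parameter set of the spherical vesicle form factor: a solvent-filled
#' core of radius `r_c` surrounded by a shell of thickness
#' `shell_thickness`, so the total radius is r_t = r_c + shell_thickness.
#' Scattering length densities are given in units of 1e-6 per square
#' Angstrom; only the squared contrast (sld_shell - sld_solvent)^2 enters
#' the intensity, and the shell volume fraction `phi` absorbs the overall
#' (arbitrary) intensity scale.
#'
#' @param phi Shell volume fraction, in (0, 1].
#' @param r_c Core radius, Angstrom, > 0.
#' @param shell_thickness Shell thickness, Angstrom, > 0.
#' @param sld_shell,sld_solvent Scattering length densities of shell and
#'   solvent, 1e-6 / A^2.
#' @param background Flat incoherent background, intensity units, >= 0.
#' @return An object of class `vesicle_params` (a named list with the
#'   derived radii and volumes attached).
#' @export
#' @examples
#' vesicle_params(phi = 1e-4, r_c = 350, shell_thickness = 80)
vesicle_params <- function(phi = 1e-4, r_c, shell_thickness,
                           sld_shell = 10.8, sld_solvent = 9.4,
                           background = 0) {
  vals <- c(phi = phi, r_c = r_c, shell_thickness = shell_thickness,
            sld_shell = sld_shell, sld_solvent = sld_solvent,
            background = background)
  if (any(!is.finite(vals))) {
    stop("all vesicle parameters must be finite", call. = FALSE)
  }
  if (phi <= 0 || phi > 1) {
    stop("`phi` must lie in (0, 1]", call. = FALSE)
  }
  if (r_c <= 0 || shell_thickness <= 0) {
    stop("`r_c` and `shell_thickness` must be positive", call. = FALSE)
  }
  if (background < 0) {
    stop("`background` must be non-negative", call. = FALSE)
  }
  p <- list(phi = phi, r_c = r_c, shell_thickness = shell_thickness,
            sld_shell = sld_shell, sld_solvent = sld_solvent,
            background = background)
  p$r_t <- r_c + shell_thickness
  p$v_core <- 4 / 3 * pi * r_c^3
  p$v_total <- 4 / 3 * pi * p$r_t^3
  p$v_shell <- p$v_total - p$v_core
  class(p) <- "vesicle_params"
  p
}

#' @export
print.vesicle_params <- function(x, ...) {
  cat("<vesicle_params>\n")
  cat(sprintf("  core radius      %.1f A\n", x$r_c))
  cat(sprintf("  shell thickness  %.1f A\n", x$shell_thickness))
  cat(sprintf("  total diameter   %.1f nm\n", vesicle_diameter_nm(x)))
  cat(sprintf("  phi              %.4g\n", x$phi))
  cat(sprintf("  SLD shell/solv   %.2f / %.2f (1e-6 A^-2)\n",
              x$sld_shell, x$sld_solvent))
  cat(sprintf("  background       %.4g\n", x$background))
  invisible(x)
}

#' Total vesicle diameter in nanometres
#'
#' @param params A [vesicle_params].
#' @return 2 (r_c + shell_thickness) / 10, in nm.
#' @export
vesicle_diameter_nm <- function(params) {
  stopifnot(inherits(params, "vesicle_params"))
  2 * params$r_t / 10
}

#' Spherical vesicle form-factor intensity
#'
#' Evaluates
#' P(q) = (phi / V_shell) * \[ 3 V_c (rho_solv - rho_shell) j1(q r_c)/(q r_c)
#'       + 3 V_t (rho_shell - rho_solv) j1(q r_t)/(q r_t) \]^2 + b
#' pointwise on `q_grid`. When the contrast vanishes, or the shell
#' thickness tends to zero, the bracket cancels and P(q) tends to the flat
#' background.
#'
#' @param params A [vesicle_params].
#' @param q_grid Positive momentum-transfer values, inverse Angstrom.
#' @return Intensities, same length as `q_grid`.
#' @export
vesicle_intensity <- function(params, q_grid) {
  stopifnot(inherits(params, "vesicle_params"))
  q_grid <- as.numeric(q_grid)
  if (any(!is.finite(q_grid)) || any(q_grid <= 0)) {
    stop("`q_grid` must be finite and strictly positive", call. = FALSE)
  }
  contrast <- params$sld_solvent - params$sld_shell
  xc <- q_grid * params$r_c
  xt <- q_grid * params$r_t
  amp <- 3 * params$v_core * contrast * spherical_bessel_j1(xc) / xc -
    3 * params$v_total * contrast * spherical_bessel_j1(xt) / xt
  params$phi / params$v_shell * amp^2 + params$background
}

#' Default analysis q-grid
#'
#' 200 log-spaced points over 0.001-0.5 inverse Angstrom, the measurement
#' range of the synchrotron configuration the pipeline targets.
#'
#' @param n Number of points.
#' @param q_min,q_max Grid limits, inverse Angstrom.
#' @return Numeric vector of length `n`.
#' @export
default_q_grid <- function(n = 200, q_min = 0.001, q_max = 0.5) {
  if (n < 2 || q_min <= 0 || q_max <= q_min) {
    stop("invalid q-grid specification", call. = FALSE)
  }
  10^seq(log10(q_min), log10(q_max), length.out = n)
}
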