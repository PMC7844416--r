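#' Circular dichroism spectrum with acquisition metadata
#'
#' Observed ellipticity in millidegrees over a uniformly spaced
#' far-UV wavelength grid, together with the cuvette path length, protein
#' concentration and protein constants needed for the mean-residue
#' normalization.
#'
#' @param wavelength Wavelengths in nm, ascending, uniform pitch, within
#'   190-260 nm.
#' @param theta_obs Observed ellipticity, millidegrees.
#' @param path_cm Cuvette path length, cm, > 0.
#' @param conc_g_per_ml Protein concentration, g/mL, > 0.
#' @param n_residues Number of amino-acid residues (default: BSA, 583).
#' @param mw_da Protein molecular weight, Da (default: BSA, 66430.3).
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength, theta_obs, path_cm, conc_g_per_ml,
                        n_residues = 583, mw_da = 66430.3) {
  wavelength <- as.numeric(wavelength)
  theta_obs <- as.numeric(theta_obs)
  if (length(wavelength) != length(theta_obs)) {
    stop("`wavelength` and `theta_obs` must have the same length",
         call. = FALSE)
  }
  if (length(wavelength) < 2 || is.unsorted(wavelength, strictly = TRUE)) {
    stop("`wavelength` must be ascending with at least two points",
         call. = FALSE)
  }
  pitch <- diff(wavelength)
  if (max(abs(pitch - pitch[1])) > 1e-8 * pitch[1]) {
    stop("`wavelength` must have uniform pitch", call. = FALSE)
  }
  if (min(wavelength) < 190 - 1e-9 || max(wavelength) > 260 + 1e-9) {
    stop("`wavelength` must lie within 190-260 nm", call. = FALSE)
  }
  if (!is.finite(path_cm) || path_cm <= 0) {
    stop("`path_cm` must be positive", call. = FALSE)
  }
  if (!is.finite(conc_g_per_ml) || conc_g_per_ml <= 0) {
    stop("`conc_g_per_ml` must be positive", call. = FALSE)
  }
  if (!is.finite(n_residues) || n_residues <= 1) {
    stop("`n_residues` must exceed 1", call. = FALSE)
  }
  out <- list(wavelength = wavelength, theta_obs = theta_obs,
              path_cm = path_cm, conc_g_per_ml = conc_g_per_ml,
              n_residues = n_residues, mw_da = mw_da)
  class(out) <- "cd_spectrum"
  out
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf(
    "<cd_spectrum> %d points, %g-%g nm, d = %g cm, c = %g g/mL\n",
    length(x$wavelength), min(x$wavelength), max(x$wavelength),
    x$path_cm, x$conc_g_per_ml
  ))
  invisible(x)
}

#' Mean residue ellipticity spectrum
#'
#' MRE(lambda) = W_r * theta_obs(lambda) / (10 * d * c), with the mean
#' residue weight W_r = MW / n_residues. The observed ellipticity is
#' accepted in millidegrees (the usual spectrometer export) and converted
#' to degrees internally, so the implemented constant is
#' 10 * d * c * 1000. Resulting units: deg cm^2 / dmol.
#'
#' @param spectrum A [cd_spectrum].
#' @return An object of class `mre_spectrum`: list with `wavelength` (nm)
#'   and `mre` (deg cm^2/dmol).
#' @export
#' @examples
#' wl <- seq(200, 220, by = 0.5)
#' s <- cd_spectrum(wl, rep(-23.03, length(wl)), path_cm = 0.1,
#'                  conc_g_per_ml = 2e-4)
#' mre_spectrum(s)$mre[1] # ~ -13119 deg cm^2/dmol
mre_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  w_r <- spectrum$mw_da / spectrum$n_residues
  mre <- w_r * spectrum$theta_obs /
    (10 * spectrum$path_cm * spectrum$conc_g_per_ml * 1000)
  out <- list(wavelength = spectrum$wavelength, mre = mre)
  class(out) <- "mre_spectrum"
  out
}

#' @export
print.mre_spectrum <- function(x, ...) {
  cat(sprintf("<mre_spectrum> %d points, %g-%g nm\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Alpha-helicity from the mean residue ellipticity at 208 nm
#'
#' Single-wavelength estimator of helix content:
#' percent = (-theta_208 - 4000) / (33000 - 4000) * 100,
#' where theta_208 is the MRE at exactly 208 nm, extracted by linear
#' interpolation on the wavelength grid. Values outside \[0, 100\] are
#' reported as-is with `out_of_range = TRUE`, never clamped, so that
#' implausible inputs stay diagnosable.
#'
#' @param mre An [mre_spectrum] whose grid brackets 208 nm.
#' @return An object of class `helicity_result`: list with `percent`,
#'   `theta_208` and `out_of_range`.
#' @export
helicity_from_mre208 <- function(mre) {
  stopifnot(inherits(mre, "mre_spectrum"))
  if (208 < min(mre$wavelength) || 208 > max(mre$wavelength)) {
    stop("208 nm lies outside the spectrum's wavelength range (",
         min(mre$wavelength), "-", max(mre$wavelength), " nm)",
         call. = FALSE)
  }
  theta_208 <- stats::approx(mre$wavelength, mre$mre, xout = 208)$y
  percent <- (-theta_208 - 4000) / (33000 - 4000) * 100
  out <- list(percent = percent, theta_208 = theta_208,
              out_of_range = percent < 0 || percent > 100)
  class(out) <- "helicity_result"
  out
}

#' @export
print.helicity_result <- function(x, ...) {
  cat(sprintf("<helicity_result> %.1f%% alpha helix (theta_208 = %.0f)%s\n",
              x$percent, x$theta_208,
              if (x$out_of_range) " [OUT OF 0-100 RANGE]" else ""))
  invisible(x)
}

#' Difference spectrum relative to a reference
#'
#' Pointwise sample - reference, used to visualize adsorption-induced
#' secondary-structure changes against the natively folded protein. The
#' two spectra must share an identical wavelength grid; no implicit
#' resampling is performed.
#'
#' @param sample,reference [mre_spectrum] objects on the same grid.
#' @return An [mre_spectrum] of differences.
#' @export
difference_spectrum <- function(sample, reference) {
  stopifnot(inherits(sample, "mre_spectrum"),
            inherits(reference, "mre_spectrum"))
  if (length(sample$wavelength) != length(reference$wavelength) ||
      any(abs(sample$wavelength - reference$wavelength) > 1e-9)) {
    stop("sample and reference must share an identical wavelength grid",
         call. = FALSE)
  }
  out <- list(wavelength = sample$wavelength,
              mre = sample$mre - reference$mre)
  class(out) <- "mre_spectrum"
  out
}

#' Tryptophan emission spectrum
#'
#' @param wavelength Emission wavelengths in nm, ascending, within
#'   300-400 nm.
#' @param fluorescence Fluorescence intensity, arbitrary units.
#' @param background_corrected Logical flag recording whether a blank has
#'   already been subtracted.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, fluorescence,
                              background_corrected = FALSE) {
  wavelength <- as.numeric(wavelength)
  fluorescence <- as.numeric(fluorescence)
  if (length(wavelength) != length(fluorescence)) {
    stop("`wavelength` and `fluorescence` must have the same length",
         call. = FALSE)
  }
  if (length(wavelength) < 2 || is.unsorted(wavelength, strictly = TRUE)) {
    stop("`wavelength` must be ascending", call. = FALSE)
  }
  if (min(wavelength) < 300 - 1e-9 || max(wavelength) > 400 + 1e-9) {
    stop("`wavelength` must lie within 300-400 nm", call. = FALSE)
  }
  out <- list(wavelength = wavelength, fluorescence = fluorescence,
              background_corrected = isTRUE(background_corrected))
  class(out) <- "emission_spectrum"
  out
}

#' Background-subtracted, normalized tryptophan emission AUC
#'
#' Subtracts the blank pointwise, integrates the corrected emission band
#' over its wavelength range by the trapezoid rule, and, when a
#' folded-control AUC is supplied, reports the ratio to it. Quenching of
#' intrinsic tryptophan fluorescence (emission 300-400 nm, excitation
#' 280 nm) reports on loss of the native fold.
#'
#' @param spectrum An [emission_spectrum] of the sample.
#' @param blank An [emission_spectrum] of the matching protein-free blank,
#'   on the same wavelength grid.
#' @param folded_control_auc Optional positive AUC of the folded-protein
#'   control, used for normalization.
#' @return An object of class `quench_result`: list with `auc` and
#'   `normalized_auc` (NA when no control is supplied).
#' @export
#' @examples
#' wl <- 300:400
#' s <- emission_spectrum(wl, 100 * exp(-(wl - 340)^2 / 450) + 5)
#' b <- emission_spectrum(wl, rep(5, length(wl)))
#' quench_auc(s, b)
quench_auc <- function(spectrum, blank, folded_control_auc = NULL) {
  stopifnot(inherits(spectrum, "emission_spectrum"),
            inherits(blank, "emission_spectrum"))
  if (length(spectrum$wavelength) != length(blank$wavelength) ||
      any(abs(spectrum$wavelength - blank$wavelength) > 1e-9)) {
    stop("spectrum and blank must share a wavelength grid", call. = FALSE)
  }
  corrected <- spectrum$fluorescence - blank$fluorescence
  auc <- pracma::trapz(spectrum$wavelength, corrected)
  normalized <- NA_real_
  if (!is.null(folded_control_auc)) {
    if (!is.finite(folded_control_auc) || folded_control_auc <= 0) {
      stop("`folded_control_auc` must be positive", call. = FALSE)
    }
    normalized <- auc / folded_control_auc
  }
  out <- list(auc = auc, normalized_auc = normalized)
  class(out) <- "quench_result"
  out
}

#' Read a CD spectrum from CSV with a metadata header
#'
#' Expects `#`-prefixed `key: value` header lines (`path_cm`,
#' `conc_g_per_ml`, `n_residues`, `mw_da`) followed by two columns:
#' wavelength (nm) and observed ellipticity (mdeg).
#'
#' @param path Path to the file.
#' @return A [cd_spectrum].
#' @export
read_cd_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  need <- c("path_cm", "conc_g_per_ml")
  if (!all(need %in% names(meta))) {
    stop("header must declare ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.csv(text = body, header = FALSE)
  cd_spectrum(tab[[1]], tab[[2]],
              path_cm = meta$path_cm, conc_g_per_ml = meta$conc_g_per_ml,
              n_residues = meta$n_residues %||% 583,
              mw_da = meta$mw_da %||% 66430.3)
}

#' Write a CD spectrum to CSV with a metadata header
#'
#' @param spectrum A [cd_spectrum].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cd_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# path_cm: %g", spectrum$path_cm),
    sprintf("# conc_g_per_ml: %g", spectrum$conc_g_per_ml),
    sprintf("# n_residues: %g", spectrum$n_residues),
    sprintf("# mw_da: %g", spectrum$mw_da),
    "# wavelength_nm,theta_obs_mdeg"
  ), con)
  utils::write.table(
    data.frame(spectrum$wavelength, spectrum$theta_obs), con,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
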