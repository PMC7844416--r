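#' Proteolysis time course
#'
#' A t0-normalized intact-protein peak-area series: time in minutes
#' (ascending, starting at 0) against the AUC normalized to its value
#' before protease addition, so y at t = 0 is 1 by construction.
#'
#' @param t Times in minutes, ascending, `t[1] == 0`.
#' @param y Normalized peak areas, same length.
#' @param normalize If `TRUE` (default) divide `y` by `y[1]`.
#' @return An object of class `time_course` (data frame with `t`, `y`).
#' @export
time_course <- function(t, y, normalize = TRUE) {
  t <- as.numeric(t)
  y <- as.numeric(y)
  if (length(t) != length(y)) {
    stop("`t` and `y` must have the same length", call. = FALSE)
  }
  if (length(t) < 2 || is.unsorted(t, strictly = TRUE) || t[1] != 0) {
    stop("`t` must be ascending, starting at 0", call. = FALSE)
  }
  if (normalize) {
    if (!is.finite(y[1]) || y[1] <= 0) {
      stop("cannot t0-normalize: y at t = 0 must be positive",
           call. = FALSE)
    }
    y <- y / y[1]
  }
  df <- data.frame(t = t, y = y)
  class(df) <- c("time_course", "data.frame")
  df
}

#' One-phase exponential decay
#'
#' Plateau-offset form y(t) = y_plateau + (y0 - y_plateau) * exp(-k t):
#' the curve starts at `y0` and relaxes toward the asymptote `y_plateau`
#' with rate `k`. The alternative literal form
#' y(t) = (y0 - y_plateau) * exp(-k t), which decays to zero rather than
#' to the plateau, is available with `form = "literal"` for auditing; it
#' is not the default because only the offset form has an asymptote equal
#' to the plateau parameter.
#'
#' @param t Times (minutes).
#' @param y0 Value at t = 0.
#' @param y_plateau Asymptote.
#' @param k Rate constant, 1/min, > 0.
#' @param form `"offset"` (default) or `"literal"`.
#' @return y evaluated at `t`.
#' @export
#' @examples
#' one_phase_decay(c(0, 10, 120), y0 = 1, y_plateau = 0.2, k = 0.09)
one_phase_decay <- function(t, y0, y_plateau, k,
                            form = c("offset", "literal")) {
  form <- match.arg(form)
  if (!is.finite(k) || k <= 0) {
    stop("`k` must be positive", call. = FALSE)
  }
  if (form == "offset") {
    y_plateau + (y0 - y_plateau) * exp(-k * t)
  } else {
    (y0 - y_plateau) * exp(-k * t)
  }
}

#' One-phase association
#'
#' y(x) = y_start + (y_plateau - y_start) * (1 - exp(-k x)): rises (or
#' falls) from `y_start` at x = 0 toward `y_plateau`.
#'
#' @param x Abscissa values.
#' @param y_start Value at x = 0.
#' @param y_plateau Asymptote.
#' @param k Rate constant, inverse x-units, > 0.
#' @return y evaluated at `x`.
#' @export
one_phase_association <- function(x, y_start, y_plateau, k) {
  if (!is.finite(k) || k <= 0) {
    stop("`k` must be positive", call. = FALSE)
  }
  y_start + (y_plateau - y_start) * (1 - exp(-k * x))
}

# shared exponential fitting engine: plateau-offset decay parameterized by
# (y0, y_plateau, log k), seeded multi-start over perturbed rate guesses
fit_exponential <- function(x, y, y0_init, yp_init, k_init,
                            max_iter = 200) {
  resid_fn <- function(par) {
    y - (par[2] + (par[1] - par[2]) * exp(-exp(par[3]) * x))
  }
  k_factors <- c(1, 0.5, 2, 0.25, 4)
  best <- NULL
  for (f in k_factors) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = c(y0_init, yp_init, log(k_init * f)), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("exponential fit failed from every start", call. = FALSE)
  }
  best
}

#' Fit a one-phase decay to a proteolysis time course
#'
#' Least-squares fit of the plateau-offset decay
#' y = y_plateau + (y0 - y_plateau) exp(-k t) by Levenberg-Marquardt,
#' with a seeded multi-start over perturbed rate initializations (5
#' starts, best residual sum of squares kept) to avoid local minima.
#' Default initialization: y0 = y at t = 0, y_plateau = min(y),
#' k = ln 2 / median(t > 0).
#'
#' @param tc A [time_course].
#' @param y0_init,yp_init,k_init Optional initial guesses.
#' @return An object of class `decay_fit`: list with `y0`, `y_plateau`,
#'   `k` (1/min), `r2`, `converged`, `degenerate` (TRUE when the series
#'   shows no resolvable decay or the rate ran to an extreme), `fitted`.
#' @export
#' @examples
#' tc <- gen_proteolysis_timecourse(k = 0.31, y_plateau = 0.1, seed = 1,
#'                                  noise_rel = 0)
#' fit_decay(tc)$k
fit_decay <- function(tc, y0_init = NULL, yp_init = NULL, k_init = NULL) {
  stopifnot(inherits(tc, "time_course"))
  if (nrow(tc) < 4) {
    stop("at least 4 timepoints are required", call. = FALSE)
  }
  t <- tc$t
  y <- tc$y
  y0_init <- y0_init %||% y[1]
  yp_init <- yp_init %||% min(y)
  k_init <- k_init %||% (log(2) / max(stats::median(t[t > 0]), .Machine$double.eps))

  degenerate <- FALSE
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    # constant series: no decay to resolve
    out <- list(y0 = y[1], y_plateau = y[1], k = NA_real_, r2 = NA_real_,
                converged = TRUE, degenerate = TRUE, fitted = y)
    class(out) <- "decay_fit"
    return(out)
  }

  best <- fit_exponential(t, y, y0_init, yp_init, k_init)
  k_hat <- exp(best$par[3])
  # a rate slower than resolvable over the sampled span, or so fast the
  # decay completes before the first positive timepoint, is unidentifiable
  span <- diff(range(t[t > 0]))
  if (k_hat * span < 1e-6 || k_hat * min(t[t > 0]) > 20) {
    degenerate <- TRUE
    warning("fitted rate ran to an extreme; series may not resolve a decay",
            call. = FALSE)
  }
  converged <- best$info %in% 1:3
  if (!converged) {
    warning("decay fit did not converge: ", best$message, call. = FALSE)
  }
  fitted <- y - best$fvec
  ss_tot <- sum((y - mean(y))^2)
  out <- list(y0 = best$par[1], y_plateau = best$par[2], k = k_hat,
              r2 = 1 - best$deviance / ss_tot,
              converged = converged, degenerate = degenerate,
              fitted = fitted)
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> k = %.4g /min, y0 = %.4g, plateau = %.4g, r2 = %.4f%s\n",
    x$k, x$y0, x$y_plateau, x$r2,
    if (x$degenerate) " [DEGENERATE]" else ""
  ))
  invisible(x)
}

#' Fit a one-phase association or exponential decay to (x, y) data
#'
#' Used for saturating calibration-like relationships such as zeta
#' potential versus adsorbed protein. `direction = "associate"` fits
#' y = y_start + (y_plateau - y_start)(1 - exp(-k x));
#' `direction = "decay"` fits the plateau-offset exponential decay. Both
#' use the same Levenberg-Marquardt multi-start engine as [fit_decay].
#'
#' @param x,y Paired numeric vectors, at least 4 points.
#' @param direction `"associate"` or `"decay"`.
#' @return An object of class `association_fit`: list with `y_start`,
#'   `y_plateau`, `k`, `r2`, `converged`, `fitted`, `direction`.
#' @export
fit_association <- function(x, y, direction = c("associate", "decay")) {
  direction <- match.arg(direction)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 4) {
    stop("need at least 4 paired points", call. = FALSE)
  }
  # both directions are the same two-endpoint exponential family:
  # value y_start at x = 0 relaxing toward y_plateau
  i0 <- which.min(x)
  y_start_init <- y[i0]
  yp_init <- if (direction == "associate") y[which.max(x)] else min(y)
  k_init <- log(2) / max(stats::median(x[x > 0]), .Machine$double.eps)
  best <- fit_exponential(x, y, y_start_init, yp_init, k_init)
  converged <- best$info %in% 1:3
  if (!converged) {
    warning("association fit did not converge: ", best$message,
            call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  out <- list(y_start = best$par[1], y_plateau = best$par[2],
              k = exp(best$par[3]),
              r2 = 1 - best$deviance / ss_tot,
              converged = converged, fitted = y - best$fvec,
              direction = direction)
  class(out) <- "association_fit"
  out
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf(
    "<association_fit:%s> start = %.4g, plateau = %.4g, k = %.4g, r2 = %.4f\n",
    x$direction, x$y_start, x$y_plateau, x$k, x$r2
  ))
  invisible(x)
}

#' Linear calibration curve
#'
#' Ordinary least squares fit of instrument response against standard
#' concentrations, e.g. a fluorescence or absorbance dilution series.
#'
#' @param standards_x Standard concentrations (>= 3 values).
#' @param standards_y Measured responses.
#' @param x_units,y_units Optional unit labels carried in the result.
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r2`, `n`, `x_units`, `y_units`.
#' @export
#' @examples
#' cal <- fit_calibration(c(0, 10, 25, 50, 100), c(2, 1002, 2502, 5002, 10002))
#' invert_calibration(cal, 2502)
fit_calibration <- function(standards_x, standards_y,
                            x_units = "", y_units = "") {
  x <- as.numeric(standards_x)
  y <- as.numeric(standards_y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("at least 3 standards are required", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  out <- list(slope = stats::coef(fit)[[2]],
              intercept = stats::coef(fit)[[1]],
              r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
              n = length(x), x_units = x_units, y_units = y_units)
  class(out) <- "calibration_curve"
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> y = %.4g x + %.4g (r2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r2, x$n
  ))
  invisible(x)
}

#' Invert a calibration curve
#'
#' x = (y - intercept) / slope. Readings that invert to a negative
#' concentration (below-intercept extrapolation) are returned as-is with
#' an `extrapolated` attribute flagging them.
#'
#' @param curve A [fit_calibration] result.
#' @param y Measured response(s).
#' @return Concentration(s), with attribute `extrapolated` (logical
#'   vector, TRUE where the inverted value is negative).
#' @export
invert_calibration <- function(curve, y) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) ||
      abs(curve$slope) < 1e-12 * max(abs(curve$intercept), 1)) {
    stop("calibration slope is zero; cannot invert", call. = FALSE)
  }
  x <- (as.numeric(y) - curve$intercept) / curve$slope
  attr(x, "extrapolated") <- x < 0
  x
}

#' Encapsulation efficiency
#'
#' EE = (M_i - M_u) / M_i * 100: the percentage of offered cargo mass
#' that ended up encapsulated, from the input mass and the mass recovered
#' unencapsulated.
#'
#' @param m_input Cargo mass offered, micrograms, > 0.
#' @param m_unencapsulated Unencapsulated cargo mass, micrograms, >= 0.
#' @return An object of class `loading_result`: list with `m_input`,
#'   `m_unencapsulated`, `ee_percent`.
#' @export
#' @examples
#' encapsulation_efficiency(375, 243.75) # 35%
encapsulation_efficiency <- function(m_input, m_unencapsulated) {
  if (!is.finite(m_input) || m_input <= 0) {
    stop("`m_input` must be positive", call. = FALSE)
  }
  if (!is.finite(m_unencapsulated) || m_unencapsulated < 0) {
    stop("`m_unencapsulated` must be non-negative", call. = FALSE)
  }
  out <- list(m_input = m_input, m_unencapsulated = m_unencapsulated,
              ee_percent = (m_input - m_unencapsulated) / m_input * 100)
  class(out) <- "loading_result"
  out
}

#' Adsorbed protein concentration by supernatant subtraction
#'
#' adsorbed = input - supernatant: the protein unaccounted for in the
#' supernatant after pelleting nanocarrier-protein complexes is taken as
#' adsorbed. A negative difference (supernatant reading above the input)
#' is reported as-is and flagged, never raised as an error.
#'
#' @param input_conc Input protein concentration, mg/mL, > 0.
#' @param supernatant_conc Supernatant concentration, mg/mL.
#' @return An object of class `adsorption_measurement`: list with
#'   `input_conc`, `supernatant_conc`, `adsorbed_conc`, `negative_flag`.
#' @export
adsorbed_from_supernatant <- function(input_conc, supernatant_conc) {
  if (!is.finite(input_conc) || input_conc <= 0) {
    stop("`input_conc` must be positive", call. = FALSE)
  }
  adsorbed <- input_conc - supernatant_conc
  out <- list(input_conc = input_conc,
              supernatant_conc = supernatant_conc,
              adsorbed_conc = adsorbed,
              negative_flag = adsorbed < 0)
  class(out) <- "adsorption_measurement"
  out
}

#' Percent decrease between two measurements
#'
#' (pre - post) / pre * 100, e.g. the loss of pre-adsorbed labeled
#' protein after exchange with serum.
#'
#' @param pre Measurement before, > 0.
#' @param post Measurement after.
#' @return Percent decrease.
#' @export
percent_decrease <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0)) {
    stop("`pre` must be positive", call. = FALSE)
  }
  (pre - post) / pre * 100
}
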