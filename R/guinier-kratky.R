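#' Guinier estimate of the radius of gyration
#'
#' Fits the low-q Guinier law ln I(q) = ln I0 - q^2 Rg^2 / 3 by ordinary
#' least squares, selecting the fitting window iteratively: starting from
#' the lowest-q points, the window is updated to all points satisfying
#' q * Rg <= qmax_Rg with the current Rg estimate, until the window is
#' stable. The default bound q * Rg <= 1.3 is standard practice for
#' compact globular particles.
#'
#' @param profile A [scattering_profile]. Non-positive intensities are
#'   excluded before taking logs.
#' @param qmax_Rg Upper bound on q * Rg for points entering the fit.
#' @param min_points Minimum number of points the window must retain.
#' @return An object of class `guinier_fit`: list with `Rg` (Angstrom),
#'   `I0` (forward intensity), `qmax_Rg`, `n_window` and `window` (indices
#'   of fitted points).
#' @export
#' @examples
#' prof <- gen_globule_profile(Rg = 30, kind = "guinier", seed = 1,
#'                             noise_rel = 0)
#' guinier_fit(prof)$Rg
guinier_fit <- function(profile, qmax_Rg = 1.3, min_points = 5) {
  stopifnot(inherits(profile, "scattering_profile"))
  ok <- which(profile$intensity > 0)
  if (length(ok) < min_points) {
    stop("fewer than ", min_points, " points with positive intensity",
         call. = FALSE)
  }
  q <- profile$q[ok]
  logI <- log(profile$intensity[ok])

  fit_window <- function(idx) {
    co <- stats::coef(stats::lm(logI[idx] ~ I(q[idx]^2)))
    list(logI0 = co[[1]], slope = co[[2]])
  }

  # seed with the lowest-q fifth of the curve (at least min_points)
  idx <- seq_len(max(min_points, ceiling(length(q) / 5)))
  seen <- list()
  for (iter in seq_len(100)) {
    f <- fit_window(idx)
    if (f$slope >= 0) {
      # no decay visible: shrink from the high-q end and retry
      if (length(idx) <= min_points) {
        stop("no Guinier window with a negative slope and at least ",
             min_points, " points (bound q*Rg <= ", qmax_Rg, ")",
             call. = FALSE)
      }
      idx <- idx[seq_len(length(idx) - max(1, length(idx) %/% 5))]
      next
    }
    Rg <- sqrt(-3 * f$slope)
    new_idx <- which(q * Rg <= qmax_Rg)
    if (length(new_idx) < min_points) {
      stop("no window with at least ", min_points,
           " points satisfies q*Rg <= ", qmax_Rg, call. = FALSE)
    }
    if (identical(new_idx, idx)) break
    key <- paste(range(new_idx), collapse = ":")
    if (key %in% seen) break # window cycling: accept current estimate
    seen <- c(seen, key)
    idx <- new_idx
  }
  f <- fit_window(idx)
  if (f$slope >= 0) {
    stop("Guinier fit failed: non-negative slope in the final window",
         call. = FALSE)
  }
  out <- list(Rg = sqrt(-3 * f$slope), I0 = exp(f$logI0),
              qmax_Rg = qmax_Rg, n_window = length(idx),
              window = ok[idx])
  class(out) <- "guinier_fit"
  out
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> Rg = %.2f A, I0 = %.4g (%d points, q*Rg <= %.2f)\n",
    x$Rg, x$I0, x$n_window, x$qmax_Rg
  ))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Converts a scattering profile to the dimensionless Kratky form
#' v = (q Rg)^2 I(q) / I0 against u = q Rg, normalized by the
#' Guinier-estimated radius of gyration and forward intensity. Compact
#' globular particles that obey the Guinier approximation peak at
#' (sqrt(3), 3/e ~ 1.104) regardless of size or concentration; flexible
#' chains instead plateau at large u. The peak is located by parabolic
#' interpolation through the grid maximum and its two neighbours.
#'
#' @param profile A [scattering_profile].
#' @param guinier A [guinier_fit] for the same profile.
#' @return An object of class `kratky_curve`: list with vectors `u`, `v`
#'   and scalars `peak_u`, `peak_v`.
#' @export
#' @examples
#' prof <- gen_globule_profile(Rg = 30, kind = "guinier", seed = 1,
#'                             noise_rel = 0, n_points = 500)
#' k <- dimensionless_kratky(prof, guinier_fit(prof))
#' c(k$peak_u, k$peak_v) # ~ (sqrt(3), 3/e)
dimensionless_kratky <- function(profile, guinier) {
  stopifnot(inherits(profile, "scattering_profile"),
            inherits(guinier, "guinier_fit"))
  if (!is.finite(guinier$I0) || guinier$I0 <= 0) {
    stop("`guinier$I0` must be positive", call. = FALSE)
  }
  u <- profile$q * guinier$Rg
  v <- u^2 * profile$intensity / guinier$I0
  i <- which.max(v)
  if (i > 1 && i < length(u)) {
    pk <- parabolic_peak(u[(i - 1):(i + 1)], v[(i - 1):(i + 1)])
  } else {
    pk <- c(u[i], v[i])
  }
  out <- list(u = u, v = v, peak_u = pk[[1]], peak_v = pk[[2]])
  class(out) <- "kratky_curve"
  out
}

#' @export
print.kratky_curve <- function(x, ...) {
  cat(sprintf("<kratky_curve> %d points, peak at u = %.4f, v = %.4f\n",
              length(x$u), x$peak_u, x$peak_v))
  invisible(x)
}

# vertex of the parabola through three (not necessarily equispaced) points
parabolic_peak <- function(x, y) {
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  a <- co[[3]]
  if (!is.finite(a) || a >= 0) {
    i <- which.max(y)
    return(c(x[i], y[i]))
  }
  xv <- -co[[2]] / (2 * a)
  # keep the vertex inside the bracketing interval
  xv <- min(max(xv, x[1]), x[3])
  c(xv, co[[1]] + co[[2]] * xv + a * xv^2)
}
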