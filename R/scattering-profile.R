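#' 1D scattering profile
#'
#' Container for a reduced small-angle scattering curve: momentum transfer
#' `q` (inverse Angstrom), scattered intensity (arbitrary units or 1/cm) and,
#' optionally, a per-point standard deviation on the intensity.
#'
#' @param q Numeric vector of momentum transfer values, strictly increasing
#'   and positive, in inverse Angstrom.
#' @param intensity Numeric vector of scattered intensities, same length as
#'   `q`, finite.
#' @param uncertainty Optional numeric vector of per-point standard
#'   deviations (same units as `intensity`), strictly positive.
#'
#' @return An object of class `scattering_profile`: a data frame with
#'   columns `q`, `intensity` and (when supplied) `uncertainty`.
#' @export
#' @examples
#' q <- 10^seq(-3, log10(0.5), length.out = 50)
#' scattering_profile(q, exp(-q^2 * 300))
scattering_profile <- function(q, intensity, uncertainty = NULL) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) {
    stop("`q` and `intensity` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("`q` must be finite and strictly positive", call. = FALSE)
  }
  if (is.unsorted(q, strictly = TRUE)) {
    stop("`q` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("`intensity` must be finite", call. = FALSE)
  }
  df <- data.frame(q = q, intensity = intensity)
  if (!is.null(uncertainty)) {
    uncertainty <- as.numeric(uncertainty)
    if (length(uncertainty) != length(q)) {
      stop("`uncertainty` must match the length of `q`", call. = FALSE)
    }
    if (any(!is.finite(uncertainty)) || any(uncertainty <= 0)) {
      stop("`uncertainty` must be finite and strictly positive",
           call. = FALSE)
    }
    df$uncertainty <- uncertainty
  }
  class(df) <- c("scattering_profile", "data.frame")
  df
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf(
    "<scattering_profile> %d points, q in [%.4g, %.4g] A^-1%s\n",
    nrow(x), min(x$q), max(x$q),
    if ("uncertainty" %in% names(x)) ", with uncertainties" else ""
  ))
  invisible(x)
}

#' Read a scattering profile from a delimited text file
#'
#' Accepts the common 2- or 3-column plain-text exchange format for reduced
#' SAXS curves: columns `q`, `I` and optionally `sigma`, separated by
#' whitespace or commas, with comment lines starting with `#`.
#'
#' @param path Path to the file.
#' @return A [scattering_profile].
#' @export
read_scattering_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("no data rows in ", path, call. = FALSE)
  }
  sep <- if (grepl(",", lines[[1]])) "," else ""
  tab <- utils::read.table(text = lines, sep = sep, header = FALSE,
                           strip.white = TRUE)
  if (ncol(tab) < 2) {
    stop("expected at least two columns (q, intensity) in ", path,
         call. = FALSE)
  }
  scattering_profile(tab[[1]], tab[[2]],
                     uncertainty = if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' Write a scattering profile to a delimited text file
#'
#' @param profile A [scattering_profile].
#' @param path Output path; columns are comma separated with a `#` header.
#' @return `path`, invisibly.
#' @export
write_scattering_profile <- function(profile, path) {
  stopifnot(inherits(profile, "scattering_profile"))
  hdr <- paste0("# q,intensity",
                if ("uncertainty" %in% names(profile)) ",uncertainty" else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(profile), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
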