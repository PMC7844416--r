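#' Cross-assay Pearson correlation with linear regression
#'
#' Pearson correlation coefficient with its two-sided t-transform
#' p-value, together with the ordinary least squares line and 95%
#' confidence intervals on slope and intercept -- the standard way to
#' relate pairs of structural metrics (e.g. proteolysis rate versus
#' normalized tryptophan fluorescence) across conditions.
#'
#' @param x,y Paired finite numeric vectors, n >= 3, each with non-zero
#'   variance.
#' @param names Optional length-2 character vector naming the variables.
#' @return An object of class `correlation_report`: list with
#'   `pearson_r`, `p_value`, `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci` (95% intervals), `n`, `names`.
#' @export
#' @examples
#' correlate_assays(1:10, 2 * (1:10) + 1)
correlate_assays <- function(x, y, names = c("x", "y")) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must be paired", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("at least 3 pairs are required", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in `", names[if (stats::sd(x) == 0) 1 else 2],
         "`; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  # exact linear inputs trigger a benign "essentially perfect fit" notice
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  out <- list(
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    slope = stats::coef(fit)[[2]],
    intercept = stats::coef(fit)[[1]],
    slope_ci = unname(ci["x", ]),
    intercept_ci = unname(ci["(Intercept)", ]),
    n = length(x),
    names = names
  )
  class(out) <- "correlation_report"
  out
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "<correlation_report> %s vs %s: r = %.3f (p = %.3g, n = %d)\n",
    x$names[1], x$names[2], x$pearson_r, x$p_value, x$n
  ))
  cat(sprintf("  fit: y = %.4g x + %.4g; 95%% CI slope [%.4g, %.4g]\n",
              x$slope, x$intercept, x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Run the protein-structure assay panel across conditions
#'
#' Computes, for each experimental condition, the full set of structural
#' metrics the pipeline produces: alpha-helicity from the CD spectrum,
#' background-subtracted tryptophan AUC normalized to a folded-protein
#' reference, the apparent proteolysis rate from the time course, and
#' the dimensionless Kratky peak from the scattering profile. Assays a
#' condition does not provide are left `NA`, never imputed. Per-assay
#' failures are caught, recorded, and do not abort the remaining panel.
#'
#' @param conditions Named list; each element is a list with any of:
#'   * `cd`: a [cd_spectrum];
#'   * `trp`: a list with `spectrum` and `blank` ([emission_spectrum]s);
#'   * `timecourse`: a [time_course];
#'   * `saxs`: a [scattering_profile].
#' @param trp_reference Name of the condition whose tryptophan AUC
#'   serves as the folded control for normalization; defaults to the
#'   first condition providing a `trp` assay.
#' @return A data frame with one row per condition and columns
#'   `condition`, `helicity_pct`, `trp_auc`, `trp_auc_norm`,
#'   `proteolysis_k`, `proteolysis_r2`, `kratky_peak_u`,
#'   `kratky_peak_v`. Collected error messages, if any, are attached as
#'   attribute `errors` (named character vector).
#' @export
run_structure_panel <- function(conditions, trp_reference = NULL) {
  if (!is.list(conditions) || length(conditions) == 0 ||
      is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("`conditions` must be a non-empty named list", call. = FALSE)
  }
  errors <- character(0)
  note <- function(cond, assay, e) {
    errors[[paste(cond, assay, sep = "/")]] <<- conditionMessage(e)
    NULL
  }

  # tryptophan AUCs first, so the reference is available for all rows
  aucs <- vapply(names(conditions), function(nm) {
    trp <- conditions[[nm]]$trp
    if (is.null(trp)) return(NA_real_)
    res <- tryCatch(quench_auc(trp$spectrum, trp$blank),
                    error = function(e) note(nm, "trp", e))
    if (is.null(res)) NA_real_ else res$auc
  }, numeric(1))
  trp_reference <- trp_reference %||%
    names(conditions)[which(!is.na(aucs))[1]]
  ref_auc <- if (!is.null(trp_reference) && !is.na(trp_reference)) {
    aucs[[trp_reference]]
  } else {
    NA_real_
  }

  rows <- lapply(names(conditions), function(nm) {
    cond <- conditions[[nm]]
    helicity <- NA_real_
    if (!is.null(cond$cd)) {
      h <- tryCatch(helicity_from_mre208(mre_spectrum(cond$cd)),
                    error = function(e) note(nm, "cd", e))
      if (!is.null(h)) helicity <- h$percent
    }
    k <- r2 <- NA_real_
    if (!is.null(cond$timecourse)) {
      d <- tryCatch(fit_decay(cond$timecourse),
                    error = function(e) note(nm, "timecourse", e))
      if (!is.null(d)) {
        k <- d$k
        r2 <- d$r2
      }
    }
    pk_u <- pk_v <- NA_real_
    if (!is.null(cond$saxs)) {
      kr <- tryCatch({
        g <- guinier_fit(cond$saxs)
        dimensionless_kratky(cond$saxs, g)
      }, error = function(e) note(nm, "saxs", e))
      if (!is.null(kr)) {
        pk_u <- kr$peak_u
        pk_v <- kr$peak_v
      }
    }
    data.frame(
      condition = nm,
      helicity_pct = helicity,
      trp_auc = aucs[[nm]],
      trp_auc_norm = if (is.na(ref_auc) || ref_auc <= 0) NA_real_
                     else aucs[[nm]] / ref_auc,
      proteolysis_k = k,
      proteolysis_r2 = r2,
      kratky_peak_u = pk_u,
      kratky_peak_v = pk_v,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(errors) > 0) attr(out, "errors") <- errors
  out
}
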