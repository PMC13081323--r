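# ECBF correction of thermodilution EVLWI.
#
# Veno-venous ECMO recirculates the thermal indicator through the
# extracorporeal circuit, inflating thermodilution EVLWI roughly in
# proportion to extracorporeal blood flow (ECBF).  Regressing bedside
# EVLWI_TPTD on the CT reference and ECBF gives the per-litre inflation
# (the correction factor); subtracting factor * ECBF yields the corrected
# bedside estimate.

#' Fit the ECBF correction model
#'
#' Ordinary least squares of `evlwi_tptd` on an intercept, `evlwi_ct` and
#' `ecbf`.  The ECBF coefficient is the correction factor (ml/kg inflation
#' of bedside EVLWI per l/min of extracorporeal flow).
#'
#' @param cohort data.frame with numeric columns `evlwi_ct`, `evlwi_tptd`,
#'   `ecbf`; at least 3 complete rows; neither predictor constant.
#' @return an object of class `correction_model`: `intercept` (ml/kg),
#'   `slope_ct`, `correction_factor` (ml/kg per l/min), `residual_sd`
#'   (ml/kg, n-3 degrees of freedom), `n`.
#' @export
fit_correction_model <- function(cohort) {
  need <- c("evlwi_ct", "evlwi_tptd", "ecbf")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    lw_validation_error("cohort is missing column(s): %s",
                        paste(miss, collapse = ", "))
  d <- cohort[need]
  if (!all(vapply(d, is.numeric, logical(1))))
    lw_validation_error("evlwi_ct, evlwi_tptd and ecbf must be numeric")
  if (anyNA(d))
    lw_validation_error("cohort has missing EVLWI/ECBF values; rows are not imputed")
  n <- nrow(d)
  if (n < 3L)
    lw_validation_error("need at least 3 complete rows to fit 3 coefficients (got %d)", n)
  if (stats::var(d$ecbf) == 0)
    lw_error("lungwater_identifiability_error",
             "ECBF is constant across rows: correction factor unidentifiable")
  if (stats::var(d$evlwi_ct) == 0)
    lw_error("lungwater_identifiability_error",
             "EVLWI_CT is constant across rows: slope unidentifiable")
  fit <- stats::lm(evlwi_tptd ~ evlwi_ct + ecbf, data = d)
  co <- stats::coef(fit)
  if (anyNA(co))
    lw_error("lungwater_identifiability_error",
             "rank-deficient design: coefficients unidentifiable")
  rsd <- if (n > 3L) sqrt(sum(stats::residuals(fit)^2) / (n - 3L)) else 0
  structure(list(
    intercept = unname(co[1]),
    slope_ct = unname(co["evlwi_ct"]),
    correction_factor = unname(co["ecbf"]),
    residual_sd = rsd,
    n = n
  ), class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(paste0(
    "ECBF correction model (n = %d)\n",
    "  EVLWI_TPTD = %.4f + %.4f x EVLWI_CT + %.4f x ECBF\n",
    "  correction factor : %.4f ml/kg per l/min\n",
    "  residual SD       : %.3f ml/kg\n"),
    x$n, x$intercept, x$slope_ct, x$correction_factor,
    x$correction_factor, x$residual_sd))
  invisible(x)
}

#' Apply the ECBF correction at bedside
#'
#' `EVLWI_TPTDcorr = EVLWI_TPTD - correction_factor * ECBF`.  Only the ECBF
#' coefficient is applied; intercept and CT slope are reported by the model
#' but do not enter the bedside correction.
#'
#' @param evlwi_tptd thermodilution EVLWI, ml/kg (vectorised).
#' @param ecbf extracorporeal blood flow, l/min; must be >= 0.
#' @param correction_factor ml/kg per l/min.
#' @return corrected EVLWI, ml/kg.
#' @export
apply_correction <- function(evlwi_tptd, ecbf, correction_factor) {
  if (any(!is.finite(ecbf)) || any(ecbf < 0))
    lw_validation_error("ecbf must be finite and >= 0")
  evlwi_tptd - correction_factor * ecbf
}

#' Correct a whole cohort
#'
#' Adds an `evlwi_tptd_corr` column computed per row with
#' [apply_correction()]; original columns are untouched.
#'
#' @param cohort data.frame with `evlwi_tptd` and `ecbf` columns.
#' @param model a `correction_model` (or a bare numeric correction factor).
#' @return the cohort with an added `evlwi_tptd_corr` column.
#' @export
correct_cohort <- function(cohort, model) {
  factor <- if (inherits(model, "correction_model")) model$correction_factor
            else as.numeric(model)
  if (nrow(cohort) == 0L) {
    cohort$evlwi_tptd_corr <- numeric(0)
    return(cohort)
  }
  miss <- setdiff(c("evlwi_tptd", "ecbf"), names(cohort))
  if (length(miss))
    lw_validation_error("cohort is missing column(s): %s",
                        paste(miss, collapse = ", "))
  if (anyNA(cohort$evlwi_tptd) || anyNA(cohort$ecbf))
    lw_validation_error("cohort has missing EVLWI_TPTD/ECBF values")
  cohort$evlwi_tptd_corr <- apply_correction(cohort$evlwi_tptd, cohort$ecbf, factor)
  cohort
}

#' Persist a correction model as flat key=value text
#'
#' Coefficients are written with full double precision (hex float alongside
#' decimal) so the round-trip is bit exact.
#'
#' @param model a `correction_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "correction_model"))
  num <- function(x) sprintf("%s", format(x, digits = 22))
  lines <- c(
    sprintf("intercept=%s", num(model$intercept)),
    sprintf("intercept_hex=%a", model$intercept),
    sprintf("slope_ct=%s", num(model$slope_ct)),
    sprintf("slope_ct_hex=%a", model$slope_ct),
    sprintf("correction_factor=%s", num(model$correction_factor)),
    sprintf("correction_factor_hex=%a", model$correction_factor),
    sprintf("residual_sd=%s", num(model$residual_sd)),
    sprintf("residual_sd_hex=%a", model$residual_sd),
    sprintf("n=%d", model$n),
    sprintf("fit_date=%s", format(Sys.Date()))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a persisted correction model
#'
#' @param path file written by [write_model()].
#' @return a `correction_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) lw_format_error("model file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) < 2L
  if (any(bad)) lw_format_error("malformed model file line: '%s'",
                                lines[which(bad)[1]])
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  get_num <- function(k) {
    hx <- vals[match(paste0(k, "_hex"), keys)]
    if (!is.na(hx)) return(strtoi_hexdouble(hx))
    v <- vals[match(k, keys)]
    if (is.na(v)) lw_format_error("model file missing key '%s'", k)
    as.numeric(v)
  }
  structure(list(
    intercept = get_num("intercept"),
    slope_ct = get_num("slope_ct"),
    correction_factor = get_num("correction_factor"),
    residual_sd = get_num("residual_sd"),
    n = as.integer(vals[match("n", keys)])
  ), class = "correction_model")
}

# parse C99 hex-float literals ("%a" output); base R scan() handles them
strtoi_hexdouble <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  if (is.na(out)) lw_format_error("cannot parse hex float '%s'", s)
  out
}
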