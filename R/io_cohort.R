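# Cohort CSV I/O and the flat key=value run configuration.

COHORT_NUMERIC <- c("evlwi_ct", "evlwi_tptd", "ecbf", "height_m")
COHORT_REQUIRED <- c("patient_id", COHORT_NUMERIC, "sex")

#' Read a patient cohort CSV
#'
#' Expected header: `patient_id, evlwi_ct, evlwi_tptd, ecbf, height_m, sex`
#' with optional `time_offset_h` (hours between CT and thermodilution) and
#' `evlwi_tptd_corr`.  Comment lines start with `#`.  Duplicate patient ids
#' are rejected (one scan per patient); non-numeric values are reported with
#' their line number.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) lw_format_error("cohort file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", colClasses = "character",
                    check.names = FALSE, strip.white = TRUE),
    error = function(e) lw_format_error("cannot parse CSV %s: %s",
                                        path, conditionMessage(e)))
  miss <- setdiff(COHORT_REQUIRED, names(df))
  if (length(miss))
    lw_format_error("cohort CSV missing column(s): %s",
                    paste(miss, collapse = ", "))
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup))
    lw_validation_error("duplicated patient_id: %s (one scan per patient)",
                        paste(unique(dup), collapse = ", "))
  numcols <- intersect(c(COHORT_NUMERIC, "time_offset_h", "evlwi_tptd_corr"),
                       names(df))
  for (col in numcols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad))
      lw_validation_error("non-numeric %s value '%s' at data row %d of %s",
                          col, df[[col]][bad[1]], bad[1], path)
    df[[col]] <- v
  }
  if (any(!is.na(df$ecbf) & df$ecbf < 0))
    lw_validation_error("negative ECBF in %s", path)
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex))
    lw_validation_error("sex must be male/female, got: %s",
                        paste(bad_sex, collapse = ", "))
  df
}

#' Write a patient cohort CSV
#'
#' Full double precision (17 significant digits), decimal point, UTF-8.
#'
#' @param cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Default run configuration
#'
#' @return list of defaults: HU window \[-700, 200\], IBW rule `pbw`,
#'   difference direction `reference_minus_test` (fixed), alpha 0.05,
#'   power 0.80, seed 1, log level `info`.
#' @export
default_config <- function() {
  list(hu_window_lower = -700, hu_window_upper = 200,
       ibw_rule = "pbw", diff_direction = "reference_minus_test",
       alpha = 0.05, power = 0.80, seed = 1L, log_level = "info")
}

#' Write a run configuration as flat key=value text
#'
#' Numeric values are written with 17 significant digits so doubles
#' round-trip bit-exactly.
#'
#' @param config list as from [default_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.integer(v)) sprintf("%d", v)
    else if (is.numeric(v)) sprintf("%.17g", v)
    else as.character(v)
  }
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' Read a run configuration
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#'
#' @param path key=value file.
#' @return config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) lw_format_error("config file not found: %s", path)
  def <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) lw_format_error("malformed config line '%s'", ln)
    key <- substr(ln, 1, eq - 1); val <- substr(ln, eq + 1, nchar(ln))
    if (!key %in% names(def))
      lw_format_error("unknown config key '%s'", key)
    def[[key]] <- if (is.integer(def[[key]])) as.integer(val)
                  else if (is.numeric(def[[key]])) as.numeric(val)
                  else val
  }
  if (!identical(def$diff_direction, "reference_minus_test"))
    lw_validation_error("diff_direction is fixed as reference_minus_test")
  def
}
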