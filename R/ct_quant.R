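# CT densitometry: EVLWI from an HU volume plus a lung mask.
#
# A voxel of lung parenchyma at HU h has tissue (water-equivalent) density
# 1 + h/1000 g/ml (air = -1000 HU -> 0, water = 0 HU -> 1).  Lung weight is
# the sum of per-voxel tissue weights over the edema HU window; excess weight
# over the height-predicted normal lung, indexed to ideal body weight, is the
# CT estimate of extravascular lung water.

#' CT volume in Hounsfield units
#'
#' Container for a 3-D CT attenuation array with its voxel spacing.
#'
#' @param hu 3-D numeric array of Hounsfield units.
#' @param spacing numeric vector of 3 voxel edge lengths in millimetres.
#' @return an object of class `ct_volume` with elements `hu` and `spacing`.
#' @examples
#' v <- ct_volume(array(-500, c(4, 4, 4)), spacing = c(1, 1, 1))
#' @export
ct_volume <- function(hu, spacing) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    lw_validation_error("'hu' must be a 3-D array (got rank %d)",
                        length(dim(hu) %||% dim(as.array(hu))))
  if (!all(is.finite(hu)))
    lw_validation_error("HU values must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    lw_validation_error("'spacing' must be 3 positive finite values (mm)")
  structure(list(hu = hu, spacing = spacing), class = "ct_volume")
}

#' Binary lung mask
#'
#' @param mask 3-D array of 0/1 (logical or numeric).
#' @param spacing numeric vector of 3 voxel edge lengths in millimetres.
#' @return an object of class `lung_mask` with elements `mask` (logical array)
#'   and `spacing`.
#' @export
lung_mask <- function(mask, spacing) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    lw_validation_error("'mask' must be a 3-D array")
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1)))
      lw_validation_error("mask values must be 0 or 1")
    mask <- array(mask == 1, dim(mask))
  }
  if (!is.logical(mask)) lw_validation_error("mask must be logical or 0/1 numeric")
  if (anyNA(mask)) lw_validation_error("mask must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    lw_validation_error("'spacing' must be 3 positive finite values (mm)")
  structure(list(mask = mask, spacing = spacing), class = "lung_mask")
}

#' Edema HU window
#'
#' Inclusive Hounsfield-unit interval taken to represent edematous lung
#' tissue.  The default, -700 to 200 HU, excludes hyperaerated voxels below
#' and contrast agent (> 200 HU) above.
#'
#' @param lower,upper inclusive window bounds in HU; `lower < upper`.
#' @return an object of class `hu_window`.
#' @export
hu_window <- function(lower = -700, upper = 200) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    lw_validation_error("HU window requires finite lower < upper")
  structure(list(lower = lower, upper = upper), class = "hu_window")
}

#' Patient anthropometrics
#'
#' @param height body height in metres.
#' @param sex `"male"` or `"female"`.
#' @param actual_weight optional actual body weight in kg (informational).
#' @return an object of class `patient_anthro`.
#' @export
patient_anthro <- function(height, sex = c("male", "female"),
                           actual_weight = NULL) {
  height <- as.numeric(height)
  if (length(height) != 1L || !is.finite(height) || height <= 0)
    lw_validation_error("height must be a single positive number (metres)")
  if (height < 1.2 || height > 2.2)
    warning(sprintf("height %.2f m is outside the plausible range [1.2, 2.2]",
                    height))
  sex <- match.arg(sex)
  structure(list(height = height, sex = sex, actual_weight = actual_weight),
            class = "patient_anthro")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_aligned <- function(volume, mask) {
  if (!identical(dim(volume$hu), dim(mask$mask)))
    lw_alignment_error("volume %s and mask %s shapes differ",
                       paste(dim(volume$hu), collapse = "x"),
                       paste(dim(mask$mask), collapse = "x"))
  if (!isTRUE(all.equal(volume$spacing, mask$spacing, tolerance = 1e-6)))
    lw_alignment_error("volume and mask voxel spacing differ")
  invisible(TRUE)
}

#' Voxel volume in millilitres
#'
#' @param spacing voxel edge lengths in mm.
#' @return volume of one voxel in ml (product of spacing / 1000).
#' @export
voxel_volume_ml <- function(spacing) prod(as.numeric(spacing)) / 1000

#' Select edema-window voxels
#'
#' Returns the HU values of masked voxels falling inside the edema window
#' (bounds inclusive).  Voxels above the window (contrast agent) and below it
#' (hyperaerated lung) are dropped.
#'
#' @param volume a [ct_volume()].
#' @param mask an aligned [lung_mask()]; must contain at least one voxel.
#' @param window an [hu_window()].
#' @return list with `hu` (numeric vector of retained HU values) and
#'   `included_voxel_count`.
#' @export
select_edema_voxels <- function(volume, mask, window = hu_window()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lung_mask"),
            inherits(window, "hu_window"))
  check_aligned(volume, mask)
  if (!any(mask$mask))
    lw_validation_error("lung mask is empty: nothing to quantify")
  hu <- volume$hu[mask$mask]
  keep <- hu >= window$lower & hu <= window$upper
  list(hu = hu[keep], included_voxel_count = sum(keep))
}

#' Lung weight from selected HU values
#'
#' Integrates per-voxel tissue weight `(1 + HU/1000) * voxel volume` over the
#' selection.  Algebraically identical to the mean-HU closed form
#' `(1 - meanHU/(-1000)) * total volume`.
#'
#' @param hu numeric vector of selected HU values; must be non-empty.
#' @param voxel_volume volume of one voxel in ml.
#' @return lung weight in grams.
#' @export
lung_weight <- function(hu, voxel_volume) {
  if (length(hu) == 0L)
    lw_validation_error("no voxels selected: lung weight undefined (empty mean HU)")
  if (!is.numeric(voxel_volume) || voxel_volume <= 0)
    lw_validation_error("voxel_volume must be > 0 (ml)")
  sum(1 + hu / 1000) * voxel_volume
}

#' Expected (normal) lung weight from height
#'
#' Height-predicted normal lung weight in grams,
#' `-1806.1 + 1633.7 * height(m)`.
#'
#' @param anthro a [patient_anthro()], or a bare height in metres.
#' @return expected lung weight in grams.
#' @export
expected_lung_weight <- function(anthro) {
  height <- if (inherits(anthro, "patient_anthro")) anthro$height
            else as.numeric(anthro)
  w <- -1806.1 + 1633.7 * height
  if (w <= 0)
    lw_validation_error(
      "expected lung weight non-positive at height %.3f m: formula outside validity",
      height)
  w
}

#' Ideal (predicted) body weight
#'
#' Sex-specific predicted-body-weight rule used to index lung water:
#' male `50 + 0.91 * (height_cm - 152.4)` kg, female `45.5 + 0.91 *
#' (height_cm - 152.4)` kg.  Alternative rules can be registered via `rule`
#' as a function `(height_m, sex) -> kg`.
#'
#' @param anthro a [patient_anthro()].
#' @param rule `"pbw"` (default) or a custom function.
#' @return ideal body weight in kg, with attribute `ibw_rule` recording the
#'   rule applied.
#' @export
ideal_body_weight <- function(anthro, rule = "pbw") {
  stopifnot(inherits(anthro, "patient_anthro"))
  if (is.function(rule)) {
    ibw <- rule(anthro$height, anthro$sex)
    attr(ibw, "ibw_rule") <- "custom"
    return(ibw)
  }
  if (!identical(rule, "pbw"))
    lw_validation_error("unknown IBW rule '%s'", rule)
  h_cm <- anthro$height * 100
  base <- if (anthro$sex == "male") 50 else 45.5
  if (h_cm < 152.4)
    warning(sprintf("height %.1f cm below 152.4: IBW falls below the %s base constant",
                    h_cm, anthro$sex))
  ibw <- base + 0.91 * (h_cm - 152.4)
  attr(ibw, "ibw_rule") <- "pbw"
  ibw
}

#' CT-derived extravascular lung water index
#'
#' Excess lung weight over the expected normal lung, indexed to ideal body
#' weight; 1 g of excess tissue is taken as 1 ml of extravascular water.
#' Negative values (drier-than-expected lung) are returned, not clipped.
#'
#' @param lung_weight calculated lung weight, g.
#' @param expected_lung_weight height-predicted normal lung weight, g.
#' @param ibw ideal body weight, kg; must be > 0.
#' @return EVLWI in ml/kg.
#' @export
evlwi_ct <- function(lung_weight, expected_lung_weight, ibw) {
  if (!is.numeric(ibw) || ibw <= 0) lw_validation_error("ibw must be > 0")
  (lung_weight - expected_lung_weight) / as.numeric(ibw)
}

#' Quantify one CT scan
#'
#' End-to-end densitometric quantification: select edema-window voxels,
#' integrate lung volume and weight, compute expected lung weight and ideal
#' body weight from the anthropometrics, and derive EVLWI.
#'
#' By default both lung volume and weight are integrated over windowed voxels
#' only.  `integrate = "mask"` integrates over every mask voxel instead (a
#' sensitivity analysis; the window still defines which voxels enter mean HU
#' and weight is then summed over all mask voxels too).
#'
#' @param volume a [ct_volume()].
#' @param mask an aligned [lung_mask()].
#' @param anthro a [patient_anthro()].
#' @param window an [hu_window()]; default -700..200 HU.
#' @param integrate `"window"` (default) or `"mask"`.
#' @param ibw_rule passed to [ideal_body_weight()].
#' @return an object of class `lung_quant_result`: `included_voxel_count`,
#'   `lung_volume` (ml), `mean_hu`, `lung_weight` (g), `expected_lung_weight`
#'   (g), `ibw` (kg), `evlwi_ct` (ml/kg), plus the `window`, `integrate` and
#'   `ibw_rule` used.
#' @export
quantify_scan <- function(volume, mask, anthro, window = hu_window(),
                          integrate = c("window", "mask"), ibw_rule = "pbw") {
  integrate <- match.arg(integrate)
  sel <- select_edema_voxels(volume, mask, window)
  if (sel$included_voxel_count == 0L)
    lw_validation_error("no mask voxels fall inside the HU window [%g, %g]",
                        window$lower, window$upper)
  vvol <- voxel_volume_ml(volume$spacing)
  hu_used <- if (integrate == "window") sel$hu else volume$hu[mask$mask]
  lv <- length(hu_used) * vvol
  lw <- lung_weight(hu_used, vvol)
  mh <- mean(sel$hu)
  elw <- expected_lung_weight(anthro)
  ibw <- ideal_body_weight(anthro, rule = ibw_rule)
  structure(list(
    included_voxel_count = sel$included_voxel_count,
    lung_volume = lv,
    mean_hu = mh,
    lung_weight = lw,
    expected_lung_weight = elw,
    ibw = as.numeric(ibw),
    evlwi_ct = evlwi_ct(lw, elw, ibw),
    window = window,
    integrate = integrate,
    ibw_rule = attr(ibw, "ibw_rule") %||% "custom"
  ), class = "lung_quant_result")
}

#' @export
print.lung_quant_result <- function(x, ...) {
  cat(sprintf(
    paste0("Lung quantification (HU window [%g, %g], %s integration, IBW rule %s)\n",
           "  voxels included : %d\n  lung volume     : %.1f ml\n",
           "  mean HU         : %.1f\n  lung weight     : %.1f g\n",
           "  expected weight : %.1f g\n  IBW             : %.2f kg\n",
           "  EVLWI_CT        : %.2f ml/kg\n"),
    x$window$lower, x$window$upper, x$integrate, x$ibw_rule,
    x$included_voxel_count, x$lung_volume, x$mean_hu, x$lung_weight,
    x$expected_lung_weight, x$ibw, x$evlwi_ct))
  invisible(x)
}

#' DICE similarity coefficient
#'
#' Overlap between two aligned binary masks, `2|A n B| / (|A| + |B|)`.
#'
#' @param mask_a,mask_b [lung_mask()] objects (or bare logical arrays) of
#'   identical shape; not both empty.
#' @return DICE coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "lung_mask")) mask_a$mask else mask_a
  b <- if (inherits(mask_b, "lung_mask")) mask_b$mask else mask_b
  if (!identical(dim(a), dim(b)))
    lw_alignment_error("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0)
    lw_validation_error("both masks are empty: DICE undefined (0/0)")
  2 * sum(a & b) / (na + nb)
}

#' Write quantification results as CSV
#'
#' One row per scan, with a leading comment line documenting units.
#'
#' @param results a `lung_quant_result` or list of them.
#' @param path output file path, or `""` for stdout.
#' @param scan_id optional character vector of scan identifiers.
#' @return the data.frame written, invisibly.
#' @export
write_quant_csv <- function(results, path = "", scan_id = NULL) {
  if (inherits(results, "lung_quant_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) data.frame(
    included_voxel_count = r$included_voxel_count,
    lung_volume_ml = r$lung_volume, mean_hu = r$mean_hu,
    lung_weight_g = r$lung_weight, expected_lung_weight_g = r$expected_lung_weight,
    ibw_kg = r$ibw, evlwi_ct_ml_per_kg = r$evlwi_ct,
    hu_window_lower = r$window$lower, hu_window_upper = r$window$upper,
    integrate = r$integrate, ibw_rule = r$ibw_rule)))
  if (!is.null(scan_id)) df <- cbind(scan_id = scan_id, df)
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  writeLines(paste("# units: volume ml, weight g, ibw kg, evlwi ml/kg,",
                   "window HU"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}
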