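# Ground-truth-known synthetic data: CT phantoms and patient cohorts.
#
# Phantoms are two ellipsoidal "lungs" inside a soft-tissue body ellipsoid on
# an air background -- enough geometry to exercise every densitometric
# formula, with the truth computed from the realized (post-noise) voxels so
# recovery tests can be exact.  Cohorts are drawn from the three-parameter
# linear model the correction module is meant to recover.

# Run expr with a local RNG seeded at `seed`; the caller's global
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gamma parameters for the EVLWI_CT marginal, calibrated by weighted
# quantile matching to median 10.2 and quartiles 5.8 / 14.8 ml/kg.
EVLWI_CT_GAMMA_SHAPE <- 2.664175
EVLWI_CT_GAMMA_SCALE <- 4.286586

#' Phantom specification
#'
#' @param shape integer vector of 3: voxels per axis.
#' @param spacing voxel edge lengths, mm.
#' @param lung_centers list of two numeric length-3 centres (voxel indices).
#' @param lung_semiaxes list of two numeric length-3 ellipsoid semi-axes
#'   (voxels).
#' @param lung_mean_hu mean lung HU in (-1000, 200].
#' @param hu_noise_sd Gaussian HU noise SD inside the lung.
#' @param contrast_fraction fraction of lung voxels replaced by contrast
#'   (HU in (200, 500]); in \[0, 1).
#' @param effusion_fraction fraction of body voxels set to effusion-like
#'   ~+10 HU adjacent to the lung; in \[0, 1).
#' @param body_hu soft-tissue HU (default 40).
#' @param background_hu air HU (default -1000).
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 48L), spacing = c(3, 3, 5),
                         lung_centers = list(c(18, 32, 24), c(47, 32, 24)),
                         lung_semiaxes = list(c(14, 18, 22), c(14, 18, 22)),
                         lung_mean_hu = -500, hu_noise_sd = 0,
                         contrast_fraction = 0, effusion_fraction = 0,
                         body_hu = 40, background_hu = -1000, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    lw_validation_error("shape must be 3 axis lengths >= 4")
  if (lung_mean_hu <= -1000 || lung_mean_hu > 200)
    lw_validation_error("lung_mean_hu must lie in (-1000, 200]")
  for (f in c(contrast_fraction, effusion_fraction))
    if (f < 0 || f >= 1) lw_validation_error("fractions must lie in [0, 1)")
  for (i in 1:2) {
    c0 <- lung_centers[[i]]; ax <- lung_semiaxes[[i]]
    if (any(c0 - ax < 1) || any(c0 + ax > shape))
      lw_validation_error("lung ellipsoid %d does not fit inside the volume", i)
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 lung_centers = lung_centers, lung_semiaxes = lung_semiaxes,
                 lung_mean_hu = lung_mean_hu, hu_noise_sd = hu_noise_sd,
                 contrast_fraction = contrast_fraction,
                 effusion_fraction = effusion_fraction,
                 body_hu = body_hu, background_hu = background_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(shape, center, semiaxes) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  di <- ((i - center[1]) / semiaxes[1])^2
  dj <- ((j - center[2]) / semiaxes[2])^2
  dk <- ((k - center[3]) / semiaxes[3])^2
  outer(outer(di, dj, `+`), dk, `+`) <= 1
}

# 6-connectivity dilation by one voxel
dilate6 <- function(m) {
  d <- dim(m); out <- m
  shift <- function(m, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    if (by == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else         { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out <- array(FALSE, d)
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(1, -1)) out <- out | shift(m, ax, by)
  out
}

# 6-connectivity erosion by one voxel (complement of dilated complement,
# with out-of-volume treated as background)
erode6 <- function(m) !dilate6(!m) & m

#' Generate a CT phantom with known ground truth
#'
#' Lung voxels draw `N(lung_mean_hu, hu_noise_sd)` clipped to (-1000, 200];
#' `floor(contrast_fraction * n_lung)` of them are then replaced by contrast
#' HU drawn uniformly in (200, 500].  The ground truth (windowed volume,
#' mean HU, lung weight, and EVLWI if anthropometrics are given) is computed
#' from the realized voxel values, so quantification must recover it exactly.
#'
#' @param spec a [phantom_spec()].
#' @param anthro optional [patient_anthro()]; enables `true_evlwi_ct`.
#' @param window the [hu_window()] the truth is computed under.
#' @return list with `volume` ([ct_volume()]), `mask` ([lung_mask()]) and
#'   `truth` (list: `true_lung_volume` ml, `true_mean_hu`, `true_lung_weight`
#'   g, `true_evlwi_ct` or NA, `n_lung_voxels`, `n_contrast_voxels`).
#' @export
generate_phantom <- function(spec, anthro = NULL, window = hu_window()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    lung <- ellipsoid_mask(spec$shape, spec$lung_centers[[1]],
                           spec$lung_semiaxes[[1]]) |
            ellipsoid_mask(spec$shape, spec$lung_centers[[2]],
                           spec$lung_semiaxes[[2]])
    body_center <- spec$shape / 2 + 0.5
    body_ax <- spec$shape / 2 - 0.5
    body <- ellipsoid_mask(spec$shape, body_center, body_ax) & !lung

    hu <- array(spec$background_hu, spec$shape)
    hu[body] <- spec$body_hu
    n_lung <- sum(lung)
    lung_hu <- spec$lung_mean_hu +
      if (spec$hu_noise_sd > 0) stats::rnorm(n_lung, 0, spec$hu_noise_sd) else 0
    lung_hu <- pmin(pmax(lung_hu, -999.999), 200)
    if (length(lung_hu) == 1L) lung_hu <- rep(lung_hu, n_lung)
    n_contrast <- floor(spec$contrast_fraction * n_lung)
    if (n_contrast > 0) {
      pick <- sample.int(n_lung, n_contrast)
      lung_hu[pick] <- 200 + stats::runif(n_contrast) * 300
    }
    hu[lung] <- lung_hu

    n_eff <- floor(spec$effusion_fraction * sum(body))
    if (n_eff > 0) {
      shell <- dilate6(lung) & body
      cand <- which(shell)
      take <- cand[seq_len(min(n_eff, length(cand)))]
      hu[take] <- 10
    }

    vvol <- voxel_volume_ml(spec$spacing)
    win_hu <- lung_hu[lung_hu >= window$lower & lung_hu <= window$upper]
    truth <- list(
      true_lung_volume = length(win_hu) * vvol,
      true_mean_hu = mean(win_hu),
      true_lung_weight = sum(1 + win_hu / 1000) * vvol,
      true_evlwi_ct = NA_real_,
      n_lung_voxels = n_lung,
      n_contrast_voxels = n_contrast
    )
    if (!is.null(anthro)) {
      ibw <- ideal_body_weight(anthro)
      truth$true_evlwi_ct <- (truth$true_lung_weight -
                                expected_lung_weight(anthro)) / as.numeric(ibw)
    }
    list(volume = ct_volume(hu, spec$spacing),
         mask = lung_mask(lung, spec$spacing),
         truth = truth)
  })
}

#' Cohort generator parameters
#'
#' Defaults reproduce the clinical cohort's stated structure: EVLWI_CT
#' gamma-distributed (median ~10.2, IQR ~5.8-14.8 ml/kg), ECBF normal
#' 3.9 +/- 1.1 l/min truncated to \[1.0, 6.5\], height normal 1.77 +/- 0.09 m,
#' 23% female, and the generative linear model
#' `EVLWI_TPTD = 5.054 + 0.4711 * EVLWI_CT + 3.439 * ECBF + N(0, residual_sd)`.
#'
#' @param n number of patients.
#' @param intercept,slope_ct,ecbf_coef generative coefficients.
#' @param residual_sd Gaussian residual SD, ml/kg (default 8).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n = 64L, intercept = 5.054, slope_ct = 0.4711,
                              ecbf_coef = 3.439, residual_sd = 8,
                              seed = 1L) {
  n <- as.integer(n)
  if (n < 0L) lw_validation_error("n must be >= 0")
  if (residual_sd < 0) lw_validation_error("residual_sd must be >= 0")
  structure(list(n = n, intercept = intercept, slope_ct = slope_ct,
                 ecbf_coef = ecbf_coef, residual_sd = residual_sd,
                 evlwi_ct_shape = EVLWI_CT_GAMMA_SHAPE,
                 evlwi_ct_scale = EVLWI_CT_GAMMA_SCALE,
                 ecbf_mean = 3.9, ecbf_sd = 1.1,
                 ecbf_range = c(1.0, 6.5),
                 height_mean = 1.77, height_sd = 0.09,
                 female_fraction = 0.23, seed = as.integer(seed)),
            class = "cohort_gen_params")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF sampling; exact truncation, no rejection loop
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient EVLWI_CT, ECBF, height and sex independently, then sets
#' `evlwi_tptd` from the generative linear model plus Gaussian residual
#' noise.  The generative parameters are attached as attribute `gen_params`
#' for recovery testing.
#'
#' @param params a [cohort_gen_params()].
#' @return data.frame with columns `patient_id`, `evlwi_ct`, `evlwi_tptd`,
#'   `ecbf`, `height_m`, `sex`, `time_offset_h`; attribute `gen_params`.
#' @export
generate_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  n <- params$n
  if (n == 0L) {
    out <- data.frame(patient_id = character(0), evlwi_ct = numeric(0),
                      evlwi_tptd = numeric(0), ecbf = numeric(0),
                      height_m = numeric(0), sex = character(0),
                      time_offset_h = numeric(0))
    attr(out, "gen_params") <- params
    return(out)
  }
  with_seed(params$seed, {
    evlwi_ct <- stats::rgamma(n, shape = params$evlwi_ct_shape,
                              scale = params$evlwi_ct_scale)
    ecbf <- rtruncnorm1(n, params$ecbf_mean, params$ecbf_sd,
                        params$ecbf_range[1], params$ecbf_range[2])
    height <- stats::rnorm(n, params$height_mean, params$height_sd)
    sex <- ifelse(stats::runif(n) < params$female_fraction, "female", "male")
    # CT-to-thermodilution delay, median ~2 h with IQR ~1-4 h
    time_offset <- stats::rlnorm(n, meanlog = log(2), sdlog = 0.7)
    eps <- if (params$residual_sd > 0) stats::rnorm(n, 0, params$residual_sd)
           else 0
    tptd <- params$intercept + params$slope_ct * evlwi_ct +
      params$ecbf_coef * ecbf + eps
    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      evlwi_ct = evlwi_ct, evlwi_tptd = tptd, ecbf = ecbf,
      height_m = height, sex = sex, time_offset_h = time_offset,
      stringsAsFactors = FALSE)
    attr(out, "gen_params") <- params
    out
  })
}

#' Degrade a lung mask
#'
#' Morphological 6-connectivity erosion by `erosion_steps`, optionally
#' followed by random flips of boundary voxels, to emulate an imperfect
#' (e.g. manual) segmentation for overlap scoring.  With `flip_fraction = 0`
#' the output is a subset of the input.
#'
#' @param mask a [lung_mask()].
#' @param erosion_steps integer >= 0.
#' @param flip_fraction fraction of boundary voxels to flip (default 0).
#' @param seed RNG seed used when flipping.
#' @return a degraded [lung_mask()].
#' @export
degrade_mask <- function(mask, erosion_steps = 1L, flip_fraction = 0,
                         seed = 1L) {
  stopifnot(inherits(mask, "lung_mask"))
  if (erosion_steps < 0) lw_validation_error("erosion_steps must be >= 0")
  m <- mask$mask
  for (i in seq_len(erosion_steps)) m <- erode6(m)
  if (flip_fraction > 0) {
    with_seed(seed, {
      boundary <- which((dilate6(m) & !m) | (m & !erode6(m)))
      nflip <- floor(flip_fraction * length(boundary))
      if (nflip > 0) {
        pick <- sample(boundary, nflip)
        m[pick] <- !m[pick]
      }
      m
    }) -> m
  }
  if (!any(m))
    lw_validation_error("degraded mask is empty (erosion removed all voxels)")
  lung_mask(m, mask$spacing)
}
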