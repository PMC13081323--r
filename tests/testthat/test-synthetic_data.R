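test_that("noise-free phantom truth matches the closed form", {
  spec <- phantom_spec(lung_mean_hu = -500, hu_noise_sd = 0, seed = 2)
  ph <- generate_phantom(spec, anthro = small_anthro())
  vvol <- voxel_volume_ml(spec$spacing)
  expect_equal(ph$truth$true_lung_volume, ph$truth$n_lung_voxels * vvol)
  expect_equal(ph$truth$true_lung_weight, 0.5 * ph$truth$true_lung_volume,
               tolerance = 1e-12)
  expect_equal(ph$truth$true_mean_hu, -500)
  # default geometry is adult-lung sized
  expect_gt(ph$truth$true_lung_volume, 1500)
  expect_lt(ph$truth$true_lung_volume, 3500)
})

test_that("quantify_scan recovers phantom truth, noise-free and noisy", {
  a <- small_anthro()
  for (s in list(phantom_spec(hu_noise_sd = 0, seed = 4),
                 phantom_spec(lung_mean_hu = -350, hu_noise_sd = 60, seed = 5),
                 phantom_spec(hu_noise_sd = 40, contrast_fraction = 0.07,
                              seed = 6))) {
    ph <- generate_phantom(s, anthro = a)
    r <- quantify_scan(ph$volume, ph$mask, a)
    expect_equal(r$lung_weight, ph$truth$true_lung_weight, tolerance = 1e-6)
    expect_equal(r$lung_volume, ph$truth$true_lung_volume, tolerance = 1e-6)
    expect_equal(r$mean_hu, ph$truth$true_mean_hu, tolerance = 1e-6)
    expect_equal(r$evlwi_ct, ph$truth$true_evlwi_ct, tolerance = 1e-6)
  }
})

test_that("contrast fraction injects exactly the constructed voxel count", {
  spec <- phantom_spec(contrast_fraction = 0.05, hu_noise_sd = 20, seed = 9)
  ph <- generate_phantom(spec)
  n_lung <- ph$truth$n_lung_voxels
  expect_equal(ph$truth$n_contrast_voxels, floor(0.05 * n_lung))
  hu_in_mask <- ph$volume$hu[ph$mask$mask]
  expect_equal(sum(hu_in_mask > 200), floor(0.05 * n_lung))
})

test_that("generators are deterministic in their seed", {
  s <- phantom_spec(hu_noise_sd = 25, contrast_fraction = 0.03, seed = 12)
  expect_identical(generate_phantom(s)$volume$hu, generate_phantom(s)$volume$hu)
  s2 <- phantom_spec(hu_noise_sd = 25, contrast_fraction = 0.03, seed = 13)
  expect_false(identical(generate_phantom(s)$volume$hu,
                         generate_phantom(s2)$volume$hu))

  p <- cohort_gen_params(n = 40, seed = 8)
  expect_identical(generate_cohort(p), generate_cohort(p))
  # generator does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_cohort(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("cohort marginals match their stated targets", {
  co <- generate_cohort(cohort_gen_params(n = 1e5, seed = 2))
  q <- unname(quantile(co$evlwi_ct, c(.25, .5, .75)))
  expect_lt(abs(q[2] - 10.2), 1.0)
  expect_lt(abs(q[1] - 5.8), 1.5)
  expect_lt(abs(q[3] - 14.8), 1.5)

  # truncated-normal ECBF moment oracle
  a <- (1.0 - 3.9) / 1.1; b <- (6.5 - 3.9) / 1.1
  tn_mean <- 3.9 + 1.1 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- sd(co$ecbf) / sqrt(nrow(co))
  expect_lt(abs(mean(co$ecbf) - tn_mean), 3 * se + 1e-3)
  expect_true(all(co$ecbf >= 1.0 & co$ecbf <= 6.5))

  expect_lt(abs(mean(co$height_m) - 1.77), 0.005)
  expect_lt(abs(mean(co$sex == "female") - 0.23), 0.01)
})

test_that("noise-free cohorts reproduce the generative model through the fit", {
  co <- generate_cohort(cohort_gen_params(n = 30, residual_sd = 0, seed = 3))
  m <- fit_correction_model(co)
  expect_equal(m$intercept, 5.054, tolerance = 1e-8)
  expect_equal(m$slope_ct, 0.4711, tolerance = 1e-8)
  expect_equal(m$correction_factor, 3.439, tolerance = 1e-8)

  expect_equal(nrow(generate_cohort(cohort_gen_params(n = 0))), 0L)
})

test_that("degrade_mask erodes predictably and DICE decays monotonically", {
  cube <- solid_cube_mask(20, 2)
  d0 <- degrade_mask(cube, 0)
  expect_equal(dice_coefficient(cube, d0), 1)

  d1 <- degrade_mask(cube, 1)
  expect_equal(sum(d1$mask), 18^3)
  expect_equal(dice_coefficient(cube, d1), 2 * 18^3 / (20^3 + 18^3))
  expect_true(all(cube$mask[d1$mask]))  # subset when no flips

  steps <- 0:4
  dice <- vapply(steps, function(s)
    dice_coefficient(cube, degrade_mask(cube, s)), 0)
  expect_true(all(diff(dice) <= 0))

  expect_error(degrade_mask(cube, 50), class = "lungwater_validation_error")

  df <- degrade_mask(cube, 1, flip_fraction = 0.3, seed = 2)
  expect_identical(df$mask,
                   degrade_mask(cube, 1, flip_fraction = 0.3, seed = 2)$mask)
  expect_lt(dice_coefficient(cube, df), 1)
})

test_that("phantom spec validates geometry and fractions", {
  expect_error(phantom_spec(lung_centers = list(c(2, 32, 24), c(47, 32, 24))),
               class = "lungwater_validation_error")
  expect_error(phantom_spec(contrast_fraction = 1),
               class = "lungwater_validation_error")
  expect_error(phantom_spec(lung_mean_hu = 300),
               class = "lungwater_validation_error")
})
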