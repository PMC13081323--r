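test_that("edema-window selection is inclusive at both bounds and drops contrast", {
  fx <- hu_vector_fixture(c(-900, -750, -700, -500, 0, 150, 200, 201, 300, 1000))
  sel <- select_edema_voxels(fx$volume, fx$mask, hu_window(-700, 200))
  expect_equal(sel$included_voxel_count, 5L)
  expect_setequal(sel$hu, c(-700, -500, 0, 150, 200))

  all_air <- hu_vector_fixture(rep(-1000, 12))
  expect_equal(
    select_edema_voxels(all_air$volume, all_air$mask)$included_voxel_count, 0L)
})

test_that("selection errors on misalignment and empty masks", {
  fx <- block_fixture()
  small <- lung_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(select_edema_voxels(fx$volume, small, hu_window()),
               class = "lungwater_alignment_error")
  off_spacing <- lung_mask(fx$mask$mask, c(1, 1, 2))
  expect_error(select_edema_voxels(fx$volume, off_spacing, hu_window()),
               class = "lungwater_alignment_error")
  empty <- lung_mask(array(FALSE, dim(fx$volume$hu)), c(1, 1, 1))
  expect_error(select_edema_voxels(fx$volume, empty, hu_window()),
               class = "lungwater_validation_error")
})

test_that("lung weight matches the per-voxel density formula", {
  expect_equal(lung_weight(-1000, 1), 0)        # pure gas
  expect_equal(lung_weight(0, 1), 1)            # water-equivalent
  expect_equal(lung_weight(rep(-500, 1000), 1e-3), 0.5)  # 1000 x 1 mm^3
  expect_error(lung_weight(numeric(0), 1), class = "lungwater_validation_error")
  expect_error(lung_weight(0, 0), class = "lungwater_validation_error")
})

test_that("per-voxel summation equals the mean-HU closed form", {
  set.seed(42)
  for (i in 1:20) {
    hu <- runif(sample(5:400, 1), -700, 200)
    v <- runif(1, 0.001, 0.05)
    expect_equal(lung_weight(hu, v),
                 (1 - mean(hu) / -1000) * (length(hu) * v), tolerance = 1e-12)
  }
})

test_that("expected lung weight follows the height formula and its validity range", {
  expect_equal(expected_lung_weight(1.77), -1806.1 + 1633.7 * 1.77)
  expect_equal(expected_lung_weight(2.00), 1461.3, tolerance = 1e-10)
  expect_lt(abs(-1806.1 + 1633.7 * 1.1055), 0.1)  # root of the formula
  expect_error(expected_lung_weight(1.10), class = "lungwater_validation_error")
  h <- seq(1.3, 2.1, by = 0.1)
  expect_true(all(diff(vapply(h, expected_lung_weight, 0)) > 0))
})

test_that("ideal body weight uses the sex-specific predicted-body-weight rule", {
  expect_equal(as.numeric(ideal_body_weight(patient_anthro(1.77, "male"))),
               50 + 0.91 * (177 - 152.4))
  expect_equal(as.numeric(ideal_body_weight(patient_anthro(1.524, "female"))), 45.5)
  expect_equal(as.numeric(ideal_body_weight(patient_anthro(1.524, "male"))), 50)
  expect_warning(ideal_body_weight(patient_anthro(1.40, "male")), "base constant")
  custom <- function(h, s) 60
  expect_equal(as.numeric(ideal_body_weight(small_anthro(), rule = custom)), 60)
})

test_that("evlwi_ct indexes excess weight and permits negative values", {
  ibw <- 50 + 0.91 * (177 - 152.4)
  expect_equal(evlwi_ct(1585.5, 1085.5, ibw), 500 / ibw)
  expect_equal(evlwi_ct(1085.5, 1085.5, ibw), 0)
  expect_lt(evlwi_ct(1000, 1085.5, ibw), 0)
  expect_error(evlwi_ct(1000, 900, 0), class = "lungwater_validation_error")
})

test_that("quantify_scan reproduces a homogeneous phantom analytically", {
  # 2000 ml of lung at -300 HU in 1-ml voxels
  shape <- c(15, 15, 15)
  m <- array(FALSE, shape); m[seq_len(2000)] <- TRUE
  arr <- array(-1000, shape); arr[m] <- -300
  vol <- ct_volume(arr, c(10, 10, 10))
  msk <- lung_mask(m, c(10, 10, 10))
  r <- quantify_scan(vol, msk, small_anthro())
  expect_equal(r$lung_volume, 2000)
  expect_equal(r$lung_weight, 1400)
  expect_equal(r$mean_hu, -300)
  ibw <- 50 + 0.91 * (177 - 152.4)
  expect_equal(r$evlwi_ct, (1400 - expected_lung_weight(1.77)) / ibw)
  expect_true(r$mean_hu >= r$window$lower && r$mean_hu <= r$window$upper)
  expect_equal(r$evlwi_ct,
               (r$lung_weight - r$expected_lung_weight) / r$ibw)

  # turning 150 lung voxels into contrast drops them from the integration
  arr2 <- arr
  arr2[which(m)[1:150]] <- 400
  r2 <- quantify_scan(ct_volume(arr2, c(10, 10, 10)),
                      lung_mask(m, c(10, 10, 10)), small_anthro())
  expect_equal(r2$included_voxel_count, 1850L)
  expect_equal(r2$mean_hu, -300)
  expect_equal(r2$lung_weight, 0.7 * 1850)

  empty <- lung_mask(array(FALSE, shape), c(10, 10, 10))
  expect_error(quantify_scan(vol, empty, small_anthro()),
               class = "lungwater_validation_error")
})

test_that("window invariance: out-of-window voxels never change the result", {
  set.seed(7)
  base_hu <- runif(300, -700, 200)
  for (extra in list(rep(300, 40), rep(-900, 25), c(201, 1500, -1000))) {
    fx1 <- hu_vector_fixture(base_hu)
    fx2 <- hu_vector_fixture(c(base_hu, extra))
    r1 <- quantify_scan(fx1$volume, fx1$mask, small_anthro())
    r2 <- quantify_scan(fx2$volume, fx2$mask, small_anthro())
    expect_equal(r1$lung_weight, r2$lung_weight)
    expect_equal(r1$lung_volume, r2$lung_volume)
    expect_equal(r1$evlwi_ct, r2$evlwi_ct)
  }
})

test_that("monotonicity: lung weight in HU, evlwi in height", {
  fx_lo <- hu_vector_fixture(rep(-400, 100))
  fx_hi <- hu_vector_fixture(rep(-350, 100))
  r_lo <- quantify_scan(fx_lo$volume, fx_lo$mask, small_anthro())
  r_hi <- quantify_scan(fx_hi$volume, fx_hi$mask, small_anthro())
  expect_gt(r_hi$lung_weight, r_lo$lung_weight)

  heights <- seq(1.6, 2.0, by = 0.1)
  e <- vapply(heights, function(h) {
    a <- patient_anthro(h, "male")
    evlwi_ct(1500, expected_lung_weight(a), as.numeric(ideal_body_weight(a)))
  }, 0)
  expect_true(all(diff(e) < 0))
})

test_that("DICE coefficient: closed forms and symmetry", {
  m <- solid_cube_mask(6, 1)
  expect_equal(dice_coefficient(m, m), 1)

  a <- array(FALSE, c(6, 6, 6)); b <- a
  a[1:3, , ] <- TRUE; b[4:6, , ] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)

  sub <- array(FALSE, c(10, 10, 10)); sup <- sub
  sup[seq_len(100)] <- TRUE; sub[seq_len(50)] <- TRUE
  expect_equal(dice_coefficient(sub, sup), 2 * 50 / 150)
  expect_equal(dice_coefficient(sup, sub), dice_coefficient(sub, sup))

  expect_error(dice_coefficient(array(FALSE, c(3, 3, 3)),
                                array(FALSE, c(3, 3, 3))),
               class = "lungwater_validation_error")
  expect_error(dice_coefficient(a, array(FALSE, c(5, 5, 5))),
               class = "lungwater_alignment_error")
})

test_that("constructors validate their invariants", {
  expect_error(ct_volume(matrix(0, 3, 3), c(1, 1, 1)),
               class = "lungwater_validation_error")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)),
               class = "lungwater_validation_error")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, 0, 1)),
               class = "lungwater_validation_error")
  expect_error(lung_mask(array(2, c(2, 2, 2)), c(1, 1, 1)),
               class = "lungwater_validation_error")
  expect_error(hu_window(200, -700), class = "lungwater_validation_error")
  expect_warning(patient_anthro(1.1055 + 0.01, "male"), "plausible range")
  expect_error(patient_anthro(-1, "male"), class = "lungwater_validation_error")
})
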