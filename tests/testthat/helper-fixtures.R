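# Shared fixture builders.  Everything is generated in code; no binary
# fixtures on disk.

# Uniform block volume: every mask voxel at `hu`, mask a centred cuboid.
block_fixture <- function(hu = -500, shape = c(8, 8, 8), spacing = c(1, 1, 1),
                          margin = 1) {
  arr <- array(-1000, shape)
  idx <- lapply(shape, function(s) (1 + margin):(s - margin))
  m <- array(FALSE, shape)
  m[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  arr[m] <- hu
  list(volume = ct_volume(arr, spacing), mask = lung_mask(m, spacing))
}

# Volume whose masked voxels carry exactly the given HU vector.
hu_vector_fixture <- function(hu_values, spacing = c(1, 1, 1)) {
  n <- length(hu_values)
  side <- ceiling(n^(1 / 3)) + 1
  shape <- rep(side, 3)
  arr <- array(-1000, shape)
  m <- array(FALSE, shape)
  m[seq_len(n)] <- TRUE
  arr[seq_len(n)] <- hu_values
  list(volume = ct_volume(arr, spacing), mask = lung_mask(m, spacing))
}

solid_cube_mask <- function(side = 20, pad = 2, spacing = c(1, 1, 1)) {
  shape <- rep(side + 2 * pad, 3)
  m <- array(FALSE, shape)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  lung_mask(m, spacing)
}

# Noise-free cohort straight from the generative linear model.
exact_cohort <- function(n = 20, intercept = 5.054, slope = 0.4711,
                         coef = 3.439) {
  evlwi_ct <- seq(2, 30, length.out = n)
  ecbf <- seq(1, 6, length.out = n) + rep_len(c(0, .3, -.2, .1), n)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    evlwi_ct = evlwi_ct,
    evlwi_tptd = intercept + slope * evlwi_ct + coef * ecbf,
    ecbf = ecbf,
    height_m = rep(1.77, n), sex = rep("male", n))
}

small_anthro <- function() patient_anthro(1.77, "male")
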