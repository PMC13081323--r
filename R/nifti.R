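# Minimal single-file NIfTI-1 reader/writer.
#
# Only what the pipeline needs: 3-D volumes, voxel spacing from pixdim,
# scl_slope/scl_inter scaling, both endiannesses on read, gzip via the file
# extension.  Orientation metadata (qform/sform) is written as a plain
# diagonal sform and otherwise ignored: masks must share the volume's grid,
# so no resampling or reorientation is ever performed here.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume as a CT volume
#'
#' Single-file `.nii` / `.nii.gz`, data of rank exactly 3.  HU values are
#' taken as `stored * scl_slope + scl_inter` when a non-trivial scaling is
#' present.
#'
#' @param path file path.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path) {
  arr <- read_nifti(path)
  ct_volume(arr$data, arr$spacing)
}

#' Read a NIfTI-1 volume as a binary lung mask
#'
#' Float or integer masks are binarised at 0.5.
#'
#' @param path file path.
#' @return a [lung_mask()].
#' @export
read_mask <- function(path) {
  arr <- read_nifti(path)
  lung_mask(array(arr$data > 0.5, dim(arr$data)), arr$spacing)
}

read_nifti <- function(path) {
  if (!file.exists(path)) lw_format_error("file not found: %s", path)
  con <- nii_con(path, "rb")
  on.exit(close(con))
  endian <- .Platform$endian
  szh <- readBin(con, "integer", 1, 4, endian = endian)
  if (length(szh) == 0) lw_format_error("empty or truncated NIfTI file: %s", path)
  if (szh != 348L) {
    endian <- if (endian == "little") "big" else "little"
    if (szh != 1543503872L)  # 348 byte-swapped
      lw_format_error("not a NIfTI-1 file (sizeof_hdr = %d): %s", szh, path)
  }
  readBin(con, "raw", 36)                               # unused fields
  dim <- readBin(con, "integer", 8, 2, endian = endian) # offset 40
  readBin(con, "raw", 14)                               # intents etc.
  datatype <- readBin(con, "integer", 1, 2, endian = endian)  # offset 70
  readBin(con, "integer", 1, 2, endian = endian)        # bitpix
  readBin(con, "raw", 2)                                # slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = endian)     # offset 76
  vox_offset <- readBin(con, "double", 1, 4, endian = endian) # 108
  scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  readBin(con, "raw", 344 - 120)                        # to magic
  magic <- readBin(con, "raw", 4)
  ms <- rawToChar(magic[magic != as.raw(0)])
  if (!ms %in% c("n+1", "ni1"))
    lw_format_error("bad NIfTI magic '%s': %s", ms, path)
  if (ms == "ni1")
    lw_format_error("two-file NIfTI (.hdr/.img) is not supported: %s", path)
  rank <- dim[1]
  extra <- if (rank > 3) dim[(4 + 1):(rank + 1)] else integer(0)
  if (rank < 3 || (rank > 3 && any(extra != 1L)))
    lw_format_error("expected a 3-D volume, got rank %d: %s", rank, path)
  shape <- dim[2:4]
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    lw_format_error("unsupported NIfTI datatype %d: %s", datatype, path)
  skip <- round(vox_offset) - 348L
  if (skip < 0) lw_format_error("vox_offset < 348: %s", path)
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n)
    lw_format_error("truncated NIfTI data (%d of %d voxels): %s",
                    length(vals), n, path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, shape), spacing = abs(pixdim[2:4]))
}

write_nifti <- function(data, spacing, path, datatype = 16L) {
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) lw_usage_error("unsupported write datatype %d", datatype)
  shape <- dim(data)
  con <- nii_con(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, 4)
  w_i16 <- function(x) writeBin(as.integer(x), con, 2)
  w_f32 <- function(x) writeBin(as.numeric(x), con, 4)
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L); w_raw(36)
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))                   # dim
  w_raw(14)                                             # intent fields
  w_i16(datatype); w_i16(dt$size * 8L); w_i16(0L)       # datatype/bitpix
  w_f32(c(1, spacing, 1, 1, 1, 1))                      # pixdim
  w_f32(352); w_f32(1); w_f32(0)                        # vox_offset, scl
  w_raw(124 - 120)
  w_f32(c(0, 0, 0, 0))                                  # cal/slice/toffset
  w_i32(0L); w_i32(0L)
  desc <- charToRaw("lungwater synthetic/derived volume")
  w_raw_vec <- function(r, len) writeBin(c(r, raw(len - length(r))), con)
  w_raw_vec(desc, 80); w_raw(24)                        # descrip, aux_file
  w_i16(0L); w_i16(1L)                                  # qform, sform codes
  w_f32(c(0, 0, 0, 0, 0, 0))                            # quaternion
  w_f32(c(spacing[1], 0, 0, 0))                         # srow_x
  w_f32(c(0, spacing[2], 0, 0))
  w_f32(c(0, 0, spacing[3], 0))
  w_raw(16)                                             # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)            # magic
  w_raw(4)                                              # extension flag
  if (dt$what == "double") writeBin(as.numeric(data), con, dt$size)
  else writeBin(as.integer(data), con, dt$size)
  invisible(path)
}

#' Write a CT volume as NIfTI-1 (float64)
#'
#' float64 storage keeps the HU array bit-exact on round-trip.
#'
#' @param volume a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  write_nifti(volume$hu, volume$spacing, path, datatype = 64L)
}

#' Write a lung mask as NIfTI-1 (uint8)
#'
#' @param mask a [lung_mask()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lung_mask"))
  write_nifti(array(as.integer(mask$mask), dim(mask$mask)), mask$spacing,
              path, datatype = 2L)
}
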