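# Shared fixtures: all built in code at test time.

# small phantom used across suites (lungs ~7k voxels each)
small_phantom <- function(seed = 1, fraction = 0.2, pattern = "uniform",
                          grid = c(32, 48, 48)) {
  generate_phantom(phantom_spec(grid_shape = grid, seed = seed,
                                design_fibrotic_fraction = fraction,
                                pattern = pattern))
}

# --- hand-assembled DICOM bytes (independent of the package writer) -------
# Implicit-VR little-endian single-frame CT file, built element by element
# straight from the encoding rules.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(v, pad = charToRaw(" ")) {
  if (length(v) %% 2 == 1) c(v, pad) else v
}

# implicit VR: tag (4 bytes) + 32-bit length + payload
dcm_implicit <- function(group, elem, payload) {
  c(dcm_u16(group), dcm_u16(elem), dcm_u32(length(payload)), payload)
}

# explicit VR (short form), used only for the file meta group
dcm_explicit <- function(group, elem, vr, payload) {
  c(dcm_u16(group), dcm_u16(elem), charToRaw(vr),
    dcm_u16(length(payload)), payload)
}

# Write one implicit-VR slice file. `stored` is a row-major integer vector
# (rows x cols), `z` the slice position, `rescale` toggles the slope and
# intercept elements.
write_raw_dicom_slice <- function(path, stored, rows, cols, z,
                                  slope = 1, intercept = -1024,
                                  series = "1.2.3.4", rescale = TRUE) {
  ds <- function(x) dcm_pad(charToRaw(paste(format(x, scientific = FALSE),
                                            collapse = "\\")))
  ui <- function(x) dcm_pad(charToRaw(x), as.raw(0))
  meta <- dcm_explicit(0x0002, 0x0010, "UI", ui("1.2.840.10008.1.2"))
  body <- c(
    dcm_implicit(0x0008, 0x0060, dcm_pad(charToRaw("CT"))),
    dcm_implicit(0x0020, 0x000e, ui(series)),
    dcm_implicit(0x0020, 0x0032, ds(c(0, 0, z))),
    dcm_implicit(0x0028, 0x0010, dcm_u16(rows)),
    dcm_implicit(0x0028, 0x0011, dcm_u16(cols)),
    dcm_implicit(0x0028, 0x0030, ds(c(0.8, 0.75))),
    dcm_implicit(0x0028, 0x0100, dcm_u16(16)),
    dcm_implicit(0x0028, 0x0103, dcm_u16(0)))
  if (rescale)
    body <- c(body,
              dcm_implicit(0x0028, 0x1052, ds(intercept)),
              dcm_implicit(0x0028, 0x1053, ds(slope)))
  body <- c(body,
            dcm_implicit(0x7fe0, 0x0010,
                         writeBin(as.integer(stored), raw(), size = 2,
                                  endian = "little")))
  con <- file(path, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  close(con)
  invisible(path)
}
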