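# Minimal DICOM codec for uncompressed single-frame CT series.
# Supports the explicit and implicit VR little-endian transfer syntaxes,
# which is all a threshold-densitometry pipeline needs; compressed or
# multi-frame enhanced-CT objects are out of scope.

.ts_explicit_le <- "1.2.840.10008.1.2.1"
.ts_implicit_le <- "1.2.840.10008.1.2"
.ct_sop_class   <- "1.2.840.10008.5.1.4.1.1.2"
.uid_root       <- "1.2.826.0.1.3680043.9.7484"

# VRs carrying a 2-byte reserved field and 4-byte length in explicit mode
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# tag -> VR dictionary for the elements this codec interprets (needed to
# decode implicit-VR files)
.dicom_dict <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0010,0020" = "LO", "0018,0050" = "DS",
  "0020,000d" = "UI", "0020,000e" = "UI", "0020,0013" = "IS",
  "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS",
  "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US",
  "0028,0103" = "US", "0028,1052" = "DS", "0028,1053" = "DS",
  "7fe0,0010" = "OW")

.tag_key <- function(group, elem) sprintf("%04x,%04x", group, elem)

.u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}
.u32 <- function(raw, off) {
  .u16(raw, off) + 65536 * .u16(raw, off + 2L)
}

.is_dicom_file <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 136) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", 128L))
  identical(rawToChar(readBin(con, "raw", 4L)), "DICM")
}

# parse one single-frame file into a named list of decoded elements
.read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 136 || !identical(rawToChar(raw[129:132]), "DICM"))
    stop("not a DICOM file: ", path)
  off <- 132L
  elems <- list()
  explicit <- TRUE   # file meta group is always explicit
  in_meta <- TRUE
  ts <- NULL
  while (off + 8L <= length(raw)) {
    group <- .u16(raw, off); elem <- .u16(raw, off + 2L)
    off <- off + 4L
    if (in_meta && group != 0x0002L) {
      # leaving the file meta group: dataset encoding follows the declared
      # transfer syntax (explicit VR LE unless implicit VR LE is declared)
      in_meta <- FALSE
      if (is.null(ts)) ts <- .ts_explicit_le
      if (!ts %in% c(.ts_explicit_le, .ts_implicit_le))
        stop("unsupported transfer syntax: ", ts)
      explicit <- ts != .ts_implicit_le
    }
    if (explicit) {
      vr <- rawToChar(raw[(off + 1L):(off + 2L)])
      if (vr %in% .long_vrs) {
        len <- .u32(raw, off + 4L); off <- off + 8L
      } else {
        len <- .u16(raw, off + 2L); off <- off + 4L
      }
    } else {
      key <- .tag_key(group, elem)
      vr <- if (key %in% names(.dicom_dict)) .dicom_dict[[key]] else "UN"
      len <- .u32(raw, off); off <- off + 4L
    }
    if (off + len > length(raw)) stop("truncated DICOM element in ", path)
    val <- raw[seq_len(len) + off]
    off <- off + len
    key <- .tag_key(group, elem)
    elems[[key]] <- .decode_value(vr, val)
    if (key == "0002,0010") ts <- elems[[key]]
    if (group == 0x7fe0L && elem == 0x0010L) break
  }
  elems
}

.decode_value <- function(vr, val) {
  if (vr %in% c("US"))
    return(readBin(val, "integer", length(val) / 2L, size = 2L,
                   signed = FALSE, endian = "little"))
  if (vr %in% c("UL"))
    return(readBin(val, "integer", length(val) / 4L, size = 4L,
                   endian = "little"))
  if (vr %in% c("SS"))
    return(readBin(val, "integer", length(val) / 2L, size = 2L,
                   signed = TRUE, endian = "little"))
  if (vr %in% c("DS", "IS")) {
    s <- trimws(strsplit(rawToChar(val), "\\", fixed = TRUE)[[1]])
    return(as.numeric(s))
  }
  if (vr %in% c("UI", "LO", "CS", "SH", "PN", "DA", "TM", "AE"))
    return(trimws(rawToChar(val[val != as.raw(0)])))
  val   # raw payload (pixel data and uninterpreted elements)
}

#' Read a DICOM series into a calibrated CT volume
#'
#' Reads every single-frame CT file in `directory_path`, checks that all
#' files belong to one series, converts stored pixel values to Hounsfield
#' units via each file's rescale slope and intercept, and stacks the slices
#' sorted by spatial position (the z component of the image position, so the
#' slice index increases toward the head regardless of file order on disk).
#'
#' @param directory_path directory containing one DICOM series.
#' @return A [ct_volume]. Spacing is taken from the pixel spacing and the
#'   inter-slice distance (falling back to the slice thickness for a
#'   single-slice series).
#' @details Files from mixed series raise `"inconsistent series"`; files
#'   without rescale tags raise `"uncalibrated data"` — stored values are
#'   never passed through silently.
#' @export
read_dicom_series <- function(directory_path) {
  if (!dir.exists(directory_path)) stop("no such directory: ", directory_path)
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[vapply(files, .is_dicom_file, logical(1))]
  if (length(files) == 0L) stop("no DICOM files in ", directory_path)
  parsed <- lapply(sort(files), .read_dicom_file)

  series <- vapply(parsed, function(e) {
    uid <- e[["0020,000e"]]
    if (is.null(uid)) "" else uid
  }, character(1))
  if (length(unique(series)) != 1L) stop("inconsistent series")

  for (e in parsed)
    if (is.null(e[["0028,1052"]]) || is.null(e[["0028,1053"]]))
      stop("uncalibrated data: missing rescale slope/intercept")

  zpos <- vapply(parsed, function(e) {
    ipp <- e[["0020,0032"]]
    if (is.null(ipp) || length(ipp) < 3) NA_real_ else ipp[3]
  }, numeric(1))
  if (anyNA(zpos)) stop("missing image position in series")
  ord <- order(zpos)
  parsed <- parsed[ord]; zpos <- zpos[ord]

  rows <- parsed[[1]][["0028,0010"]]
  cols <- parsed[[1]][["0028,0011"]]
  if (is.null(rows) || is.null(cols)) stop("missing image dimensions")
  for (e in parsed)
    if (!identical(e[["0028,0010"]], rows) || !identical(e[["0028,0011"]], cols))
      stop("inconsistent series")

  ps <- parsed[[1]][["0028,0030"]]   # row spacing, column spacing
  if (is.null(ps) || length(ps) < 2) stop("missing pixel spacing")
  dz <- if (length(zpos) > 1) {
    d <- diff(zpos)
    if (any(d <= 0)) stop("duplicate slice positions in series")
    stats::median(d)
  } else {
    st <- parsed[[1]][["0018,0050"]]
    if (is.null(st)) 1 else st
  }

  nslice <- length(parsed)
  vox <- array(NA_real_, c(nslice, rows, cols))
  for (s in seq_len(nslice)) {
    e <- parsed[[s]]
    signed <- !identical(e[["0028,0103"]], 0L)
    px <- readBin(e[["7fe0,0010"]], "integer", rows * cols, size = 2L,
                  signed = signed, endian = "little")
    if (length(px) != rows * cols) stop("pixel data size mismatch")
    slope <- e[["0028,1053"]]; inter <- e[["0028,1052"]]
    # pixel data is row-major (top row first)
    vox[s, , ] <- t(matrix(slope * px + inter, nrow = cols, ncol = rows))
  }

  pid <- parsed[[1]][["0010,0020"]]
  ct_volume(vox, c(dz, ps[1], ps[2]),
            patient_id = if (is.null(pid)) "anonymous" else pid,
            meta = list(series_uid = series[1], transfer_syntax = "little-endian"))
}

# ---- writer ---------------------------------------------------------------

.enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                 endian = "little")
.enc_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                 endian = "little")

.enc_string <- function(s, pad = charToRaw(" ")) {
  v <- charToRaw(s)
  if (length(v) %% 2L == 1L) v <- c(v, pad)
  v
}

# one explicit-VR little-endian element
.enc_element <- function(group, elem, vr, value) {
  payload <- switch(vr,
    UI = .enc_string(value, pad = as.raw(0)),
    DS = .enc_string(paste(format(value, trim = TRUE, scientific = FALSE),
                           collapse = "\\")),
    IS = .enc_string(paste(as.integer(value), collapse = "\\")),
    US = do.call(c, lapply(value, .enc_u16)),
    CS = , LO = , SH = .enc_string(value),
    OB = , OW = value,
    stop("unsupported VR: ", vr))
  head <- c(.enc_u16(group), .enc_u16(elem), charToRaw(vr))
  if (vr %in% .long_vrs)
    c(head, as.raw(c(0, 0)), .enc_u32(length(payload)), payload)
  else
    c(head, .enc_u16(length(payload)), payload)
}

#' Write a CT volume as a DICOM series
#'
#' Emits one explicit-VR little-endian single-frame CT file per slice, with
#' stored values `(HU - intercept) / slope` and slice positions consistent
#' with the volume's canonical slice order (z increasing with slice index).
#'
#' @param volume a [ct_volume].
#' @param directory_path output directory (created if needed).
#' @param slope,intercept rescale calibration written to each file; stored
#'   values must land in the signed 16-bit range.
#' @return The output directory, invisibly.
#' @export
write_dicom_series <- function(volume, directory_path,
                               slope = 1, intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(directory_path))
    dir.create(directory_path, recursive = TRUE)
  d <- dim(volume$voxels)
  stored_all <- round((volume$voxels - intercept) / slope)
  if (min(stored_all) < -32768 || max(stored_all) > 32767)
    stop("stored values exceed the signed 16-bit range for this calibration")

  uid_tail <- sum(utf8ToInt(volume$patient_id)) %% 100000L
  study_uid  <- sprintf("%s.1.%d", .uid_root, uid_tail)
  series_uid <- sprintf("%s.2.%d", .uid_root, uid_tail)

  for (s in seq_len(d[1])) {
    sop_uid <- sprintf("%s.3.%d.%d", .uid_root, uid_tail, s)
    px <- as.vector(t(stored_all[s, , ]))   # row-major
    pix_raw <- writeBin(as.integer(px), raw(), size = 2L, endian = "little")

    meta_body <- c(
      .enc_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .enc_element(0x0002, 0x0002, "UI", .ct_sop_class),
      .enc_element(0x0002, 0x0003, "UI", sop_uid),
      .enc_element(0x0002, 0x0010, "UI", .ts_explicit_le),
      .enc_element(0x0002, 0x0012, "UI", paste0(.uid_root, ".0.1")))
    # group length element (UL) followed by the meta elements it measures
    meta <- c(.enc_u16(0x0002), .enc_u16(0x0000), charToRaw("UL"),
              .enc_u16(4L), .enc_u32(length(meta_body)), meta_body)

    body <- c(
      .enc_element(0x0008, 0x0016, "UI", .ct_sop_class),
      .enc_element(0x0008, 0x0018, "UI", sop_uid),
      .enc_element(0x0008, 0x0060, "CS", "CT"),
      .enc_element(0x0010, 0x0020, "LO", volume$patient_id),
      .enc_element(0x0018, 0x0050, "DS", volume$spacing_mm[1]),
      .enc_element(0x0020, 0x000d, "UI", study_uid),
      .enc_element(0x0020, 0x000e, "UI", series_uid),
      .enc_element(0x0020, 0x0013, "IS", s),
      .enc_element(0x0020, 0x0032, "DS",
                   c(0, 0, (s - 1) * volume$spacing_mm[1])),
      .enc_element(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
      .enc_element(0x0028, 0x0002, "US", 1L),
      .enc_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .enc_element(0x0028, 0x0010, "US", d[2]),
      .enc_element(0x0028, 0x0011, "US", d[3]),
      .enc_element(0x0028, 0x0030, "DS", volume$spacing_mm[2:3]),
      .enc_element(0x0028, 0x0100, "US", 16L),
      .enc_element(0x0028, 0x0101, "US", 16L),
      .enc_element(0x0028, 0x0102, "US", 15L),
      .enc_element(0x0028, 0x0103, "US", 1L),
      .enc_element(0x0028, 0x1052, "DS", intercept),
      .enc_element(0x0028, 0x1053, "DS", slope),
      .enc_element(0x7fe0, 0x0010, "OW", pix_raw))

    path <- file.path(directory_path, sprintf("IM_%04d.dcm", s))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(directory_path)
}
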