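#' Load a CT series from a directory of DICOM files
#'
#' A deliberately small DICOM part-10 reader covering the subset of the
#' standard that uncompressed CT series use: explicit-VR little-endian
#' transfer syntax, 16-bit signed pixel data, one slice per file. Slices
#' are assembled in spatial order (image position along the slice axis,
#' falling back to instance number), spacing is taken from the series
#' metadata, and stored values are rescaled to Hounsfield units with the
#' slope/intercept tags.
#'
#' @param directory_path directory containing >= 2 slices of one series.
#' @return an [intensity_volume()]; axes are (column, row, slice) with
#'   spacing (column spacing, row spacing, slice step) in mm.
#' @export
load_dicom_series <- function(directory_path) {
  if (!dir.exists(directory_path))
    cs_abort(sprintf("directory '%s' does not exist", directory_path),
             "cranioshape_input_error")
  files <- list.files(directory_path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) < 2L)
    cs_abort("need at least 2 DICOM slices", "cranioshape_input_error")
  slices <- lapply(files, read_dicom_slice)
  rows <- vapply(slices, function(s) s$rows, 0L)
  cols <- vapply(slices, function(s) s$cols, 0L)
  uid <- vapply(slices, function(s) s$series_uid, "")
  if (length(unique(rows)) != 1L || length(unique(cols)) != 1L)
    cs_abort("inconsistent slice dimensions", "cranioshape_format_error")
  if (length(unique(uid)) != 1L)
    cs_abort("directory mixes multiple series", "cranioshape_format_error")
  zpos <- vapply(slices, function(s) s$position[3], 0)
  ord <- if (anyDuplicated(zpos) == 0L) order(zpos)
         else order(vapply(slices, function(s) s$instance, 0L))
  slices <- slices[ord]
  zpos <- zpos[ord]
  dz <- if (length(slices) > 1 && diff(range(diff(zpos))) < 1e-6 &&
            abs(diff(zpos)[1]) > 0) abs(diff(zpos)[1]) else slices[[1]]$thickness
  nx <- slices[[1]]$cols
  ny <- slices[[1]]$rows
  vox <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    vox[, , k] <- s$slope * array(s$pixels, c(nx, ny)) + s$intercept
  }
  intensity_volume(vox,
                   spacing = c(slices[[1]]$pixel_spacing[2],
                               slices[[1]]$pixel_spacing[1], dz),
                   origin = slices[[1]]$position)
}

#' @keywords internal
#' @noRd
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    cs_abort(sprintf("'%s' is not a DICOM part-10 file", path),
             "cranioshape_format_error")
  pos <- 133L
  out <- list(slope = 1, intercept = 0, thickness = 1,
              position = c(0, 0, 0), pixel_spacing = c(1, 1),
              instance = 0L, series_uid = "")
  u16 <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
  u32 <- function(b) as.numeric(b[1]) + 256 * as.numeric(b[2]) +
    65536 * as.numeric(b[3]) + 16777216 * as.numeric(b[4])
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw) + 1L) {
    grp <- u16(raw[pos:(pos + 1)])
    ele <- u16(raw[(pos + 2):(pos + 3)])
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- u32(raw[(pos + 8):(pos + 11)])
      vstart <- pos + 12L
    } else {
      len <- u16(raw[(pos + 6):(pos + 7)])
      vstart <- pos + 8L
    }
    val <- if (len > 0) raw[vstart:(vstart + len - 1)] else raw(0)
    tag <- sprintf("%04X%04X", grp, ele)
    txt <- function() trimws(rawToChar(val))
    if (tag == "00280010") out$rows <- u16(val)
    else if (tag == "00280011") out$cols <- u16(val)
    else if (tag == "00280030")
      out$pixel_spacing <- as.numeric(strsplit(txt(), "\\\\")[[1]])
    else if (tag == "00180050") out$thickness <- as.numeric(txt())
    else if (tag == "00200032")
      out$position <- as.numeric(strsplit(txt(), "\\\\")[[1]])
    else if (tag == "00200013") out$instance <- as.integer(txt())
    else if (tag == "0020000E") out$series_uid <- txt()
    else if (tag == "00281052") out$intercept <- as.numeric(txt())
    else if (tag == "00281053") out$slope <- as.numeric(txt())
    else if (tag == "00280100") out$bits <- u16(val)
    else if (tag == "7FE00010") {
      out$pixels <- readBin(val, "integer", n = len / 2, size = 2,
                            endian = "little", signed = TRUE)
    }
    pos <- vstart + len
  }
  if (is.null(out$rows) || is.null(out$cols) || is.null(out$pixels))
    cs_abort(sprintf("'%s' lacks image data", path), "cranioshape_format_error")
  if (length(out$pixels) != out$rows * out$cols)
    cs_abort(sprintf("'%s' pixel data does not match dimensions", path),
             "cranioshape_format_error")
  out
}

#' Write an intensity volume as a DICOM series
#'
#' Companion writer to [load_dicom_series()]: one explicit-VR
#' little-endian part-10 file per slice, 16-bit signed pixels, with the
#' given rescale slope/intercept (stored value = (HU - intercept)/slope).
#' Used to exercise the CT input path with synthetic phantoms.
#'
#' @param volume an [intensity_volume()].
#' @param directory_path output directory (created if missing).
#' @param slope,intercept rescale tags; defaults 1 and -1024.
#' @param series_uid series identifier shared by all slices.
#' @return the directory path, invisibly.
#' @export
write_dicom_series <- function(volume, directory_path, slope = 1,
                               intercept = -1024,
                               series_uid = "1.2.826.0.1.3680043.9999.1") {
  if (!dir.exists(directory_path))
    dir.create(directory_path, recursive = TRUE)
  d <- dim(volume$voxels)
  for (k in seq_len(d[3])) {
    sl <- volume$voxels[, , k]
    stored <- round((sl - intercept) / slope)
    pos <- volume$origin + c(0, 0, (k - 1) * volume$spacing[3])
    write_dicom_slice(
      file.path(directory_path, sprintf("slice%04d.dcm", k)),
      stored, rows = d[2], cols = d[1],
      pixel_spacing = c(volume$spacing[2], volume$spacing[1]),
      thickness = volume$spacing[3], position = pos, instance = k,
      slope = slope, intercept = intercept, series_uid = series_uid)
  }
  invisible(directory_path)
}

#' @keywords internal
#' @noRd
write_dicom_slice <- function(path, stored, rows, cols, pixel_spacing,
                              thickness, position, instance, slope,
                              intercept, series_uid) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  short_el <- function(grp, ele, vr, val) {
    if (is.character(val)) {
      b <- charToRaw(val)
      if (length(b) %% 2 == 1)
        b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    } else b <- val
    w16(grp); w16(ele)
    writeBin(charToRaw(vr), con)
    w16(length(b))
    writeBin(b, con)
  }
  us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  ds <- function(x) paste(sprintf("%.8g", x), collapse = "\\")
  short_el(0x0020, 0x000E, "UI", series_uid)
  short_el(0x0020, 0x0013, "IS", sprintf("%d", instance))
  short_el(0x0020, 0x0032, "DS", ds(position))
  short_el(0x0018, 0x0050, "DS", ds(thickness))
  short_el(0x0028, 0x0010, "US", us(rows))
  short_el(0x0028, 0x0011, "US", us(cols))
  short_el(0x0028, 0x0030, "DS", ds(pixel_spacing))
  short_el(0x0028, 0x0100, "US", us(16))
  short_el(0x0028, 0x0101, "US", us(16))
  short_el(0x0028, 0x0102, "US", us(15))
  short_el(0x0028, 0x0103, "US", us(1))
  short_el(0x0028, 0x1052, "DS", sprintf("%.8g", intercept))
  short_el(0x0028, 0x1053, "DS", sprintf("%.8g", slope))
  px <- as.integer(round(stored))
  w16(0x7FE0); w16(0x0010)
  writeBin(charToRaw("OW"), con)
  w16(0)
  writeBin(as.integer(2 * length(px)), con, size = 4, endian = "little")
  writeBin(px, con, size = 2, endian = "little")
  invisible(path)
}
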