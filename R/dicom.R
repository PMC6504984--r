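#' Write and read a DICOM series
#'
#' Minimal single-frame CT DICOM support (explicit VR little endian,
#' MONOCHROME2, signed 16-bit stored pixels with RescaleSlope and
#' RescaleIntercept), one file per axial slice. This is deliberately a
#' small, self-contained subset of the standard: enough to round-trip
#' the package's voxel volumes and to read series whose slice files
#' arrive in arbitrary order (slices are re-assembled by their
#' ImagePositionPatient, not by file name).
#'
#' @param vol a [voxel_volume()].
#' @param dir directory for the slice files (created if missing).
#' @return `write_dicom_series`: the directory, invisibly.
#'   `read_dicom_series`: a [voxel_volume()]; stored HU values are
#'   quantized to integers via slope/intercept, so round-trip error is
#'   at most 0.5 HU with the default slope of 1.
#' @export
write_dicom_series <- function(vol, dir) {
  if (!inherits(vol, "voxel_volume"))
    mf_stop("mf_invalid_volume", "vol must be a voxel_volume")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$values)
  sp <- vol$spacing_mm
  slope <- 1
  intercept <- 0
  series_uid <- dicom_uid(1L)
  study_uid <- dicom_uid(2L)
  for (k in seq_len(d[3])) {
    slice <- vol$values[, , k]
    stored <- as.integer(round((slice - intercept) / slope))
    if (any(stored < -32768L | stored > 32767L))
      mf_stop("mf_format_error", "HU values out of int16 range in slice %d", k)
    ipp <- vol$origin_mm + 0.5 * sp
    ipp[3] <- ipp[3] + (k - 1) * sp[3]
    path <- file.path(dir, sprintf("slice_%04d.dcm", k))
    write_dicom_slice(path, stored, nx = d[1], ny = d[2],
                      spacing = sp, ipp = ipp, slope = slope,
                      intercept = intercept, instance = k,
                      series_uid = series_uid, study_uid = study_uid)
  }
  invisible(dir)
}

dicom_uid <- local({
  counter <- 0L
  function(extra = 0L) {
    counter <<- counter + 1L
    sprintf("1.2.826.0.1.3680043.9.7433.%d.%d.%d",
            as.integer(Sys.getpid()) %% 100000L, extra, counter)
  }
})

# -- element encoders (explicit VR little endian) ---------------------------

dcm_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

dcm_elem_str <- function(group, elem, vr, value) {
  val <- charToRaw(value)
  if (length(val) %% 2L == 1L)
    val <- c(val, if (vr == "UI") as.raw(0) else charToRaw(" "))
  c(dcm_uint(group, 2L), dcm_uint(elem, 2L), charToRaw(vr),
    dcm_uint(length(val), 2L), val)
}

dcm_elem_us <- function(group, elem, value) {
  c(dcm_uint(group, 2L), dcm_uint(elem, 2L), charToRaw("US"),
    dcm_uint(2L, 2L), dcm_uint(value, 2L))
}

dcm_elem_ow <- function(group, elem, payload) {
  c(dcm_uint(group, 2L), dcm_uint(elem, 2L), charToRaw("OW"),
    as.raw(c(0, 0)), dcm_uint(length(payload), 4L), payload)
}

dcm_ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

write_dicom_slice <- function(path, stored, nx, ny, spacing, ipp,
                              slope, intercept, instance,
                              series_uid, study_uid) {
  sop_class <- "1.2.840.10008.5.1.4.1.1.2" # CT Image Storage
  sop_uid <- dicom_uid(3L)
  meta <- c(
    dcm_elem_str(0x0002, 0x0002, "UI", sop_class),
    dcm_elem_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  meta <- c(
    c(dcm_uint(0x0002, 2L), dcm_uint(0x0000, 2L), charToRaw("UL"),
      dcm_uint(4L, 2L), dcm_uint(length(meta), 4L)),
    meta
  )
  pix <- writeBin(stored, raw(), size = 2L, endian = "little")
  body <- c(
    dcm_elem_str(0x0008, 0x0016, "UI", sop_class),
    dcm_elem_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_elem_str(0x0008, 0x0060, "CS", "CT"),
    dcm_elem_str(0x0018, 0x0050, "DS", dcm_ds(spacing[3])),
    dcm_elem_str(0x0020, 0x000D, "UI", study_uid),
    dcm_elem_str(0x0020, 0x000E, "UI", series_uid),
    dcm_elem_str(0x0020, 0x0013, "IS", sprintf("%d", instance)),
    dcm_elem_str(0x0020, 0x0032, "DS", dcm_ds(ipp)),
    dcm_elem_str(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    dcm_elem_us(0x0028, 0x0002, 1L),                 # SamplesPerPixel
    dcm_elem_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_elem_us(0x0028, 0x0010, ny),                 # Rows
    dcm_elem_us(0x0028, 0x0011, nx),                 # Columns
    dcm_elem_str(0x0028, 0x0030, "DS", dcm_ds(spacing[c(2, 1)])),
    dcm_elem_us(0x0028, 0x0100, 16L),                # BitsAllocated
    dcm_elem_us(0x0028, 0x0101, 16L),                # BitsStored
    dcm_elem_us(0x0028, 0x0102, 15L),                # HighBit
    dcm_elem_us(0x0028, 0x0103, 1L),                 # PixelRepresentation
    dcm_elem_str(0x0028, 0x1052, "DS", dcm_ds(intercept)),
    dcm_elem_str(0x0028, 0x1053, "DS", dcm_ds(slope)),
    dcm_elem_ow(0x7FE0, 0x0010, pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
}

# -- reader -----------------------------------------------------------------

read_dicom_slice <- function(path) {
  size <- file.info(path)$size
  buf <- readBin(path, "raw", n = size)
  if (size < 140 || rawToChar(buf[129:132]) != "DICM")
    mf_stop("mf_format_error", "not a DICOM file: %s", basename(path))
  pos <- 133L
  u16 <- function(at) {
    as.integer(buf[at]) + 256L * as.integer(buf[at + 1L])
  }
  u32 <- function(at) {
    as.integer(buf[at]) + 256 * as.integer(buf[at + 1L]) +
      65536 * as.integer(buf[at + 2L]) + 16777216 * as.integer(buf[at + 3L])
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  while (pos + 7L <= size + 1L) {
    group <- u16(pos)
    elem <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      val_at <- pos + 8L
    }
    if (val_at + len - 1L > size)
      mf_stop("mf_format_error", "truncated DICOM element in %s",
              basename(path))
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr,
                        value = buf[seq.int(val_at, length.out = len)])
    pos <- val_at + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  str_of <- function(key) {
    v <- tags[[key]]
    if (is.null(v)) mf_stop("mf_format_error", "missing DICOM tag (%s) in %s",
                            key, basename(path))
    val <- v$value
    while (length(val) && val[length(val)] %in% as.raw(c(0x00, 0x20)))
      val <- val[-length(val)]
    rawToChar(val)
  }
  ds_of <- function(key) as.numeric(strsplit(str_of(key), "\\", fixed = TRUE)[[1]])
  us_of <- function(key) {
    v <- tags[[key]]
    as.integer(v$value[1]) + 256L * as.integer(v$value[2])
  }
  nx <- us_of("0028,0011")
  ny <- us_of("0028,0010")
  signed <- us_of("0028,0103") == 1L
  pix <- readBin(tags[["7fe0,0010"]]$value, "integer", n = nx * ny,
                 size = 2L, signed = signed, endian = "little")
  if (length(pix) != nx * ny)
    mf_stop("mf_format_error", "pixel payload size mismatch in %s",
            basename(path))
  slope <- ds_of("0028,1053")
  intercept <- ds_of("0028,1052")
  list(ipp = ds_of("0020,0032"),
       spacing_xy = ds_of("0028,0030")[c(2, 1)],
       nx = nx, ny = ny,
       hu = matrix(pix * slope + intercept, nrow = nx, ncol = ny))
}

#' @rdname write_dicom_series
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir))
    mf_stop("mf_format_error", "no such directory: %s", dir)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L)
    mf_stop("mf_format_error", "no DICOM slices found in %s", dir)
  slices <- lapply(files, read_dicom_slice)
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  files <- files[ord]
  z <- z[ord]
  nx <- slices[[1]]$nx
  ny <- slices[[1]]$ny
  sp_xy <- slices[[1]]$spacing_xy
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (s$nx != nx || s$ny != ny ||
        max(abs(s$spacing_xy - sp_xy)) > 1e-6)
      mf_stop("mf_format_error",
              "slice %s has mismatched dimensions or pixel spacing",
              basename(files[i]))
  }
  if (length(slices) < 2L)
    mf_stop("mf_format_error", "series needs at least two slices")
  dz <- diff(z)
  if (max(dz) - min(dz) > 1e-4 * mean(dz))
    mf_stop("mf_format_error",
            "non-uniform slice spacing around %s (missing slice?)",
            basename(files[which.max(abs(dz - mean(dz)))]))
  vals <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) vals[, , k] <- slices[[k]]$hu
  spacing <- c(sp_xy, mean(dz))
  origin <- slices[[1]]$ipp - 0.5 * spacing
  voxel_volume(vals, spacing, origin)
}
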