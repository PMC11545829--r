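# Minimal DICOM I/O: explicit-VR little-endian, uncompressed, single-frame
# grayscale only.  The reader covers what CT slice files need (geometry,
# rescale calibration, pixel data); the writer exists to build test fixtures
# and phantom exports, nothing more.

.dcm_u16 <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
.dcm_u32 <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")

.dcm_pad <- function(s, pad = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

# one explicit-VR data element
.dcm_element <- function(group, elem, vr, value_raw) {
  n <- length(value_raw)
  head <- c(.dcm_u16(group), .dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .dcm_u32(n), value_raw)
  } else {
    c(head, .dcm_u16(n), value_raw)
  }
}

#' Write a single CT slice as a DICOM file (fixture writer)
#'
#' Writes an explicit-VR little-endian single-frame DICOM file holding signed
#' 16-bit raw values plus the rescale calibration and geometry tags that
#' [read_dicom_series] consumes.  Intended for building test fixtures and
#' exporting phantom slices.
#'
#' @param raw_pixels integer matrix `[y, x]` of stored values in -32768..32767.
#' @param path output file path.
#' @param slope,intercept rescale calibration (`HU = slope * raw + intercept`).
#' @param spacing_mm length-2 pixel spacing (y, x) in mm.
#' @param position_z z coordinate (mm) written to ImagePositionPatient and
#'   SliceLocation.
#' @param instance InstanceNumber tag value.
#' @export
write_dicom_slice <- function(raw_pixels, path, slope = 1, intercept = -1024,
                              spacing_mm = c(1, 1), position_z = 0, instance = 1) {
  px <- round(.as_pixels(raw_pixels))
  if (length(dim(px)) != 2)
    .stop_typed("lungscreen_format_error", "write_dicom_slice requires a 2D matrix")
  if (any(px < -32768 | px > 32767))
    .stop_typed("lungscreen_format_error", "raw values outside signed 16-bit range")
  ds <- function(x) .dcm_pad(paste(format(x, trim = TRUE, scientific = FALSE), collapse = "\\"))
  # pixel data row-major within each row direction: DICOM stores row by row
  pix <- writeBin(as.integer(t(px)), raw(), size = 2, endian = "little")
  body <- c(
    .dcm_element(0x0008, 0x0060, "CS", .dcm_pad("CT")),
    .dcm_element(0x0020, 0x0013, "IS", ds(instance)),
    .dcm_element(0x0020, 0x0032, "DS", ds(c(0, 0, position_z))),
    .dcm_element(0x0020, 0x1041, "DS", ds(position_z)),
    .dcm_element(0x0028, 0x0002, "US", .dcm_u16(1)),
    .dcm_element(0x0028, 0x0004, "CS", .dcm_pad("MONOCHROME2")),
    .dcm_element(0x0028, 0x0010, "US", .dcm_u16(nrow(px))),
    .dcm_element(0x0028, 0x0011, "US", .dcm_u16(ncol(px))),
    .dcm_element(0x0028, 0x0030, "DS", ds(spacing_mm)),
    .dcm_element(0x0028, 0x0100, "US", .dcm_u16(16)),
    .dcm_element(0x0028, 0x0101, "US", .dcm_u16(16)),
    .dcm_element(0x0028, 0x0102, "US", .dcm_u16(15)),
    .dcm_element(0x0028, 0x0103, "US", .dcm_u16(1)),
    .dcm_element(0x0028, 0x1052, "DS", ds(intercept)),
    .dcm_element(0x0028, 0x1053, "DS", ds(slope)),
    .dcm_element(0x7FE0, 0x0010, "OW", pix))
  meta <- c(
    .dcm_element(0x0002, 0x0010, "UI", .dcm_pad("1.2.840.10008.1.2.1", as.raw(0))))
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", .dcm_u32(length(meta))), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# parse one DICOM file into a list of the tags we use
.read_dicom_file <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(buf) >= 132 && rawToChar(buf[129:132]) == "DICM") pos <- 133L
  u16 <- function(at) sum(as.integer(buf[at:(at + 1)]) * c(1, 256))
  u32 <- function(at) sum(as.integer(buf[at:(at + 3)]) * c(1, 256, 65536, 16777216))
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(buf)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) { len <- u32(pos + 8); pos <- pos + 12L }
      else { len <- u16(pos + 6); pos <- pos + 8L }
    } else { # implicit VR fallback
      vr <- "UN"; len <- u32(pos + 4); pos <- pos + 8L
    }
    if (len == 0xFFFFFFFF || pos + len - 1 > length(buf))
      .stop_typed("lungscreen_format_error", "unsupported or truncated DICOM element in %s", path)
    val <- buf[pos:(pos + len - 1)]
    pos <- pos + len
    key <- sprintf("%04X%04X", group, elem)
    out[[key]] <- list(vr = vr, raw = val)
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  str_tag <- function(key) {
    v <- out[[key]]; if (is.null(v)) return(NULL)
    trimws(rawToChar(v$raw))
  }
  num_tag <- function(key) {
    s <- str_tag(key); if (is.null(s) || s == "") return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us_tag <- function(key) {
    v <- out[[key]]; if (is.null(v)) return(NULL)
    sum(as.integer(v$raw[1:2]) * c(1, 256))
  }
  rows <- us_tag("00280010"); cols <- us_tag("00280011")
  pd <- out[["7FE00010"]]
  if (is.null(rows) || is.null(cols) || is.null(pd))
    .stop_typed("lungscreen_format_error", "no readable pixel data in %s", path)
  bits <- us_tag("00280100"); if (is.null(bits)) bits <- 16
  if (bits != 16)
    .stop_typed("lungscreen_format_error", "only 16-bit pixel data supported (%s)", path)
  signed <- identical(us_tag("00280103"), 1L) || identical(us_tag("00280103"), 1)
  vals <- readBin(pd$raw, "integer", n = rows * cols, size = 2,
                  endian = "little", signed = TRUE)
  if (!signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  ipp <- num_tag("00200032")
  list(pixels = t(matrix(vals, nrow = cols, ncol = rows)),  # stored row-major
       rows = rows, cols = cols,
       slope = num_tag("00281053"), intercept = num_tag("00281052"),
       spacing = num_tag("00280030"),
       z = if (!is.null(ipp)) ipp[3] else num_tag("00201041"),
       instance = num_tag("00200013"))
}

#' Read a DICOM series from a directory
#'
#' Reads every file in `path`, sorts slices by spatial position
#' (ImagePositionPatient z, falling back to SliceLocation then
#' InstanceNumber), applies the rescale calibration
#' `HU = slope * raw + intercept` when present, and stacks the slices into a
#' [ct_image].  A single-slice directory yields a 2D image.
#'
#' @param path directory containing at least one readable DICOM file.
#' @return a [ct_image] in HU when calibration tags are present.
#' @export
read_dicom_series <- function(path) {
  if (!dir.exists(path)) .stop_typed("lungscreen_io_error", "no such directory: %s", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) .stop_typed("lungscreen_io_error", "empty directory: %s", path)
  slices <- list()
  for (f in files) {
    s <- tryCatch(.read_dicom_file(f), error = function(e) NULL)
    if (!is.null(s)) slices[[length(slices) + 1]] <- s
  }
  if (length(slices) == 0)
    .stop_typed("lungscreen_format_error", "no readable DICOM pixel data under %s", path)
  shapes <- vapply(slices, function(s) paste(s$rows, s$cols), "")
  if (length(unique(shapes)) != 1)
    .stop_typed("lungscreen_format_error", "inconsistent slice shapes: %s",
                paste(unique(shapes), collapse = " vs "))
  zs <- vapply(slices, function(s) {
    z <- s$z; if (is.null(z) || is.na(z)) s$instance %||% 0 else z
  }, 0)
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  has_cal <- !is.null(slices[[1]]$slope) && !is.null(slices[[1]]$intercept)
  px <- lapply(slices, function(s) {
    if (has_cal) s$slope * s$pixels + s$intercept else s$pixels
  })
  sp <- slices[[1]]$spacing
  if (is.null(sp)) sp <- c(1, 1)
  dz <- if (length(zs) > 1) median(diff(zs)) else 1
  if (!is.finite(dz) || dz <= 0) dz <- 1
  if (length(px) == 1) {
    ct_image(px[[1]], spacing_mm = sp, is_hu = has_cal)
  } else {
    vol <- array(unlist(px), dim = c(nrow(px[[1]]), ncol(px[[1]]), length(px)))
    ct_image(vol, spacing_mm = c(sp, dz), is_hu = has_cal)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
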