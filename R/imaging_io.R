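#' CT image container
#'
#' A light container for a 2D slice or 3D volume of CT intensities together
#' with the geometry and calibration metadata the pipeline needs.  Pixels are
#' stored column-major as R arrays indexed `[y, x]` (2D) or `[y, x, z]` (3D),
#' 1-based; physical coordinates reported downstream are
#' `(index - 1) * spacing_mm`.
#'
#' @param pixels numeric matrix (2D) or 3D array of intensities, all finite.
#' @param spacing_mm positive per-axis voxel spacing in mm, ordered (y, x)
#'   or (y, x, z).  Recycled from length 1.
#' @param rescale_slope,rescale_intercept DICOM-style affine calibration
#'   mapping stored values to Hounsfield units (HU): `HU = slope * raw +
#'   intercept`.
#' @param is_hu logical; `TRUE` when `pixels` are already in HU.
#' @return an object of class `ct_image`.
#' @export
ct_image <- function(pixels, spacing_mm = 1, rescale_slope = 1,
                     rescale_intercept = 0, is_hu = FALSE) {
  if (!is.numeric(pixels)) .stop_typed("lungscreen_format_error", "pixels must be numeric")
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1)
  nd <- length(dim(pixels))
  if (nd != 2 && nd != 3)
    .stop_typed("lungscreen_format_error", "pixels must be a 2D matrix or 3D array, got rank %d", nd)
  if (!all(is.finite(pixels)))
    .stop_typed("lungscreen_format_error", "pixels contain non-finite values")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, nd)
  if (length(spacing_mm) != nd || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    .stop_typed("lungscreen_parameter_error", "spacing_mm must be %d strictly positive reals", nd)
  structure(list(pixels = pixels, spacing_mm = as.numeric(spacing_mm),
                 rescale_slope = as.numeric(rescale_slope),
                 rescale_intercept = as.numeric(rescale_intercept),
                 is_hu = isTRUE(is_hu)),
            class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ct_image> %s px, spacing %s mm, %s, range [%.1f, %.1f]\n",
              paste(d, collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = "x"),
              if (x$is_hu) "HU" else "raw",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ct_image <- function(x) dim(x$pixels)

.as_pixels <- function(img) {
  if (inherits(img, "ct_image")) img$pixels else img
}

#' Read a 2D grayscale raster image
#'
#' Reads an 8-bit grayscale PNG or a TIFF into a [ct_image] with unit spacing
#' and `is_hu = FALSE`.  Multi-channel images are converted to luminance
#' (0.299 R + 0.587 G + 0.114 B) with a warning.  PNG samples are returned on
#' the 0..255 scale; TIFF samples are returned as stored.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a 2D [ct_image].
#' @export
read_image2d <- function(path) {
  if (!file.exists(path))
    .stop_typed("lungscreen_io_error", "image file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    .stop_typed("lungscreen_format_error", "unsupported image extension: %s", ext))
  if (length(dim(px)) == 3) {
    nch <- dim(px)[3]
    w <- c(0.299, 0.587, 0.114, 0)[seq_len(min(nch, 4))]
    if (nch < 3) w <- rep(1 / nch, nch)
    warning(sprintf("converting %d-channel image to luminance", nch))
    px <- Reduce(`+`, lapply(seq_len(nch), function(i) px[, , i] * w[i]))
  }
  ct_image(px, spacing_mm = 1, is_hu = FALSE)
}

#' Write a 2D image as 8-bit grayscale PNG
#'
#' Values are expected on the 0..255 scale (see [rescale_for_display]) and are
#' clipped and quantized before writing.
#'
#' @param img a [ct_image] or numeric matrix on the 0..255 scale.
#' @param path output path.
#' @export
write_image2d <- function(img, path) {
  px <- .as_pixels(img)
  if (length(dim(px)) != 2)
    .stop_typed("lungscreen_format_error", "write_image2d requires a 2D image")
  px <- pmin(pmax(px, 0), 255)
  png::writePNG(round(px) / 255, target = path)
  invisible(path)
}

#' Window a CT image for 8-bit display
#'
#' Clips intensities to the window `[center - width/2, center + width/2]` and
#' maps them monotonically to 0..255.  The default window is the standard
#' lung window (center -600 HU, width 1500 HU).  When `inverse_log = TRUE`
#' the normalized value `x` in `[0, 1]` is passed through the exponential tone
#' curve `(base^x - 1) / (base - 1)` before quantization; the default is the
#' plain linear mapping, since all downstream arithmetic works on intensities
#' rather than display values.
#'
#' @param img a [ct_image] or numeric array.
#' @param window_center window center (same units as the image).
#' @param window_width window width, strictly positive.
#' @param inverse_log apply the exponential tone curve before quantization?
#' @param base base of the tone curve (must be > 1).
#' @return numeric array of the same shape with values in 0..255.
#' @export
rescale_for_display <- function(img, window_center = -600, window_width = 1500,
                                inverse_log = FALSE, base = 10) {
  if (!is.finite(window_width) || window_width <= 0)
    .stop_typed("lungscreen_parameter_error", "window_width must be > 0")
  px <- .as_pixels(img)
  lo <- window_center - window_width / 2
  x <- (pmin(pmax(px, lo), lo + window_width) - lo) / window_width
  if (inverse_log) {
    if (base <= 1) .stop_typed("lungscreen_parameter_error", "tone-curve base must be > 1")
    x <- (base^x - 1) / (base - 1)
  }
  x * 255
}

#' Write nodule candidates to CSV
#'
#' One row per candidate with the header
#' `id,x_mm,y_mm,z_mm,area_mm2,volume_mm3,elongation,overlap,solid,score`.
#' Physical coordinates are `(index - 1) * spacing` in mm.
#'
#' @param candidates a data frame as returned by [measure_candidates].
#' @param path output path.
#' @export
write_candidates_csv <- function(candidates, path) {
  cols <- c("id", "x_mm", "y_mm", "z_mm", "area_mm2", "volume_mm3",
            "elongation", "overlap", "solid", "score")
  df <- as.data.frame(candidates)
  if (nrow(df) == 0) df <- setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .stop_typed("lungscreen_format_error", "candidates lack columns: %s",
                paste(missing, collapse = ", "))
  df <- df[cols]
  num <- setdiff(cols, c("id", "solid"))
  df[num] <- lapply(df[num], function(v) signif(as.numeric(v), 8))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) .stop_typed("lungscreen_io_error", "cannot write candidates to %s", path)
  invisible(path)
}

#' Read a candidate CSV written by [write_candidates_csv]
#' @param path input path.
#' @return a data frame of candidates.
#' @export
read_candidates_csv <- function(path) {
  if (!file.exists(path)) .stop_typed("lungscreen_io_error", "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df)) df$solid <- as.logical(df$solid)
  df
}
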