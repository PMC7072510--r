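#' A single fluorescence field
#'
#' Light container for one grayscale micrograph: an integer-valued intensity
#' matrix in raw camera units (a.u.), the physical pixel size, and the
#' saturation value of the detector (65535 for the canonical 16-bit case).
#' The matrix is indexed `[row = y, col = x]`, matching how TIFFs are read.
#'
#' @param pixels Numeric matrix of non-negative intensities (a.u.).
#' @param pixel_size_um Physical size of one pixel side, in micrometres (> 0).
#' @param saturation_value Maximum representable intensity (default 65535).
#' @return An object of class `mn_image`.
#' @export
image_plane <- function(pixels, pixel_size_um, saturation_value = 65535) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have width >= 1 and height >= 1", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains missing pixel values", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0) stop("negative pixel intensities are not allowed", call. = FALSE)
  if (rng[2] > saturation_value) {
    stop("pixel values exceed `saturation_value`", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      pixel_size_um = as.numeric(pixel_size_um),
      saturation_value = as.numeric(saturation_value)
    ),
    class = "mn_image"
  )
}

#' @export
print.mn_image <- function(x, ...) {
  cat(sprintf(
    "<mn_image> %d x %d px (%.3g x %.3g um), pixel size %.3g um, max %g / %g a.u.\n",
    ncol(x$pixels), nrow(x$pixels),
    ncol(x$pixels) * x$pixel_size_um, nrow(x$pixels) * x$pixel_size_um,
    x$pixel_size_um, max(x$pixels), x$saturation_value
  ))
  invisible(x)
}

#' @export
dim.mn_image <- function(x) dim(x$pixels)

#' Read a single-channel TIFF field
#'
#' Reads one grayscale TIFF plane as raw integer intensities. Multi-page and
#' RGB/multi-sample TIFFs are rejected: the assay consumes exactly one
#' DNA-stain channel per field. The saturation value is inferred from the
#' file's bit depth (8 or 16 bits per sample).
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Physical pixel size in micrometres; mandatory because
#'   TIFF metadata from plate readers is unreliable and every size threshold
#'   in the method is expressed in micrometres.
#' @return An [image_plane()] object.
#' @export
read_field <- function(path, pixel_size_um) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, as.is = TRUE, all = TRUE, info = TRUE),
    error = function(e) stop("unreadable TIFF: ", path, " (", conditionMessage(e), ")",
                             call. = FALSE)
  )
  if (length(pages) != 1L) {
    stop("multi-page TIFF not supported (", length(pages), " pages): ", path,
         call. = FALSE)
  }
  px <- pages[[1L]]
  if (length(dim(px)) != 2L) {
    stop("not single-channel: ", path, " has ", dim(px)[3L], " samples per pixel",
         call. = FALSE)
  }
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported bit depth (", bits, "); expected 8- or 16-bit grayscale",
         call. = FALSE)
  }
  image_plane(matrix(as.numeric(px), nrow(px), ncol(px)),
              pixel_size_um = pixel_size_um,
              saturation_value = 2^bits - 1)
}

#' Write a field as a grayscale TIFF
#'
#' Inverse of [read_field()]: intensities are stored losslessly at the bit
#' depth implied by the image's saturation value (255 -> 8-bit, 65535 ->
#' 16-bit), so a write/read round trip is pixel-identical.
#'
#' @param image An [image_plane()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(image, path) {
  stopifnot(inherits(image, "mn_image"))
  bits <- if (image$saturation_value <= 255) 8L else 16L
  sat <- 2^bits - 1
  if (image$saturation_value != sat) {
    stop("saturation_value must be 255 or 65535 for TIFF export", call. = FALSE)
  }
  tiff::writeTIFF(round(image$pixels) / sat, path, bits.per.sample = bits,
                  compression = "none")
  invisible(path)
}

#' Advisory exposure / clipping check
#'
#' Exposure for this assay is set to the longest time that keeps typical
#' interphase nuclei around 80% of detector saturation, so that dim
#' micronuclei remain measurable while bright nuclei do not clip. This helper
#' reports, among bright-object candidate pixels, the fraction sitting at or
#' above `fraction` of saturation, and warns when that fraction suggests the
#' field is clipped.
#'
#' @param image An [image_plane()] object.
#' @param fraction Saturation fraction regarded as the exposure ceiling
#'   (default 0.8).
#' @param candidate_threshold_au Intensity above which a pixel is treated as
#'   belonging to a bright object (default half of saturation).
#' @return A one-row tibble with `n_candidate_px`, `fraction_at_ceiling`, and
#'   a logical `pass` flag. Advisory only; never errors.
#' @export
check_saturation <- function(image, fraction = 0.8,
                             candidate_threshold_au = 0.5 * image$saturation_value) {
  stopifnot(inherits(image, "mn_image"), fraction > 0, fraction <= 1)
  ceiling_au <- fraction * image$saturation_value
  cand <- image$pixels[image$pixels >= candidate_threshold_au]
  frac_hi <- if (length(cand) == 0L) 0 else mean(cand >= ceiling_au)
  pass <- frac_hi <= 0.5
  if (!pass) {
    warning(sprintf(
      "possible clipping: %.0f%% of bright-object pixels are at or above %.0f%% of saturation",
      100 * frac_hi, 100 * fraction), call. = FALSE)
  }
  tibble::tibble(
    n_candidate_px = length(cand),
    fraction_at_ceiling = frac_hi,
    ceiling_au = ceiling_au,
    pass = pass
  )
}
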