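#' Segment one field end-to-end
#'
#' Runs the full per-field chain: optional rolling-ball background
#' flattening, primary (nuclear) mask, optional mask reduction, secondary
#' ring mask, spot detection, and the periphery / intensity exclusion
#' filters. Thresholding operates on the flattened image when flattening is
#' enabled; all object intensities are measured on the raw image so the
#' mean-intensity filter sees true stain brightness. The micronucleus size
#' cap needs a plate-level calibration and is applied here only when one is
#' supplied (otherwise apply [mn_size_filter()] later, after calibrating on
#' pooled control fields).
#'
#' @param image [image_plane()] raw field.
#' @param params [seg_params()] profile.
#' @param filters [filter_params()]; the intensity filter runs only if
#'   `max_mean_intensity_au` is set.
#' @param size_calibration Optional [calibrate_mn_size()] result.
#' @return An object of class `mn_field`: list with tibbles `nuclei` and
#'   `spots`, the `mask` and `rings` objects, and the parameters used.
#' @export
segment_field <- function(image, params, filters = filter_params(),
                          size_calibration = NULL) {
  stopifnot(inherits(image, "mn_image"), inherits(params, "mn_seg_params"),
            inherits(filters, "mn_filter_params"))
  work <- if (params$background_flatten) {
    flatten_background(image, params$rolling_ball_radius_um)
  } else {
    image
  }
  mask <- primary_mask(work, params, measure = image)
  if (params$reduce_primary_mask_um > 0) {
    mask <- reduce_mask(mask, params$reduce_primary_mask_um, measure = image)
  }
  rings <- secondary_mask(mask, params$ring_width_um)
  spots <- detect_spots(work, mask, rings, params, measure = image)
  nuclei <- ensure_nucleus_flags(mask$objects)

  nuclei <- periphery_filter(nuclei, dim(image), filters$periphery_margin_um,
                             image$pixel_size_um)
  if (!is.null(filters$max_mean_intensity_au)) {
    nuclei <- intensity_filter(nuclei, filters$max_mean_intensity_au)
    spots <- intensity_filter(spots, filters$max_mean_intensity_au)
  }
  if (!is.null(size_calibration)) {
    spots <- mn_size_filter(spots, size_calibration)
  }
  spots <- flag_orphans(spots, nuclei)

  structure(
    list(nuclei = nuclei, spots = spots, mask = mask, rings = rings,
         params = params, filters = filters, dims = dim(image),
         pixel_size_um = image$pixel_size_um),
    class = "mn_field"
  )
}

#' @export
print.mn_field <- function(x, ...) {
  cat(sprintf(
    "<mn_field> %d nuclei (%d retained), %d micronucleus candidates (%d retained)\n",
    nrow(x$nuclei), sum(x$nuclei$retained),
    nrow(x$spots), sum(x$spots$retained)))
  invisible(x)
}

#' Retained counts of one segmented field
#'
#' @param field An `mn_field` from [segment_field()].
#' @return One-row tibble with `n_nuclei` and `n_micronuclei` (retained).
#' @export
count_field <- function(field) {
  stopifnot(inherits(field, "mn_field"))
  tibble::tibble(
    n_nuclei = sum(field$nuclei$retained),
    n_micronuclei = sum(field$spots$retained)
  )
}

#' Segment every field of a plate directory
#'
#' Consumes the directory layout the synthetic generator (and the command
#' line tool) use: one subdirectory per well, holding that well's field
#' TIFFs. Corrupt or unreadable fields are skipped with a warning and
#' recorded, and the run continues.
#'
#' @param dir Plate directory (subdirectories = well ids).
#' @param pixel_size_um Physical pixel size (um).
#' @param params,filters,size_calibration As in [segment_field()].
#' @param wells Optional character vector restricting the wells processed.
#' @return A list: `field_counts` (tibble well_id/field/n_nuclei/
#'   n_micronuclei), `nuclei` and `spots` (object tables with well and field
#'   columns), `skipped` (tibble of unreadable files).
#' @export
segment_plate_dir <- function(dir, pixel_size_um, params,
                              filters = filter_params(),
                              size_calibration = NULL, wells = NULL) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  well_dirs <- list.dirs(dir, recursive = FALSE)
  if (!is.null(wells)) well_dirs <- well_dirs[basename(well_dirs) %in% wells]
  if (!length(well_dirs)) stop("no images found under ", dir, call. = FALSE)
  counts <- list(); nuc_all <- list(); spot_all <- list(); skipped <- list()
  for (wd in well_dirs) {
    well <- basename(wd)
    tifs <- sort(list.files(wd, pattern = "\\.tiff?$", full.names = TRUE))
    for (k in seq_along(tifs)) {
      img <- tryCatch(read_field(tifs[k], pixel_size_um), error = identity)
      if (inherits(img, "error")) {
        warning("skipping unreadable field ", tifs[k], ": ",
                conditionMessage(img), call. = FALSE)
        skipped[[length(skipped) + 1L]] <-
          tibble::tibble(well_id = well, path = tifs[k],
                         reason = conditionMessage(img))
        next
      }
      fld <- segment_field(img, params, filters, size_calibration)
      counts[[length(counts) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(well_id = well, field = k),
                         count_field(fld))
      nuc_all[[length(nuc_all) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(well_id = well, field = k), fld$nuclei)
      spot_all[[length(spot_all) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(well_id = well, field = k), fld$spots)
    }
  }
  if (!length(counts)) stop("no images found under ", dir, call. = FALSE)
  list(
    field_counts = dplyr::bind_rows(counts),
    nuclei = dplyr::bind_rows(nuc_all),
    spots = dplyr::bind_rows(spot_all),
    skipped = dplyr::bind_rows(skipped)
  )
}

#' Export label masks of a segmented field
#'
#' Writes the primary and secondary masks as 16-bit label TIFFs (0 =
#' background, pixel value = object label), mirroring what interactive
#' packages show as mask overlays.
#'
#' @param field An `mn_field`.
#' @param primary_path,secondary_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
export_masks <- function(field, primary_path = NULL, secondary_path = NULL) {
  stopifnot(inherits(field, "mn_field"))
  wrote <- character()
  w <- function(m, p) {
    tiff::writeTIFF(m / 65535, p, bits.per.sample = 16L, compression = "none")
    p
  }
  if (!is.null(primary_path)) wrote <- c(wrote, w(field$mask$labels, primary_path))
  if (!is.null(secondary_path)) wrote <- c(wrote, w(field$rings$labels, secondary_path))
  invisible(wrote)
}
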