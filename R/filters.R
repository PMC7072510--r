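#' Image-periphery exclusion filter
#'
#' Flags every nucleus whose region intersects the band within `margin_um` of
#' any image edge (pixel-centre convention). Nuclei truncated by the field
#' edge would otherwise be small enough to be scored as micronuclei; the
#' analysis is therefore restricted to nuclei wholly clear of the band, and a
#' flagged nucleus takes its micronuclei with it (see [flag_orphans()]).
#' Filters only ever add flags — objects are never removed or un-flagged, so
#' the three exclusion filters commute.
#'
#' @param nuclei Nucleus tibble (from [primary_mask()] objects with flag
#'   columns, e.g. inside [segment_field()], or any tibble carrying
#'   `xmin`/`xmax`/`ymin`/`ymax` in pixels).
#' @param dims Image dimensions `c(n_rows, n_cols)` in pixels.
#' @param margin_um Band width in micrometres (default 30).
#' @param pixel_size_um Pixel size (um).
#' @return `nuclei` with `excl_periphery` set and `retained` updated.
#' @export
periphery_filter <- function(nuclei, dims, margin_um = 30, pixel_size_um) {
  if (margin_um < 0) stop("margin_um must be >= 0", call. = FALSE)
  half_min_um <- min(dims) * pixel_size_um / 2
  if (margin_um >= half_min_um) {
    stop("margin excludes entire field (margin ", margin_um,
         " um >= half the smaller image dimension, ", half_min_um, " um)",
         call. = FALSE)
  }
  nuclei <- ensure_nucleus_flags(nuclei)
  if (nrow(nuclei)) {
    nr <- dims[1L]; nc <- dims[2L]
    near <- (nuclei$xmin - 0.5) * pixel_size_um < margin_um |
            (nc - nuclei$xmax + 0.5) * pixel_size_um < margin_um |
            (nuclei$ymin - 0.5) * pixel_size_um < margin_um |
            (nr - nuclei$ymax + 0.5) * pixel_size_um < margin_um
    nuclei$excl_periphery <- nuclei$excl_periphery | near
  }
  update_retained(nuclei)
}

#' Maximal mean-intensity exclusion filter
#'
#' Flags objects whose mean stain intensity exceeds `cutoff_au`. Apoptotic
#' bodies and condensed mitotic chromosomes fluoresce brighter than
#' interphase nuclei; without this filter they are miscounted as nuclei or
#' micronuclei. Applies to nucleus tables and to spot tables alike (bright
#' spot-sized chromosome fragments are equally excluded).
#'
#' @param objects Nucleus or spot tibble with `mean_intensity_au`.
#' @param cutoff_au Cutoff in a.u. (> 0); see [calibrate_intensity_cutoff()].
#' @return `objects` with `excl_intensity` set and `retained` updated.
#' @export
intensity_filter <- function(objects, cutoff_au) {
  if (!is.numeric(cutoff_au) || length(cutoff_au) != 1L || cutoff_au <= 0) {
    stop("cutoff_au must be a single positive number", call. = FALSE)
  }
  objects <- if ("nucleus_label" %in% names(objects)) {
    ensure_spot_flags(objects)
  } else {
    ensure_nucleus_flags(objects)
  }
  objects$excl_intensity <- objects$excl_intensity |
    objects$mean_intensity_au > cutoff_au
  update_retained(objects)
}

#' Calibrate the mean-intensity cutoff
#'
#' Places the cutoff midway between the mean intensity of interphase nuclei
#' to keep and of the bright mitotic/apoptotic bodies to eliminate, both
#' sampled from representative control images. The midpoint is a starting
#' point the user may override.
#'
#' @param control_intensities Mean intensities of sampled interphase nuclei.
#' @param bright_intensities Mean intensities of sampled bright bodies.
#' @return The cutoff (a.u.).
#' @export
calibrate_intensity_cutoff <- function(control_intensities, bright_intensities) {
  if (!length(control_intensities) || !length(bright_intensities)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m_ctrl <- mean(control_intensities)
  m_bright <- mean(bright_intensities)
  if (m_bright <= m_ctrl) {
    stop("bright-body mean (", format(m_bright), ") does not exceed the ",
         "interphase mean (", format(m_ctrl), "); populations overlap - ",
         "set a manual cutoff", call. = FALSE)
  }
  (m_ctrl + m_bright) / 2
}

#' Calibrate the micronucleus size cap
#'
#' The micronucleus definition caps size at a fraction (conventionally 1/3)
#' of the average control nucleus. The mean size is computed over the
#' retained nuclei of control-condition fields; the cap is `mean x fraction`
#' in area mode, or the same fraction of the mean equivalent diameter in
#' diameter mode.
#'
#' @param control_nuclei Nucleus tibble from control conditions; only rows
#'   with `retained == TRUE` (or all rows if no flag columns) are used.
#' @param fraction Cap fraction, strictly in (0, 1); default 1/3.
#' @param mode `"area"` or `"diameter"`.
#' @param condition Optional source condition label, recorded for reporting.
#' @return An object of class `mn_size_calibration`.
#' @export
calibrate_mn_size <- function(control_nuclei, fraction = 1 / 3,
                              mode = c("area", "diameter"), condition = NA_character_) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  nuc <- control_nuclei
  if ("retained" %in% names(nuc)) nuc <- nuc[nuc$retained, , drop = FALSE]
  if (!nrow(nuc)) {
    stop("no retained control nuclei to calibrate from", call. = FALSE)
  }
  mean_area <- mean(nuc$area_um2)
  mean_diam <- mean(nuc$equivalent_diameter_um)
  structure(
    list(
      mean_control_nucleus_area_um2 = mean_area,
      mean_control_diameter_um = mean_diam,
      mn_max_area_um2 = mean_area * fraction,
      mn_max_diameter_um = mean_diam * fraction,
      n_nuclei_used = nrow(nuc),
      fraction = fraction,
      mode = mode,
      condition = condition
    ),
    class = "mn_size_calibration"
  )
}

#' @export
print.mn_size_calibration <- function(x, ...) {
  cat(sprintf(
    "<mn_size_calibration> mean control nucleus %.1f um2 (%.1f um) over %d nuclei;\n  cap: %s (%s mode, fraction %s)\n",
    x$mean_control_nucleus_area_um2, x$mean_control_diameter_um, x$n_nuclei_used,
    if (x$mode == "area") sprintf("%.2f um2", x$mn_max_area_um2)
    else sprintf("%.2f um", x$mn_max_diameter_um),
    x$mode, format(x$fraction)
  ))
  invisible(x)
}

#' Micronucleus size-cap filter
#'
#' Flags spots larger than the calibrated cap. The cap is inclusive: a spot
#' exactly at the cap is retained (the definition is "at most" the fraction
#' of an average nucleus).
#'
#' @param spots Spot tibble from [detect_spots()].
#' @param calibration An [calibrate_mn_size()] result.
#' @return `spots` with `excl_size_cap` set and `retained` updated.
#' @export
mn_size_filter <- function(spots, calibration) {
  stopifnot(inherits(calibration, "mn_size_calibration"))
  spots <- ensure_spot_flags(spots)
  over <- if (calibration$mode == "area") {
    spots$area_um2 > calibration$mn_max_area_um2
  } else {
    spots$equivalent_diameter_um > calibration$mn_max_diameter_um
  }
  spots$excl_size_cap <- spots$excl_size_cap | over
  update_retained(spots)
}

#' Propagate nucleus exclusions to their micronuclei
#'
#' An excluded nucleus contributes neither itself nor its micronuclei to any
#' count: spots assigned to an excluded (or absent) nucleus gain the
#' `orphan` flag. Re-run after any change to nucleus flags; the flag is
#' recomputed, so filter ordering does not matter.
#'
#' @param spots Spot tibble with `nucleus_label`.
#' @param nuclei Nucleus tibble with `label` and flag columns.
#' @return `spots` with `excl_orphan` recomputed and `retained` updated.
#' @export
flag_orphans <- function(spots, nuclei) {
  spots <- ensure_spot_flags(spots)
  nuclei <- ensure_nucleus_flags(nuclei)
  ok_labels <- nuclei$label[nuclei$retained]
  spots$excl_orphan <- !(spots$nucleus_label %in% ok_labels)
  update_retained(spots)
}

ensure_nucleus_flags <- function(nuclei) {
  nuclei <- tibble::as_tibble(nuclei)
  if (!"excl_periphery" %in% names(nuclei)) nuclei$excl_periphery <- logical(nrow(nuclei))
  if (!"excl_intensity" %in% names(nuclei)) nuclei$excl_intensity <- logical(nrow(nuclei))
  update_retained(nuclei)
}

ensure_spot_flags <- function(spots) {
  spots <- tibble::as_tibble(spots)
  for (f in c("excl_size_cap", "excl_intensity", "excl_orphan")) {
    if (!f %in% names(spots)) spots[[f]] <- logical(nrow(spots))
  }
  update_retained(spots)
}

update_retained <- function(objects) {
  flags <- grep("^excl_", names(objects), value = TRUE)
  objects$retained <- if (length(flags)) {
    !Reduce(`|`, objects[flags])
  } else {
    rep(TRUE, nrow(objects))
  }
  objects
}

#' Calibration report
#'
#' One-row tibble summarising a size calibration, suitable for CSV export.
#'
#' @param calibration An [calibrate_mn_size()] result.
#' @return A tibble.
#' @export
calibration_report <- function(calibration) {
  stopifnot(inherits(calibration, "mn_size_calibration"))
  tibble::tibble(
    condition = calibration$condition,
    n_nuclei_used = calibration$n_nuclei_used,
    mean_area_um2 = calibration$mean_control_nucleus_area_um2,
    cap_value = if (calibration$mode == "area") calibration$mn_max_area_um2
                else calibration$mn_max_diameter_um,
    mode = calibration$mode,
    fraction = calibration$fraction
  )
}
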