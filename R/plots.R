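#' Plot a dose-response summary
#'
#' Mean relative micronucleus induction per dose with error bars (sample SD,
#' also vehicle-relative), on a log dose axis with the vehicle control shown
#' at the left edge. Mirrors the conventional presentation: mean +/- SD for
#' each concentration relative to the vehicle control.
#'
#' @param object An [dose_response()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot mn_dose_response
#' @importFrom ggplot2 autoplot
autoplot.mn_dose_response <- function(object, ...) {
  df <- tibble::as_tibble(object)
  doses <- df$dose[df$dose > 0]
  # position the dose-0 vehicle one dilution step below the lowest dose
  x0 <- if (length(doses)) min(doses) / 2 else 1
  df$dose_x <- ifelse(df$dose == 0, x0, df$dose)
  units <- stats::na.omit(df$dose_units)
  xl <- if (length(units)) paste0("dose (", units[1], "; vehicle at left)") else "dose"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_x, y = .data$relative_mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$relative_mean - .data$relative_sd,
                   ymax = .data$relative_mean + .data$relative_sd),
      width = 0.08, na.rm = TRUE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xl, y = "micronucleus frequency (relative to vehicle)") +
    ggplot2::theme_classic()
}

#' Plot gene-silencing fold changes
#'
#' Dot plot of per-replicate fold changes by condition, with the group
#' median marked and the siControl mean (1.00 by construction) as a dashed
#' reference line.
#'
#' @param object An [fold_change()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot mn_fold_change
autoplot.mn_fold_change <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$fold_change)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.35, colour = "red", linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "fold change in micronucleus frequency") +
    ggplot2::theme_classic()
}

#' Overlay segmentation results on a field
#'
#' Raster view of the field with retained nuclei and micronucleus centroids
#' marked; a quick visual confirmation aid — the protocol's manual check of
#' a random image subset — not a publication figure.
#'
#' @param field An `mn_field` from [segment_field()].
#' @param image The [image_plane()] the field was segmented from.
#' @return A ggplot object.
#' @export
plot_field_overlay <- function(field, image) {
  stopifnot(inherits(field, "mn_field"), inherits(image, "mn_image"))
  px <- image$pixels
  psz <- image$pixel_size_um
  df <- tidyr::expand_grid(y = seq_len(nrow(px)), x = seq_len(ncol(px)))
  df$value <- as.vector(t(px))  # row-major expand_grid order
  nuc <- dplyr::filter(field$nuclei, .data$retained)
  spt <- dplyr::filter(field$spots, .data$retained)
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x * psz, y = .data$y * psz,
                                      fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_point(data = nuc,
                        ggplot2::aes(x = .data$cx_um, y = .data$cy_um),
                        colour = "yellow", shape = 1, size = 4) +
    ggplot2::geom_point(data = spt,
                        ggplot2::aes(x = .data$cx_um, y = .data$cy_um),
                        colour = "green", shape = 3, size = 2) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_void()
}
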