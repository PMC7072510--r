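#' Primary (nuclear) mask
#'
#' Defines each individual nucleus: pixels at or above the primary detection
#' threshold are foreground; 8-connected components with interior holes
#' filled become candidate nuclei; candidates with equivalent circular
#' diameter below `min_object_size_um` or above `max_object_size_um` are
#' discarded. Geometry and mean intensity are measured on `measure` —
#' by default the input image, but callers that threshold a
#' background-flattened image should pass the original here so the
#' mean-intensity exclusion filter operates on true stain brightness.
#'
#' @param image [image_plane()] whose pixels are thresholded.
#' @param params [seg_params()] profile.
#' @param measure [image_plane()] on which object intensities are measured
#'   (defaults to `image`).
#' @return An object of class `mn_mask`: list with `labels` (integer matrix,
#'   0 = background), `objects` (tibble of per-nucleus features), and
#'   `pixel_size_um`. An empty field yields zero objects, not an error.
#' @export
primary_mask <- function(image, params, measure = image) {
  stopifnot(inherits(image, "mn_image"), inherits(params, "mn_seg_params"))
  fg <- image$pixels >= params$primary_detection_threshold_au
  L <- label8(fg)
  L <- fill_holes(L)
  feats <- region_features(L, measure$pixels, image$pixel_size_um)
  keep <- feats$equivalent_diameter_um >= params$min_object_size_um &
          feats$equivalent_diameter_um <= params$max_object_size_um
  kept <- feats[keep, , drop = FALSE]
  # renumber survivors 1..n (spatial order preserved from labeling)
  map <- integer(if (nrow(feats)) max(feats$label) else 0L)
  map[kept$label] <- seq_len(nrow(kept))
  pos <- which(L > 0L)
  L[pos] <- map[L[pos]]
  kept$label <- seq_len(nrow(kept))
  structure(
    list(labels = L, objects = kept, pixel_size_um = image$pixel_size_um),
    class = "mn_mask"
  )
}

#' @export
print.mn_mask <- function(x, ...) {
  cat(sprintf("<mn_mask> %d object(s) in a %d x %d px field\n",
              nrow(x$objects), ncol(x$labels), nrow(x$labels)))
  invisible(x)
}

#' Reduce (erode) the primary mask
#'
#' Morphologically erodes each nuclear region by a disc of radius
#' `shrink_um`, improving the spatial separation between a nucleus and a
#' proximal micronucleus. Objects eroded to emptiness are dropped; surviving
#' labels are preserved. Features are re-measured on `measure`.
#'
#' @param mask An `mn_mask` from [primary_mask()].
#' @param shrink_um Erosion radius (um, >= 0; 0 is the identity).
#' @param measure [image_plane()] for intensity measurement.
#' @return A reduced `mn_mask`.
#' @export
reduce_mask <- function(mask, shrink_um, measure) {
  stopifnot(inherits(mask, "mn_mask"), inherits(measure, "mn_image"))
  if (!is.numeric(shrink_um) || length(shrink_um) != 1L || shrink_um < 0) {
    stop("shrink_um must be a single number >= 0", call. = FALSE)
  }
  r <- as.integer(round(shrink_um / mask$pixel_size_um))
  if (r == 0L) return(mask)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  L <- mask$labels
  out <- matrix(0L, nrow(L), ncol(L))
  for (i in seq_len(nrow(mask$objects))) {
    ob <- mask$objects[i, ]
    # window padded by r so erosion at the bbox edge sees the full region
    y0 <- max(1L, ob$ymin - r); y1 <- min(nrow(L), ob$ymax + r)
    x0 <- max(1L, ob$xmin - r); x1 <- min(ncol(L), ob$xmax + r)
    win <- (L[y0:y1, x0:x1, drop = FALSE] == ob$label) * 1
    er <- EBImage::erode(win, brush)
    sel <- which(er > 0)
    if (length(sel)) {
      sub <- out[y0:y1, x0:x1, drop = FALSE]
      sub[sel] <- ob$label
      out[y0:y1, x0:x1] <- sub
    }
  }
  feats <- region_features(out, measure$pixels, mask$pixel_size_um)
  structure(
    list(labels = out, objects = feats, pixel_size_um = mask$pixel_size_um),
    class = "mn_mask"
  )
}

#' Secondary (cell body) ring mask
#'
#' Approximates each cell body as the set of pixels within `ring_width_um`
#' of the nuclear periphery, outside all primary regions. Pixels within reach
#' of several nuclei are assigned to the nucleus whose region is nearest
#' (Euclidean distance to the region; ties broken by the lower label), so the
#' rings partition the contested space deterministically. Rings are clipped
#' at the image bounds.
#'
#' @param mask An `mn_mask` from [primary_mask()] (optionally reduced).
#' @param ring_width_um Ring width in micrometres (>= 0; 0 gives empty rings).
#' @return An object of class `mn_rings`: list with `labels` (integer matrix;
#'   pixel value = owning nucleus label, 0 = no ring) and `pixel_size_um`.
#' @export
secondary_mask <- function(mask, ring_width_um) {
  stopifnot(inherits(mask, "mn_mask"))
  if (!is.numeric(ring_width_um) || length(ring_width_um) != 1L || ring_width_um < 0) {
    stop("ring_width_um must be a single number >= 0", call. = FALSE)
  }
  L <- mask$labels
  nr <- nrow(L); nc <- ncol(L)
  ring <- matrix(0L, nr, nc)
  w_px <- ring_width_um / mask$pixel_size_um
  if (w_px > 0 && nrow(mask$objects)) {
    pad <- as.integer(ceiling(w_px)) + 1L
    best_d <- matrix(Inf, nr, nc)
    best_l <- matrix(0L, nr, nc)
    for (i in seq_len(nrow(mask$objects))) {
      ob <- mask$objects[i, ]
      y0 <- max(1L, ob$ymin - pad); y1 <- min(nr, ob$ymax + pad)
      x0 <- max(1L, ob$xmin - pad); x1 <- min(nc, ob$xmax + pad)
      # distance of every window pixel to this nucleus region: distmap of the
      # complement (region pixels are the background it measures towards)
      comp <- (L[y0:y1, x0:x1, drop = FALSE] != ob$label) * 1
      d <- EBImage::distmap(comp)
      bd <- best_d[y0:y1, x0:x1, drop = FALSE]
      bl <- best_l[y0:y1, x0:x1, drop = FALSE]
      upd <- d < bd  # strict: equal distance keeps the earlier (lower) label
      bd[upd] <- d[upd]
      bl[upd] <- ob$label
      best_d[y0:y1, x0:x1] <- bd
      best_l[y0:y1, x0:x1] <- bl
    }
    sel <- best_d <= w_px & L == 0L
    ring[sel] <- best_l[sel]
  }
  structure(list(labels = ring, pixel_size_um = mask$pixel_size_um),
            class = "mn_rings")
}

#' @export
print.mn_rings <- function(x, ...) {
  cat(sprintf("<mn_rings> %d ring pixel(s) over %d nucleus/nuclei\n",
              sum(x$labels > 0L), length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}
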