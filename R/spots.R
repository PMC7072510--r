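#' Detect micronucleus candidate spots
#'
#' Spot (micronucleus) detection delineates small supra-threshold objects
#' inside the secondary (cell body) rings but outside every primary (nuclear)
#' region. Pixels at or above the spot detection threshold and not in a
#' primary region form 8-connected candidate components; a component is kept
#' iff at least 50% of its area lies inside the ring union, is assigned to
#' the ring holding its largest overlap (ties to the lower nucleus label),
#' and is then clipped to that ring. Components with equivalent diameter
#' outside `[min_spot_size_um, max_spot_size_um]` (evaluated before
#' clipping) are discarded, as are — when
#' `params$drop_mask_adjacent_spots` is on — components touching a primary
#' region in the 8-neighbourhood, which are partial-nucleus edge artifacts
#' rather than micronuclei.
#'
#' @param image [image_plane()] whose pixels are thresholded (the flattened
#'   image when background flattening is enabled).
#' @param mask `mn_mask` primary mask from the same field.
#' @param rings `mn_rings` secondary mask from the same field.
#' @param params [seg_params()] profile.
#' @param measure [image_plane()] on which spot intensities are measured
#'   (defaults to `image`; pass the raw image when `image` is flattened).
#' @return Tibble of spots with geometry measured on the clipped region,
#'   `nucleus_label`, and exclusion flag columns (`excl_size_cap`,
#'   `excl_intensity`, `excl_orphan`, all initialised `FALSE`) plus
#'   `retained`. Attribute `spot_labels` holds the clipped spot label matrix.
#' @export
detect_spots <- function(image, mask, rings, params, measure = image) {
  stopifnot(inherits(image, "mn_image"), inherits(mask, "mn_mask"),
            inherits(rings, "mn_rings"), inherits(params, "mn_seg_params"))
  if (!all(dim(mask$labels) == dim(image$pixels))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  psz <- image$pixel_size_um
  fg <- image$pixels >= params$spot_detection_threshold_au & mask$labels == 0L
  L <- label8(fg)
  out <- spot_table_empty()
  spot_lab <- matrix(0L, nrow(L), ncol(L))
  ncomp <- max(L)
  if (ncomp > 0L) {
    pos <- which(L > 0L)
    lab <- L[pos]
    area_px <- tabulate(lab, nbins = ncomp)
    eq_d <- 2 * sqrt(area_px * psz^2 / pi)
    size_ok <- eq_d >= params$min_spot_size_um & eq_d <= params$max_spot_size_um
    # adjacency to any primary region (8-neighbourhood)
    adj_ok <- rep(TRUE, ncomp)
    if (params$drop_mask_adjacent_spots) {
      adj <- touches_positive(L, mask$labels)
      adj_ok <- !adj
    }
    # ring overlap per (component, ring owner)
    rl <- rings$labels[pos]
    in_ring <- rl > 0L
    frac_in <- as.numeric(rowsum(as.numeric(in_ring), lab)[, 1]) / area_px
    keep <- size_ok & adj_ok & frac_in >= 0.5
    if (any(keep)) {
      # majority ring owner among in-ring pixels, ties -> lower label
      sel <- in_ring & keep[lab]
      if (any(sel)) {
        comp_f <- factor(lab[sel], levels = sort(unique(lab[sel])))
        owner_f <- factor(rl[sel], levels = sort(unique(rl[sel])))
        tab <- table(comp = comp_f, owner = owner_f)
        owners <- as.integer(levels(owner_f))
        comp_ids <- as.integer(levels(comp_f))
        assigned <- owners[apply(tab, 1L, which.max)]  # which.max: first (lowest) on ties
        names(assigned) <- comp_ids
        keep_pos <- pos[keep[lab] & in_ring & rl == assigned[as.character(lab)]]
        # clip: spot region = component pixels inside its assigned ring
        keep_lab <- lab[keep[lab] & in_ring & rl == assigned[as.character(lab)]]
        newid <- integer(ncomp)
        newid[comp_ids] <- seq_along(comp_ids)
        spot_lab[keep_pos] <- newid[keep_lab]
        feats <- region_features(spot_lab, measure$pixels, psz)
        feats$nucleus_label <- as.integer(assigned[as.character(comp_ids[feats$label])])
        out <- spot_flags(feats)
      }
    }
  }
  attr(out, "spot_labels") <- spot_lab
  out
}

spot_table_empty <- function() {
  spot_flags(tibble::tibble(
    label = integer(), area_px = integer(), area_um2 = numeric(),
    equivalent_diameter_um = numeric(), cx_um = numeric(), cy_um = numeric(),
    mean_intensity_au = numeric(),
    xmin = integer(), xmax = integer(), ymin = integer(), ymax = integer(),
    nucleus_label = integer()
  ))
}

spot_flags <- function(feats) {
  feats$excl_size_cap <- logical(nrow(feats))
  feats$excl_intensity <- logical(nrow(feats))
  feats$excl_orphan <- logical(nrow(feats))
  feats$retained <- !logical(nrow(feats))
  feats
}

# TRUE per label of `L` that has an 8-neighbour pixel positive in `M`
touches_positive <- function(L, M) {
  n <- max(L)
  hit <- logical(n)
  if (n == 0L) return(hit)
  nr <- nrow(L); nc <- ncol(L)
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  Mpos <- M > 0L
  for (s in shifts) {
    dy <- s[1L]; dx <- s[2L]
    ys <- seq.int(max(1L, 1L + dy), min(nr, nr + dy))
    xs <- seq.int(max(1L, 1L + dx), min(nc, nc + dx))
    Lsub <- L[ys - dy, xs - dx, drop = FALSE]
    Msub <- Mpos[ys, xs, drop = FALSE]
    k <- Lsub > 0L & Msub
    if (any(k)) hit[unique(Lsub[k])] <- TRUE
  }
  hit
}
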