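# Independent reference implementation of the per-field rules, used to
# cross-check the production pipeline. Everything here is deliberately
# written from scratch in plain R — exhaustive frontier flood fill instead
# of EBImage labeling, border flooding instead of fillHull, brute-force
# nearest-boundary distances instead of distance maps — so that agreement
# between the two code paths is evidence, not tautology.

# 8-connected component labeling by exhaustive flood fill; labels are
# assigned in column-major order of each component's first pixel
ref_flood_label <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  todo <- which(fg)
  if (!length(todo)) return(lab)
  nb <- function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    out <- integer(0)
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      out <- c(out, (cc[keep] - 1L) * nr + rr[keep])
    }
    out
  }
  current <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    lab[seed] <- current
    frontier <- seed
    while (length(frontier)) {
      cand <- unique(nb(frontier))
      cand <- cand[fg[cand] & lab[cand] == 0L]
      lab[cand] <- current
      frontier <- cand
    }
  }
  lab
}

# fill enclosed holes: 4-connected background flood from the border (the
# proper dual of 8-connected foreground); unreachable background is hole
ref_fill_holes <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  reach <- matrix(FALSE, nr, nc)
  border <- unique(c(
    seq_len(nr), (nc - 1L) * nr + seq_len(nr),
    (seq_len(nc) - 1L) * nr + 1L, (seq_len(nc) - 1L) * nr + nr
  ))
  frontier <- border[!fg[border]]
  reach[frontier] <- TRUE
  nb4 <- function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    out <- integer(0)
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      rr <- r + d[1L]; cc <- c + d[2L]
      keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      out <- c(out, (cc[keep] - 1L) * nr + rr[keep])
    }
    out
  }
  while (length(frontier)) {
    cand <- unique(nb4(frontier))
    cand <- cand[!fg[cand] & !reach[cand]]
    reach[cand] <- TRUE
    frontier <- cand
  }
  fg | !reach
}

ref_features <- function(lab, pixels, psz) {
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(label = integer(), area_px = integer(),
                          area_um2 = numeric(), equivalent_diameter_um = numeric(),
                          mean_intensity_au = numeric(),
                          xmin = integer(), xmax = integer(),
                          ymin = integer(), ymax = integer()))
  }
  pos <- which(lab > 0L)
  l <- lab[pos]
  nr <- nrow(lab)
  r <- ((pos - 1L) %% nr) + 1L
  c <- ((pos - 1L) %/% nr) + 1L
  area <- tabulate(l, nbins = n)
  msum <- as.numeric(rowsum(pixels[pos], l)[, 1])
  tibble::tibble(
    label = seq_len(n),
    area_px = as.integer(area),
    area_um2 = area * psz^2,
    equivalent_diameter_um = 2 * sqrt(area * psz^2 / pi),
    mean_intensity_au = msum / area,
    xmin = as.integer(tapply(c, l, min)), xmax = as.integer(tapply(c, l, max)),
    ymin = as.integer(tapply(r, l, min)), ymax = as.integer(tapply(r, l, max))
  )
}

#' Reference per-field counts by exhaustive flood fill
#'
#' A from-scratch reimplementation of the per-field rules (threshold,
#' 8-connected flood-fill labeling, hole filling by border flooding, size
#' windows, nearest-boundary ring partition by brute force, the 50% ring
#' rule, and the three exclusion filters), kept free of any code or library
#' shared with [segment_field()]. Used to validate the pipeline: on
#' noise-free synthetic fields the two must agree exactly in counts and
#' per-object areas. Quadratic in places and therefore only suitable for
#' small fields; it is a checker, not a pipeline.
#'
#' @inheritParams segment_field
#' @return List of tibbles `nuclei` and `spots` with `retained` flags.
#' @export
reference_counts <- function(image, params, filters = filter_params(),
                             size_calibration = NULL) {
  stopifnot(inherits(image, "mn_image"), inherits(params, "mn_seg_params"))
  if (params$background_flatten) {
    stop("the reference checker thresholds the image as given; flatten first",
         call. = FALSE)
  }
  px <- image$pixels
  psz <- image$pixel_size_um
  nr <- nrow(px); nc <- ncol(px)

  fg <- px >= params$primary_detection_threshold_au
  filled <- ref_fill_holes(fg)
  lab <- ref_flood_label(filled)
  feats <- ref_features(lab, px, psz)
  keep <- feats$equivalent_diameter_um >= params$min_object_size_um &
          feats$equivalent_diameter_um <= params$max_object_size_um
  kept <- feats[keep, , drop = FALSE]
  relab <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(kept))) relab[lab == kept$label[i]] <- i
  kept$label <- seq_len(nrow(kept))

  # ring partition: per-pixel nearest kept region (via its boundary pixels),
  # strict improvement so distance ties keep the lower label
  w_px <- params$ring_width_um / psz
  best_d <- matrix(Inf, nr, nc)
  best_l <- matrix(0L, nr, nc)
  if (w_px > 0 && nrow(kept)) {
    pad <- as.integer(ceiling(w_px)) + 1L
    for (i in seq_len(nrow(kept))) {
      reg <- which(relab == kept$label[i])
      rr <- ((reg - 1L) %% nr) + 1L
      cc <- ((reg - 1L) %/% nr) + 1L
      on_b <- rep(FALSE, length(reg))
      inreg <- matrix(FALSE, nr, nc); inreg[reg] <- TRUE
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        r2 <- rr + d[1L]; c2 <- cc + d[2L]
        outside <- r2 < 1L | r2 > nr | c2 < 1L | c2 > nc
        idx2 <- (pmax(pmin(c2, nc), 1L) - 1L) * nr + pmax(pmin(r2, nr), 1L)
        on_b <- on_b | outside | !inreg[idx2]
      }
      br <- rr[on_b]; bc <- cc[on_b]
      y0 <- max(1L, kept$ymin[i] - pad); y1 <- min(nr, kept$ymax[i] + pad)
      x0 <- max(1L, kept$xmin[i] - pad); x1 <- min(nc, kept$xmax[i] + pad)
      wy <- y0:y1; wx <- x0:x1
      gy <- rep(wy, times = length(wx))
      gx <- rep(wx, each = length(wy))
      d2 <- outer(gy, br, `-`)^2 + outer(gx, bc, `-`)^2
      dmin <- sqrt(do.call(pmin, as.data.frame(d2)))
      dmin[inreg[cbind(gy, gx)]] <- 0
      sub_idx <- (gx - 1L) * nr + gy
      upd <- dmin < best_d[sub_idx]
      best_d[sub_idx[upd]] <- dmin[upd]
      best_l[sub_idx[upd]] <- kept$label[i]
    }
  }
  ring <- matrix(0L, nr, nc)
  sel <- best_d <= w_px & relab == 0L
  ring[sel] <- best_l[sel]

  # spots
  sfg <- px >= params$spot_detection_threshold_au & relab == 0L
  slab <- ref_flood_label(sfg)
  spots <- ref_features(slab, px, psz)
  out_spots <- NULL
  if (nrow(spots)) {
    size_ok <- spots$equivalent_diameter_um >= params$min_spot_size_um &
               spots$equivalent_diameter_um <= params$max_spot_size_um
    adj_ok <- rep(TRUE, nrow(spots))
    if (params$drop_mask_adjacent_spots) {
      prim <- relab > 0L
      for (j in seq_len(nrow(spots))) {
        reg <- which(slab == spots$label[j])
        rr <- ((reg - 1L) %% nr) + 1L
        cc <- ((reg - 1L) %/% nr) + 1L
        touch <- FALSE
        for (dr in -1L:1L) for (dc in -1L:1L) {
          if (dr == 0L && dc == 0L) next
          r2 <- rr + dr; c2 <- cc + dc
          okp <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
          if (any(prim[(c2[okp] - 1L) * nr + r2[okp]])) { touch <- TRUE; break }
        }
        if (touch) adj_ok[j] <- FALSE
      }
    }
    rows <- list()
    for (j in seq_len(nrow(spots))) {
      if (!size_ok[j] || !adj_ok[j]) next
      reg <- which(slab == spots$label[j])
      owners <- ring[reg]
      if (mean(owners > 0L) < 0.5) next
      tab <- tapply(rep(1L, sum(owners > 0L)), owners[owners > 0L], sum)
      labs <- as.integer(names(tab))
      o <- sort(labs)[which.max(tab[match(sort(labs), labs)])]
      clip <- reg[owners == o]
      area <- length(clip)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = length(rows) + 1L,
        area_px = area,
        area_um2 = area * psz^2,
        equivalent_diameter_um = 2 * sqrt(area * psz^2 / pi),
        mean_intensity_au = mean(px[clip]),
        nucleus_label = o
      )
    }
    out_spots <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  }
  if (is.null(out_spots)) {
    out_spots <- tibble::tibble(label = integer(), area_px = integer(),
                                area_um2 = numeric(),
                                equivalent_diameter_um = numeric(),
                                mean_intensity_au = numeric(),
                                nucleus_label = integer())
  }

  # exclusion filters (independent re-statement of the same rules)
  m <- filters$periphery_margin_um
  nper <- (kept$xmin - 0.5) * psz < m | (nc - kept$xmax + 0.5) * psz < m |
          (kept$ymin - 0.5) * psz < m | (nr - kept$ymax + 0.5) * psz < m
  nint <- if (is.null(filters$max_mean_intensity_au)) rep(FALSE, nrow(kept))
          else kept$mean_intensity_au > filters$max_mean_intensity_au
  kept$excl_periphery <- nper
  kept$excl_intensity <- nint
  kept$retained <- !nper & !nint

  s_int <- if (is.null(filters$max_mean_intensity_au)) rep(FALSE, nrow(out_spots))
           else out_spots$mean_intensity_au > filters$max_mean_intensity_au
  s_cap <- if (is.null(size_calibration)) rep(FALSE, nrow(out_spots))
           else if (size_calibration$mode == "area") {
             out_spots$area_um2 > size_calibration$mn_max_area_um2
           } else {
             out_spots$equivalent_diameter_um > size_calibration$mn_max_diameter_um
           }
  s_orph <- !(out_spots$nucleus_label %in% kept$label[kept$retained])
  out_spots$excl_size_cap <- s_cap
  out_spots$excl_intensity <- s_int
  out_spots$excl_orphan <- s_orph
  out_spots$retained <- !s_cap & !s_int & !s_orph

  list(nuclei = kept, spots = out_spots)
}
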