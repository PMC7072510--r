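#' Specification of a synthetic fluorescence field
#'
#' Generative description of one fake DNA-stain field with known ground
#' truth. The defaults emulate a well-exposed 20x Hoechst field: bright
#' elliptical interphase nuclei near 0.7x of 16-bit saturation (the exposure
#' rule keeps typical nuclei around 80% of saturation, and biological
#' variation sits below that ceiling), dim micronuclei a few micrometres
#' outside their parent's boundary, very bright compact mitotic/apoptotic
#' bodies near saturation, a few nuclei intersecting the image periphery
#' band, plus uniform background, an optional planar ramp, and additive
#' Gaussian noise. All randomness is governed by a single integer seed;
#' identical specs render bit-identical fields.
#'
#' Placement is by rejection sampling with clearances chosen so the planted
#' geometry is unambiguous at pixel resolution: interior nuclei keep 2 um
#' clear of the periphery band, objects keep 3 um clear of each other, and a
#' micronucleus is strictly nearer its parent than any other object by a
#' margin exceeding its own diameter, so ring ownership of every
#' micronucleus pixel is decided by construction.
#'
#' @param width_px,height_px Field size in pixels.
#' @param pixel_size_um Physical pixel size (um/px).
#' @param n_nuclei Interior interphase nuclei to plant.
#' @param nucleus_diameter_um Range (min, max) of equivalent diameters (um).
#' @param nucleus_intensity_au Mean and sd of nucleus intensity (a.u.);
#'   draws are truncated to mean +/- ~2 sd so the bright-body intensity
#'   cutoff separates populations cleanly.
#' @param mn_probability Per-nucleus probability of one planted micronucleus.
#' @param mn_diameter_um Range of micronucleus diameters (um).
#' @param mn_distance_um Range of the gap between the parent's boundary and
#'   the micronucleus edge (um); `max(mn_distance_um) + max(mn_diameter_um)`
#'   must stay inside the narrowest ring width the field will be analysed
#'   with.
#' @param mn_intensity_au Mean and sd of micronucleus intensity (a.u.);
#'   draws are floored well above typical spot detection thresholds.
#' @param n_bright_bodies Mitotic/apoptotic bodies to plant (interior).
#' @param bright_body_diameter_um Range of body diameters (um).
#' @param bright_body_intensity_au Body intensity (a.u.), near saturation.
#' @param n_edge_nuclei Nuclei forced to intersect the periphery band (and
#'   possibly the image border).
#' @param periphery_margin_um Periphery band the edge/interior placement
#'   rules refer to (um); match the analysis filter.
#' @param background_au Uniform background level (a.u.).
#' @param ramp_au Amplitude of an additive planar ramp across the field.
#' @param noise_sd_au Additive Gaussian noise sd (a.u.); 0 renders the
#'   noise-free fields used as the exact-match test surface.
#' @param edge_softening_px Gaussian sigma (px) smoothing object edges; 0
#'   gives hard edges.
#' @param seed Integer seed.
#' @param max_attempts Placement-attempt budget per object.
#' @return An object of class `mn_synthetic_spec`.
#' @export
synthetic_spec <- function(width_px = 768L, height_px = 768L,
                           pixel_size_um = 0.65,
                           n_nuclei = 110L,
                           nucleus_diameter_um = c(12, 22),
                           nucleus_intensity_au = c(mean = 45000, sd = 3000),
                           mn_probability = 0.05,
                           mn_diameter_um = c(1.8, 4.5),
                           mn_distance_um = c(1.5, 4.5),
                           mn_intensity_au = c(mean = 9000, sd = 1200),
                           n_bright_bodies = 3L,
                           bright_body_diameter_um = c(12, 16),
                           bright_body_intensity_au = 63000,
                           n_edge_nuclei = 6L,
                           periphery_margin_um = 30,
                           background_au = 500,
                           ramp_au = 0,
                           noise_sd_au = 300,
                           edge_softening_px = 0.35,
                           seed = 1L,
                           max_attempts = 500L) {
  ordered_range <- function(x, nm) {
    if (length(x) != 2L || !is.numeric(x) || any(x <= 0) || x[1] >= x[2]) {
      stop("`", nm, "` must be an increasing positive range (min, max)", call. = FALSE)
    }
    as.numeric(x)
  }
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = as.numeric(pixel_size_um),
    n_nuclei = as.integer(n_nuclei),
    nucleus_diameter_um = ordered_range(nucleus_diameter_um, "nucleus_diameter_um"),
    nucleus_intensity_au = as.numeric(nucleus_intensity_au),
    mn_probability = as.numeric(mn_probability),
    mn_diameter_um = ordered_range(mn_diameter_um, "mn_diameter_um"),
    mn_distance_um = ordered_range(mn_distance_um, "mn_distance_um"),
    mn_intensity_au = as.numeric(mn_intensity_au),
    n_bright_bodies = as.integer(n_bright_bodies),
    bright_body_diameter_um = ordered_range(bright_body_diameter_um,
                                            "bright_body_diameter_um"),
    bright_body_intensity_au = as.numeric(bright_body_intensity_au),
    n_edge_nuclei = as.integer(n_edge_nuclei),
    periphery_margin_um = as.numeric(periphery_margin_um),
    background_au = as.numeric(background_au),
    ramp_au = as.numeric(ramp_au),
    noise_sd_au = as.numeric(noise_sd_au),
    edge_softening_px = as.numeric(edge_softening_px),
    seed = as.integer(seed),
    max_attempts = as.integer(max_attempts)
  )
  if (spec$width_px < 1L || spec$height_px < 1L) {
    stop("field must be at least 1 x 1 px", call. = FALSE)
  }
  if (spec$mn_probability < 0 || spec$mn_probability > 1) {
    stop("mn_probability must lie in [0, 1]", call. = FALSE)
  }
  if (spec$noise_sd_au < 0 || spec$background_au < 0 || spec$ramp_au < 0) {
    stop("background, ramp, and noise sd must be >= 0", call. = FALSE)
  }
  structure(spec, class = "mn_synthetic_spec")
}

# ellipse boundary radius from the centre along global angle `theta_g`
.ellipse_radius <- function(a, b, rot, theta_g) {
  psi <- theta_g - rot
  1 / sqrt((cos(psi) / a)^2 + (sin(psi) / b)^2)
}

#' Render one synthetic field
#'
#' Rasterises the spec into an [image_plane()] and returns the planted-object
#' truth tables. Placement failures beyond the attempt budget abort with an
#' error naming the budget (the spec is too crowded). Deterministic under the
#' spec's seed; the caller's RNG state is left untouched.
#'
#' @param spec An [synthetic_spec()].
#' @return List: `image` ([image_plane()]), `truth` (list of tibbles
#'   `nuclei` — id, role, centre, axes, orientation, equivalent diameter,
#'   axis-aligned half-extents, drawn intensity — and `micronuclei` — id,
#'   parent id, centre, diameter, boundary gap, drawn intensity).
#' @export
render_field <- function(spec) {
  stopifnot(inherits(spec, "mn_synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  psz <- spec$pixel_size_um
  W <- spec$width_px * psz; H <- spec$height_px * psz
  margin <- spec$periphery_margin_um

  nuc <- list(); n_id <- 0L
  place <- function(role, d_range, int_draw, at_edge = FALSE) {
    for (attempt in seq_len(spec$max_attempts)) {
      d <- stats::runif(1, d_range[1], d_range[2])
      q <- stats::runif(1, 0.8, 1.0)
      rot <- stats::runif(1, 0, pi)
      a <- (d / 2) / sqrt(q); b <- (d / 2) * sqrt(q)
      if (at_edge) {
        side <- sample.int(4L, 1L)
        off <- stats::runif(1, 0, max(margin - 5, 1))
        along <- stats::runif(1, 0, if (side <= 2L) H else W)
        cx <- switch(side, off, W - off, along, along)
        cy <- switch(side, along, along, off, H - off)
      } else {
        lo <- margin + 2 + a
        if (W - lo < lo || H - lo < lo) next
        cx <- stats::runif(1, lo, W - lo)
        cy <- stats::runif(1, lo, H - lo)
      }
      ok <- TRUE
      for (o in nuc) {
        if (sqrt((cx - o$cx)^2 + (cy - o$cy)^2) < a + o$a + 3) { ok <- FALSE; break }
      }
      if (!ok) next
      n_id <<- n_id + 1L
      rx <- sqrt((a * cos(rot))^2 + (b * sin(rot))^2)
      ry <- sqrt((a * sin(rot))^2 + (b * cos(rot))^2)
      nuc[[length(nuc) + 1L]] <<- list(
        id = n_id, role = role, cx = cx, cy = cy, a = a, b = b, rot = rot,
        d = d, rx = rx, ry = ry, intensity = int_draw()
      )
      return(invisible(NULL))
    }
    stop("field too crowded: could not place a ", role, " object within the ",
         spec$max_attempts, "-attempt placement budget", call. = FALSE)
  }

  nuc_int <- function() {
    m <- spec$nucleus_intensity_au[[1]]; s <- spec$nucleus_intensity_au[[2]]
    min(max(stats::rnorm(1, m, s), m - 2.33 * s), m + 2 * s)
  }
  if (spec$n_nuclei > 0L) {
    for (i in seq_len(spec$n_nuclei)) place("interphase", spec$nucleus_diameter_um, nuc_int)
  }
  if (spec$n_edge_nuclei > 0L) {
    for (i in seq_len(spec$n_edge_nuclei)) {
      place("edge", spec$nucleus_diameter_um, nuc_int, at_edge = TRUE)
    }
  }
  if (spec$n_bright_bodies > 0L) {
    for (i in seq_len(spec$n_bright_bodies)) {
      place("mitotic", spec$bright_body_diameter_um,
            function() spec$bright_body_intensity_au)
    }
  }

  # micronuclei: one per parent with probability mn_probability, planted
  # strictly nearer the parent than any other object
  mn <- list(); mn_id <- 0L
  mn_int <- function() {
    m <- spec$mn_intensity_au[[1]]; s <- spec$mn_intensity_au[[2]]
    max(stats::rnorm(1, m, s), 4000)
  }
  parents <- Filter(function(o) o$role %in% c("interphase", "edge"), nuc)
  for (par in parents) {
    if (stats::runif(1) >= spec$mn_probability) next
    placed <- FALSE
    for (attempt in seq_len(spec$max_attempts)) {
      d <- stats::runif(1, spec$mn_diameter_um[1], spec$mn_diameter_um[2])
      g <- stats::runif(1, spec$mn_distance_um[1], spec$mn_distance_um[2])
      th <- stats::runif(1, 0, 2 * pi)
      rb <- .ellipse_radius(par$a, par$b, par$rot, th)
      cd <- rb + g + d / 2
      cx <- par$cx + cd * cos(th); cy <- par$cy + cd * sin(th)
      if (par$role == "interphase" &&
          (cx - d / 2 < 1 || cx + d / 2 > W - 1 || cy - d / 2 < 1 || cy + d / 2 > H - 1)) next
      ok <- TRUE
      for (o in nuc) {
        if (o$id == par$id) next
        # keep every micronucleus pixel nearer the parent than this object
        if (sqrt((cx - o$cx)^2 + (cy - o$cy)^2) - max(o$a, o$b) < g + 1.5 * d + 1) {
          ok <- FALSE; break
        }
      }
      if (ok) for (m in mn) {
        if (sqrt((cx - m$cx)^2 + (cy - m$cy)^2) < (d + m$d) / 2 + 2) { ok <- FALSE; break }
      }
      if (!ok) next
      mn_id <- mn_id + 1L
      mn[[length(mn) + 1L]] <- list(id = mn_id, parent = par$id, cx = cx, cy = cy,
                                    d = d, gap = g, intensity = mn_int())
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("field too crowded: could not place a micronucleus within the ",
           spec$max_attempts, "-attempt placement budget", call. = FALSE)
    }
  }

  # rasterise (pixel-centre convention)
  nr <- spec$height_px; nc <- spec$width_px
  canvas <- matrix(0, nr, nc)
  draw_ellipse <- function(cx, cy, a, b, rot, value) {
    rx <- sqrt((a * cos(rot))^2 + (b * sin(rot))^2)
    ry <- sqrt((a * sin(rot))^2 + (b * cos(rot))^2)
    x0 <- max(1L, floor((cx - rx) / psz)); x1 <- min(nc, ceiling((cx + rx) / psz) + 1L)
    y0 <- max(1L, floor((cy - ry) / psz)); y1 <- min(nr, ceiling((cy + ry) / psz) + 1L)
    if (x0 > x1 || y0 > y1) return(invisible(NULL))
    xs <- (x0:x1 - 0.5) * psz - cx
    ys <- (y0:y1 - 0.5) * psz - cy
    dx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    dy <- matrix(ys, length(ys), length(xs))
    u <- (dx * cos(rot) + dy * sin(rot)) / a
    v <- (-dx * sin(rot) + dy * cos(rot)) / b
    inside <- u^2 + v^2 <= 1
    sub <- canvas[y0:y1, x0:x1, drop = FALSE]
    sub[inside] <- pmax(sub[inside], value)
    canvas[y0:y1, x0:x1] <<- sub
    invisible(NULL)
  }
  for (o in nuc) draw_ellipse(o$cx, o$cy, o$a, o$b, o$rot, o$intensity)
  for (m in mn) draw_ellipse(m$cx, m$cy, m$d / 2, m$d / 2, 0, m$intensity)

  if (spec$edge_softening_px > 0 && any(canvas > 0)) {
    canvas <- gaussian_blur(canvas, spec$edge_softening_px)
  }

  bg <- spec$background_au
  if (spec$ramp_au > 0) {
    xr <- (seq_len(nc) - 1) / max(nc - 1L, 1L)
    yr <- (seq_len(nr) - 1) / max(nr - 1L, 1L)
    bg <- bg + spec$ramp_au * (outer(yr, xr, `+`) / 2)
  }
  img <- canvas + bg
  if (spec$noise_sd_au > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd_au)
  }
  img <- matrix(pmin(pmax(round(img), 0), 65535), nr, nc)

  truth_nuclei <- if (length(nuc)) {
    tibble::tibble(
      id = vapply(nuc, `[[`, integer(1), "id"),
      role = vapply(nuc, `[[`, character(1), "role"),
      cx_um = vapply(nuc, `[[`, numeric(1), "cx"),
      cy_um = vapply(nuc, `[[`, numeric(1), "cy"),
      a_um = vapply(nuc, `[[`, numeric(1), "a"),
      b_um = vapply(nuc, `[[`, numeric(1), "b"),
      rot = vapply(nuc, `[[`, numeric(1), "rot"),
      equivalent_diameter_um = vapply(nuc, `[[`, numeric(1), "d"),
      rx_um = vapply(nuc, `[[`, numeric(1), "rx"),
      ry_um = vapply(nuc, `[[`, numeric(1), "ry"),
      intensity_au = vapply(nuc, `[[`, numeric(1), "intensity")
    )
  } else {
    tibble::tibble(id = integer(), role = character(), cx_um = numeric(),
                   cy_um = numeric(), a_um = numeric(), b_um = numeric(),
                   rot = numeric(), equivalent_diameter_um = numeric(),
                   rx_um = numeric(), ry_um = numeric(), intensity_au = numeric())
  }
  truth_mn <- if (length(mn)) {
    tibble::tibble(
      id = vapply(mn, `[[`, integer(1), "id"),
      parent = vapply(mn, `[[`, integer(1), "parent"),
      cx_um = vapply(mn, `[[`, numeric(1), "cx"),
      cy_um = vapply(mn, `[[`, numeric(1), "cy"),
      diameter_um = vapply(mn, `[[`, numeric(1), "d"),
      gap_um = vapply(mn, `[[`, numeric(1), "gap"),
      intensity_au = vapply(mn, `[[`, numeric(1), "intensity")
    )
  } else {
    tibble::tibble(id = integer(), parent = integer(), cx_um = numeric(),
                   cy_um = numeric(), diameter_um = numeric(),
                   gap_um = numeric(), intensity_au = numeric())
  }

  list(
    image = image_plane(img, psz, 65535),
    truth = list(nuclei = truth_nuclei, micronuclei = truth_mn)
  )
}

# separable Gaussian convolution with replicated edges (no wrap-around)
gaussian_blur <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) {
    # x: matrix, convolve along rows (dim 1) with replicate padding
    n <- nrow(x)
    acc <- matrix(0, n, ncol(x))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      acc <- acc + k[i] * x[idx, , drop = FALSE]
    }
    acc
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Expected retained counts from planted geometry
#'
#' The independent rule-checker: recomputes, from the ground-truth geometry
#' alone (never from pixels), how many nuclei and micronuclei the analysis
#' parameters should retain in a field. A nucleus is expected-retained iff
#' its role is interphase, its axis-aligned extent clears the periphery band,
#' its equivalent diameter lies within the primary size window, and (when an
#' intensity cutoff applies) its drawn intensity is at or below the cutoff.
#' A planted micronucleus is expected-retained iff its parent is retained
#' and its diameter lies within the spot size window (and under the size cap
#' when a calibration is given).
#'
#' @param truth Truth list from [render_field()].
#' @param spec The [synthetic_spec()] used to render.
#' @param params [seg_params()] the field will be analysed with.
#' @param filters [filter_params()] the field will be analysed with.
#' @param size_calibration Optional [calibrate_mn_size()].
#' @return One-row tibble: `n_nuclei`, `n_micronuclei`.
#' @export
expected_counts <- function(truth, spec, params, filters = filter_params(),
                            size_calibration = NULL) {
  W <- spec$width_px * spec$pixel_size_um
  H <- spec$height_px * spec$pixel_size_um
  m <- filters$periphery_margin_um
  nu <- truth$nuclei
  clear <- nu$cx_um - nu$rx_um >= m & nu$cx_um + nu$rx_um <= W - m &
           nu$cy_um - nu$ry_um >= m & nu$cy_um + nu$ry_um <= H - m
  size_ok <- nu$equivalent_diameter_um >= params$min_object_size_um &
             nu$equivalent_diameter_um <= params$max_object_size_um
  int_ok <- if (is.null(filters$max_mean_intensity_au)) TRUE
            else nu$intensity_au <= filters$max_mean_intensity_au
  kept <- nu$role == "interphase" & clear & size_ok & int_ok
  kept_ids <- nu$id[kept]
  mnt <- truth$micronuclei
  mn_ok <- mnt$parent %in% kept_ids &
           mnt$diameter_um >= params$min_spot_size_um &
           mnt$diameter_um <= params$max_spot_size_um
  if (!is.null(size_calibration)) {
    mn_ok <- mn_ok & if (size_calibration$mode == "area") {
      pi * (mnt$diameter_um / 2)^2 <= size_calibration$mn_max_area_um2
    } else {
      mnt$diameter_um <= size_calibration$mn_max_diameter_um
    }
  }
  tibble::tibble(n_nuclei = sum(kept), n_micronuclei = sum(mn_ok))
}

# deterministic per-field seed from (seed, well index, field index)
field_seed <- function(seed, well_index, field) {
  as.integer((as.numeric(seed) + 1000003 * well_index + 9973 * field) %% 2147483587L)
}

#' Render a whole synthetic plate
#'
#' Renders `fields_per_well(layout)` fields per well, with per-field seeds
#' derived deterministically from `(seed, well index, field index)` so wells
#' are independent yet reproducible. Fields are either written to a plate
#' directory (one subdirectory per well, TIFF fields plus truth CSVs — a
#' drop-in data source for [segment_plate_dir()] and the command line tool)
#' or handed to a callback one at a time, which keeps a full plate out of
#' memory.
#'
#' @param layout [plate_layout()].
#' @param mn_probability Named numeric vector: per-condition micronucleus
#'   probability; every condition in the layout must be present.
#' @param spec Base [synthetic_spec()]; its seed and `mn_probability` are
#'   overridden per field.
#' @param seed Plate-level integer seed.
#' @param dir Optional output directory.
#' @param field_fun Optional `function(image, truth, well_id, field)`; its
#'   results are collected and returned.
#' @return List: `truth_nuclei`, `truth_micronuclei` (tibbles with
#'   `well_id`/`field`), `planted` (per-field planted counts), `results`
#'   (list of `field_fun` values, or `NULL`).
#' @export
render_plate <- function(layout, mn_probability, spec = synthetic_spec(),
                         seed = 1L, dir = NULL, field_fun = NULL) {
  stopifnot(inherits(layout, "mn_layout"), inherits(spec, "mn_synthetic_spec"))
  conds <- unique(layout$condition)
  missing_p <- setdiff(conds, names(mn_probability))
  if (length(missing_p)) {
    stop("mn_probability missing for condition(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  fpw <- fields_per_well(layout)
  tn <- list(); tm <- list(); planted <- list(); results <- list()
  for (wi in seq_len(nrow(layout))) {
    well <- layout$well_id[wi]
    if (!is.null(dir)) dir.create(file.path(dir, well), recursive = TRUE,
                                  showWarnings = FALSE)
    for (k in seq_len(fpw)) {
      sp <- spec
      sp$seed <- field_seed(seed, wi, k)
      sp$mn_probability <- unname(mn_probability[[layout$condition[wi]]])
      rf <- render_field(sp)
      if (!is.null(dir)) {
        write_field(rf$image, file.path(dir, well, sprintf("field_%02d.tif", k)))
      }
      if (nrow(rf$truth$nuclei)) {
        tn[[length(tn) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(well_id = well, field = k), rf$truth$nuclei)
      }
      if (nrow(rf$truth$micronuclei)) {
        tm[[length(tm) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(well_id = well, field = k), rf$truth$micronuclei)
      }
      planted[[length(planted) + 1L]] <- tibble::tibble(
        well_id = well, field = k,
        n_nuclei_planted = sum(rf$truth$nuclei$role == "interphase"),
        n_parents_planted = sum(rf$truth$nuclei$role %in% c("interphase", "edge")),
        n_micronuclei_planted = nrow(rf$truth$micronuclei)
      )
      if (!is.null(field_fun)) {
        results[[length(results) + 1L]] <- field_fun(rf$image, rf$truth, well, k)
      }
    }
  }
  truth_nuclei <- dplyr::bind_rows(tn)
  truth_mn <- dplyr::bind_rows(tm)
  if (!is.null(dir)) {
    readr::write_csv(truth_nuclei, file.path(dir, "truth_nuclei.csv"), progress = FALSE)
    readr::write_csv(truth_mn, file.path(dir, "truth_micronuclei.csv"), progress = FALSE)
  }
  list(
    truth_nuclei = truth_nuclei,
    truth_micronuclei = truth_mn,
    planted = dplyr::bind_rows(planted),
    results = if (is.null(field_fun)) NULL else results
  )
}

#' Simulate and score a plate in one pass
#'
#' Renders each synthetic field, runs the full segmentation/filter chain on
#' it, and aggregates per-well scores, without holding more than one field
#' in memory. The geometric expected counts ([expected_counts()]) are
#' returned alongside, so pipeline recovery can be checked against the
#' planted truth.
#'
#' @inheritParams render_plate
#' @param params,filters,size_calibration As in [segment_field()].
#' @return List: `wells` ([score_plate()] result), `field_counts`,
#'   `expected` (per-field expected retained counts), `truth_micronuclei`.
#' @export
simulate_plate <- function(layout, mn_probability, spec = synthetic_spec(),
                           params = builtin_profile("HCT116"),
                           filters = filter_params(max_mean_intensity_au = 54000),
                           size_calibration = NULL, seed = 1L) {
  expected <- list()
  res <- render_plate(
    layout, mn_probability, spec, seed,
    field_fun = function(image, truth, well_id, field) {
      fld <- segment_field(image, params, filters, size_calibration)
      sp2 <- spec
      expected[[length(expected) + 1L]] <<- dplyr::bind_cols(
        tibble::tibble(well_id = well_id, field = field),
        expected_counts(truth, spec, params, filters, size_calibration))
      dplyr::bind_cols(tibble::tibble(well_id = well_id, field = field),
                       count_field(fld))
    }
  )
  field_counts <- dplyr::bind_rows(res$results)
  list(
    wells = score_plate(field_counts, layout),
    field_counts = field_counts,
    expected = dplyr::bind_rows(expected),
    truth_micronuclei = res$truth_micronuclei
  )
}
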