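.layout_roles <- c("vehicle-control", "treatment", "siControl", "siGene", "untreated")

#' Plate layout
#'
#' Describes every analysed well of a multiwell plate: condition label, dose
#' (with units) for dose-response designs, replicate index, and the well's
#' role. Roles drive downstream normalisation: dose series are expressed
#' relative to the single `vehicle-control` group and silencing fold changes
#' relative to the single `siControl` condition.
#'
#' @param wells Data frame with columns `well_id`, `condition`, `dose`,
#'   `dose_units`, `replicate`, `role`. `dose`/`dose_units` may be `NA` for
#'   non-dose designs.
#' @param fields_per_well Number of non-overlapping fields imaged per well
#'   (default 9, acquired from the well centre to avoid edge effects).
#' @return A tibble of class `mn_layout` with attribute `fields_per_well`.
#' @export
plate_layout <- function(wells, fields_per_well = 9L) {
  wells <- tibble::as_tibble(wells)
  needed <- c("well_id", "condition", "replicate", "role")
  miss <- setdiff(needed, names(wells))
  if (length(miss)) {
    stop("layout is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"dose" %in% names(wells)) wells$dose <- NA_real_
  if (!"dose_units" %in% names(wells)) wells$dose_units <- NA_character_
  wells$dose <- as.numeric(wells$dose)
  wells$replicate <- as.integer(wells$replicate)
  if (anyDuplicated(wells$well_id)) {
    stop("layout invariant violated: well_id values must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(wells$role), .layout_roles)
  if (length(bad)) {
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.layout_roles, collapse = ", "), call. = FALSE)
  }
  n_veh <- length(unique(wells$condition[wells$role == "vehicle-control"]))
  if (any(wells$role == "treatment")) {
    if (n_veh != 1L) {
      stop("layout invariant violated: a dose series needs exactly one ",
           "vehicle-control condition (found ", n_veh, ")", call. = FALSE)
    }
    if (anyNA(wells$dose[wells$role == "treatment"])) {
      stop("treatment wells must carry a dose", call. = FALSE)
    }
  }
  n_sic <- length(unique(wells$condition[wells$role == "siControl"]))
  if (any(wells$role == "siGene") && n_sic != 1L) {
    stop("layout invariant violated: fold-change groups need exactly one ",
         "siControl condition (found ", n_sic, ")", call. = FALSE)
  }
  if (!is.numeric(fields_per_well) || fields_per_well < 1) {
    stop("fields_per_well must be >= 1", call. = FALSE)
  }
  wells <- wells[, c("well_id", "condition", "dose", "dose_units", "replicate", "role")]
  attr(wells, "fields_per_well") <- as.integer(fields_per_well)
  class(wells) <- c("mn_layout", class(wells))
  wells
}

#' @export
#' @rdname plate_layout
#' @param x An `mn_layout`.
fields_per_well <- function(x) {
  fp <- attr(x, "fields_per_well")
  if (is.null(fp)) 9L else fp
}

#' Read a plate layout from CSV
#'
#' Columns: `well_id,condition,dose,dose_units,replicate,role`.
#'
#' @param path CSV path.
#' @inheritParams plate_layout
#' @return An [plate_layout()] tibble.
#' @export
read_plate_layout <- function(path, fields_per_well = 9L) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  plate_layout(df, fields_per_well = fields_per_well)
}

#' Read a run configuration
#'
#' One structured YAML file holds everything a run needs: the mandatory
#' physical pixel size, a segmentation profile (either `profile: <cell line>`
#' naming a built-in row or an explicit `segmentation:` block), an optional
#' `filters:` block, and the plate layout (inline under `layout:` or a CSV
#' sidecar via `layout_csv:`, resolved relative to the config file). The pixel
#' size is never defaulted: all size thresholds are in micrometres and the
#' camera's um/pixel varies between instruments.
#'
#' @param path Path to a YAML config.
#' @return A list with elements `pixel_size_um`, `params` ([seg_params()]),
#'   `filters` ([filter_params()]), `layout` ([plate_layout()] or `NULL`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pixel_size_um)) {
    stop("config error: `pixel_size_um` is required and has no default",
         call. = FALSE)
  }
  psz <- cfg$pixel_size_um
  if (!is.numeric(psz) || psz <= 0) {
    stop("config error: `pixel_size_um` must be a positive number", call. = FALSE)
  }

  params <- if (!is.null(cfg$profile)) {
    prof <- builtin_profile(cfg$profile)
    if (!is.null(cfg$segmentation)) {
      # explicit keys override the named profile
      over <- cfg$segmentation
      args <- utils::modifyList(unclass(prof)[!vapply(unclass(prof), is.null, TRUE)], over)
      do.call(seg_params, args)
    } else prof
  } else if (!is.null(cfg$segmentation)) {
    do.call(seg_params, cfg$segmentation)
  } else {
    stop("config error: provide `profile:` or a `segmentation:` block", call. = FALSE)
  }

  filters <- if (is.null(cfg$filters)) filter_params() else do.call(filter_params, cfg$filters)

  layout <- NULL
  fpw <- if (is.null(cfg$fields_per_well)) 9L else cfg$fields_per_well
  if (!is.null(cfg$layout_csv)) {
    lp <- cfg$layout_csv
    if (!file.exists(lp)) lp <- file.path(dirname(path), cfg$layout_csv)
    layout <- read_plate_layout(lp, fields_per_well = fpw)
  } else if (!is.null(cfg$layout)) {
    df <- dplyr::bind_rows(lapply(cfg$layout, tibble::as_tibble))
    layout <- plate_layout(df, fields_per_well = fpw)
  }

  list(pixel_size_um = as.numeric(psz), params = params, filters = filters,
       layout = layout)
}

#' Write a run configuration
#'
#' Serialises parameters back to YAML such that [read_config()] reproduces
#' identical values (round-trip property).
#'
#' @param pixel_size_um Physical pixel size (um).
#' @param params An [seg_params()] object.
#' @param filters An [filter_params()] object.
#' @param layout Optional [plate_layout()]; written inline.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(pixel_size_um, params, filters = filter_params(),
                         layout = NULL, path) {
  stopifnot(inherits(params, "mn_seg_params"), inherits(filters, "mn_filter_params"))
  cfg <- list(
    pixel_size_um = pixel_size_um,
    segmentation = unclass(params)[!vapply(unclass(params), is.null, TRUE)],
    filters = unclass(filters)[!vapply(unclass(filters), is.null, TRUE)]
  )
  if (!is.null(layout)) {
    cfg$fields_per_well <- fields_per_well(layout)
    rows <- lapply(seq_len(nrow(layout)), function(i) {
      r <- as.list(layout[i, ])
      r[!vapply(r, function(v) is.na(v) && !is.character(v), TRUE)]
    })
    cfg$layout <- rows
  }
  # 17 significant digits: doubles (e.g. a 1/3 size fraction) survive the
  # round trip bit-exactly
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}
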