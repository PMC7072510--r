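#' Score one well
#'
#' The well-level statistic is the micronucleus frequency: total retained
#' micronuclei divided by total retained nuclei, with both totals summed over
#' the well's fields *before* division (a ratio of totals, not a mean of
#' per-field ratios — fields with more cells carry proportionally more
#' weight, which also corrects for confluency differences between
#' conditions). A well with zero retained nuclei has no defined frequency:
#' it is flagged and excluded from downstream statistics with a warning,
#' rather than scored 0, because cytotoxic doses kill the very cells that
#' would have been counted.
#'
#' @param field_counts Tibble with one row per field: `n_nuclei`,
#'   `n_micronuclei` (e.g. rows of [count_field()]).
#' @param well_id Optional well identifier recorded in the result.
#' @return One-row tibble: `well_id`, `n_fields`, `n_nuclei`,
#'   `n_micronuclei`, `frequency`, `percent`, `flag`.
#' @export
score_well <- function(field_counts, well_id = NA_character_) {
  stopifnot(nrow(field_counts) >= 1L)
  n_nuc <- sum(field_counts$n_nuclei)
  n_mn <- sum(field_counts$n_micronuclei)
  if (n_nuc > 0L) {
    freq <- n_mn / n_nuc
    flag <- NA_character_
  } else {
    warning("well ", well_id, " has zero retained nuclei; frequency undefined",
            call. = FALSE)
    freq <- NA_real_
    flag <- "no_nuclei"
  }
  tibble::tibble(
    well_id = well_id, n_fields = nrow(field_counts),
    n_nuclei = n_nuc, n_micronuclei = n_mn,
    frequency = freq, percent = 100 * freq, flag = flag
  )
}

#' Score every well of a plate
#'
#' Applies [score_well()] per well and joins the plate layout, yielding the
#' per-well table downstream statistics consume.
#'
#' @param field_counts Tibble with `well_id`, `n_nuclei`, `n_micronuclei`
#'   (one row per field).
#' @param layout [plate_layout()].
#' @return Tibble of class `mn_wells`.
#' @export
score_plate <- function(field_counts, layout) {
  stopifnot(inherits(layout, "mn_layout"))
  unknown <- setdiff(unique(field_counts$well_id), layout$well_id)
  if (length(unknown)) {
    stop("field counts reference wells absent from the layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  wells <- field_counts |>
    dplyr::group_by(.data$well_id) |>
    dplyr::group_modify(function(df, key) {
      score_well(df, well_id = key$well_id)[, -1L]
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(tibble::as_tibble(layout), by = "well_id") |>
    dplyr::select("well_id", "condition", "dose", "dose_units", "replicate",
                  "role", "n_fields", "n_nuclei", "n_micronuclei",
                  "frequency", "percent", "flag")
  class(wells) <- c("mn_wells", class(wells))
  wells
}

#' Dose-response summary
#'
#' Per-dose mean and sample (n-1) standard deviation of the replicate well
#' frequencies, expressed relative to the vehicle-control mean. The vehicle
#' group is treated as dose 0 and its relative mean is 1 by construction.
#' Flagged wells (no retained nuclei) are dropped before summarising.
#'
#' @param wells An `mn_wells` table with exactly one vehicle-control group
#'   and at least one treatment dose.
#' @return Tibble of class `mn_dose_response`: `dose`, `dose_units`,
#'   `n_replicates`, `mean`, `sd`, `relative_mean`, `relative_sd`, sorted by
#'   ascending dose. `sd` is `NA` (flagged undefined) for single-replicate
#'   doses.
#' @export
dose_response <- function(wells) {
  use <- wells[is.na(wells$flag) & wells$role %in% c("vehicle-control", "treatment"), ]
  veh <- use[use$role == "vehicle-control", ]
  if (!nrow(veh)) stop("missing vehicle control", call. = FALSE)
  if (length(unique(veh$condition)) > 1L) {
    stop("more than one vehicle-control condition", call. = FALSE)
  }
  veh_mean <- mean(veh$frequency)
  if (veh_mean <= 0) {
    stop("vehicle-control mean frequency is zero; relative values undefined",
         call. = FALSE)
  }
  use$dose[use$role == "vehicle-control"] <- 0
  out <- use |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(
      dose_units = dplyr::first(stats::na.omit(.data$dose_units)),
      n_replicates = dplyr::n(),
      mean = mean(.data$frequency),
      sd = if (dplyr::n() >= 2L) stats::sd(.data$frequency) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      relative_mean = .data$mean / veh_mean,
      relative_sd = .data$sd / veh_mean
    ) |>
    dplyr::arrange(.data$dose)
  class(out) <- c("mn_dose_response", class(out))
  attr(out, "vehicle_mean") <- veh_mean
  out
}

#' Gene-silencing fold changes
#'
#' Divides each technical-replicate frequency (every condition, the
#' siControl included) by the mean siControl frequency, so the siControl
#' fold changes average to exactly 1.00 and a silenced CIN gene shows as a
#' multiple of that baseline.
#'
#' @param wells An `mn_wells` table containing at least one siControl well
#'   with a defined frequency.
#' @return Tibble of class `mn_fold_change`: `condition`, `role`,
#'   `replicate`, `well_id`, `frequency`, `fold_change`.
#' @export
fold_change <- function(wells) {
  use <- wells[is.na(wells$flag), ]
  ctrl <- use[use$role == "siControl", ]
  if (!nrow(ctrl)) stop("no siControl replicate with a defined frequency",
                        call. = FALSE)
  ref <- mean(ctrl$frequency)
  if (ref == 0) stop("mean siControl frequency is zero; normalization undefined",
                     call. = FALSE)
  out <- use |>
    dplyr::filter(.data$role %in% c("siControl", "siGene", "untreated")) |>
    dplyr::transmute(
      condition = .data$condition, role = .data$role,
      replicate = .data$replicate, well_id = .data$well_id,
      frequency = .data$frequency,
      fold_change = .data$frequency / ref
    )
  class(out) <- c("mn_fold_change", class(out))
  attr(out, "sicontrol_mean_frequency") <- ref
  out
}
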