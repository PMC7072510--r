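make_nuclei <- function(xmin_um, width_um = 10, psz = 0.5, dims = c(256, 256),
                        mean_int = 9000) {
  tibble::tibble(
    label = seq_along(xmin_um),
    area_px = 400L, area_um2 = 100, equivalent_diameter_um = 11.3,
    cx_um = xmin_um + width_um / 2, cy_um = 64,
    mean_intensity_au = mean_int,
    xmin = as.integer(round(xmin_um / psz)) + 1L,
    xmax = as.integer(round((xmin_um + width_um) / psz)),
    ymin = 100L, ymax = 120L
  )
}

test_that("periphery exclusion flags exactly the band-intersecting nuclei", {
  psz <- 0.5; dims <- c(256L, 256L)  # 128 x 128 um field
  nuclei <- make_nuclei(c(20, 31, 50))  # bboxes start at 20 / 31 / 50 um
  out <- periphery_filter(nuclei, dims, margin_um = 30, pixel_size_um = psz)
  expect_identical(out$excl_periphery, c(TRUE, FALSE, FALSE))
  none <- periphery_filter(nuclei, dims, margin_um = 0, pixel_size_um = psz)
  expect_false(any(none$excl_periphery))
  expect_error(periphery_filter(nuclei, dims, margin_um = 64, pixel_size_um = psz),
               "entire field")
})

test_that("intensity calibration takes the midpoint and demands separation", {
  expect_identical(calibrate_intensity_cutoff(8000, 20000), 14000)
  expect_identical(calibrate_intensity_cutoff(c(7000, 9000), c(19000, 21000)), 14000)
  expect_error(calibrate_intensity_cutoff(10000, 9000), "overlap")
  expect_error(calibrate_intensity_cutoff(numeric(0), 9000), "non-empty")
})

test_that("the intensity filter excludes bright bodies and keeps nuclei", {
  objs <- make_nuclei(c(50, 70), mean_int = 9000)
  objs$mean_intensity_au <- c(9000, 30000)
  out <- intensity_filter(objs, 14000)
  expect_identical(out$excl_intensity, c(FALSE, TRUE))
  expect_identical(out$retained, c(TRUE, FALSE))
  all_in <- intensity_filter(objs, 65535)
  expect_false(any(all_in$excl_intensity))
})

test_that("size calibration computes the stated cap", {
  one <- tibble::tibble(area_um2 = 120, equivalent_diameter_um = 12.4)
  cal <- calibrate_mn_size(one, fraction = 1 / 3)
  expect_identical(cal$mn_max_area_um2, 40)
  expect_identical(cal$n_nuclei_used, 1L)
  three <- tibble::tibble(area_um2 = c(90, 110, 130),
                          equivalent_diameter_um = c(10.7, 11.8, 12.9))
  cal3 <- calibrate_mn_size(three, fraction = 1 / 3)
  expect_equal(cal3$mn_max_area_um2, 110 / 3)
  expect_error(calibrate_mn_size(three, fraction = 0), "between 0 and 1")
  excluded <- three; excluded$retained <- FALSE
  expect_error(calibrate_mn_size(excluded), "no retained")
})

test_that("the micronucleus size cap is inclusive at the boundary", {
  cal <- calibrate_mn_size(tibble::tibble(area_um2 = 120,
                                          equivalent_diameter_um = 12.4))
  spots <- tibble::tibble(
    label = 1:3, area_px = 1L, area_um2 = c(39, 40, 41),
    equivalent_diameter_um = 2 * sqrt(c(39, 40, 41) / pi),
    cx_um = 0, cy_um = 0, mean_intensity_au = 5000,
    xmin = 1L, xmax = 1L, ymin = 1L, ymax = 1L, nucleus_label = 1L
  )
  out <- mn_size_filter(spots, cal)
  expect_identical(out$excl_size_cap, c(FALSE, FALSE, TRUE))
})

test_that("orphan flags follow their nucleus and are recomputed, not sticky", {
  nuclei <- make_nuclei(c(20, 50))
  spots <- tibble::tibble(
    label = 1:2, area_px = 10L, area_um2 = 2.5, equivalent_diameter_um = 1.8,
    cx_um = 0, cy_um = 0, mean_intensity_au = 5000,
    xmin = 1L, xmax = 1L, ymin = 1L, ymax = 1L, nucleus_label = c(1L, 2L)
  )
  flagged <- periphery_filter(nuclei, c(256L, 256L), 30, 0.5)
  out <- flag_orphans(spots, flagged)
  expect_identical(out$excl_orphan, c(TRUE, FALSE))
  # recomputing against unflagged nuclei clears the orphan flag
  expect_false(any(flag_orphans(out, make_nuclei(c(20, 50)))$excl_orphan))
})

test_that("filter flags commute across all six orderings", {
  hct <- builtin_profile("HCT116")
  rf <- render_field(small_spec(13))
  fld <- segment_field(rf$image, hct, filter_params())  # unfiltered intensity
  cal <- calibrate_mn_size(fld$nuclei)
  apply_order <- function(ord) {
    nuc <- fld$nuclei; sp <- fld$spots
    for (step in ord) {
      if (step == "periphery") {
        nuc <- periphery_filter(nuc, fld$dims, 30, fld$pixel_size_um)
      } else if (step == "intensity") {
        nuc <- intensity_filter(nuc, 54000)
        sp <- intensity_filter(sp, 54000)
      } else {
        sp <- mn_size_filter(sp, cal)
      }
    }
    sp <- flag_orphans(sp, nuc)
    list(n = nuc[order(nuc$label), c("excl_periphery", "excl_intensity")],
         s = sp[order(sp$label),
                c("excl_size_cap", "excl_intensity", "excl_orphan")])
  }
  orders <- list(
    c("periphery", "intensity", "size"), c("periphery", "size", "intensity"),
    c("intensity", "periphery", "size"), c("intensity", "size", "periphery"),
    c("size", "periphery", "intensity"), c("size", "intensity", "periphery")
  )
  results <- lapply(orders, apply_order)
  for (k in 2:6) expect_identical(results[[k]], results[[1]])
})

test_that("filters only ever shrink the retained set", {
  hct <- builtin_profile("HCT116")
  rf <- render_field(small_spec(19))
  fld <- segment_field(rf$image, hct, filter_params())
  n0 <- sum(fld$nuclei$retained)
  nuc <- periphery_filter(fld$nuclei, fld$dims, 30, fld$pixel_size_um)
  n1 <- sum(nuc$retained)
  nuc2 <- intensity_filter(nuc, 54000)
  n2 <- sum(nuc2$retained)
  expect_true(n0 >= n1 && n1 >= n2)
})
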