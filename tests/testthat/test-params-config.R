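profile_row <- function(p) {
  c(p$min_object_size_um, p$max_object_size_um, p$primary_detection_threshold_au,
    p$ring_width_um, p$min_spot_size_um, p$max_spot_size_um,
    p$spot_detection_threshold_au)
}

test_that("built-in profiles reproduce the published parameter rows exactly", {
  expect_identical(profile_row(builtin_profile("HCT116")),
                   c(10, 100, 7000, 10, 1, 5, 3000))
  expect_identical(profile_row(builtin_profile("FT194")),
                   c(10, 100, 7000, 15, 1, 6, 3000))
  expect_identical(profile_row(builtin_profile("FT246")),
                   c(10, 100, 7000, 15, 1, 6, 3000))
})

test_that("unknown cell lines are rejected with the list of known profiles", {
  expect_error(builtin_profile("HeLa"), "HCT116, FT194, FT246")
})

test_that("parameter invariants are enforced at construction", {
  expect_error(seg_params(100, 10, 7000, 10, 1, 5, 3000), "min_object_size_um")
  expect_error(seg_params(10, 100, 7000, 10, 5, 1, 3000), "min_spot_size_um")
  expect_error(seg_params(10, 100, 0, 10, 1, 5, 3000), "thresholds")
  expect_error(seg_params(10, 100, 7000, 10, 1, 5, 3000,
                          background_flatten = TRUE),
               "rolling_ball_radius_um")
  expect_error(filter_params(mn_area_fraction = 0), "between 0 and 1")
  expect_error(filter_params(periphery_margin_um = -1), ">= 0")
})

test_that("layout invariants are enforced", {
  base <- data.frame(
    well_id = c("A1", "A2", "B1"), condition = c("veh", "drug", "drug"),
    dose = c(NA, 1, 2), dose_units = "uM", replicate = 1L,
    role = c("vehicle-control", "treatment", "treatment")
  )
  expect_s3_class(plate_layout(base), "mn_layout")
  dup <- base; dup$well_id[2] <- "A1"
  expect_error(plate_layout(dup), "unique")
  two_veh <- rbind(base, data.frame(well_id = "C1", condition = "veh2", dose = NA,
                                    dose_units = NA, replicate = 1L,
                                    role = "vehicle-control"))
  expect_error(plate_layout(two_veh), "exactly one")
  si <- data.frame(well_id = "A1", condition = "siSMC1A", dose = NA,
                   dose_units = NA, replicate = 1L, role = "siGene")
  expect_error(plate_layout(si), "siControl")
  expect_error(plate_layout(transform(base, role = "mystery")), "unknown role")
})

test_that("config round trip reproduces identical parameter values", {
  params <- seg_params(10, 100, 7000, 15, 1, 6, 3000,
                       reduce_primary_mask_um = 1.5,
                       background_flatten = TRUE, rolling_ball_radius_um = 20)
  filters <- filter_params(periphery_margin_um = 30,
                           max_mean_intensity_au = 54000,
                           mn_area_fraction = 1 / 3)
  layout <- plate_layout(data.frame(
    well_id = c("A1", "A2"), condition = c("siControl", "siSMC1A"),
    replicate = 1:2 * 0 + 1L, role = c("siControl", "siGene")
  ), fields_per_well = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(0.65, params, filters, layout, path)
  cfg <- read_config(path)
  expect_identical(cfg$pixel_size_um, 0.65)
  expect_identical(unclass(cfg$params), unclass(params))
  expect_identical(unclass(cfg$filters), unclass(filters))
  expect_identical(tibble::as_tibble(cfg$layout), tibble::as_tibble(layout))
  expect_identical(fields_per_well(cfg$layout), 9L)
})

test_that("configs resolve named profiles and reject broken ones", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pixel_size_um: 0.65", "profile: FT246"), path)
  cfg <- read_config(path)
  expect_identical(profile_row(cfg$params), c(10, 100, 7000, 15, 1, 6, 3000))

  no_psz <- withr::local_tempfile(fileext = ".yaml")
  writeLines("profile: HCT116", no_psz)
  expect_error(read_config(no_psz), "pixel_size_um")

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pixel_size_um: 0.65", "segmentation:",
               "  min_object_size_um: 100", "  max_object_size_um: 10",
               "  primary_detection_threshold_au: 7000", "  ring_width_um: 10",
               "  min_spot_size_um: 1", "  max_spot_size_um: 5",
               "  spot_detection_threshold_au: 3000"), bad)
  expect_error(read_config(bad), "min_object_size_um")
})

test_that("layout CSV sidecars are resolved relative to the config", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(
    well_id = c("A1", "A2"), condition = c("veh", "veh"), dose = NA,
    dose_units = NA, replicate = 1:2, role = "untreated"
  ), file.path(dir, "layout.csv"))
  writeLines(c("pixel_size_um: 0.65", "profile: HCT116",
               "layout_csv: layout.csv"), file.path(dir, "run.yaml"))
  cfg <- read_config(file.path(dir, "run.yaml"))
  expect_identical(cfg$layout$well_id, c("A1", "A2"))
})
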