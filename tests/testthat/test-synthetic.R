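hct <- builtin_profile("HCT116")

test_that("rendering is bit-identical under a fixed seed", {
  sp <- small_spec(7, noise_sd_au = 300)
  a <- render_field(sp)
  b <- render_field(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  # and leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  invisible(render_field(sp))
  set.seed(99); expect_identical(rnorm(1), before)
})

test_that("a zero-object spec renders background only with empty truth", {
  sp <- synthetic_spec(width_px = 128, height_px = 128, n_nuclei = 0,
                       n_edge_nuclei = 0, n_bright_bodies = 0,
                       noise_sd_au = 0, seed = 1)
  rf <- render_field(sp)
  expect_true(all(rf$image$pixels == sp$background_au))
  expect_identical(nrow(rf$truth$nuclei), 0L)
  expect_identical(nrow(rf$truth$micronuclei), 0L)
})

test_that("overcrowded specs fail with an error naming the budget", {
  sp <- synthetic_spec(width_px = 160, height_px = 160, n_nuclei = 40,
                       max_attempts = 50, seed = 1)
  expect_error(render_field(sp), "50-attempt placement budget")
})

test_that("every planted micronucleus references a planted nucleus", {
  for (seed in c(2, 12)) {
    rf <- render_field(small_spec(seed))
    if (nrow(rf$truth$micronuclei)) {
      parents <- rf$truth$nuclei$id[rf$truth$nuclei$role %in% c("interphase", "edge")]
      expect_true(all(rf$truth$micronuclei$parent %in% parents))
    }
    # roles present as requested
    expect_identical(sum(rf$truth$nuclei$role == "interphase"), 8L)
    expect_identical(sum(rf$truth$nuclei$role == "edge"), 2L)
    expect_identical(sum(rf$truth$nuclei$role == "mitotic"), 1L)
  }
})

test_that("pipeline counts on noise-free renders equal the geometric truth", {
  for (seed in c(4, 23, 31)) {
    sp <- small_spec(seed)
    rf <- render_field(sp)
    fld <- segment_field(rf$image, hct, std_filters())
    want <- expected_counts(rf$truth, sp, hct, std_filters())
    expect_identical(count_field(fld), want)
  }
})

test_that("plate rendering derives independent, reproducible per-well fields", {
  lay <- plate_layout(tibble::tibble(
    well_id = c("A1", "A2"), condition = "veh", dose = NA, dose_units = NA,
    replicate = 1:2, role = "untreated"
  ), fields_per_well = 2)
  sp <- small_spec(1)
  imgs <- list()
  r1 <- render_plate(lay, c(veh = 0.3), sp, seed = 5,
                     field_fun = function(img, truth, w, f) img$pixels)
  r2 <- render_plate(lay, c(veh = 0.3), sp, seed = 5,
                     field_fun = function(img, truth, w, f) img$pixels)
  expect_identical(r1$results, r2$results)
  # different wells and fields get different content
  expect_false(identical(r1$results[[1]], r1$results[[2]]))
  expect_false(identical(r1$results[[1]], r1$results[[3]]))
  expect_error(render_plate(lay, c(other = 0.3), sp, seed = 5),
               "mn_probability missing")
})

test_that("planted frequencies track the per-condition probabilities", {
  lay <- plate_layout(tibble::tibble(
    well_id = c("V1", "V2", "V3", "T1", "T2", "T3"),
    condition = rep(c("veh", "drug"), each = 3),
    dose = NA, dose_units = NA, replicate = rep(1:3, 2),
    role = rep(c("untreated", "untreated"), each = 3)
  ), fields_per_well = 3)
  sp <- synthetic_spec(width_px = 384, height_px = 384, n_nuclei = 25,
                       n_edge_nuclei = 2, n_bright_bodies = 1,
                       noise_sd_au = 0, seed = 1)
  res <- render_plate(lay, c(veh = 0.02, drug = 0.25), sp, seed = 9)
  planted <- res$planted |>
    dplyr::left_join(tibble::as_tibble(lay), by = "well_id") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(p_hat = sum(.data$n_micronuclei_planted) /
                       sum(.data$n_parents_planted))
  p_veh <- planted$p_hat[planted$condition == "veh"]
  p_drug <- planted$p_hat[planted$condition == "drug"]
  n_per <- (25 + 2) * 3 * 3
  expect_lt(abs(p_veh - 0.02), 3 * sqrt(0.02 * 0.98 / n_per) + 1e-9)
  expect_lt(abs(p_drug - 0.25), 3 * sqrt(0.25 * 0.75 / n_per))
})
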