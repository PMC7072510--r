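fc_tbl <- function(nuc, mn) tibble::tibble(n_nuclei = nuc, n_micronuclei = mn)

test_that("well frequency is the ratio of totals, not a mean of ratios", {
  w <- score_well(fc_tbl(c(100L, 150L, 250L), c(2L, 3L, 5L)), "A1")
  expect_identical(w$frequency, 10 / 500)
  expect_identical(w$percent, 2)
  expect_identical(w$n_fields, 3L)
  # a mean of per-field ratios would differ on unbalanced fields
  w2 <- score_well(fc_tbl(c(10L, 1000L), c(5L, 0L)), "B1")
  expect_identical(w2$frequency, 5 / 1010)
  expect_identical(score_well(fc_tbl(200L, 0L))$frequency, 0)
})

test_that("score_well is invariant to field order and flags empty wells", {
  a <- fc_tbl(c(10L, 30L, 20L), c(1L, 0L, 2L))
  expect_identical(score_well(a)$frequency, score_well(a[c(3, 1, 2), ])$frequency)
  expect_warning(w <- score_well(fc_tbl(c(0L, 0L), c(0L, 0L)), "C1"),
                 "zero retained nuclei")
  expect_identical(w$flag, "no_nuclei")
  expect_true(is.na(w$frequency))
})

dose_layout <- function() {
  plate_layout(tibble::tibble(
    well_id = sprintf("W%02d", 1:12),
    condition = rep(c("vehicle", "etoposide"), c(3, 9)),
    dose = c(rep(NA, 3), rep(c(1, 2, 4), each = 3)),
    dose_units = c(rep(NA, 3), rep("uM", 9)),
    replicate = rep(1:3, 4),
    role = rep(c("vehicle-control", "treatment"), c(3, 9))
  ))
}

wells_from_freq <- function(freqs, layout) {
  n <- 1000L
  fc <- tibble::tibble(
    well_id = layout$well_id,
    n_nuclei = n,
    n_micronuclei = as.integer(round(freqs * n))
  )
  score_plate(fc, layout)
}

test_that("dose-response normalises to the vehicle mean", {
  lay <- dose_layout()
  wells <- wells_from_freq(c(0.01, 0.01, 0.01, 0.05, 0.06, 0.04,
                             0.1, 0.1, 0.1, 0.2, 0.21, 0.19), lay)
  dr <- dose_response(wells)
  expect_identical(dr$dose, c(0, 1, 2, 4))
  expect_identical(dr$relative_mean[1], 1)
  expect_identical(dr$relative_mean[2], 5)
  expect_equal(dr$sd[2], sd(c(0.05, 0.06, 0.04)))
  # relative values are invariant to a common rescaling
  wells2 <- wells_from_freq(2 * c(0.01, 0.01, 0.01, 0.05, 0.06, 0.04,
                                  0.1, 0.1, 0.1, 0.2, 0.21, 0.19) / 4, lay)
  expect_equal(dose_response(wells2)$relative_mean, dr$relative_mean)
})

test_that("single-replicate doses have undefined sd and missing vehicle errors", {
  lay <- plate_layout(tibble::tibble(
    well_id = c("A1", "A2"), condition = c("veh", "drug"),
    dose = c(NA, 1), dose_units = c(NA, "uM"), replicate = 1L,
    role = c("vehicle-control", "treatment")
  ))
  wells <- wells_from_freq(c(0.01, 0.05), lay)
  dr <- dose_response(wells)
  expect_true(is.na(dr$sd[2]))
  expect_identical(dr$mean[2], 0.05)
  no_veh <- wells[wells$role == "treatment", ]
  expect_error(dose_response(no_veh), "vehicle control")
})

si_layout <- function() {
  plate_layout(tibble::tibble(
    well_id = sprintf("S%d", 1:6),
    condition = rep(c("siControl", "siSMC1A"), each = 3),
    dose = NA, dose_units = NA, replicate = rep(1:3, 2),
    role = rep(c("siControl", "siGene"), each = 3)
  ))
}

test_that("fold changes divide by the mean siControl frequency", {
  wells <- wells_from_freq(c(0.02, 0.02, 0.02, 0.08, 0.10, 0.06), si_layout())
  fc <- fold_change(wells)
  expect_equal(fc$fold_change[fc$role == "siGene"], c(4, 5, 3))
  expect_equal(fc$fold_change[fc$role == "siControl"], c(1, 1, 1))
})

test_that("siControl folds average to one even when replicates differ", {
  lay <- plate_layout(tibble::tibble(
    well_id = c("S1", "S2"), condition = "siControl", dose = NA,
    dose_units = NA, replicate = 1:2, role = "siControl"
  ))
  wells <- wells_from_freq(c(0.01, 0.03), lay)
  fc <- fold_change(wells)
  expect_equal(sort(fc$fold_change), c(0.5, 1.5))
  expect_equal(mean(fc$fold_change), 1)
  zero <- wells_from_freq(c(0, 0), lay)
  expect_error(fold_change(zero), "zero")
})

test_that("silencing comparisons report an exact rank test per condition", {
  wells <- wells_from_freq(c(0.02, 0.021, 0.019, 0.08, 0.10, 0.06), si_layout())
  st <- silencing_tests(fold_change(wells))
  expect_identical(nrow(st), 1L)
  expect_identical(st$method, "MW-exact")
  expect_identical(st$p_value, 0.1)  # 3 vs 3, complete separation
})
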