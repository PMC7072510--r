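hct <- builtin_profile("HCT116")

test_that("an empty field yields zero nuclei, not an error", {
  img <- image_plane(matrix(0, 64, 64), 0.5)
  expect_identical(nrow(primary_mask(img, hct)$objects), 0L)
})

test_that("disjoint supra-threshold disks in the size window are each found", {
  img <- disk_image(list(
    list(cx = 25, cy = 25, d = 15, value = 10000),
    list(cx = 75, cy = 25, d = 15, value = 10000),
    list(cx = 25, cy = 75, d = 15, value = 10000),
    list(cx = 75, cy = 75, d = 15, value = 10000),
    list(cx = 50, cy = 105, d = 15, value = 10000)
  ))
  mask <- primary_mask(img, hct)
  expect_identical(nrow(mask$objects), 5L)
  expect_true(all(abs(mask$objects$equivalent_diameter_um - 15) < 0.5))
  expect_true(all(mask$objects$mean_intensity_au == 10000))
})

test_that("objects outside the size window are discarded", {
  small <- disk_image(list(list(cx = 60, cy = 60, d = 8, value = 10000)))
  expect_identical(nrow(primary_mask(small, hct)$objects), 0L)
  # below detection threshold: invisible regardless of size
  dim_disk <- disk_image(list(list(cx = 60, cy = 60, d = 15, value = 6900)))
  expect_identical(nrow(primary_mask(dim_disk, hct)$objects), 0L)
})

test_that("interior holes are filled and intensity is measured where asked", {
  img <- disk_image(list(list(cx = 60, cy = 60, d = 16, value = 10000)))
  holey <- img$pixels
  holey[118:122, 118:122] <- 100  # dim interior, as in weakly stained centres
  mask <- primary_mask(image_plane(holey, 0.5), hct)
  expect_identical(nrow(mask$objects), 1L)
  expect_identical(mask$objects$area_px, sum(img$pixels > 0))  # hole filled
  # mean over the filled region includes the dim pixels
  expect_lt(mask$objects$mean_intensity_au, 10000)
})

test_that("translation moves centroids exactly and preserves counts and areas", {
  base <- disk_image(list(list(cx = 40, cy = 44, d = 14, value = 9000),
                          list(cx = 80, cy = 70, d = 18, value = 9000)))
  m1 <- primary_mask(base, hct)
  shifted <- matrix(0, 256, 256)
  shifted[(1:256) > 10, (1:256) > 10] <- base$pixels[1:246, 1:246]
  m2 <- primary_mask(image_plane(shifted, 0.5), hct)
  expect_identical(m1$objects$area_px, m2$objects$area_px)
  expect_equal(m2$objects$cx_um, m1$objects$cx_um + 10 * 0.5)
  expect_equal(m2$objects$cy_um, m1$objects$cy_um + 10 * 0.5)
})

test_that("raising the detection threshold never grows the foreground", {
  set.seed(5)
  px <- matrix(sample.int(20000, 96 * 96, replace = TRUE) + 0, 96, 96)
  thresholds <- c(2000, 5000, 9000, 15000)
  counts <- vapply(thresholds, function(t) sum(px >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mask reduction erodes by the stated radius and drops vanished objects", {
  img <- disk_image(list(list(cx = 60, cy = 60, d = 20, value = 10000)))
  mask <- primary_mask(img, hct)
  same <- reduce_mask(mask, 0, measure = img)
  expect_identical(same$objects$area_px, mask$objects$area_px)
  red <- reduce_mask(mask, 2, measure = img)
  expect_identical(nrow(red$objects), 1L)
  expect_identical(red$objects$label, mask$objects$label)
  expect_lt(abs(red$objects$equivalent_diameter_um - 16), 1)
  # a 3 um object eroded by 2 um vanishes
  tiny_params <- seg_params(1, 100, 7000, 10, 0.5, 5, 3000)
  tiny <- disk_image(list(list(cx = 60, cy = 60, d = 3, value = 10000)))
  tm <- primary_mask(tiny, tiny_params)
  expect_identical(nrow(tm$objects), 1L)
  expect_identical(nrow(reduce_mask(tm, 2, measure = tiny)$objects), 0L)
})

test_that("ring area matches the analytic annulus within a pixel perimeter", {
  r <- 8; w <- 10; psz <- 0.5
  img <- disk_image(list(list(cx = 64, cy = 64, d = 2 * r, value = 10000)))
  mask <- primary_mask(img, hct)
  rings <- secondary_mask(mask, w)
  ring_area_um2 <- sum(rings$labels > 0) * psz^2
  analytic <- pi * ((r + w)^2 - r^2)
  tol <- 2 * pi * (r + w) * psz  # one pixel of perimeter
  expect_lt(abs(ring_area_um2 - analytic), tol)
  expect_identical(sum(secondary_mask(mask, 0)$labels), 0L)  # width 0: no ring
})

test_that("contested ring pixels go to the nearer nucleus, ties to lower label", {
  psz <- 0.5
  img <- disk_image(list(list(cx = 50, cy = 64, d = 14, value = 10000),
                         list(cx = 69, cy = 64, d = 14, value = 10000)))
  mask <- primary_mask(img, hct)
  expect_identical(nrow(mask$objects), 2L)
  rings <- secondary_mask(mask, 10)
  # brute force: per non-primary pixel, nearest region by exhaustive distance
  L <- mask$labels
  reg1 <- which(L == 1L); reg2 <- which(L == 2L)
  nr <- nrow(L)
  rc <- function(idx) cbind(((idx - 1L) %% nr) + 1L, ((idx - 1L) %/% nr) + 1L)
  p1 <- rc(reg1); p2 <- rc(reg2)
  ring_px <- which(rings$labels > 0L)
  pr <- rc(ring_px)
  for (k in seq_along(ring_px)) {
    d1 <- sqrt(min((pr[k, 1] - p1[, 1])^2 + (pr[k, 2] - p1[, 2])^2))
    d2 <- sqrt(min((pr[k, 1] - p2[, 1])^2 + (pr[k, 2] - p2[, 2])^2))
    want <- if (d1 < d2) 1L else if (d2 < d1) 2L else 1L
    expect_identical(rings$labels[ring_px[k]], want)
  }
  # rings are disjoint from the primary mask by construction
  expect_true(all(L[ring_px] == 0L))
})

test_that("segmentation masks are pairwise disjoint on random synthetic fields", {
  for (seed in c(3, 17)) {
    rf <- render_field(small_spec(seed))
    fld <- segment_field(rf$image, hct, std_filters())
    overlap <- fld$mask$labels > 0L & fld$rings$labels > 0L
    expect_identical(sum(overlap), 0L)
  }
})
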