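# Fixture builders: hard-edged geometric fields built in code, where exact
# pixel counts are predictable. pixel-centre convention matches the package.

# draw filled disks onto a matrix; `disks` is a list of
# list(cx, cy, d, value) in micrometres / a.u.
disk_image <- function(disks, nrow_px = 256, ncol_px = 256, pixel_size_um = 0.5,
                       background = 0) {
  m <- matrix(background, nrow_px, ncol_px)
  xs <- (seq_len(ncol_px) - 0.5) * pixel_size_um
  ys <- (seq_len(nrow_px) - 0.5) * pixel_size_um
  for (dk in disks) {
    dx <- matrix(xs - dk$cx, nrow_px, ncol_px, byrow = TRUE)
    dy <- matrix(ys - dk$cy, nrow_px, ncol_px)
    inside <- dx^2 + dy^2 <= (dk$d / 2)^2
    m[inside] <- dk$value
  }
  image_plane(m, pixel_size_um)
}

# small noise-free synthetic spec for fast whole-pipeline tests
small_spec <- function(seed, n_nuclei = 8, noise_sd_au = 0, ...) {
  synthetic_spec(width_px = 256L, height_px = 256L, n_nuclei = n_nuclei,
                 n_edge_nuclei = 2L, n_bright_bodies = 1L,
                 mn_probability = 0.3, noise_sd_au = noise_sd_au,
                 seed = seed, ...)
}

std_filters <- function() filter_params(max_mean_intensity_au = 54000)

# compare pipeline field and reference checker: retained counts and the
# multisets of retained per-object pixel areas must agree exactly
expect_matches_reference <- function(image, params, filters) {
  fld <- segment_field(image, params, filters)
  ref <- reference_counts(image, params, filters)
  expect_identical(sum(fld$nuclei$retained), sum(ref$nuclei$retained))
  expect_identical(nrow(fld$nuclei), nrow(ref$nuclei))
  expect_identical(sort(fld$nuclei$area_px[fld$nuclei$retained]),
                   sort(ref$nuclei$area_px[ref$nuclei$retained]))
  expect_identical(sum(fld$spots$retained), sum(ref$spots$retained))
  expect_identical(sort(fld$spots$area_px[fld$spots$retained]),
                   sort(ref$spots$area_px[ref$spots$retained]))
  invisible(fld)
}
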