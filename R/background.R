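# Grayscale disc morphology, used for rolling-ball background flattening.
# Implemented as shift-based sliding min/max: a disc-shaped window is the
# union over row offsets dy of horizontal segments of half-width w(dy), and a
# 1-D sliding extremum over window length L is the combination of two
# overlapping power-of-two windows (doubling trick), giving O(log L) passes.

# sliding extremum over columns, window [j - w, j + w], `cmp` = pmin or pmax
.slide_cols <- function(m, w, cmp, pad) {
  if (w == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  L <- 2L * w + 1L
  # f(j) = extremum over columns [j, j + s - 1]
  f <- m
  s <- 1L
  while (2L * s <= L) {
    shifted <- cbind(f[, -seq_len(s), drop = FALSE],
                     matrix(pad, nr, min(s, nc)))
    f <- cmp(f, shifted)
    s <- 2L * s
  }
  rest <- L - s  # 0 <= rest < s
  start <- function(g, k) {
    # g evaluated at column j + k (k may be negative: pad on the left)
    if (k == 0L) return(g)
    if (k > 0L) cbind(g[, -seq_len(min(k, nc)), drop = FALSE],
                      matrix(pad, nr, min(k, nc)))
    else cbind(matrix(pad, nr, min(-k, nc)),
               g[, seq_len(max(nc + k, 0L)), drop = FALSE])
  }
  out <- start(f, -w)
  if (rest > 0L) out <- cmp(out, start(f, -w + rest))
  out
}

.shift_rows <- function(m, k, pad) {
  nr <- nrow(m); nc <- ncol(m)
  if (k == 0L) return(m)
  if (abs(k) >= nr) return(matrix(pad, nr, nc))
  if (k > 0L) rbind(m[-seq_len(k), , drop = FALSE], matrix(pad, k, nc))
  else rbind(matrix(pad, -k, nc), m[seq_len(nr + k), , drop = FALSE])
}

.disc_filter <- function(m, r, cmp, pad) {
  if (r == 0L) return(m)
  out <- NULL
  for (dy in -r:r) {
    w <- as.integer(floor(sqrt(r^2 - dy^2) + 1e-9))
    row_sh <- .shift_rows(m, dy, pad)
    h <- .slide_cols(row_sh, w, cmp, pad)
    out <- if (is.null(out)) h else cmp(out, h)
  }
  out
}

disc_erode_gray <- function(m, r) .disc_filter(m, as.integer(r), pmin, Inf)
disc_dilate_gray <- function(m, r) .disc_filter(m, as.integer(r), pmax, -Inf)

#' Rolling-ball background flattening
#'
#' Estimates the slowly varying background of a field by a grayscale opening
#' with a disc of the given radius (erosion then dilation — the standard
#' "rolling ball" construction) and subtracts it. Objects smaller than the
#' ball are removed from the background estimate and therefore preserved in
#' the output; the flat or ramped background itself is suppressed. The output
#' is everywhere non-negative and never exceeds the input.
#'
#' @param image An [image_plane()] object.
#' @param rolling_ball_radius_um Ball radius in micrometres (> 0); choose it
#'   comfortably larger than the largest object to preserve (in practice,
#'   larger than a nucleus diameter when flattening for the primary mask).
#' @return An [image_plane()] with the background removed.
#' @export
flatten_background <- function(image, rolling_ball_radius_um) {
  stopifnot(inherits(image, "mn_image"))
  if (!is.numeric(rolling_ball_radius_um) || length(rolling_ball_radius_um) != 1L ||
      rolling_ball_radius_um <= 0) {
    stop("rolling_ball_radius_um must be a single positive number", call. = FALSE)
  }
  r <- max(1L, as.integer(round(rolling_ball_radius_um / image$pixel_size_um)))
  bg <- disc_dilate_gray(disc_erode_gray(image$pixels, r), r)
  out <- pmax(image$pixels - bg, 0)
  image_plane(out, image$pixel_size_um, image$saturation_value)
}
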