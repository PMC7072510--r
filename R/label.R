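# Internal labeling and per-object measurement helpers.
#
# EBImage::bwlabel is 4-connectivity; the method requires 8-connectivity
# (Hoechst-stained nuclei are treated as solid objects and diagonal contact
# counts as contact), so labels are merged across diagonal adjacencies with a
# small union-find pass and renumbered deterministically.

label8 <- function(binary) {
  L <- EBImage::bwlabel(binary)
  L <- matrix(as.integer(L), nrow(binary), ncol(binary))
  nmax <- max(L)
  if (nmax == 0L) return(L)
  nr <- nrow(L); nc <- ncol(L)
  # diagonal neighbour label pairs (down-right and down-left)
  a1 <- L[-nr, -nc]; b1 <- L[-1, -1]
  a2 <- L[-nr, -1]; b2 <- L[-1, -nc]
  k1 <- a1 > 0L & b1 > 0L & a1 != b1
  k2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[k1], b1[k1]), cbind(a2[k2], b2[k2])))
  if (nrow(pairs)) {
    parent <- seq_len(nmax)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(nmax), find, integer(1))
    L[L > 0L] <- roots[L[L > 0L]]
  }
  relabel_compact(L)
}

# renumber labels 1..n in order of first occurrence (column-major scan),
# so labeling is deterministic and independent of intermediate label values
relabel_compact <- function(L) {
  pos <- which(L > 0L)
  if (!length(pos)) return(L)
  lab <- L[pos]
  first <- tapply(pos, lab, min)
  ord <- order(first)
  map <- integer(max(L))
  map[as.integer(names(first))[ord]] <- seq_along(ord)
  L[pos] <- map[lab]
  L
}

fill_holes <- function(labels) {
  F <- EBImage::fillHull(labels)
  matrix(as.integer(F), nrow(labels), ncol(labels))
}

# Per-object geometry and intensity, measured on `image` (raw a.u.).
# Coordinates use the pixel-centre convention: pixel (row = y, col = x) has
# centre ((x - 0.5) * psz, (y - 0.5) * psz) um from the image origin.
region_features <- function(labels, image, pixel_size_um) {
  pos <- which(labels > 0L)
  empty <- tibble::tibble(
    label = integer(), area_px = integer(), area_um2 = numeric(),
    equivalent_diameter_um = numeric(), cx_um = numeric(), cy_um = numeric(),
    mean_intensity_au = numeric(),
    xmin = integer(), xmax = integer(), ymin = integer(), ymax = integer()
  )
  if (!length(pos)) return(empty)
  lab <- labels[pos]
  nr <- nrow(labels)
  row <- ((pos - 1L) %% nr) + 1L   # y
  col <- ((pos - 1L) %/% nr) + 1L  # x
  f <- factor(lab)
  area_px <- as.integer(tabulate(f))
  val <- image[pos]
  g <- function(v, fun) as.numeric(tapply(v, f, fun))
  psz <- pixel_size_um
  area_um2 <- area_px * psz^2
  tibble::tibble(
    label = as.integer(levels(f)),
    area_px = area_px,
    area_um2 = area_um2,
    equivalent_diameter_um = 2 * sqrt(area_um2 / pi),
    cx_um = (g(col, mean) - 0.5) * psz,
    cy_um = (g(row, mean) - 0.5) * psz,
    mean_intensity_au = g(val, sum) / area_px,
    xmin = as.integer(g(col, min)), xmax = as.integer(g(col, max)),
    ymin = as.integer(g(row, min)), ymax = as.integer(g(row, max))
  )
}
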