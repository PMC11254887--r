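# Binary morphology on small 2-D masks (64x64 raw space, up to ~200x200
# report-panel space). Dilation/erosion use a Euclidean disc structuring
# element; connected components use vectorised frontier propagation, which is
# plenty fast at these grid sizes.

#' Binary dilation with a disc structuring element
#'
#' @param mask 0/1 integer matrix.
#' @param radius disc radius in pixels (Euclidean); `radius = 0` is the
#'   identity.
#' @return 0/1 integer matrix of the same size.
#' @export
mask_dilate <- function(mask, radius) {
  mask <- as_mask(mask)
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    acc <- acc | shift_mat(mask, off$dr[i], off$dc[i])
  }
  as_mask(acc * 1L)
}

#' Binary erosion with a disc structuring element
#' @inheritParams mask_dilate
#' @export
mask_erode <- function(mask, radius) {
  mask <- as_mask(mask)
  if (radius <= 0) return(mask)
  as_mask(1L - mask_dilate(1L - mask, radius))
}

#' Morphological closing (dilation then erosion)
#' @inheritParams mask_dilate
#' @export
mask_close <- function(mask, radius) {
  mask_erode(mask_dilate(mask, radius), radius)
}

# One step of 4- or 8-connected neighbourhood expansion.
neighbour_or <- function(mask, connectivity = 8L) {
  out <- shift_mat(mask, 1, 0) | shift_mat(mask, -1, 0) |
    shift_mat(mask, 0, 1) | shift_mat(mask, 0, -1)
  if (connectivity == 8L) {
    out <- out | shift_mat(mask, 1, 1) | shift_mat(mask, 1, -1) |
      shift_mat(mask, -1, 1) | shift_mat(mask, -1, -1)
  }
  (out | mask) * 1L
}

#' Label connected components of a binary mask
#'
#' @param mask 0/1 integer matrix.
#' @param connectivity 4 or 8 (default 8, conventional for small binary ROIs).
#' @return integer matrix of component labels (0 = background), with an
#'   attribute `sizes` giving pixel counts per label in label order.
#' @export
mask_components <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask == 1L & labels == 0L
  lab <- 0L
  sizes <- integer(0)
  while (any(remaining)) {
    lab <- lab + 1L
    seed_idx <- which(remaining)[1L]  # smallest linear (column-major) index
    comp <- matrix(0L, nrow(mask), ncol(mask))
    comp[seed_idx] <- 1L
    repeat {
      grown <- neighbour_or(comp, connectivity) & (mask == 1L)
      grown <- grown * 1L
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    labels[comp == 1L] <- lab
    sizes <- c(sizes, sum(comp))
    remaining <- mask == 1L & labels == 0L
  }
  attr(labels, "sizes") <- sizes
  labels
}

#' Fill interior holes of a binary mask
#'
#' Background is flood-filled from the image border with 4-connectivity (the
#' dual of 8-connected foreground); unreached background pixels are holes and
#' get set.
#' @param mask 0/1 integer matrix.
#' @return 0/1 integer matrix.
#' @export
mask_fill_holes <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- mask == 0L
  reach <- matrix(FALSE, nr, nc)
  reach[1, ] <- bg[1, ]; reach[nr, ] <- bg[nr, ]
  reach[, 1] <- bg[, 1]; reach[, nc] <- bg[, nc]
  # alternating directional sweeps converge in a few passes (vs one pixel per
  # iteration for frontier dilation)
  repeat {
    before <- sum(reach)
    for (i in 2:nr) reach[i, ] <- reach[i, ] | (reach[i - 1, ] & bg[i, ])
    for (i in (nr - 1):1) reach[i, ] <- reach[i, ] | (reach[i + 1, ] & bg[i, ])
    for (j in 2:nc) reach[, j] <- reach[, j] | (reach[, j - 1] & bg[, j])
    for (j in (nc - 1):1) reach[, j] <- reach[, j] | (reach[, j + 1] & bg[, j])
    if (sum(reach) == before) break
  }
  as_mask((mask == 1L | (bg & !reach)) * 1L)
}

# Inner boundary: mask pixels with a 4-neighbour outside the mask. Forms an
# 8-connected closed curve for a solid region.
mask_inner_boundary <- function(mask) {
  mask <- as_mask(mask)
  er <- mask & shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
    shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1)
  as_mask((mask - er * 1L))
}

# Centroid (row, col) of a mask in pixel coordinates.
mask_centroid <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid", call. = FALSE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Clockwise-from-image-up angle (degrees, [0, 360)) of pixels relative to a
# centre; image-up is decreasing row. 3 o'clock (image right) is 90 degrees.
clock_angle <- function(rows, cols, centre) {
  dr <- rows - centre[1]; dc <- cols - centre[2]
  (atan2(dc, -dr) * 180 / pi) %% 360
}
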