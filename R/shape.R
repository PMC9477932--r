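#' In-plane shape and size features
#'
#' Two-dimensional descriptors of the segmented slice region: area
#' (voxel count times in-plane voxel area, mm^2), perimeter (marching-
#' squares contour length at the 0.5 iso-level, mm), circularity
#' `4 pi A / P^2` (1 for a perfect disk), and maximum in-plane diameter
#' (largest pairwise distance between member voxel centers, mm; 0 for a
#' single voxel).
#'
#' @param seg a [autocontour_lesion()] result (or any object with an
#'   `voxels` matrix whose first two columns are in-slice indices).
#' @param spacing in-plane voxel spacing in mm, length 2.
#' @return Named numeric vector.
#' @export
shape_features <- function(seg, spacing = c(1, 1)) {
  vox <- seg$voxels[, 1:2, drop = FALSE]
  n <- nrow(vox)
  if (n == 0L) stop("empty segmentation")
  dx <- spacing[1]; dy <- spacing[2]
  area <- n * dx * dy
  mask <- matrix(FALSE, max(vox[, 1]) - min(vox[, 1]) + 3L,
                 max(vox[, 2]) - min(vox[, 2]) + 3L)
  mask[cbind(vox[, 1] - min(vox[, 1]) + 2L,
             vox[, 2] - min(vox[, 2]) + 2L)] <- TRUE
  per <- marching_squares_perimeter(mask, dx, dy)
  circ <- if (per > 0) 4 * pi * area / per^2 else 1
  # max pairwise distance between voxel centers
  xy <- cbind(vox[, 1] * dx, vox[, 2] * dy)
  dmax <- if (n == 1L) 0 else max(stats::dist(xy))
  c(shape_area = area, shape_perimeter = per,
    shape_circularity = circ, shape_max_diameter = dmax)
}

# Contour length of the 0.5 iso-level of a padded binary mask, by the
# marching-squares case table with edge-midpoint interpolation.
marching_squares_perimeter <- function(mask, dx, dy) {
  nr <- nrow(mask); nc <- ncol(mask)
  a <- mask[-nr, -nc] # top-left of each 2x2 cell
  b <- mask[-nr, -1]  # top-right
  c_ <- mask[-1, -nc] # bottom-left
  d <- mask[-1, -1]   # bottom-right
  code <- a + 2 * b + 4 * c_ + 8 * d
  diag_len <- sqrt((dx / 2)^2 + (dy / 2)^2)
  # segment length per marching-squares case (cases 6 and 9 are saddles:
  # two corner cuts)
  len <- c(0,                      # 0: empty
           diag_len, diag_len,     # 1, 2: single corner
           dy,                     # 3: a,b in -> cut runs along j
           diag_len,               # 4
           dx,                     # 5: a,c in -> cut runs along i
           2 * diag_len,           # 6: saddle b,c
           diag_len,               # 7: three in
           diag_len,               # 8
           2 * diag_len,           # 9: saddle a,d
           dx,                     # 10: b,d in
           diag_len,               # 11
           dy,                     # 12: c,d in
           diag_len, diag_len,     # 13, 14
           0)                      # 15: full
  sum(len[code + 1])
}
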