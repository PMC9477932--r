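#' Fractal features
#'
#' Two box-counting estimates on the segmented slice:
#'
#' * `fractal_boundary_dim`: box-counting dimension of the lesion
#'   boundary (mask voxels with at least one 4-neighbor outside).  Boxes
#'   of dyadic side lengths tile the bounding square; the dimension is the
#'   least-squares slope of `log N(eps)` against `log(1/eps)`.  A smooth
#'   closed contour gives values near 1.
#' * `fractal_dbc_dim`: differential box-counting dimension of the
#'   intensity surface.  Intensities are scaled to the patch side length;
#'   each s x s box contributes the number of height cells its local
#'   min-max range spans.  A constant surface gives values near 2, rough
#'   surfaces push toward 3.
#'
#' Degenerate regions (fewer than 4 boundary pixels, or fewer than two
#' usable scales) fall back to the smooth-limit values 1 and 2.
#'
#' @param droi a [discretize()] result (mask and intensity surface are
#'   taken from it).
#' @return Named numeric vector.
#' @export
fractal_features <- function(droi) {
  if (!inherits(droi, "discretized_roi")) stop("need a discretized_roi")
  mask <- !is.na(droi$levels)
  c(fractal_boundary_dim = boundary_boxcount_dim(mask),
    fractal_dbc_dim = dbc_dimension(droi$tbr))
}

# Least-squares slope without the lm() machinery.
ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

# Boundary pixels: in-mask with a 4-neighbor outside (or on matrix edge).
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1), drop = FALSE]
  up <- pad[1:nr, 2:(nc + 1), drop = FALSE]
  dn <- pad[3:(nr + 2), 2:(nc + 1), drop = FALSE]
  lf <- pad[2:(nr + 1), 1:nc, drop = FALSE]
  rt <- pad[2:(nr + 1), 3:(nc + 2), drop = FALSE]
  core & !(up & dn & lf & rt)
}

boundary_boxcount_dim <- function(mask) {
  bp <- which(boundary_pixels(mask), arr.ind = TRUE)
  if (nrow(bp) < 4L) return(1)
  side <- max(max(bp[, 1]) - min(bp[, 1]), max(bp[, 2]) - min(bp[, 2])) + 1L
  b1 <- bp[, 1] - min(bp[, 1])
  b2 <- bp[, 2] - min(bp[, 2])
  # boxes wider than a quarter of the extent are dominated by the region's
  # gross size and bias the slope; keep eps <= side/4
  eps <- 2^(0:max(0, floor(log2(side))))
  eps <- unique(c(1, eps[eps <= side / 4]))
  if (length(eps) < 2L) return(1)
  n_boxes <- vapply(eps, function(e) {
    length(unique((b1 %/% e) * 1e6 + (b2 %/% e)))
  }, numeric(1))
  -ls_slope(log(eps), log(n_boxes))
}

# Pairwise dyadic reduction of rows then columns (side must be even).
halve <- function(z, f) {
  odd <- seq(1, nrow(z), by = 2)
  z <- f(z[odd, , drop = FALSE], z[odd + 1, , drop = FALSE])
  odd <- seq(1, ncol(z), by = 2)
  f(z[, odd, drop = FALSE], z[, odd + 1, drop = FALSE])
}

# Differential box counting on an intensity patch; NA cells (outside the
# ROI) are filled with the ROI mean so they contribute flat background.
# The patch is embedded in a dyadic square so that block maxima/minima at
# every scale come from chained pairwise reductions.
dbc_dimension <- function(surface) {
  vals <- surface[!is.na(surface)]
  rng <- diff(range(vals))
  if (rng < 1e-12) return(2)
  side <- 2^ceiling(log2(max(dim(surface), 4)))
  sq <- matrix(mean(vals), side, side)
  m <- surface
  m[is.na(m)] <- mean(vals)
  sq[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  z <- (sq - min(vals)) / rng * side # height in box units at scale 1
  k_max <- floor(log2(side / 2))
  if (k_max < 2L) return(2)
  zmax <- z; zmin <- z
  sizes <- numeric(0); counts <- numeric(0)
  for (k in seq_len(k_max)) {
    zmax <- halve(zmax, pmax)
    zmin <- halve(zmin, pmin)
    s <- 2^k # box height in intensity cells equals the box side
    sizes <- c(sizes, s)
    counts <- c(counts, sum(floor(zmax / s) - floor(zmin / s) + 1))
  }
  -ls_slope(log(sizes), log(counts))
}
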