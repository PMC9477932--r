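#' Discretize lesion intensities to gray levels
#'
#' Converts lesion SUVs to tumor-to-brain ratios (`SUV / background`) and
#' bins them with a fixed absolute bin width anchored at 0: a TBR value
#' `t` maps to gray level `floor(t / w) + 1`, so level g covers
#' `[(g-1) w, g w)`.  No min-anchoring relabel is applied and no spatial
#' resampling is performed, which keeps bins comparable across subjects.
#' A min-anchored variant (level 1 = lowest occupied bin) is available via
#' `anchor = "min"` for compatibility with relative resampling schemes.
#'
#' The result carries the gray levels laid out in their in-slice positions
#' (bounding-box matrix with `NA` outside the lesion), which is the form
#' the texture-matrix builders consume.
#'
#' @param values lesion voxel SUVs (or already-ratioed values when
#'   `background = 1`).
#' @param background mean SUV of healthy brain (> 0).
#' @param bin_width bin width in TBR units; default 0.1.
#' @param coords optional n x 2 integer matrix of in-slice voxel (row,
#'   col) indices; if omitted the ROI is treated as a 1 x n strip.
#' @param spacing in-plane voxel spacing in mm, length 2.
#' @param anchor `"zero"` (absolute binning, default) or `"min"`.
#'
#' @return An object of class `discretized_roi`: `levels` (integer matrix,
#'   `NA` outside the ROI), `tbr` (per-voxel TBR in matrix order),
#'   `n_g` (maximum level present), `bin_width`, `anchor`, `spacing`.
#' @export
discretize <- function(values, background = 1, bin_width = 0.1,
                       coords = NULL, spacing = c(1, 1),
                       anchor = c("zero", "min")) {
  anchor <- match.arg(anchor)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive width")
  if (background <= 0) stop("`background` must be positive")
  if (length(values) == 0L) stop("empty lesion: nothing to discretize")
  tbr <- values / background
  # tiny epsilon so exact bin edges (e.g. TBR 1.6 at width 0.1) land in the
  # bin they open despite floating-point division error
  lev <- floor(tbr / bin_width + 1e-9) + 1L
  if (anchor == "min") lev <- lev - min(lev) + 1L
  if (is.null(coords)) coords <- cbind(1L, seq_along(values))
  coords <- cbind(coords[, 1] - min(coords[, 1]) + 1L,
                  coords[, 2] - min(coords[, 2]) + 1L)
  m <- matrix(NA_integer_, max(coords[, 1]), max(coords[, 2]))
  m[coords] <- as.integer(lev)
  tb <- matrix(NA_real_, nrow(m), ncol(m))
  tb[coords] <- tbr
  structure(list(levels = m, tbr = tb, n_g = max(lev),
                 bin_width = bin_width, anchor = anchor,
                 spacing = as.numeric(spacing[1:2])),
            class = "discretized_roi")
}

# Discretized ROI from arbitrary real values (e.g. wavelet coefficients)
# using a fixed number of equal-width bins over the occupied range.
discretize_fixed_bins <- function(m, n_bins = 16L) {
  vals <- m[!is.na(m)]
  rng <- range(vals)
  if (diff(rng) < 1e-12) {
    lev <- m
    lev[!is.na(m)] <- 1L
  } else {
    w <- diff(rng) / n_bins
    lev <- floor((m - rng[1]) / w) + 1L
    lev[lev > n_bins] <- n_bins # right edge closed
  }
  structure(list(levels = matrix(as.integer(lev), nrow(m), ncol(m)),
                 tbr = m, n_g = max(lev, na.rm = TRUE),
                 bin_width = NA_real_, anchor = "range",
                 spacing = c(1, 1)),
            class = "discretized_roi")
}

# Build a discretized ROI directly from a segmentation + volume.
discretize_segmentation <- function(volume, seg, background,
                                    bin_width = 0.1, anchor = "zero") {
  vals <- volume$data[seg$voxels]
  discretize(vals, background = background, bin_width = bin_width,
             coords = seg$voxels[, 1:2, drop = FALSE],
             spacing = volume$spacing[1:2], anchor = anchor)
}
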