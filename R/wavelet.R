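#' One-level 2D discrete wavelet transform
#'
#' Separable single-level DWT of an image patch with the 6-tap Daubechies
#' orthogonal wavelet (db3), using symmetric (half-sample) boundary
#' extension so that a constant patch produces exactly zero detail
#' coefficients.  Returns the four sub-bands; the first letter of a band
#' name is the filter applied along rows (first index), the second along
#' columns.
#'
#' @param patch numeric matrix (no `NA`s).
#' @return List with matrices `LL`, `LH`, `HL`, `HH`.
#' @export
dwt2 <- function(patch) {
  if (any(is.na(patch))) stop("patch must not contain NA")
  h <- db3_lowpass
  g <- db3_highpass
  # filter along rows (all columns at once), then along columns
  lo_r <- dwt_cols(patch, h)
  hi_r <- dwt_cols(patch, g)
  list(LL = t(dwt_cols(t(lo_r), h)),
       LH = t(dwt_cols(t(lo_r), g)),
       HL = t(dwt_cols(t(hi_r), h)),
       HH = t(dwt_cols(t(hi_r), g)))
}

# One analysis step down every column of a matrix: symmetric extension,
# convolution, dyadic downsampling.
dwt_cols <- function(m, filt) {
  n <- nrow(m)
  L <- length(filt)
  if (n < L - 1) # tiny patches: per-column fallback with re-reflection
    return(vapply(seq_len(ncol(m)), function(j) dwt_step(m[, j], filt),
                  numeric(floor((n + L - 1) / 2))))
  ext <- rbind(m[(L - 1):1, , drop = FALSE], m,
               m[n:(n - L + 2), , drop = FALSE])
  nv <- n + L - 1
  y <- matrix(0, nv, ncol(m))
  for (t in seq_len(L))
    y <- y + filt[t] * ext[t:(t + nv - 1), , drop = FALSE]
  y[seq(2, nv, by = 2), , drop = FALSE]
}

# Daubechies db3 analysis filters (6 taps, orthonormal; lowpass sums to
# sqrt(2) so the LL gain on a constant is 2 after both passes).
db3_lowpass <- c(0.03522629188570953, -0.08544127388202666,
                 -0.13501102001025458, 0.45987750211849154,
                 0.8068915093110925, 0.33267055295008263)
db3_highpass <- c(-0.33267055295008263, 0.8068915093110925,
                  -0.45987750211849154, -0.13501102001025458,
                  0.08544127388202666, 0.03522629188570953)

# One analysis step: symmetric extension, convolve, downsample by 2.
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  ext <- c(rev(x[seq_len(min(L - 1, n))]),
           x,
           x[seq.int(n, by = -1, length.out = min(L - 1, n))])
  while (length(ext) < n + 2 * (L - 1)) # tiny signals: re-reflect
    ext <- c(rev(ext[seq_len(min(L - 1, length(ext)))]), ext)
  y <- stats::filter(ext, rev(filt), method = "convolution", sides = 1)
  y <- y[!is.na(y)]
  y[seq(2, length(y), by = 2)]
}

#' Wavelet-domain features
#'
#' Decomposes the in-slice patch around the lesion with a one-level 2D
#' DWT and re-extracts first-order, texture (GLCM/GLRLM/GLSZM) and fractal
#' features per sub-band, restricted to the downsampled lesion mask (a
#' sub-band cell is in-mask when any voxel of its 2 x 2 block is).
#' Sub-band coefficients have no absolute intensity scale, so they are
#' discretized into a fixed number of equal-width bins over their occupied
#' range rather than with the absolute TBR bin width.
#'
#' @param patch numeric matrix: the TBR-scaled slice values over the
#'   lesion bounding box (background context included).
#' @param mask logical matrix of the same size marking lesion voxels.
#' @param n_bins bins for coefficient discretization; default 16.
#' @return Named numeric vector; names carry the sub-band suffix, e.g.
#'   `wav_LH_fo_mean`.
#' @export
wavelet_features <- function(patch, mask, n_bins = 16L) {
  stopifnot(identical(dim(patch), dim(mask)))
  bands <- dwt2(patch)
  out <- numeric(0)
  for (bn in names(bands)) {
    b <- bands[[bn]]
    dm <- downsample_mask(mask, dim(b))
    if (!any(dm)) next
    bm <- b
    bm[!dm] <- NA_real_
    droi <- discretize_fixed_bins(bm, n_bins = n_bins)
    vals <- bm[!is.na(bm)]
    fo <- first_order_features(vals, droi)
    fr <- fractal_features(droi)["fractal_dbc_dim"]
    tex <- texture_feature_block(droi)
    block <- c(fo, fr, tex)
    names(block) <- paste0("wav_", bn, "_", names(block))
    out <- c(out, block)
  }
  out
}

# Map the lesion mask onto a sub-band grid: a coefficient is in-mask when
# any voxel of the 2x2 block it (approximately, given the filter delay)
# summarizes is in-mask.  Indices are clamped at the patch border, so edge
# coefficients inherit the nearest block.
downsample_mask <- function(mask, out_dim, offset = 2L) {
  nr <- nrow(mask); nc <- ncol(mask)
  r1 <- pmin(pmax(2L * seq_len(out_dim[1]) - 1L - offset, 1L), nr)
  r2 <- pmin(pmax(2L * seq_len(out_dim[1]) - offset, 1L), nr)
  c1 <- pmin(pmax(2L * seq_len(out_dim[2]) - 1L - offset, 1L), nc)
  c2 <- pmin(pmax(2L * seq_len(out_dim[2]) - offset, 1L), nc)
  mask[r1, c1, drop = FALSE] | mask[r1, c2, drop = FALSE] |
    mask[r2, c1, drop = FALSE] | mask[r2, c2, drop = FALSE]
}

# All three texture families on one discretized ROI, with degenerate
# fallbacks when the ROI is a single voxel.
texture_feature_block <- function(droi) {
  if (sum(!is.na(droi$levels)) >= 2L) {
    glcm <- glcm_features(compute_glcm(droi))
  } else {
    glcm <- stats::setNames(rep(0, length(glcm_feature_names)),
                            glcm_feature_names)
    glcm[["glcm_energy"]] <- 1
    glcm[["glcm_homogeneity"]] <- 1
  }
  c(glcm,
    glrlm_features(compute_glrlm(droi)),
    glszm_features(compute_glszm(droi)))
}
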