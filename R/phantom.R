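#' Phantom specification
#'
#' Describes a single synthetic FET PET volume: a brain-like uniform
#' background with additive voxel noise, plus one ellipsoidal lesion whose
#' noise-free tumor-to-brain ratio (TBR) profile is shaped so that its
#' maximum equals `tbr_max` and its mean over the detectable lesion
#' (TBR >= 1.6) approximates `tbr_mean`.  Intra-lesion heterogeneity is a
#' Gaussian random field (smoothed white noise with the stated correlation
#' length) added inside the lesion; its amplitude is what separates
#' texturally heterogeneous lesions (tumor progression) from homogeneous
#' ones (treatment-related changes).
#'
#' Volumes are generated directly in SUV units; injected dose and body
#' weight play no role here (SUV conversion is exercised separately by
#' [compute_suv()]).
#'
#' @param shape integer length-3 grid size in voxels.
#' @param spacing voxel spacing in mm, length 3.
#' @param bg_mean mean background uptake (SUV).
#' @param noise_sd SD of additive white voxel noise (SUV).
#' @param center lesion center in mm (grid coordinates, voxel i spans
#'   `[(i-1), i] * spacing`); default left-of-midline, mid-grid.
#' @param semi_axes lesion ellipsoid semi-axes in mm.
#' @param label class label, `"TP"` (tumor progression) or `"TRC"`
#'   (treatment-related changes).
#' @param tbr_max,tbr_mean target noise-free TBR maximum and mean
#'   (dimensionless, `tbr_max >= tbr_mean >= 1.6`).
#' @param texture_amp SD of the intra-lesion texture field (SUV); 0 gives
#'   a smooth radially symmetric lesion.
#' @param texture_corr_mm correlation length of the texture field (mm).
#' @param seed integer seed; fully determines the phantom.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 24L),
                         spacing = c(2, 2, 2),
                         bg_mean = 1.0,
                         noise_sd = 0.05,
                         center = NULL,
                         semi_axes = c(16, 14, 12),
                         label = c("TP", "TRC"),
                         tbr_max = 3.7,
                         tbr_mean = 2.1,
                         texture_amp = 0,
                         texture_corr_mm = 8,
                         seed = 1L) {
  label <- match.arg(label)
  shape <- as.integer(shape)
  extent <- shape * spacing
  if (is.null(center)) center <- extent * c(0.3, 0.5, 0.5)
  if (any(center - semi_axes < 0) || any(center + semi_axes > extent))
    stop("lesion ellipsoid does not fit inside the grid")
  if (tbr_max < tbr_mean)
    stop("tbr_max must be >= tbr_mean")
  if (tbr_mean < 1.6)
    stop("a detectable lesion requires tbr_mean >= 1.6")
  if (bg_mean <= 0) stop("bg_mean must be positive")
  if (noise_sd < 0 || texture_amp < 0) stop("noise/texture SDs must be >= 0")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 bg_mean = bg_mean, noise_sd = noise_sd,
                 center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), label = label,
                 tbr_max = tbr_max, tbr_mean = tbr_mean,
                 texture_amp = texture_amp,
                 texture_corr_mm = texture_corr_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume with truth masks
#'
#' Builds the noise-free lesion first: a power-law radial TBR profile
#' (exponent calibrated per lesion) plus the texture field, affinely
#' rescaled so that the hottest voxel attains exactly `tbr_max` and the
#' mean over the hottest transversal slice matches `tbr_mean` -- the two
#' quantities the downstream 2D auto-contour measures.
#' White measurement noise is then added everywhere.  The truth lesion
#' mask marks the voxels whose noise-free TBR is >= 1.6; the background
#' ROI is an ellipsoid mirrored through the mid-sagittal plane of the
#' grid, emulating a reference region in the semioval center of the
#' unaffected hemisphere.
#'
#' @param spec a [phantom_spec()].
#'
#' @return A list with elements `volume` (a [pet_volume()] in SUV),
#'   `lesion_mask` and `background_roi` (0/1 arrays on the same grid),
#'   `label`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  ell <- ellipsoid_r2(d, sp, spec$center, spec$semi_axes)
  inside <- ell$mask
  if (!any(inside)) stop("lesion ellipsoid contains no voxel centers")
  u <- 1 - ell$r2_inside # 0 at rim, 1 at center

  # texture field: smoothed white noise, standardized inside the lesion;
  # computed on the lesion bounding box (plus kernel support) only
  g <- numeric(sum(inside))
  if (spec$texture_amp > 0 && sum(inside) > 1) {
    ii <- which(inside, arr.ind = TRUE)
    pad <- ceiling(2.5 * spec$texture_corr_mm / min(sp)) + 1L
    lo <- pmax(apply(ii, 2, min) - pad, 1L)
    hi <- pmin(apply(ii, 2, max) + pad, d)
    sub <- lapply(1:3, function(a) lo[a]:hi[a])
    wn <- array(stats::rnorm(prod(hi - lo + 1L)), dim = hi - lo + 1L)
    for (ax in 1:3)
      wn <- convolve_axis_gauss(wn, ax, spec$texture_corr_mm / sp[ax],
                                trunc_sigmas = 2.5)
    sm <- array(0, dim = d)
    sm[sub[[1]], sub[[2]], sub[[3]]] <- wn
    gv <- sm[inside]
    g <- (gv - mean(gv)) / stats::sd(gv)
  }
  amp_tbr <- spec$texture_amp / spec$bg_mean

  # power-law radial TBR profile u^p, with p calibrated on the hottest
  # transversal slice so that the slice mean and maximum match the targets
  # (the quantities the 2D auto-contour measures); the texture field is
  # added and the affine pinning of (mean, max) re-applied
  slice_k <- which(inside, arr.ind = TRUE)[, 3]
  in_max_slice <- slice_k == slice_k[which.max(u)]
  tbr <- shape_lesion_tbr(u, g * amp_tbr, spec$tbr_mean, spec$tbr_max,
                          in_max_slice)

  vol <- array(spec$bg_mean, dim = d)
  vol[inside] <- tbr * spec$bg_mean
  truth <- array(0L, dim = d)
  truth[inside] <- as.integer(tbr >= 1.6 - 1e-9)

  if (spec$noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)

  roi <- background_roi_mask(d, sp, spec$center, roi_semi_axes = c(6, 6, 6))
  if (any(roi == 1 & inside))
    stop("background ROI overlaps the lesion; move the lesion off-midline")

  list(volume = pet_volume(vol, spacing = sp, units = "SUV"),
       lesion_mask = truth, background_roi = roi,
       label = spec$label, spec = spec)
}

# Shape the lesion's noise-free TBR values.  u in [0, 1] is the normalized
# centrality (0 at the rim), tex the (already amplitude-scaled) texture
# field, ref the voxels of the hottest transversal slice.  The radial
# profile u^p is calibrated by uniroot so that the slice mean of
# 1.6 + (tbr_max - 1.6) * u^p equals tbr_mean; after adding texture an
# affine map re-pins (slice mean, global max) to the targets exactly.
shape_lesion_tbr <- function(u, tex, tbr_mean, tbr_max, ref) {
  n <- length(u)
  if (tbr_max == tbr_mean) return(rep(tbr_mean, n))
  eps <- (tbr_mean - 1.6) / (tbr_max - 1.6)
  if (eps > 0.9) {
    # near-flat lesion: plateau at tbr_mean with the hottest voxel bumped
    v <- rep(tbr_mean, n) + tex
    v <- v - (mean(v[ref]) - tbr_mean) # re-center the slice mean
    v[which.max(u)] <- tbr_max
    return(pmax(pmin(v, tbr_max), 0.01))
  }
  uh <- u / max(u) # hottest voxel sits exactly at profile value 1
  us <- uh[ref]
  f_gap <- function(lp) mean(us^exp(lp)) - eps
  lp <- tryCatch(stats::uniroot(f_gap, c(log(0.05), log(50)))$root,
                 error = function(e) 0) # fall back to a linear profile
  raw <- 1.6 + (tbr_max - 1.6) * uh^exp(lp)
  if (any(tex != 0)) {
    # texture re-centered on the reference slice, then (mean, max)
    # re-pinned; textured rims may dip below the detectability threshold
    raw <- raw + tex - mean(tex[ref])
    mu <- mean(raw[ref]); mx <- max(raw)
    if (mx - mu < 1e-9) return(rep(tbr_mean, n))
    a <- (tbr_max - tbr_mean) / (mx - mu)
    raw <- a * raw + (tbr_mean - a * mu)
  }
  pmax(raw, 0.01) # keep SUVs physical
}

# Voxel mask and squared normalized radius of an ellipsoid, computed on
# its bounding box only.
ellipsoid_r2 <- function(shape, spacing, center, semi_axes) {
  lo <- pmax(floor((center - semi_axes) / spacing), 1)
  hi <- pmin(ceiling((center + semi_axes) / spacing) + 1, shape)
  ax <- lapply(1:3, function(a) {
    x <- (lo[a]:hi[a] - 0.5) * spacing[a]
    ((x - center[a]) / semi_axes[a])^2
  })
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  mask <- array(FALSE, dim = shape)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub[] <- r2 <= 1
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  list(mask = mask, r2_inside = r2[r2 <= 1])
}

# Ellipsoidal background reference region mirrored through the grid's
# mid-sagittal (first-axis) plane relative to the lesion center.
background_roi_mask <- function(shape, spacing, lesion_center_mm,
                                roi_semi_axes = c(6, 6, 6)) {
  extent <- shape * spacing
  ctr <- lesion_center_mm
  ctr[1] <- extent[1] - ctr[1] # mirror left-right
  ell <- ellipsoid_r2(shape, spacing, ctr, roi_semi_axes)
  out <- array(0L, dim = shape)
  out[ell$mask] <- 1L
  out
}
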