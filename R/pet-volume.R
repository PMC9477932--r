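#' PET volume container
#'
#' A `pet_volume` wraps a 3D numeric array together with its voxel spacing
#' and an intensity-unit flag.  Voxel values are either activity
#' concentration in kBq/ml (as reconstructed) or standardized uptake values
#' (SUV).  Tumor-to-brain ratios may only be computed from SUV (or any
#' other quantity proportional to activity per unit mass, since the TBR is
#' a ratio of voxel values within one volume).
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing numeric length-3, voxel edge length in mm per axis (> 0).
#' @param units intensity unit flag, `"kBq/ml"` or `"SUV"`.
#'
#' @return An object of class `pet_volume` with elements `data`, `spacing`
#'   and `units`.
#' @export
pet_volume <- function(data, spacing = c(1, 1, 1), units = c("SUV", "kBq/ml")) {
  units <- match.arg(units)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing, units = units),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              x$units))
  invisible(x)
}

#' Subject metadata for SUV conversion
#'
#' @param injected_mbq injected tracer activity in MBq (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @param label optional binary class label (1 = tumor progression,
#'   0 = treatment-related changes).
#'
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(injected_mbq, weight_kg, label = NA) {
  if (!is.numeric(injected_mbq) || length(injected_mbq) != 1L ||
      !is.finite(injected_mbq) || injected_mbq <= 0)
    stop("`injected_mbq` must be a single positive number")
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L ||
      !is.finite(weight_kg) || weight_kg <= 0)
    stop("`weight_kg` must be a single positive number")
  structure(list(injected_mbq = injected_mbq, weight_kg = weight_kg,
                 label = label), class = "subject_meta")
}

#' Convert an activity-concentration volume to SUV
#'
#' SUV is the tissue radioactivity concentration (kBq/ml) divided by the
#' injected radioactivity per gram of body weight.  With an injected
#' activity A (MBq) and a body weight W (kg), the denominator is
#' `A * 1000 kBq / (W * 1000 g) = A / W` kBq/g, so
#' `SUV = tissue_kBq_per_ml * W_kg / A_MBq` (taking 1 g of tissue per ml).
#'
#' Applying the conversion to a volume already flagged as SUV is an error:
#' a double conversion would silently corrupt every downstream TBR.
#'
#' @param volume a [pet_volume()] in kBq/ml.
#' @param meta a [subject_meta()].
#'
#' @return A [pet_volume()] in SUV on the same grid.
#' @export
compute_suv <- function(volume, meta) {
  stopifnot(inherits(volume, "pet_volume"), inherits(meta, "subject_meta"))
  if (volume$units == "SUV")
    stop("volume is already in SUV; refusing to convert twice")
  injected_kbq <- meta$injected_mbq * 1000
  body_grams <- meta$weight_kg * 1000
  suv <- volume$data / (injected_kbq / body_grams)
  pet_volume(suv, spacing = volume$spacing, units = "SUV")
}

#' Gaussian harmonization filter
#'
#' Smooths a volume with an isotropic 3D Gaussian kernel of the given
#' physical size, as used to harmonize a high-resolution scanner with a
#' lower-resolution one before quantification.  The kernel size is quoted
#' as full width at half maximum (FWHM) by default, the convention for PET
#' harmonization filters (`sigma = fwhm / (2 * sqrt(2 * log(2)))` per
#' axis, divided by the voxel spacing); set `interpretation = "sigma"` to
#' read the size as the Gaussian standard deviation instead.
#'
#' The filter is applied separably along each axis with zero padding, so
#' total intensity is conserved up to boundary losses.
#'
#' @param volume a [pet_volume()].
#' @param size_mm kernel size in mm (> 0); default 2.5.
#' @param interpretation `"fwhm"` (default) or `"sigma"`.
#'
#' @return The smoothed [pet_volume()].
#' @export
harmonize <- function(volume, size_mm = 2.5,
                      interpretation = c("fwhm", "sigma")) {
  stopifnot(inherits(volume, "pet_volume"))
  interpretation <- match.arg(interpretation)
  if (!is.numeric(size_mm) || length(size_mm) != 1L || !is.finite(size_mm) ||
      size_mm <= 0)
    stop("`size_mm` must be a single positive kernel size in mm")
  sigma_mm <- if (interpretation == "fwhm")
    size_mm / (2 * sqrt(2 * log(2))) else size_mm
  out <- volume$data
  wt <- array(1, dim = dim(out)) # normalized convolution at the boundary
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / volume$spacing[ax]
    out <- convolve_axis_gauss(out, ax, sigma_vox)
    wt <- convolve_axis_gauss(wt, ax, sigma_vox)
  }
  pet_volume(out / wt, spacing = volume$spacing, units = volume$units)
}

# Separable 1D Gaussian convolution along one axis of a 3D array,
# zero-padded.  Kernel truncated at 4 sigma and renormalized to sum 1 so a
# constant volume maps to itself away from the boundary.
convolve_axis_gauss <- function(arr, axis, sigma_vox, trunc_sigmas = 4) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(trunc_sigmas * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  n <- dim(arr)[axis]
  # move target axis first, convolve columns, move back
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, nrow = d[1], ncol = ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
  }
  a <- array(out, dim = d)
  aperm(a, order(perm))
}

#' Mean uptake over a background region of interest
#'
#' The reference value for TBR computation: the arithmetic mean SUV over a
#' region placed in healthy brain tissue of the unaffected hemisphere.
#'
#' @param volume a [pet_volume()] in SUV.
#' @param roi logical or 0/1 array on the same grid, or a matrix of voxel
#'   indices (one row per voxel).
#'
#' @return The mean SUV over the ROI (a single positive number for any
#'   physically meaningful background).
#' @export
background_mean <- function(volume, roi) {
  stopifnot(inherits(volume, "pet_volume"))
  vals <- roi_values(volume$data, roi)
  if (length(vals) == 0L) stop("background ROI is empty")
  mean(vals)
}

roi_values <- function(data, roi) {
  if (is.matrix(roi) && !is.logical(roi) && ncol(roi) == 3L &&
      !identical(dim(roi), dim(data))) {
    return(data[roi])
  }
  roi <- as.array(roi)
  if (!identical(dim(roi), dim(data)))
    stop("ROI grid does not match the volume grid")
  data[roi != 0]
}
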