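#' Extraction configuration
#'
#' @param bin_width absolute discretization bin width in TBR units.
#' @param families feature families to compute; any subset of
#'   `"fractal"`, `"first_order"`, `"shape"`, `"texture"`, `"wavelet"`.
#' @param glcm_distance GLCM offset distance in voxels.
#' @param wavelet_bins fixed bin count for sub-band coefficient
#'   discretization.
#' @param patch_pad context voxels added around the lesion bounding box
#'   before the wavelet transform.
#' @param anchor discretization anchoring, `"zero"` (absolute) or `"min"`.
#' @return A list of class `extract_config`.
#' @export
extract_config <- function(bin_width = 0.1,
                           families = c("fractal", "first_order", "shape",
                                        "texture", "wavelet"),
                           glcm_distance = 1L,
                           wavelet_bins = 16L,
                           patch_pad = 2L,
                           anchor = "zero") {
  families <- match.arg(families,
                        c("fractal", "first_order", "shape", "texture",
                          "wavelet"),
                        several.ok = TRUE)
  structure(list(bin_width = bin_width, families = families,
                 glcm_distance = as.integer(glcm_distance),
                 wavelet_bins = as.integer(wavelet_bins),
                 patch_pad = as.integer(patch_pad), anchor = anchor),
            class = "extract_config")
}

#' Extract the full radiomics feature vector for one lesion
#'
#' Runs discretization and the five feature families on the segmented
#' slice: fractal, first-order, shape/size, gray-level texture
#' (GLCM/GLRLM/GLSZM), and the wavelet pass (fractal, first-order and
#' texture features re-extracted on each sub-band of a one-level 2D DWT
#' of the lesion patch).  All intensity-domain features are computed on
#' TBR-scaled values (`SUV / background`), which makes them invariant
#' under global intensity rescaling of the scan.
#'
#' The output is a named vector with deterministic order and length for a
#' fixed configuration; degenerate situations (single gray level, tiny
#' ROIs) produce documented fallback values, never `NA`.
#'
#' @param volume a [pet_volume()] in SUV.
#' @param seg a [autocontour_lesion()] result.
#' @param background mean SUV of healthy brain tissue.
#' @param config an [extract_config()].
#' @return Named numeric feature vector.
#' @export
extract_features <- function(volume, seg, background,
                             config = extract_config()) {
  stopifnot(inherits(volume, "pet_volume"),
            inherits(seg, "lesion_segmentation"),
            inherits(config, "extract_config"))
  droi <- discretize_segmentation(volume, seg, background,
                                  bin_width = config$bin_width,
                                  anchor = config$anchor)
  vals <- volume$data[seg$voxels] / background
  out <- numeric(0)
  fam <- config$families
  if ("fractal" %in% fam)
    out <- c(out, fractal_features(droi))
  if ("first_order" %in% fam)
    out <- c(out, first_order_features(vals, droi))
  if ("shape" %in% fam)
    out <- c(out, shape_features(seg, spacing = volume$spacing[1:2]))
  if ("texture" %in% fam)
    out <- c(out, texture_feature_block(droi))
  if ("wavelet" %in% fam) {
    pm <- lesion_patch(volume, seg, background, pad = config$patch_pad)
    out <- c(out, wavelet_features(pm$patch, pm$mask,
                                   n_bins = config$wavelet_bins))
  }
  out
}

# TBR-scaled slice patch over the padded lesion bounding box, plus the
# in-patch lesion mask.
lesion_patch <- function(volume, seg, background, pad = 2L) {
  sl <- volume$data[, , seg$slice] / background
  vox <- seg$voxels
  r0 <- max(1L, min(vox[, 1]) - pad); r1 <- min(nrow(sl), max(vox[, 1]) + pad)
  c0 <- max(1L, min(vox[, 2]) - pad); c1 <- min(ncol(sl), max(vox[, 2]) + pad)
  patch <- sl[r0:r1, c0:c1, drop = FALSE]
  mask <- matrix(FALSE, nrow(patch), ncol(patch))
  mask[cbind(vox[, 1] - r0 + 1L, vox[, 2] - c0 + 1L)] <- TRUE
  list(patch = patch, mask = mask)
}

#' Quantify and extract features for a whole synthetic cohort
#'
#' For every subject of a [generate_cohort()] result: compute the
#' background mean from the subject's reference ROI, auto-contour the
#' lesion at the TBR threshold, compute TBR_mean/TBR_max, and extract the
#' radiomics feature vector.  Subjects in which no voxel reaches the
#' threshold (possible under heavy noise) are dropped with a warning.
#'
#' @param subjects a [generate_cohort()] result.
#' @param config an [extract_config()].
#' @param threshold auto-contour TBR threshold; default 1.6.
#' @return A `data.frame` feature table: `subject_id`, `label`,
#'   `tbr_mean`, `tbr_max`, then one column per radiomics feature.
#' @export
extract_cohort_features <- function(subjects, config = extract_config(),
                                    threshold = 1.6) {
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    bg <- background_mean(s$volume, s$background_roi)
    seg <- autocontour_lesion(s$volume, bg, threshold = threshold)
    if (is.null(seg)) {
      warning(sprintf("subject %s: no voxel reaches TBR %.2f; dropped",
                      s$subject_id, threshold))
      next
    }
    tbr <- compute_tbr(seg, s$volume, bg)
    fv <- extract_features(s$volume, seg, bg, config)
    rows[[i]] <- c(tbr_mean = tbr$tbr_mean, tbr_max = tbr$tbr_max, fv)
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no subject produced a lesion")
  # align on the union of names (degenerate sub-bands can drop features)
  nms <- unique(unlist(lapply(rows[keep], names)))
  mat <- t(vapply(rows[keep], function(r) {
    out <- stats::setNames(rep(0, length(nms)), nms)
    out[names(r)] <- r
    out
  }, numeric(length(nms))))
  data.frame(
    subject_id = vapply(subjects[keep], `[[`, character(1), "subject_id"),
    label = vapply(subjects[keep], `[[`, integer(1), "label"),
    mat, check.names = FALSE)
}
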