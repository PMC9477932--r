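#' Read a PET volume from a NIfTI-1 file
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param units intensity unit flag to attach, `"SUV"` or `"kBq/ml"`.
#' @return A [pet_volume()].
#' @export
read_pet_nifti <- function(path, units = c("SUV", "kBq/ml")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  pet_volume(array(as.numeric(img), dim = dim(img)[1:3]),
             spacing = sp, units = units)
}

#' Write a PET volume (or mask) as NIfTI-1
#'
#' @param x a [pet_volume()] or a plain 3D array (e.g. a mask).
#' @param path output file path.
#' @param spacing voxel spacing in mm, used when `x` is a plain array.
#' @return The path, invisibly.
#' @export
write_pet_nifti <- function(x, path, spacing = c(1, 1, 1)) {
  if (inherits(x, "pet_volume")) {
    arr <- x$data
    spacing <- x$spacing
  } else arr <- as.array(x)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Saves every subject's volume, truth lesion mask and background ROI as
#' NIfTI files, plus a manifest CSV (`subject_id`, `label`, paths, seed).
#'
#' @param subjects a [generate_cohort()] result.
#' @param dir output directory, created if needed.
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(subjects, function(s) {
    base <- file.path(dir, s$subject_id)
    write_pet_nifti(s$volume, paste0(base, "_suv.nii.gz"))
    write_pet_nifti(s$lesion_mask, paste0(base, "_lesion.nii.gz"),
                    spacing = s$volume$spacing)
    write_pet_nifti(s$background_roi, paste0(base, "_bgroi.nii.gz"),
                    spacing = s$volume$spacing)
    data.frame(subject_id = s$subject_id, label = s$label,
               volume = paste0(base, "_suv.nii.gz"),
               lesion_mask = paste0(base, "_lesion.nii.gz"),
               background_roi = paste0(base, "_bgroi.nii.gz"),
               seed = s$spec$seed)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write a segmentation summary
#'
#' Serializes the lesion segmentation as a NIfTI mask plus a JSON summary
#' (slice index, threshold, background, TBR_mean, TBR_max).
#'
#' @param seg a [autocontour_lesion()] result.
#' @param volume the segmented [pet_volume()].
#' @param path_prefix output prefix; writes `<prefix>_mask.nii.gz` and
#'   `<prefix>_summary.json`.
#' @return The summary list, invisibly.
#' @export
write_segmentation <- function(seg, volume, path_prefix) {
  mask <- array(0L, dim = dim(volume$data))
  mask[seg$voxels] <- 1L
  write_pet_nifti(mask, paste0(path_prefix, "_mask.nii.gz"),
                  spacing = volume$spacing)
  tbr <- compute_tbr(seg, volume)
  summary <- list(slice = seg$slice, threshold = seg$threshold,
                  background = seg$background,
                  n_voxels = nrow(seg$voxels),
                  tbr_mean = tbr$tbr_mean, tbr_max = tbr$tbr_max)
  jsonlite::write_json(summary, paste0(path_prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
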