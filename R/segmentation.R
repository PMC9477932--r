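#' Two-dimensional auto-contour lesion segmentation
#'
#' Implements threshold auto-contouring as used for amino-acid PET: find
#' the voxel with maximum uptake (optionally within a search mask), take
#' the transversal slice containing it, and within that slice grow the
#' 8-connected region of voxels whose tumor-to-brain ratio
#' (`SUV / background`) is at least `threshold`, starting from the maximum
#' voxel.  Disjoint supra-threshold islands in the same slice are not part
#' of the lesion.  Ties for the maximum voxel are broken by the lowest
#' linear array index so the result is reproducible.
#'
#' The transversal plane is taken to be the third array axis.
#'
#' @param volume a [pet_volume()] in SUV.
#' @param background mean SUV of healthy brain tissue (> 0).
#' @param threshold TBR threshold defining lesion tissue; default 1.6.
#' @param search_mask optional logical/0-1 array restricting where the
#'   maximum voxel is looked for (the contour itself still grows over the
#'   whole slice).
#'
#' @return An object of class `lesion_segmentation` with elements `slice`
#'   (transversal slice index), `voxels` (n x 3 integer matrix of voxel
#'   indices, all in `slice`), `max_voxel` (length-3 index of the hottest
#'   voxel), `threshold`, and `background`; or `NULL` if no voxel reaches
#'   the threshold ("no lesion").
#' @export
autocontour_lesion <- function(volume, background, threshold = 1.6,
                               search_mask = NULL) {
  stopifnot(inherits(volume, "pet_volume"))
  if (volume$units != "SUV")
    stop("segmentation requires an SUV volume; run compute_suv() first")
  if (!is.numeric(background) || length(background) != 1L ||
      !is.finite(background) || background <= 0)
    stop("`background` must be a single positive mean SUV")
  dat <- volume$data
  search <- dat
  if (!is.null(search_mask)) {
    search_mask <- as.array(search_mask)
    if (!identical(dim(search_mask), dim(dat)))
      stop("search mask grid does not match the volume grid")
    search[search_mask == 0] <- -Inf
  }
  imax <- which.max(search) # lowest linear index wins ties
  if (!is.finite(search[imax])) return(NULL)
  if (dat[imax] < threshold * background) return(NULL) # no lesion
  idx <- arrayInd(imax, dim(dat))[1, ]
  slice_k <- idx[3]
  sl <- dat[, , slice_k]
  supra <- sl >= threshold * background
  lab <- label_components_8(ifelse(supra, 1L, NA_integer_))
  comp <- lab[idx[1], idx[2]]
  members <- which(lab == comp & !is.na(lab), arr.ind = TRUE)
  voxels <- cbind(members, slice_k)
  colnames(voxels) <- c("i", "j", "k")
  structure(list(slice = slice_k, voxels = voxels,
                 max_voxel = c(idx[1], idx[2], slice_k),
                 threshold = threshold, background = background),
            class = "lesion_segmentation")
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  cat(sprintf(
    "<lesion_segmentation> %d voxels in transversal slice %d (TBR >= %.2f, background %.4g)\n",
    nrow(x$voxels), x$slice, x$threshold, x$background))
  invisible(x)
}

# Label 8-connected components of equal values in a 2D integer matrix.
# NA cells are background.  Vectorized min-label propagation: every cell
# starts with its own linear index and repeatedly adopts the minimum label
# among its 8 neighbors that carry the same value, until a fixed point.
# Labels are arbitrary but constant within a component and distinct across
# components (including components of different values), which is all the
# callers need.
label_components_8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  n <- nr * nc
  lab <- matrix(NA_integer_, nr, nc)
  if (all(is.na(m))) return(lab)
  # collect equal-value 8-neighbor edges once (4 forward shifts suffice),
  # then resolve connectivity by union-find over the edge list
  pm <- matrix(NA_integer_, nr + 2, nc + 2)
  pm[2:(nr + 1), 2:(nc + 1)] <- m
  idx <- matrix(seq_len(n), nr, nc)
  pi_ <- matrix(NA_integer_, nr + 2, nc + 2)
  pi_[2:(nr + 1), 2:(nc + 1)] <- idx
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  from <- integer(0); to <- integer(0)
  for (s in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nm <- pm[ri + s[1], ci + s[2], drop = FALSE]
    ok <- !is.na(m) & !is.na(nm) & m == nm
    if (any(ok)) {
      from <- c(from, idx[ok])
      to <- c(to, pi_[ri + s[1], ci + s[2], drop = FALSE][ok])
    }
  }
  parent <- seq_len(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]] # path halving
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(from)) {
    ra <- find_root(from[e]); rb <- find_root(to[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  cells <- which(!is.na(m))
  lab[cells] <- vapply(cells, find_root, integer(1))
  lab
}

# Shift a matrix by (di, dj), filling vacated cells with NA.
shift2 <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[] <- NA
  si <- seq_len(nr) - di
  sj <- seq_len(nc) - dj
  keep_i <- si >= 1 & si <= nr
  keep_j <- sj >= 1 & sj <= nc
  out[keep_i, keep_j] <- m[si[keep_i], sj[keep_j]]
  out
}

#' Tumor-to-brain ratios of a segmented lesion
#'
#' `TBR_max` is the maximum lesion SUV divided by the background mean;
#' `TBR_mean` is the mean lesion SUV divided by the background mean.  Both
#' are dimensionless.  By construction of the auto-contour every lesion
#' voxel satisfies `TBR >= threshold`, so `TBR_max >= TBR_mean >=
#' threshold`; a segmentation violating this (e.g. built by hand) is
#' rejected.
#'
#' @param seg a [autocontour_lesion()] result.
#' @param volume the [pet_volume()] in SUV the segmentation refers to.
#' @param background mean SUV of healthy brain; defaults to the value
#'   stored in the segmentation.
#'
#' @return A list with elements `tbr_mean` and `tbr_max`.
#' @export
compute_tbr <- function(seg, volume, background = seg$background) {
  if (is.null(seg)) stop("empty segmentation: no lesion to quantify")
  stopifnot(inherits(seg, "lesion_segmentation"), inherits(volume, "pet_volume"))
  if (nrow(seg$voxels) == 0L) stop("empty segmentation: no lesion to quantify")
  vals <- volume$data[seg$voxels]
  tbr <- vals / background
  if (min(tbr) < seg$threshold - 1e-9)
    stop(sprintf(
      "segmentation member below threshold: min TBR %.4f < %.4f",
      min(tbr), seg$threshold))
  list(tbr_mean = mean(tbr), tbr_max = max(tbr))
}
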