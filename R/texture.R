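#' Gray-level co-occurrence matrices
#'
#' Counts co-occurring gray-level pairs at the given pixel distance along
#' the four in-plane directions (0, 45, 90, 135 degrees).  Each
#' directional matrix is symmetrized (a pair is counted in both orders)
#' and normalized to probabilities; matrices are kept per direction so
#' features can be computed per direction and then averaged.
#'
#' @param droi a [discretize()] result.
#' @param distance pixel offset distance; default 1.
#'
#' @return An object of class `glcm_set`: a list of four `n_g x n_g`
#'   probability matrices named by direction angle.
#' @export
compute_glcm <- function(droi, distance = 1L) {
  if (!inherits(droi, "discretized_roi")) stop("need a discretized_roi")
  m <- droi$levels
  if (sum(!is.na(m)) < 2L) stop("GLCM needs at least 2 ROI voxels")
  ng <- droi$n_g
  d <- as.integer(distance)
  offsets <- list(`0` = c(0L, d), `45` = c(-d, d),
                  `90` = c(-d, 0L), `135` = c(-d, -d))
  out <- lapply(offsets, function(off) {
    nb <- shift2(m, -off[1], -off[2]) # value at (i+di, j+dj)
    ok <- !is.na(m) & !is.na(nb)
    cm <- matrix(0, ng, ng)
    if (any(ok)) {
      idx <- (m[ok] - 1L) * ng + nb[ok]
      tab <- tabulate(idx, nbins = ng * ng)
      cm <- matrix(tab, ng, ng, byrow = TRUE)
      cm <- cm + t(cm)
      cm <- cm / sum(cm)
    }
    cm
  })
  structure(out, class = "glcm_set", n_g = ng)
}

#' GLCM texture features
#'
#' Computes, per directional matrix and then averaged over directions:
#' contrast, correlation, joint entropy (log base 2), energy (angular
#' second moment), homogeneity (inverse difference), and the two
#' informational measures of correlation
#' `IMC1 = (HXY - HXY1) / max(HX, HY)` and
#' `IMC2 = sqrt(1 - exp(-2 (HXY2 - HXY)))`, where `HXY` is the joint
#' entropy, and `HXY1`/`HXY2` are cross entropies against the product of
#' the marginal distributions.  With a single occupied gray level all
#' entropies vanish and the degenerate fallbacks are `IMC1 = IMC2 =
#' correlation = 0`.
#'
#' @param glcms a [compute_glcm()] result.
#'
#' @return Named numeric vector of direction-averaged features.
#' @export
glcm_features <- function(glcms) {
  if (!inherits(glcms, "glcm_set")) stop("need a glcm_set")
  per_dir <- vapply(glcms, glcm_features_one,
                    numeric(length(glcm_feature_names)))
  stats::setNames(rowMeans(per_dir), glcm_feature_names)
}

glcm_feature_names <- c("glcm_contrast", "glcm_correlation",
                        "glcm_joint_entropy", "glcm_energy",
                        "glcm_homogeneity", "glcm_imc1", "glcm_imc2")

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px)
  mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  contrast <- sum(p * (i - j)^2)
  correlation <- if (sd_x > 0 && sd_y > 0)
    sum(p * (i - mu_x) * (j - mu_y)) / (sd_x * sd_y) else 0
  hxy <- entropy2(p)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  pxy <- outer(px, py)
  hxy1 <- -sum(p[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- entropy2(pxy)
  hx <- entropy2(px)
  hy <- entropy2(py)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(contrast, correlation, hxy, energy, homogeneity, imc1, imc2)
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gray-level run-length matrices
#'
#' Counts maximal runs of equal gray level along each of the four in-plane
#' directions.  Voxels outside the ROI break runs.
#'
#' @param droi a [discretize()] result.
#'
#' @return An object of class `glrlm_set`: four `n_g x max_run` count
#'   matrices named by direction, with attributes `n_g` and `n_voxels`.
#' @export
compute_glrlm <- function(droi) {
  if (!inherits(droi, "discretized_roi")) stop("need a discretized_roi")
  m <- droi$levels
  nvox <- sum(!is.na(m))
  if (nvox < 1L) stop("empty ROI")
  ng <- droi$n_g
  max_run <- max(dim(m))
  out <- lapply(c(`0` = "row", `90` = "col",
                  `45` = "diag_up", `135` = "diag_dn"),
                function(d) {
    sl <- scan_lines(m, d)
    v <- sl$values; li <- sl$line
    n <- length(v)
    # run breaks: start of vector, line change, value change, NA boundary
    prev_diff <- is.na(v[-n]) | is.na(v[-1]) | v[-1] != v[-n] |
      li[-1] != li[-n]
    brk <- c(TRUE, prev_diff)
    run_id <- cumsum(brk)
    len <- tabulate(run_id)
    val <- v[brk]
    keep <- !is.na(val)
    cm <- matrix(tabulate((val[keep] - 1L) * max_run + len[keep],
                          nbins = ng * max_run),
                 ng, max_run, byrow = TRUE)
    cm
  })
  structure(out, class = "glrlm_set", n_g = ng, n_voxels = nvox)
}

# Flatten a matrix into direction-ordered scan lines: a vector of values
# and a parallel line id, consecutive within each line.
scan_lines <- function(m, dir) {
  dm <- dim(m)
  if (dir == "row")
    return(list(values = as.vector(t(m)),
                line = rep(seq_len(dm[1]), each = dm[2])))
  if (dir == "col")
    return(list(values = as.vector(m),
                line = rep(seq_len(dm[2]), each = dm[1])))
  f <- if (dir == "diag_up") .row(dm) + .col(dm) else .row(dm) - .col(dm)
  ord <- order(as.vector(f)) # stable: column-major (= increasing j) within
  list(values = m[ord], line = as.vector(f)[ord])
}

#' GLRLM texture features
#'
#' Short-run emphasis, long-run emphasis, run-length non-uniformity
#' (normalized), gray-level non-uniformity (normalized) and run
#' percentage, each computed per direction and averaged.
#'
#' @param glrlms a [compute_glrlm()] result.
#' @return Named numeric vector.
#' @export
glrlm_features <- function(glrlms) {
  if (!inherits(glrlms, "glrlm_set")) stop("need a glrlm_set")
  nvox <- attr(glrlms, "n_voxels")
  per_dir <- vapply(glrlms, function(cm) {
    nr_runs <- sum(cm)
    l <- matrix(seq_len(ncol(cm)), nrow(cm), ncol(cm), byrow = TRUE)
    run_len_tot <- colSums(cm)
    gray_tot <- rowSums(cm)
    c(sre = sum(cm / l^2) / nr_runs,
      lre = sum(cm * l^2) / nr_runs,
      rln_norm = sum(run_len_tot^2) / nr_runs^2,
      gln_norm = sum(gray_tot^2) / nr_runs^2,
      run_percentage = nr_runs / nvox)
  }, numeric(5))
  out <- rowMeans(per_dir)
  names(out) <- paste0("glrlm_", names(out))
  out
}

#' Gray-level size-zone matrix
#'
#' A zone is an 8-connected set of voxels sharing one gray level;
#' `s(g, z)` counts zones of level g and size z.  Unlike run-length
#' matrices the GLSZM is direction-free.
#'
#' @param droi a [discretize()] result.
#' @return An object of class `glszm`: an `n_g x max_zone_size` count
#'   matrix with attribute `n_voxels`.
#' @export
compute_glszm <- function(droi) {
  if (!inherits(droi, "discretized_roi")) stop("need a discretized_roi")
  m <- droi$levels
  nvox <- sum(!is.na(m))
  if (nvox < 1L) stop("empty ROI")
  lab <- label_components_8(m)
  in_roi <- !is.na(lab)
  zone_size <- tabulate(lab[in_roi], nbins = length(lab))
  zone_label <- which(zone_size > 0L)
  zone_size <- zone_size[zone_label]
  zone_level <- m[match(zone_label, lab)]
  mz <- max(zone_size)
  cm <- matrix(tabulate((zone_level - 1L) * mz + zone_size,
                        nbins = droi$n_g * mz),
               droi$n_g, mz, byrow = TRUE)
  structure(cm, class = "glszm", n_voxels = nvox)
}

#' GLSZM texture features
#'
#' Gray-level (intensity) non-uniformity normalized
#' `INN = sum_g (sum_z s(g,z))^2 / N_z^2`, zone-size non-uniformity
#' normalized, small- and large-zone emphasis, and zone percentage.
#'
#' @param szm a [compute_glszm()] result.
#' @return Named numeric vector.
#' @export
glszm_features <- function(szm) {
  if (!inherits(szm, "glszm")) stop("need a glszm")
  nz <- sum(szm)
  if (nz < 1) stop("GLSZM has no zones")
  nvox <- attr(szm, "n_voxels")
  z <- matrix(seq_len(ncol(szm)), nrow(szm), ncol(szm), byrow = TRUE)
  c(glszm_inn = sum(rowSums(szm)^2) / nz^2,
    glszm_zsnn = sum(colSums(szm)^2) / nz^2,
    glszm_sze = sum(szm / z^2) / nz,
    glszm_lze = sum(szm * z^2) / nz,
    glszm_zone_percentage = nz / nvox)
}
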