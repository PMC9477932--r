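# First-order, shape, fractal, wavelet and whole-vector extraction.

test_that("first-order statistics match closed forms", {
  coords <- cbind(1L, 1:3)
  d <- discretize(c(1.6, 1.8, 2.0), background = 1, coords = coords)
  f <- first_order_features(c(1.6, 1.8, 2.0), d)
  expect_equal(unname(f["fo_mean"]), 1.8)
  expect_equal(unname(f["fo_range"]), 0.4)
  expect_equal(unname(f["fo_energy"]), 1.6^2 + 1.8^2 + 2.0^2)

  # constant ROI: SD 0, entropy 0, uniformity 1, moment ratios 0
  dc <- discretize(rep(2.0, 5), background = 1, coords = cbind(1L, 1:5))
  fc <- first_order_features(rep(2.0, 5), dc)
  expect_equal(unname(fc["fo_sd"]), 0)
  expect_equal(unname(fc["fo_entropy"]), 0)
  expect_equal(unname(fc["fo_uniformity"]), 1)
  expect_equal(unname(fc["fo_skewness"]), 0)

  # large normal sample: skewness within 3 SE of 0
  set.seed(12)
  x <- rnorm(1000, 2.1, 0.3)
  dn <- discretize(x, background = 1, coords = cbind(1L, seq_along(x)))
  fn <- first_order_features(x, dn)
  expect_lt(abs(fn[["fo_skewness"]]), 3 * sqrt(6 / 1000))
})

test_that("shape features follow their stated conventions", {
  # single voxel at 1x1 mm: area 1, max center-to-center diameter 0
  seg1 <- list(voxels = cbind(i = 3L, j = 3L, k = 1L))
  f1 <- shape_features(seg1, spacing = c(1, 1))
  expect_equal(unname(f1["shape_area"]), 1)
  expect_equal(unname(f1["shape_max_diameter"]), 0)

  # 10x10 voxel square at 1 mm: area 100
  sq <- expand.grid(i = 1:10, j = 1:10)
  f2 <- shape_features(list(voxels = cbind(sq$i, sq$j, 1L)), c(1, 1))
  expect_equal(unname(f2["shape_area"]), 100)
  expect_equal(unname(f2["shape_max_diameter"]), 9 * sqrt(2))

  # digital disk of radius 20: circularity close to a perfect circle
  g <- expand.grid(i = -25:25, j = -25:25)
  disk <- g[g$i^2 + g$j^2 <= 20^2, ]
  f3 <- shape_features(list(voxels = cbind(disk$i + 26, disk$j + 26, 1L)),
                       c(1, 1))
  expect_gte(unname(f3["shape_circularity"]), 0.85)
  expect_lte(unname(f3["shape_circularity"]), 1.0)
})

test_that("box-counting dimensions recover smooth-limit values", {
  # filled square: boundary is a curve (dimension ~ 1)
  sq <- matrix(NA_integer_, 40, 40)
  sq[5:36, 5:36] <- 1L
  d <- fractal_features(droi_from_levels(sq))
  expect_lt(abs(d[["fractal_boundary_dim"]] - 1), 0.15)

  # straight line segment
  ln <- matrix(NA_integer_, 3, 40)
  ln[2, 3:38] <- 1L
  dl <- fractal_features(droi_from_levels(ln))
  expect_lt(abs(dl[["fractal_boundary_dim"]] - 1), 0.15)

  # constant intensity surface: differential box count ~ 2
  con <- droi_from_levels(matrix(1L, 20, 20))
  expect_lt(abs(fractal_features(con)[["fractal_dbc_dim"]] - 2), 0.15)

  # a rough random surface exceeds a smooth ramp
  set.seed(5)
  rough <- discretize(runif(400, 1.6, 3.6), background = 1,
                      coords = as.matrix(expand.grid(1:20, 1:20)))
  ramp_vals <- as.vector(outer(1:20, 1:20, function(a, b) 1.6 + 0.02 * (a + b)))
  ramp <- discretize(ramp_vals, background = 1,
                     coords = as.matrix(expand.grid(1:20, 1:20)))
  expect_gt(fractal_features(rough)[["fractal_dbc_dim"]],
            fractal_features(ramp)[["fractal_dbc_dim"]])
})

test_that("wavelet sub-bands behave like a filter bank", {
  # constant patch: all detail coefficients vanish, LL is flat with gain 2
  con <- matrix(3, 12, 12)
  w <- dwt2(con)
  expect_true(all(abs(w$LH) < 1e-12))
  expect_true(all(abs(w$HL) < 1e-12))
  expect_true(all(abs(w$HH) < 1e-12))
  expect_true(all(abs(w$LL - 6) < 1e-10))

  mask <- matrix(TRUE, 12, 12)
  f <- wavelet_features(con, mask)
  for (b in c("LL", "LH", "HL", "HH"))
    expect_equal(unname(f[paste0("wav_", b, "_fo_sd")]), 0)

  # stripes along rows (variation down the first index) load HL; stripes
  # along columns load LH; verified against a direct convolution oracle
  row_stripes <- matrix(rep(c(1, -1), each = 1, times = 6), 12, 12)
  wr <- dwt2(row_stripes)
  expect_gt(sum(wr$HL^2), 100 * sum(wr$LH^2))
  col_stripes <- t(row_stripes)
  wc <- dwt2(col_stripes)
  expect_gt(sum(wc$LH^2), 100 * sum(wc$HL^2))

  # direct filter-bank oracle: explicit correlation over the symmetric
  # extension, then dyadic downsampling
  g <- fetrad:::db3_highpass
  x <- sin(seq(0, 3, length.out = 16))
  via_matrix <- as.numeric(fetrad:::dwt_cols(matrix(x, 16, 1), g))
  ext <- c(rev(x[1:5]), x, x[16:12])
  valid <- vapply(seq_len(16 + 5), function(m) sum(g * ext[m:(m + 5)]),
                  numeric(1))
  expect_equal(via_matrix, valid[seq(2, length(valid), 2)],
               tolerance = 1e-12)
  # the scalar fallback path agrees with the matrix path
  expect_equal(as.numeric(fetrad:::dwt_step(x, g)), via_matrix,
               tolerance = 1e-12)
})

test_that("feature vectors are deterministic, complete, and config-driven", {
  ph <- toy_phantom(seed = 17, texture_amp = 0.3)
  bg <- background_mean(ph$volume, ph$background_roi)
  seg <- autocontour_lesion(ph$volume, bg)
  f1 <- extract_features(ph$volume, seg, bg)
  f2 <- extract_features(ph$volume, seg, bg)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
  expect_false(any(duplicated(names(f1))))

  no_wav <- extract_features(ph$volume, seg, bg,
                             extract_config(families = c("fractal",
                                                         "first_order",
                                                         "shape", "texture")))
  expect_false(any(grepl("^wav_", names(no_wav))))
  expect_true(all(names(no_wav) %in% names(f1)))

  # global intensity scaling leaves the whole vector unchanged
  scaled <- pet_volume(ph$volume$data * 2, spacing = ph$volume$spacing,
                       units = "SUV")
  seg_s <- autocontour_lesion(scaled, bg * 2)
  f_s <- extract_features(scaled, seg_s, bg * 2)
  expect_equal(f1, f_s, tolerance = 1e-12)
})

test_that("homogeneous and heterogeneous lesions separate in texture features", {
  n_seeds <- 50
  fv <- function(amp, s) {
    ph <- generate_phantom(phantom_spec(seed = 1000 + s, texture_amp = amp))
    bg <- background_mean(ph$volume, ph$background_roi)
    seg <- autocontour_lesion(ph$volume, bg)
    extract_features(ph$volume, seg, bg)
  }
  hom <- lapply(seq_len(n_seeds), function(s) fv(0, s))
  het <- lapply(seq_len(n_seeds), function(s) fv(0.6, s))
  common <- Reduce(intersect, lapply(c(hom, het), names))
  pvals <- vapply(common, function(f) {
    suppressWarnings(wilcox.test(vapply(hom, `[[`, numeric(1), f),
                                 vapply(het, `[[`, numeric(1), f))$p.value)
  }, numeric(1))
  names(pvals) <- common
  # zone-based intensity non-uniformity is a strong discriminator of the
  # planted blob-scale heterogeneity ...
  expect_lt(pvals[["glszm_inn"]], 0.01)
  # ... and the heterogeneity signal is broadly distributed over the
  # feature inventory
  expect_gte(sum(pvals < 0.001, na.rm = TRUE), 30)
})
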