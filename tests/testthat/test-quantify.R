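# SUV conversion, harmonization smoothing, background quantification,
# auto-contour segmentation and TBR computation.

test_that("SUV conversion implements activity per injected dose per gram", {
  vol <- pet_volume(array(3.0, c(2, 2, 2)), units = "kBq/ml")
  suv <- compute_suv(vol, subject_meta(injected_mbq = 210, weight_kg = 70))
  expect_equal(suv$data, array(1.0, c(2, 2, 2)))
  expect_identical(suv$units, "SUV")

  zero <- compute_suv(pet_volume(array(0, c(2, 2, 1)), units = "kBq/ml"),
                      subject_meta(100, 80))
  expect_true(all(zero$data == 0))

  # weight-based dosing (3 MBq/kg) cancels body weight: 6.3 kBq/ml -> 2.1
  for (w in c(50, 70, 95)) {
    suv <- compute_suv(pet_volume(array(6.3, c(1, 1, 1)), units = "kBq/ml"),
                       subject_meta(injected_mbq = 3 * w, weight_kg = w))
    expect_equal(as.numeric(suv$data), 2.1)
  }

  expect_error(compute_suv(suv, subject_meta(210, 70)), "already in SUV")
  expect_error(subject_meta(-1, 70), "positive")
  expect_error(subject_meta(210, 0), "positive")
})

test_that("Gaussian harmonization conserves intensity and matches the closed form", {
  con <- pet_volume(array(2.5, c(12, 12, 12)), units = "SUV")
  sm <- harmonize(con, 2.5)
  expect_equal(sm$data, con$data, tolerance = 1e-10)

  imp <- array(0, c(25, 25, 25)); imp[13, 13, 13] <- 1
  out <- harmonize(pet_volume(imp, spacing = c(1, 1, 1), units = "SUV"), 2.5)
  expect_equal(sum(out$data), 1, tolerance = 1e-6)

  # peak of the discrete kernel vs the continuous 3D Gaussian peak
  sigma <- 2.5 / (2 * sqrt(2 * log(2)))
  expect_equal(out$data[13, 13, 13], (2 * pi * sigma^2)^(-3 / 2),
               tolerance = 1e-3)

  # sigma interpretation uses the size directly
  out2 <- harmonize(pet_volume(imp, units = "SUV"), sigma,
                    interpretation = "sigma")
  expect_equal(out2$data, out$data, tolerance = 1e-12)

  expect_error(harmonize(con, -1), "positive")
})

test_that("background mean is the arithmetic ROI mean", {
  vol <- pet_volume(array(c(0.8, 1.0, 1.2, 9, 9, 9), c(6, 1, 1)),
                    units = "SUV")
  roi <- array(c(1, 1, 1, 0, 0, 0), c(6, 1, 1))
  expect_equal(background_mean(vol, roi), 1.0)
  expect_error(background_mean(vol, array(0, c(6, 1, 1))), "empty")

  set.seed(42)
  vals <- rnorm(1000, 1.05, 0.1)
  vol2 <- pet_volume(array(vals, c(10, 10, 10)), units = "SUV")
  expect_lt(abs(background_mean(vol2, array(1, c(10, 10, 10))) - 1.05),
            3 * 0.1 / sqrt(1000))
})

test_that("auto-contour keeps only the component of the hottest voxel", {
  # 5x5 slice: plateau of four 8-connected voxels at 2.0, rest 1.0
  sl <- matrix(1, 5, 5)
  sl[2:3, 2:3] <- 2
  vol <- pet_volume(array(sl, c(5, 5, 1)), units = "SUV")
  seg <- autocontour_lesion(vol, background = 1)
  expect_s3_class(seg, "lesion_segmentation")
  expect_equal(seg$slice, 1)
  expect_setequal(paste(seg$voxels[, 1], seg$voxels[, 2]),
                  c("2 2", "2 3", "3 2", "3 3"))

  # two disjoint supra-threshold blobs: only the max-voxel blob returned
  sl2 <- matrix(1, 7, 7)
  sl2[2:3, 2:3] <- 2.0   # blob B
  sl2[5:6, 5:6] <- 2.5   # blob A (hotter)
  vol2 <- pet_volume(array(sl2, c(7, 7, 1)), units = "SUV")
  seg2 <- autocontour_lesion(vol2, 1)
  expect_equal(nrow(seg2$voxels), 4)
  expect_true(all(seg2$voxels[, 1] >= 5))

  # nothing reaches the threshold -> "no lesion", not an error
  flat <- pet_volume(array(1, c(4, 4, 2)), units = "SUV")
  expect_null(autocontour_lesion(flat, 1))

  # diagonal contact is 8-connected
  sl3 <- matrix(1, 4, 4)
  sl3[1, 1] <- 2; sl3[2, 2] <- 1.9
  seg3 <- autocontour_lesion(pet_volume(array(sl3, c(4, 4, 1)),
                                        units = "SUV"), 1)
  expect_equal(nrow(seg3$voxels), 2)
})

test_that("TBR summary divides lesion SUVs by the background mean", {
  sl <- matrix(1, 4, 4)
  sl[2, 2] <- 2.0; sl[2, 3] <- 3.2
  vol <- pet_volume(array(sl, c(4, 4, 1)), units = "SUV")
  seg <- autocontour_lesion(vol, 1)
  tbr <- compute_tbr(seg, vol, 1)
  expect_equal(tbr$tbr_mean, 2.6)
  expect_equal(tbr$tbr_max, 3.2)

  # boundary case: all member voxels exactly at threshold
  sl2 <- matrix(1, 4, 4); sl2[2, 2:3] <- 1.6
  vol2 <- pet_volume(array(sl2, c(4, 4, 1)), units = "SUV")
  tbr2 <- compute_tbr(autocontour_lesion(vol2, 1), vol2, 1)
  expect_equal(tbr2$tbr_mean, 1.6)
  expect_equal(tbr2$tbr_max, 1.6)

  # hand-built segmentation with sub-threshold members is rejected
  bad <- structure(list(slice = 1,
                        voxels = cbind(i = c(2, 2), j = c(2, 3), k = c(1, 1)),
                        max_voxel = c(2, 3, 1), threshold = 1.6,
                        background = 2.0),
                   class = "lesion_segmentation")
  vol3 <- pet_volume(array(c(0), c(4, 4, 1)), units = "SUV")
  vol3$data[2, 2, 1] <- 1.8; vol3$data[2, 3, 1] <- 4.0
  expect_error(compute_tbr(bad, vol3, 2.0), "below threshold")
})

test_that("segmentation is scale-equivariant and monotone in the threshold", {
  ph <- toy_phantom(seed = 11, texture_amp = 0.25)
  bg <- background_mean(ph$volume, ph$background_roi)
  seg <- autocontour_lesion(ph$volume, bg)
  tbr <- compute_tbr(seg, ph$volume, bg)

  scaled <- pet_volume(ph$volume$data * 4, spacing = ph$volume$spacing,
                       units = "SUV")
  seg_s <- autocontour_lesion(scaled, bg * 4)
  expect_identical(seg$voxels, seg_s$voxels)
  tbr_s <- compute_tbr(seg_s, scaled, bg * 4)
  expect_equal(tbr$tbr_mean, tbr_s$tbr_mean)
  expect_equal(tbr$tbr_max, tbr_s$tbr_max)

  # raising the threshold never adds voxels
  prev <- nrow(autocontour_lesion(ph$volume, bg, threshold = 1.6)$voxels)
  for (thr in c(1.8, 2.0, 2.4)) {
    seg_t <- autocontour_lesion(ph$volume, bg, threshold = thr)
    n_t <- if (is.null(seg_t)) 0 else nrow(seg_t$voxels)
    expect_lte(n_t, prev)
    prev <- n_t
  }
})
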