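test_that("beam angles are equispaced along the wrapped posterior arc", {
  expect_equal(beam_angles(2, 168, 24), c(168, 24))
  a12 <- beam_angles(12, 168, 24)
  expect_equal(a12[1], 168)
  expect_equal(a12[12], 24)
  gaps <- diff((a12 - 168) %% 360)
  expect_equal(gaps, rep(216 / 11, 11), tolerance = 1e-12)
  expect_equal(beam_angles(3, 0, 180), c(0, 90, 180))
  expect_error(beam_angles(1), ">= 2")
})

test_that("radiological depth equals hand integrals on layered media", {
  uni <- voxel_image(array(1, c(40, 60, 10)), c(1, 1, 1))
  d <- radiological_depth(uni, c(20, -50, 5), c(20, 29.5, 5))
  expect_equal(d, 30, tolerance = 0.1)
  half <- voxel_image(array(0.5, c(40, 60, 10)), c(1, 1, 1))
  expect_equal(radiological_depth(half, c(20, -50, 5), c(20, 29.5, 5)),
               15, tolerance = 0.05)
  ## 20 mm at 0.328 then 30 mm at 0.988
  arr <- array(0, c(10, 60, 10))
  arr[, 1:20, ] <- 0.328
  arr[, 21:50, ] <- 0.988
  lay <- voxel_image(arr, c(1, 1, 1))
  expect_equal(radiological_depth(lay, c(5, -10, 5), c(5, 49.5, 5)),
               0.328 * 20 + 0.988 * 30, tolerance = 1e-9)
  ## ray missing the grid integrates to zero
  expect_equal(radiological_depth(lay, c(-50, -50, 5), c(-50, 100, 5)), 0)

  ## oblique rays agree with a fine-sampling oracle
  set.seed(8)
  med <- voxel_image(array(stats::runif(16^3, 0.3, 1.2), c(16, 16, 16)),
                     c(2, 2, 2))
  for (i in 1:5) {
    p0 <- stats::runif(3, -10, 0)
    p1 <- stats::runif(3, 12, 30)
    expect_equal(radiological_depth(med, p0, p1),
                 oracle_path_integral(med, p0, p1), tolerance = 0.15)
  }
})

test_that("influence entries follow the exponential-times-Gaussian kernel", {
  ## water cube, single anterior beam
  red <- voxel_image(array(1, c(16, 16, 16)), c(2, 2, 2))
  ## odd extents put the isocentre exactly on a voxel centre
  tgt <- array(FALSE, dim(red$data)); tgt[7:11, 7:11, 7:11] <- TRUE
  geo <- beam_geometry(gantry_angles = 0, beamlet_size_mm = 5, margin_mm = 5)
  ker <- kernel_params()
  infl <- build_dose_influence(geo, red, ker, tgt)
  expect_true(all(infl$D@x >= 0))

  ## dense brute-force oracle: same formula, independent fine-step integral
  centres <- liverspare:::voxel_centre_matrix(red)
  iso <- infl$isocentre
  depth_o <- vapply(seq_len(nrow(centres)), function(v)
    oracle_path_integral(red, centres[v, ] - c(0, 200, 0), centres[v, ]),
    numeric(1))
  Ddense <- matrix(0, nrow(infl$D), ncol(infl$D))
  for (b in seq_len(ncol(infl$D))) {
    u0 <- infl$beamlets$u[b]; z0 <- infl$beamlets$z[b]
    lat2 <- (centres[, 1] - iso[1] - u0)^2 + (centres[, 3] - iso[3] - z0)^2
    Ddense[, b] <- exp(-ker$mu_eff * depth_o) *
      exp(-lat2 / (2 * ker$lateral_sigma_mm^2))
    keep <- Ddense[, b] >= ker$truncation * max(Ddense[, b])
    Ddense[!keep, b] <- 0
  }
  expect_equal(as.matrix(infl$D), Ddense, tolerance = 2e-3,
               ignore_attr = TRUE)

  ## central-axis: influence decreases monotonically with depth in water
  ax <- infl$beamlets$u == 0 & infl$beamlets$z == 0
  col <- infl$D[, which(ax)[1]]
  axis_vox <- which(abs(centres[, 1] - iso[1]) < 1e-9 &
                      abs(centres[, 3] - iso[3]) < 1e-9)
  axis_vox <- axis_vox[order(centres[axis_vox, 2])]
  vals <- as.numeric(col[axis_vox])
  vals <- vals[vals > 0]
  expect_true(all(diff(vals) < 0))

  ## off-axis falloff at 2 sigma: ratio exp(-2) at matched depth
  sig <- ker$lateral_sigma_mm
  on_ax <- which(abs(centres[, 1] - iso[1]) < 1e-9 &
                   abs(centres[, 3] - iso[3]) < 1e-9 &
                   abs(centres[, 2] - iso[2]) < 1e-9)
  off_ax <- which(abs(centres[, 1] - (iso[1] + 2 * sig)) < 1e-9 &
                    abs(centres[, 3] - iso[3]) < 1e-9 &
                    abs(centres[, 2] - iso[2]) < 1e-9)
  expect_length(on_ax, 1)
  expect_length(off_ax, 1)
  ratio <- as.numeric(infl$D[off_ax, which(ax)[1]]) /
    as.numeric(infl$D[on_ax, which(ax)[1]])
  expect_equal(ratio, exp(-2), tolerance = 0.01)
  expect_error(build_dose_influence(geo, red, ker, tgt & FALSE), "empty")
})

test_that("dose is linear in fluence and vanishes without it", {
  red <- voxel_image(array(1, c(16, 16, 8)), c(2, 2, 4))
  tgt <- array(FALSE, dim(red$data)); tgt[7:10, 7:10, 4:5] <- TRUE
  infl <- build_dose_influence(beam_geometry(beam_angles(4, 168, 24)),
                               red, kernel_params(), tgt)
  nb <- ncol(infl$D)
  expect_true(all(compute_dose(infl, rep(0, nb))$data == 0))
  set.seed(2)
  f1 <- stats::runif(nb); f2 <- stats::runif(nb)
  d1 <- compute_dose(infl, f1)$data
  d2 <- compute_dose(infl, f2)$data
  d12 <- compute_dose(infl, f1 + f2)$data
  expect_equal(d12, d1 + d2, tolerance = 1e-9)
  ## doubling fluence doubles every DVH D-metric
  dose1 <- compute_dose(infl, f1)
  dose2 <- compute_dose(infl, 2 * f1)
  expect_equal(dose_at_volume_percent(dose2, tgt, 95),
               2 * dose_at_volume_percent(dose1, tgt, 95), tolerance = 1e-12)
  expect_equal(dose_at_volume_cc(dose2, tgt, 0.5),
               2 * dose_at_volume_cc(dose1, tgt, 0.5), tolerance = 1e-12)
  expect_equal(mean_dose(dose2, tgt), 2 * mean_dose(dose1, tgt),
               tolerance = 1e-12)
  expect_error(compute_dose(infl, rep(-1, nb)), "non-negative")
  expect_error(compute_dose(infl, rep(1, nb - 1)), "length")
})

test_that("influence matrices persist as documented sparse triplets", {
  red <- voxel_image(array(1, c(12, 12, 6)), c(2, 2, 4))
  tgt <- array(FALSE, dim(red$data)); tgt[5:8, 5:8, 3:4] <- TRUE
  infl <- build_dose_influence(beam_geometry(c(0, 180)), red,
                               kernel_params(), tgt)
  base <- file.path(withr::local_tempdir(), "infl")
  write_dose_influence(infl, base)
  tr <- utils::read.csv(paste0(base, ".triplets.csv"))
  D2 <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                             dims = dim(infl$D))
  expect_equal(as.matrix(D2), as.matrix(infl$D), tolerance = 1e-12)
  hdr <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(hdr$dim, dim(infl$D))
  expect_equal(hdr$grid$spacing, red$spacing)
})
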