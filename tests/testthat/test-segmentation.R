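test_that("in-plane downsampling averages blocks and scales spacing", {
  const <- voxel_image(array(700, c(8, 8, 4)), c(1.1, 1.1, 8))
  ds <- downsample_inplane(const, 2)
  expect_true(all(ds$data == 700))
  expect_equal(ds$spacing, c(2.2, 2.2, 8))
  expect_equal(dim(ds$data), c(4L, 4L, 4L))

  expect_identical(downsample_inplane(const, 1)$data, const$data)

  ## 2-D checkerboard of 0/1 becomes uniform 0.5
  chk <- array(0, c(8, 8, 2))
  chk[] <- (outer(1:8, 1:8, "+") %% 2)
  ds2 <- downsample_inplane(voxel_image(chk, c(1, 1, 1)), 2)
  expect_true(all(ds2$data == 0.5))

  ## non-divisible dims: edge padding recorded, matches the loop oracle
  odd <- voxel_image(array(stats::rnorm(7 * 5 * 3), c(7, 5, 3)), c(1, 1, 1))
  ds3 <- downsample_inplane(odd, 2)
  expect_identical(attr(ds3, "pad"), c(1L, 1L))
  expect_equal(ds3$data, oracle_block_mean(odd$data, 2))
  expect_error(downsample_inplane(const, 0), "factor")
})

test_that("cropping to a region of interest matches an exhaustive scan", {
  img <- voxel_image(array(seq_len(10 * 9 * 6), c(10, 9, 6)), c(1, 1, 1))
  full <- array(TRUE, dim(img$data))
  expect_identical(crop_to_roi(img, full)$data, img$data)

  single <- array(FALSE, dim(img$data)); single[4, 7, 2] <- TRUE
  cr1 <- crop_to_roi(img, single)
  expect_equal(dim(cr1$data), c(1L, 1L, 1L))
  expect_equal(cr1$data[1, 1, 1], img$data[4, 7, 2])

  set.seed(42)
  roi <- liverspare:::ellipsoid_mask(dim(img$data), c(1, 1, 1),
                                     c(5, 4, 3), c(3.2, 2.5, 2.1))
  cr <- crop_to_roi(img, roi)
  bb <- oracle_bbox(roi)
  expect_equal(dim(cr$data), as.integer(bb[, 2] - bb[, 1] + 1))
  expect_equal(unname(attr(cr, "bbox")), unname(bb))
  expect_equal(unname(cr$origin),
               unname(img$origin + (bb[, 1] - 1) * img$spacing))
  expect_error(crop_to_roi(img, full & FALSE), "empty roi")
})

test_that("functional thresholding is strict and matches a voxel scan", {
  shp <- c(12, 10, 6)
  roi <- array(TRUE, shp)
  uni <- array(700, shp)
  expect_identical(threshold_functional(uni, roi, 800), roi)
  expect_false(any(threshold_functional(array(800, shp), roi, 800)))

  set.seed(1)
  vals <- array(stats::runif(prod(shp), 600, 1000), shp)
  m <- threshold_functional(vals, roi, 800)
  count <- 0L
  for (i in seq_len(shp[1])) for (j in seq_len(shp[2])) for (k in seq_len(shp[3]))
    if (vals[i, j, k] < 800) count <- count + 1L
  expect_identical(sum(m), count)

  ## monotone in the threshold
  m750 <- threshold_functional(vals, roi, 750)
  m850 <- threshold_functional(vals, roi, 850)
  expect_true(all(m[m750]))
  expect_true(all(m850[m]))
})

test_that("smoothing preserves interior means and constants over the scope", {
  set.seed(3)
  arr <- array(stats::rnorm(32 * 32 * 4, 10, 2), c(32, 32, 4))
  sm <- gaussian_smooth(arr, sigma = 2, axes = c(1, 2))
  interior <- sm[13:20, 13:20, ]
  ## conservation away from boundaries: local means preserved within 0.5 %
  expect_equal(mean(interior), mean(arr[13:20, 13:20, ]), tolerance = 5e-3)

  params <- segmentation_params()
  scope <- liverspare:::ellipsoid_mask(c(24, 24, 4), c(1, 1, 1),
                                       c(12, 12, 2), c(9, 8, 2))
  ## mask = entire scope stays the scope for any sigma
  expect_identical(smooth_and_median(scope, params, scope), scope)
  ## sigma = 0 is a pass-through followed by median thresholding
  p0 <- segmentation_params(smoothing_sigma = 0)
  sub <- scope; sub[1:12, , ] <- FALSE
  expect_identical(smooth_and_median(sub, p0, scope), sub)
  ## empty in, empty out
  expect_false(any(smooth_and_median(scope & FALSE, params, scope)))
  expect_error(segmentation_params(smoothing_sigma = -1), ">= 0")
})

test_that("the full chain matches the dense brute-force oracle voxelwise", {
  for (seed in 1:4) {
    ph <- random_seg_phantom(c(24, 24, 6), seed)
    got <- segment_flv(ph$ct1, ph$liver, ph$fov)
    want <- oracle_segment_flv(ph$ct1, ph$liver, ph$fov)
    expect_identical(got$flv_mask, want)
  }
})

test_that("degenerate cT1 maps give full, empty and boundary-excluded FLVs", {
  pc <- phantom_config(grid_shape = c(48, 48, 12), spacing_mm = c(2.75, 2.75, 8),
                       seed = 9)
  pat <- generate_patient(pc)
  m <- pat$structures$masks
  roi <- m$liver & m$fov

  uni <- pat$ct1_map; uni$data[] <- 700
  seg_lo <- segment_flv(uni, m$liver, m$fov)
  ## working grid: FLV equals the downsampled ROI exactly
  bb <- seg_lo$bbox
  expect_identical(seg_lo$flv_work[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2],
                                   bb[3, 1]:bb[3, 2]], seg_lo$roi_work)
  expect_identical(sum(seg_lo$flv_work), sum(seg_lo$roi_work))

  hi <- pat$ct1_map; hi$data[] <- 900
  expect_false(any(segment_flv(hi, m$liver, m$fov)$flv_mask))

  ## voxels exactly at the threshold are excluded (strict <)
  at <- pat$ct1_map; at$data[] <- 800
  expect_false(any(segment_flv(at, m$liver, m$fov)$flv_mask))

  expect_error(segment_flv(uni, m$liver, m$fov & FALSE), "empty roi")
})

test_that("median re-thresholding removes a small blob and keeps a large one", {
  pc <- phantom_config(grid_shape = c(96, 96, 16), spacing_mm = c(2.2, 2.2, 8),
                       seed = 9)
  pat <- generate_patient(pc)
  m <- pat$structures$masks
  sp <- pat$ct1_map$spacing
  d <- dim(pat$ct1_map$data)
  ctr <- (colMeans(which(m$liver & m$fov, arr.ind = TRUE)) - 1) * sp
  X <- array(rep((seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3]), d)
  Y <- array(rep(rep((seq_len(d[2]) - 1) * sp[2], each = d[1]), d[3]), d)
  Z <- array(rep((seq_len(d[3]) - 1) * sp[3], each = d[1] * d[2]), d)
  ## centre blobs on a slice plane so the 3 mm blob lands on voxels
  zc <- round(ctr[3] / sp[3]) * sp[3]
  big <- ((X - ctr[1] + 25)^2 + (Y - ctr[2])^2 + (Z - zc)^2) <= 15^2
  small <- ((X - ctr[1] - 30)^2 + (Y - ctr[2] - 10)^2 + (Z - zc)^2) <= 3^2
  roi <- m$liver & m$fov
  expect_gt(sum(big & roi), 100)
  expect_gt(sum(small & roi), 0)
  ct1 <- pat$ct1_map
  ct1$data[] <- 900
  ct1$data[big | small] <- 700
  seg <- segment_flv(ct1, m$liver, m$fov)
  expect_identical(sum(seg$flv_mask & small), 0L)     # small blob removed
  ## the large blob survives as a solid core (the median cut erodes its rim)
  expect_gt(sum(seg$flv_mask & big) / sum(big & roi), 0.4)
  expect_gt(sum(seg$flv_mask & big), 0.5 * sum(seg$flv_mask))
})

test_that("the FLV is always contained in liver-within-FOV", {
  for (seed in c(2, 5)) {
    pat <- generate_patient(phantom_config(
      grid_shape = c(48, 48, 12), spacing_mm = c(2.75, 2.75, 8),
      functional_fraction_target = 0.4 + 0.2 * (seed == 5), seed = seed))
    m <- pat$structures$masks
    seg <- segment_flv(pat$ct1_map, m$liver, m$fov)
    expect_false(any(seg$flv_mask & !(m$liver & m$fov)))
    expect_false(any(seg$flv_work & !liverspare:::downsample_mask_inplane(
      m$liver & m$fov, pat$ct1_map$spacing, seg$factor)))
  }
})
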