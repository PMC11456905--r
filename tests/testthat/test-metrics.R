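test_that("mask volumes follow voxel arithmetic", {
  one <- array(FALSE, c(4, 4, 2)); one[2, 3, 1] <- TRUE
  expect_equal(volume_cc(one, c(2.2, 2.2, 8)), 2.2 * 2.2 * 8 / 1000)
  expect_equal(volume_cc(one & FALSE, c(2.2, 2.2, 8)), 0)
  set.seed(12)
  m <- array(stats::runif(32^3) < 0.3, c(32, 32, 32))
  count <- 0L
  for (v in as.vector(m)) if (v) count <- count + 1L
  expect_equal(volume_cc(m, c(1.5, 1.5, 3)), count * 1.5 * 1.5 * 3 / 1000)
})

test_that("functional ratios round half away from zero", {
  expect_identical(functional_ratio_percent(276, 773), 36L)
  expect_identical(functional_ratio_percent(115, 724), 16L)
  expect_identical(functional_ratio_percent(0, 500), 0L)
  expect_identical(functional_ratio_percent(1, 8), 13L)   # 12.5 -> 13
  expect_error(functional_ratio_percent(10, 0), "fov_cc")
})

test_that("Dp% uses sorted voxel doses with the documented convention", {
  uni <- array(50, c(5, 5, 4))
  mk <- array(TRUE, dim(uni))
  expect_equal(dose_at_volume_percent(uni, mk, 95), 50)
  expect_equal(dose_at_volume_percent(uni, mk, 2), 50)

  d <- array(as.numeric(1:100), c(10, 10, 1))
  m <- array(TRUE, dim(d))
  expect_equal(dose_at_volume_percent(d, m, 95), 5)
  expect_equal(dose_at_volume_percent(d, m, 100), 1)    # minimum dose
  expect_equal(dose_at_volume_percent(d, m, 1), 99)
  ## D(p) is non-increasing in p
  ps <- c(5, 25, 50, 75, 95, 100)
  vals <- vapply(ps, function(p) dose_at_volume_percent(d, m, p), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_error(dose_at_volume_percent(d, m & FALSE, 95), "empty")
})

test_that("Dcc interpolates the cumulative volume curve", {
  ## 10 voxels of 0.1 cc (10 x 10 x 1 mm) with doses 10..100
  d <- array(as.numeric(10 * (1:10)), c(10, 1, 1))
  m <- array(TRUE, dim(d))
  vi <- voxel_image(d, c(10, 10, 1))
  expect_equal(dose_at_volume_cc(vi, m, 1.0), 10)       # full volume -> min
  expect_equal(dose_at_volume_cc(vi, m, 1e-6), 100)     # cc -> 0 -> max
  ## hand-computed cumulative curve: (0.2 cc, 90), (0.3 cc, 80) -> 85 at 0.25
  expect_equal(dose_at_volume_cc(vi, m, 0.25), 85)
  ## Dcc non-increasing in cc
  ccs <- c(0.05, 0.15, 0.4, 0.8, 1.0)
  vals <- vapply(ccs, function(cc) dose_at_volume_cc(vi, m, cc), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_error(dose_at_volume_cc(vi, m, 2), "cc must lie")
})

test_that("VzGy reports both criterion directions", {
  m <- array(TRUE, c(4, 4, 2))
  expect_equal(volume_at_dose_percent(array(5, dim(m)), m, 10)[["at_or_above"]], 0)
  expect_equal(volume_at_dose_percent(array(15, dim(m)), m, 10)[["at_or_above"]], 100)
  half <- array(c(5, 15), c(4, 4, 2))
  v <- volume_at_dose_percent(half, m, 10)
  expect_equal(v[["at_or_above"]], 50)
  expect_equal(v[["below"]], 50)
})

test_that("mean dose decomposes over a partition and matches brute force", {
  set.seed(7)
  d <- array(stats::runif(24^3, 0, 60), c(24, 24, 24))
  liver <- liverspare:::ellipsoid_mask(c(24, 24, 24), c(1, 1, 1),
                                       c(12, 12, 12), c(9, 8, 10))
  flv <- liver & (array(stats::runif(24^3), dim(liver)) < 0.5)
  rest <- liver & !flv
  lhs <- mean_dose(d, liver)
  rhs <- (sum(flv) * mean_dose(d, flv) + sum(rest) * mean_dose(d, rest)) /
    sum(liver)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  acc <- 0; n <- 0L
  for (i in which(liver)) { acc <- acc + d[i]; n <- n + 1L }
  expect_equal(mean_dose(d, liver), acc / n, tolerance = 1e-12)
  expect_error(mean_dose(d, liver & FALSE), "empty")
})

test_that("DVH curves are proper cumulative distributions", {
  set.seed(9)
  dose <- voxel_image(array(stats::rgamma(16^3, 4, 0.4), c(16, 16, 16)),
                      c(2, 2, 2))
  m <- liverspare:::ellipsoid_mask(c(16, 16, 16), c(2, 2, 2),
                                   c(16, 16, 16), c(12, 12, 12))
  dv <- dvh(dose, m)
  expect_equal(dv$volume_fraction[1], 1)                # everything >= 0 Gy
  expect_true(all(diff(dv$volume_fraction) <= 0))
  ## binned DVH agrees with sorted-voxel metrics within one bin width
  for (p in c(20, 50, 90)) {
    dp <- dose_at_volume_percent(dose, m, p)
    edge <- max(dv$dose_gy[dv$volume_fraction >= p / 100])
    expect_lte(abs(dp - edge), 0.05 + 1e-12)
  }
})

test_that("volume summaries keep the Table-1 bookkeeping identities", {
  shp <- c(20, 20, 5)
  liver <- array(FALSE, shp); liver[2:19, 2:19, ] <- TRUE
  gtv <- array(FALSE, shp); gtv[9:11, 9:11, 2:3] <- TRUE
  fov <- array(FALSE, shp); fov[, , 1:4] <- TRUE
  flv <- liver & fov & (array(seq_len(prod(shp)), shp) %% 3 == 0)
  vs <- volume_summary(liver, gtv, fov, flv, c(10, 10, 10), rx_gy = 50)
  expect_equal(vs$liver_minus_gtv_cc, vs$liver_cc - vs$gtv_cc)
  expect_equal(vs$fov_cc, volume_cc(liver & fov, c(10, 10, 10)))
  expect_gte(vs$ratio_percent, 0)
  expect_lte(vs$ratio_percent, 100)
  expect_identical(vs$ratio_percent,
                   functional_ratio_percent(vs$flv_cc, vs$fov_cc))
})
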