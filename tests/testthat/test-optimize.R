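test_that("parallel damage follows the logistic dose response", {
  expect_equal(parallel_damage(rep(15, 50), 15, 3), 0.5)
  expect_equal(parallel_damage(rep(0, 10), 15, 3), 0)
  expect_equal(parallel_damage(c(rep(15, 5), rep(0, 5)), 15, 3), 0.25)
  ## elementwise dose increase never decreases the damage
  set.seed(4)
  d <- stats::runif(200, 0, 40)
  bump <- d + stats::runif(200, 0, 5)
  expect_gte(parallel_damage(bump, 15, 3), parallel_damage(d, 15, 3))
  expect_error(parallel_damage(numeric(0)), "empty")
  expect_error(parallel_damage(1, d_ref_gy = 0), "> 0")
})

test_that("a single-voxel target converges to the prescription", {
  ## one voxel, two beamlets with known unit influence
  D <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(0.6, 0.4),
                            dims = c(1, 2))
  infl <- manual_influence(D, c(1L, 1L, 1L))
  st <- structure_set(list(ptv = array(TRUE, c(1, 1, 1)),
                           body = array(TRUE, c(1, 1, 1))),
                      spacing = c(1, 1, 1))
  obj <- plan_objectives(ptv_prescription_gy = 50, liver_mean_weight = 0)
  plan <- optimize_plan(infl, st, obj, options = list(max_iter = 500,
                                                      tol = 1e-12))
  expect_equal(as.numeric(plan$dose$data[1, 1, 1]), 50, tolerance = 0.005 * 50)
  expect_true(all(plan$fluence >= 0))
  expect_true(all(diff(plan$objective_trace) <= 1e-12))
})

test_that("zero-weight sparing reproduces the standard plan exactly", {
  setup <- small_planning_setup()
  std <- optimize_plan(setup$influence, setup$structures, setup$objectives)
  obj0 <- setup$objectives
  obj0$flv_parallel <- list(d_ref_gy = 15, k_power = 3, weight = 0)
  again <- optimize_plan(setup$influence, setup$structures, obj0)
  expect_identical(std$fluence, again$fluence)
  expect_identical(std$dose$data, again$dose$data)

  ## the sparing arm lowers FLV mean dose while holding PTV coverage
  flv <- setup$structures$masks$flv
  ptv <- setup$structures$masks$ptv
  spare <- auto_sparing_weight(setup$influence, setup$structures,
                               setup$objectives, d95_floor = 0.95 * 50,
                               standard_plan = std)
  expect_true(spare$sparing_applied)
  expect_lt(mean_dose(spare$dose, flv), mean_dose(std$dose, flv))
  expect_gte(dose_at_volume_percent(spare$dose, ptv, 95), 0.95 * 50)
  expect_true(all(diff(spare$objective_trace) <= 1e-12))
  ## ladder is recorded with one row per tried weight
  expect_true(all(c("weight", "d95_gy", "flv_mean_gy") %in%
                    names(spare$ladder)))
  expect_gte(nrow(spare$ladder), 1)
})

test_that("the sparing ladder respects its floor and degenerate cases", {
  setup <- small_planning_setup(seed = 4, planning_shape = c(24, 24, 8))
  std <- optimize_plan(setup$influence, setup$structures, setup$objectives)
  ## d95_floor = 0: the largest ladder weight is returned
  s0 <- auto_sparing_weight(setup$influence, setup$structures,
                            setup$objectives, d95_floor = 0,
                            options = list(ladder_start = 10,
                                           ladder_steps = 3),
                            standard_plan = std)
  expect_equal(s0$sparing_weight, 10 * 2^2)
  ## empty FLV: the standard plan comes back flagged
  st2 <- setup$structures
  st2$masks$flv <- st2$masks$flv & FALSE
  s1 <- auto_sparing_weight(setup$influence, st2, setup$objectives,
                            d95_floor = 0.95 * 50, standard_plan = std)
  expect_false(s1$sparing_applied)
  expect_identical(s1$fluence, std$fluence)
  ## an impossible floor also falls back to the standard plan
  s2 <- auto_sparing_weight(setup$influence, setup$structures,
                            setup$objectives, d95_floor = 1e6,
                            options = list(ladder_start = 10,
                                           ladder_steps = 2),
                            standard_plan = std)
  expect_false(s2$sparing_applied)
  expect_identical(s2$fluence, std$fluence)
})

test_that("prescription tiers are walked down until the liver cap is met", {
  setup <- small_planning_setup(seed = 6, planning_shape = c(24, 24, 8))
  ## a single-tier list is returned regardless of the cap
  one <- select_prescription(setup$influence, setup$structures,
                             prescription_tiers(list(
                               list(rx_gy = 50, lmd_limit_gy = 1e-6))),
                             setup$objectives)
  expect_equal(one$rx_gy, 50)
  expect_false(one$met_lmd)
  ## an unreachable top tier drops to the lower prescription
  two <- select_prescription(setup$influence, setup$structures,
                             prescription_tiers(list(
                               list(rx_gy = 50, lmd_limit_gy = 1e-6),
                               list(rx_gy = 40, lmd_limit_gy = 50))),
                             setup$objectives)
  expect_equal(two$rx_gy, 40)
  expect_equal(two$tier, 2)
  expect_true(two$met_lmd)
  ## a generous cap keeps the top tier (the common case)
  top <- select_prescription(setup$influence, setup$structures,
                             prescription_tiers(), setup$objectives)
  expect_equal(top$rx_gy, 50)
  expect_true(top$met_lmd)
  expect_error(prescription_tiers(list(list(rx_gy = 40, lmd_limit_gy = 1),
                                       list(rx_gy = 50, lmd_limit_gy = 2))),
               "decreasing")
})

test_that("rescaling to a target D95 is exact and metric-linear", {
  setup <- small_planning_setup(seed = 5, planning_shape = c(24, 24, 8))
  std <- optimize_plan(setup$influence, setup$structures, setup$objectives)
  ptv <- setup$structures$masks$ptv
  d95 <- dose_at_volume_percent(std$dose, ptv, 95)
  same <- rescale_to_d95(std, ptv, d95)
  expect_equal(same$dose$data, std$dose$data, tolerance = 1e-12)
  dbl <- rescale_to_d95(std, ptv, 2 * d95)
  expect_equal(dose_at_volume_percent(dbl$dose, ptv, 95), 2 * d95,
               tolerance = 1e-6 * d95)
  ## all DVH D-metrics double with the dose
  flv <- setup$structures$masks$flv
  expect_equal(mean_dose(dbl$dose, flv), 2 * mean_dose(std$dose, flv),
               tolerance = 1e-9)
  expect_equal(dose_at_volume_cc(dbl$dose, ptv, 0.5),
               2 * dose_at_volume_cc(std$dose, ptv, 0.5), tolerance = 1e-9)
  zero <- std; zero$dose$data[] <- 0
  expect_error(rescale_to_d95(zero, ptv, 50), "zero")
})
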