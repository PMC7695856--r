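test_that("spoiled-GRE signal has the correct limits and closed-form value", {
  proto <- acquisition_protocol()
  # vanishing flip angle: signal goes to zero
  tiny <- acquisition_protocol(flip_angle = 1e-9)
  expect_lt(spgr_signal(12, 40, tiny), 1e-9)
  # saturation limit: r1 -> Inf at te = 0 gives m0 * sin(theta)
  p0 <- acquisition_protocol(te = 0)
  expect_equal(spgr_signal(1e9, 0, p0, m0 = 2), 2 * sin(p0$flip_angle),
               tolerance = 1e-12)
  # frozen value from an independently coded evaluation of the closed form
  expect_equal(spgr_signal(12.48, 60, proto, m0 = 1), 0.17207329218296977,
               tolerance = 1e-12)
})

test_that("signal is monotone in the relaxation rates", {
  proto <- acquisition_protocol()
  r1 <- seq(0.5, 40, length.out = 60)
  s <- spgr_signal(r1, 30, proto)
  expect_true(all(diff(s) > 0))
  r2 <- seq(0, 800, length.out = 60)
  s <- spgr_signal(5, r2, proto)
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("aggregation schedule validates its phase indices", {
  expect_error(aggregation_schedule(t_formation = 5L, t_clearance = 5L),
               "precede")
  expect_error(aggregation_schedule(t_clearance = 7L), "t_formation")
  expect_error(aggregation_schedule(-3, 10, 10), "r2agg_elevation")
  s <- aggregation_schedule(10, 300, 60, 6L, 12L)
  expect_s3_class(s, "aggregation_schedule")
})

test_that("voxel without aggregation gives a nondecreasing enhancement curve", {
  vm <- voxel_model(kinetic_params(0.045, 0.059), aggregation_schedule(),
                    v23 = 1)
  s <- simulate_voxel(vm, acquisition_protocol(), relaxivity())
  expect_true(all(diff(s$values) >= -1e-12))
  # and equals the pure-C2 SPGR curve
  cc <- solve_compartments(vm$kinetics, s$frame_times)
  rel <- relaxivity()
  ref <- spgr_signal(rel$baseline_r1 + rel$r1 * cc$c2,
                     rel$baseline_r2star + rel$r2 * cc$c2,
                     acquisition_protocol())
  expect_equal(s$values, ref, tolerance = 1e-12)
})

test_that("raising the reduction-phase aggregate rate only lowers the reduction window", {
  proto <- acquisition_protocol()
  mk <- function(rr) simulate_voxel(
    voxel_model(kinetic_params(0.045, 0.059),
                aggregation_schedule(15, rr, 70, 6L, 12L), v23 = 0.6),
    proto, relaxivity())$values
  lo <- mk(200); hi <- mk(500)
  inside <- 6:11
  expect_true(all(hi[inside] < lo[inside]))
  expect_equal(hi[-inside], lo[-inside], tolerance = 1e-12)
})

test_that("simulated signal scales exactly with m0", {
  proto <- acquisition_protocol()
  base <- voxel_model(kinetic_params(0.03, 0.08),
                      aggregation_schedule(10, 400, 80, 5L, 11L), v23 = 0.4)
  s1 <- simulate_voxel(base, proto, relaxivity())$values
  base$m0 <- 7.25
  s2 <- simulate_voxel(base, proto, relaxivity())$values
  expect_equal(s2, 7.25 * s1, tolerance = 1e-12)
})

test_that("typical parameters give a three-phase curve with its minimum in the reduction window", {
  vm <- voxel_model(kinetic_params(0.045, 0.059),
                    aggregation_schedule(1000 / 63.3, 1000 / 2.7, 1000 / 13.6,
                                         6L, 12L), v23 = 0.75)
  s <- simulate_voxel(vm, acquisition_protocol(), relaxivity())
  i <- which.min(s$values)
  expect_gte(i, 6L)
  expect_lt(i, 12L)
  # reduction attenuation well above 50%
  expect_lt(min(s$values) / max(s$values[1:5]), 0.5)
})
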