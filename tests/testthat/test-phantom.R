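test_that("noise-free phantom voxels equal the forward model of their ground truth", {
  ph <- generate_phantom(small_phantom_cfg(snr = Inf), seed = 2)
  tr <- ph$truth
  idx <- which(tr$zone >= 2)
  flat <- matrix(ph$series, prod(dim(tr$zone)), 20)
  set.seed(8)
  for (i in sample(idx, 12)) {
    vm <- voxel_model(
      kinetic_params(tr$k12[i], tr$k23[i], c1 = ph$cfg$c1),
      aggregation_schedule(tr$r2agg_elevation[i], tr$r2agg_reduction[i],
                           tr$r2agg_recovery[i], tr$t_formation[i],
                           tr$t_clearance[i]),
      v23 = tr$v23[i], m0 = tr$m0[i])
    expect_equal(flat[i, ], simulate_voxel(vm, ph$cfg$protocol, ph$cfg$rel)$values,
                 tolerance = 1e-12)
  }
  # background voxels stay dark without noise
  expect_true(all(flat[tr$zone == 0, ] == 0))
})

test_that("phantom generation is bit-reproducible and seed-sensitive", {
  a <- generate_phantom(small_phantom_cfg(), seed = 11)
  b <- generate_phantom(small_phantom_cfg(), seed = 11)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(small_phantom_cfg(), seed = 12)
  expect_false(identical(a$series, c$series))
})

test_that("ground truth lies inside the default fitting grid", {
  g <- parameter_grid("default")
  ph <- generate_phantom(phantom_config(), seed = 5)
  idx <- which(ph$truth$zone >= 2)
  expect_true(all(ph$truth$k12[idx] >= min(g$k12) &
                  ph$truth$k12[idx] <= max(g$k12)))
  expect_true(all(ph$truth$k23[idx] >= min(g$k23) &
                  ph$truth$k23[idx] <= max(g$k23)))
  expect_true(all(ph$truth$v23[idx] >= min(g$v23) &
                  ph$truth$v23[idx] <= max(g$v23)))
  expect_true(all(ph$truth$r2agg_reduction[idx] >
                  pmax(ph$truth$r2agg_elevation[idx],
                       ph$truth$r2agg_recovery[idx])))
  # formation always precedes clearance
  expect_true(all(ph$truth$t_formation[idx] < ph$truth$t_clearance[idx]))
})

test_that("the Rician noise level matches the configured SNR", {
  cfg <- phantom_config(snr = 20)
  noisy <- generate_phantom(cfg, seed = 21)
  clean <- generate_phantom(phantom_config(snr = Inf), seed = 21)
  idx <- which(noisy$truth$zone >= 2)
  fn <- matrix(noisy$series, length(noisy$truth$zone), 20)[idx, ]
  fc <- matrix(clean$series, length(clean$truth$zone), 20)[idx, ]
  expect_gt(length(fn), 1e4)
  sample_snr <- mean(fc) / sd(fn - fc)
  expect_lt(abs(sample_snr - 20) / 20, 0.1)
})

test_that("the placental mean curve shows the three-phase pattern", {
  ph <- generate_phantom(phantom_config(), seed = 1)
  mask <- ph$truth$zone >= 2
  flat <- matrix(ph$series, length(mask), 20)
  curve <- colMeans(flat[which(mask), ])
  i <- which.min(curve[3:20]) + 2L
  expect_gte(i, min(ph$truth$t_formation[which(mask)]))
  expect_lt(i, max(ph$truth$t_clearance[which(mask)]))
})

test_that("competition phantoms rise to a plateau and never form aggregates", {
  cp <- generate_competition_phantom(small_phantom_cfg(snr = Inf), seed = 7)
  idx <- which(cp$truth$zone >= 2)
  expect_true(all(cp$truth$r2agg_reduction[idx] == 0))
  expect_true(all(cp$truth$t_formation[idx] == -1L))
  flat <- matrix(cp$series, length(cp$truth$zone), 20)
  curve <- colMeans(flat[idx, ])
  expect_true(all(diff(curve[-1]) >= -1e-12))
  # paired generation: the contrast-only curve dips below the competition
  # curve inside the reduction window (the dip the competition eliminates)
  ph <- generate_phantom(small_phantom_cfg(snr = Inf), seed = 7)
  flat0 <- matrix(ph$series, length(ph$truth$zone), 20)
  c0 <- colMeans(flat0[idx, ])
  red <- 6:11
  expect_true(all(c0[red] < curve[red]))
  expect_lt(min(c0[red] / curve[red]), 0.5)
  # suppression 1 with aggregation disabled reproduces the contrast phantom
  same <- generate_competition_phantom(small_phantom_cfg(snr = Inf), seed = 7,
                                       suppression = 1)
  noagg <- generate_phantom(small_phantom_cfg(snr = Inf), seed = 7,
                            aggregation = FALSE)
  expect_identical(same$series, noagg$series)
})

test_that("degenerate phantom geometry is rejected", {
  expect_error(phantom_config(r_c1 = 10, r_labyrinth = 8, r_junctional = 12,
                              r_decidua = 22), "increasing")
  expect_error(generate_phantom(phantom_config(shape = c(4L, 4L, 1L))),
               "no placental voxels")
})

test_that("fluorescence fixtures are seeded, phase-ordered and separated", {
  a <- generate_fluorescence_fixture("reduction", seed = 13)
  b <- generate_fluorescence_fixture("reduction", seed = 13)
  expect_identical(a$green, b$green)
  expect_identical(a$blue, b$blue)
  ele <- generate_fluorescence_fixture("elevation", seed = 13)
  expect_gt(sum(a$truth$area_um2) / a$placenta_area_um2,
            sum(ele$truth$area_um2) / ele$placenta_area_um2)
  # guaranteed separation: pairwise centre distances exceed the radii sums
  ctr <- as.matrix(a$truth[, c("x", "y")])
  if (nrow(ctr) > 1) {
    dm <- as.matrix(dist(ctr))
    rs <- outer(a$truth$radius_px, a$truth$radius_px, "+")
    diag(dm) <- Inf
    expect_true(all(dm > rs))
  }
})
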