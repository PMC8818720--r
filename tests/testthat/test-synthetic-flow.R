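test_that("Poiseuille field has the closed-form wall WSS and centreline peak", {
  m <- steady_model(R = 10, Vmax = 1)
  fld <- poiseuille_field(m, centerline_straight(120, 60), 10)
  # wall WSS = 2 mu Vmax / R = 2 * 4e-3 * 1 / 0.01 = 0.8 Pa
  expect_equal(wall_wss(fld, 0, R = 10), 0.8)
  # centreline velocity equals s(t) * Vmax
  expect_equal(drop(fld$fun(rbind(c(0, 0, 60)), 0)), c(0, 0, 1))
  # outside the lumen the field vanishes
  expect_equal(drop(fld$fun(rbind(c(10.5, 0, 60)), 0)), c(0, 0, 0))
})

test_that("pulsatile scaling follows the waveform, zero flow gives zero WSS", {
  wf <- waveform_raised_cosine(cycle = 710, t_peak = 150, width = 300,
                               baseline = 0)
  m <- flow_model(R = 10, Vmax_peak = 2, waveform = wf)
  fld <- poiseuille_field(m, centerline_straight(120, 60), 10)
  expect_equal(wf(150), 1)
  expect_equal(wall_wss(fld, 150, 10), 2 * 4e-3 * 2 / 0.01)
  expect_equal(wf(600), 0)  # diastole with zero baseline
  expect_equal(wall_wss(fld, 600, 10), 0)
  expect_equal(max(abs(fld$fun(rbind(c(3, 2, 50)), 600))), 0)
})

test_that("blunt power-law profile has wall WSS p mu Vmax / R", {
  m <- steady_model()
  fld <- power_law_field(m, centerline_straight(120, 60), 10, exponent = 9)
  expect_equal(wall_wss(fld, 0, 10), 9 * 4e-3 * 1 / 0.01)
  # plug-like: near the axis the profile is nearly flat
  u0 <- fld$fun(rbind(c(0, 0, 60)), 0)[3]
  u3 <- fld$fun(rbind(c(3, 0, 60)), 0)[3]
  expect_gt(u3 / u0, 0.99)
})

test_that("oscillating series hit the OSI closed forms", {
  m <- flow_model()
  # f = 0.5: full reversal, 101 intervals put the flip mid-interval
  s05 <- oscillating_wss_series(m, 0.5, n_frames = 102)
  o <- osi(s05)
  expect_equal(max(abs(o$values[o$mask] - 0.5)), 0, tolerance = 1e-9)
  # f = 0: constant direction
  s0 <- oscillating_wss_series(m, 0, n_frames = 101)
  expect_equal(max(abs(osi(s0)$values)), 0, tolerance = 1e-12)
  # f = 0.25 with the flip mid-interval: OSI = 0.25
  s25 <- oscillating_wss_series(m, 0.25, n_frames = 103)
  o25 <- osi(s25)
  expect_equal(max(abs(o25$values[o25$mask] - 0.25)), 0, tolerance = 1e-9)
})

test_that("voxelization samples the field at voxel centres and seeds noise", {
  m <- steady_model()
  const <- velocity_source_analytic(function(p, t)
    matrix(rep(c(0.2, -0.1, 0.4), each = nrow(p)), ncol = 3))
  fld <- list(source = const)
  class(fld) <- "flow_field"
  bbox <- rbind(c(0, 0, 0), c(12, 12, 12))
  g <- voxelize(fld, grid_spec(dx = 2.4), bbox)
  expect_equal(dim(g$values)[1:3], c(5L, 5L, 5L))
  expect_equal(max(abs(g$values[, , , 1] - 0.2)), 0, tolerance = 1e-12)
  # seeded noise: reproducible, right scale, unbiased
  gs1 <- voxelize(fld, grid_spec(dx = 1.2, noise_sd_frac = 0.02, seed = 9),
                  rbind(c(0, 0, 0), c(60, 60, 60)))
  gs2 <- voxelize(fld, grid_spec(dx = 1.2, noise_sd_frac = 0.02, seed = 9),
                  rbind(c(0, 0, 0), c(60, 60, 60)))
  expect_identical(gs1$values, gs2$values)
  noise <- gs1$values[, , , 2] + 0.1
  n <- length(noise)
  expect_lt(abs(sd(noise) - 0.03), 0.03 * 0.02)       # SD = 2% of venc 1.5
  expect_lt(abs(mean(noise)), 3 * 0.03 / sqrt(n))     # unbiased within 3 SE
  expect_error(voxelize(fld, grid_spec(), rbind(c(0, 0, 0), c(0, 1, 1))),
               "degenerate")
})

test_that("voxelized sheet values converge to analytic values as dx shrinks", {
  fx <- poiseuille_fixture()
  bbox <- rbind(c(-13, -13, -3), c(13, 13, 123))
  errs <- sapply(c(2.4, 1.2, 0.6), function(dx) {
    g <- voxelize(fx$field, grid_spec(dx = dx), bbox)
    sh <- sample_velocity_sheet(g, fx$surface, 1.0, 0, fx$normals)
    mean(abs(sh$values[, , 3][sh$mask] - 0.19))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("the dataset splits by geometry and carries exact labels", {
  ds <- small_dataset()
  expect_length(ds$cases, 7)
  expect_length(intersect(ds$split$train, c(ds$split$val, ds$split$test)), 0)
  expect_equal(ds$distances, c(0.3, 0.5, 0.6, 0.8, 1.0, 2.0))
  case <- ds$cases[[1]]
  peak <- which.max(case$model$waveform(case$times))
  lab <- case$labels[[peak]]
  # straight-tube labels match 2 mu s Vmax / R with the local station radius
  v <- 47L
  Rloc <- case$field$radius[
    wallshear:::nn_query(rbind(case$surface$nodes[1, v, ]),
                         case$field$centerline)$index]
  expected <- 2 * case$model$mu * case$model$waveform(case$times[peak]) *
    case$model$Vmax_peak / (Rloc * 1e-3)
  mag <- wallshear:::flatmap_magnitude(lab)
  expect_equal(unname(mag[, v]), rep(expected, 48), tolerance = 1e-9)
  # geometries are distinct
  r1 <- ds$cases[[1]]$model$R
  r2 <- ds$cases[[2]]$model$R
  expect_false(isTRUE(all.equal(r1, r2)))
})
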