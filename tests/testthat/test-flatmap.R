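test_that("flatmap construction validates dimensions and mask", {
  fm <- flatmap(array(1, c(4, 5, 3)))
  expect_equal(dim(fm), c(4L, 5L, 3L))
  expect_true(all(fm$mask))
  expect_error(flatmap(array(1, c(4, 5, 3)), mask = matrix(TRUE, 3, 5)),
               "mask")
  expect_error(flatmap(array(1, c(4, 5, 3)), channel_names = "x"),
               "channel_names")
})

test_that("inward normals of a cylinder point radially inward with unit length", {
  surf <- cylinder_surface()
  nr <- inward_normals(surf)
  n <- matrix(nr$values, prod(dim(surf)[1:2]), 3)
  p <- matrix(surf$nodes, prod(dim(surf)[1:2]), 3)
  radial <- -cbind(p[, 1], p[, 2], 0)
  radial <- radial / sqrt(rowSums(radial^2))
  expect_lt(max(abs(sqrt(rowSums(n^2)) - 1)), 1e-6)
  # interior rings: exactly radial; end rings may tilt slightly
  expect_gt(min(rowSums(n * radial)), 0.99)
})

test_that("curved-tube normals point toward the local centerline", {
  cl <- centerline_arc(60, pi / 2, 120)
  surf <- build_coarse_template(48, 93, cl, 8)
  nr <- inward_normals(surf)
  cl93 <- wallshear:::resample_centerline(cl, 93)
  inward <- array(0, dim(surf$nodes))
  for (k in 1:3)
    inward[, , k] <- matrix(cl93[, k], 48, 93, byrow = TRUE) -
      surf$nodes[, , k]
  inward <- inward / array(sqrt(apply(inward^2, c(1, 2), sum)),
                           dim(surf$nodes))
  dots <- apply(nr$values * inward, c(1, 2), sum)
  expect_gt(min(dots), 0.99)
})

test_that("velocity sheets reproduce the Poiseuille closed form", {
  fx <- poiseuille_fixture()
  # u(d) = Vmax (1 - (R-d)^2/R^2): 0.19 at d = 1, 0.36 at d = 2 (R = 10)
  expect_equal(max(abs(fx$sheet1$values[, , 3] - 0.19)), 0, tolerance = 1e-9)
  expect_equal(max(abs(fx$sheet2$values[, , 3] - 0.36)), 0, tolerance = 1e-9)
  expect_equal(max(abs(fx$sheet1$values[, , 1:2])), 0, tolerance = 1e-9)
  expect_error(sample_velocity_sheet(fx$field$source, fx$surface, 0),
               "no-slip")
})

test_that("grid sheet sampling is exact for constant and affine fields", {
  surf <- cylinder_surface()
  ax <- seq(-15, 15, by = 2)
  az <- seq(-5, 125, by = 2)
  grid <- array(0, c(length(ax), length(ax), length(az), 3))
  grid[, , , 1] <- 0.5
  src <- velocity_source_grid(grid, dx = 2, origin = c(-15, -15, -5))
  sh <- sample_velocity_sheet(src, surf, 1.5)
  expect_true(all(sh$mask))
  expect_equal(max(abs(sh$values[, , 1] - 0.5)), 0, tolerance = 1e-12)
  expect_equal(max(abs(sh$values[, , 2:3])), 0, tolerance = 1e-12)
  # affine field vy = 0.01 x + 0.02 z - 0.1: trilinear reproduces it exactly
  co <- as.matrix(expand.grid(x = ax, y = ax, z = az))
  grid2 <- array(0, dim(grid))
  grid2[, , , 2] <- array(0.01 * co[, 1] + 0.02 * co[, 3] - 0.1,
                          dim(grid)[1:3])
  src2 <- velocity_source_grid(grid2, dx = 2, origin = c(-15, -15, -5))
  sh2 <- sample_velocity_sheet(src2, surf, 1.0)
  pts <- matrix(surf$nodes, ncol = 3) +
    matrix(inward_normals(surf)$values, ncol = 3)
  expected <- 0.01 * pts[, 1] + 0.02 * pts[, 3] - 0.1
  expect_equal(as.vector(sh2$values[, , 2]), expected, tolerance = 1e-12)
})

test_that("out-of-grid queries are masked with a warning", {
  surf <- cylinder_surface()
  grid <- array(0.3, c(8, 8, 8, 3))
  src <- velocity_source_grid(grid, dx = 2, origin = c(-7, -7, 0))
  expect_warning(sh <- sample_velocity_sheet(src, surf, 1), "outside")
  expect_true(any(!sh$mask))
})

test_that("point-cloud sheets interpolate nearby samples", {
  surf <- cylinder_surface()
  set.seed(2)
  th <- runif(20000, 0, 2 * pi)
  r <- 10 * sqrt(runif(20000))
  pts <- cbind(r * cos(th), r * sin(th), runif(20000, 0, 120))
  vel <- cbind(0, 0, 1 - (r / 10)^2)
  src <- velocity_source_points(pts, vel)
  sh <- sample_velocity_sheet(src, surf, 2)
  expect_true(mean(abs(sh$values[, , 3][sh$mask] - 0.36)) < 0.05)
})

test_that("WSS label transfer follows nearest-neighbour within 5 mm", {
  surf <- cylinder_surface(n_U = 12, n_V = 24, length = 100)
  pts <- matrix(surf$nodes, ncol = 3)
  wss <- matrix(rep(c(1, 0, 0), each = nrow(pts)), ncol = 3)
  lab <- transfer_wss_labels(pts, wss, surf)
  expect_true(all(lab$mask))
  expect_equal(max(abs(lab$values[, , 1] - 1)), 0, tolerance = 1e-12)
  # nodes farther than the radius from every source point are masked
  far <- transfer_wss_labels(pts + 100, wss, surf, radius = 5)
  expect_false(any(far$mask))
  # nearest of two candidate points wins
  node <- surf$nodes[1, 5, ]
  two <- rbind(node + c(1, 0, 0), node + c(2, 0, 0))
  lab2 <- transfer_wss_labels(two, rbind(c(9, 9, 9), c(5, 5, 5)), surf)
  expect_equal(lab2$values[1, 5, ], c(9, 9, 9))
})

test_that("branch mask excludes ostia (strictly) and the first inlet rings", {
  surf <- cylinder_surface(n_U = 12, n_V = 24, length = 100)
  m0 <- build_branch_mask(surf)
  expect_false(any(m0[, 1:3]))
  expect_true(all(m0[, 4:24]))
  node <- surf$nodes[3, 10, ]
  m1 <- build_branch_mask(surf, list(list(center = node, radius = 5)))
  expect_false(m1[3, 10])
  d <- sqrt(apply(sweep(surf$nodes, 3, node)^2, c(1, 2), sum))
  expect_identical(unname(m1[, 4:24]), unname(d[, 4:24] >= 5))
  # a node exactly on the boundary stays valid
  ring_gap <- min(d[d > 0])
  m2 <- build_branch_mask(surf, list(list(center = node, radius = ring_gap)))
  expect_equal(sum(!m2[, 4:24]), 1L)  # only the centre node
})

test_that("the assembled network input has 15 ordered channels and an AND mask", {
  fx <- poiseuille_fixture()
  wall <- coordinate_flatmap(fx$surface)
  wall$mask[5, 7] <- FALSE
  in1 <- inner_coordinates(fx$surface, 1, fx$normals)
  in2 <- inner_coordinates(fx$surface, 2, fx$normals)
  inp <- assemble_input(wall, in1, in2, fx$sheet1, fx$sheet2)
  expect_equal(dim(inp)[3], 15L)
  expect_false(inp$mask[5, 7])
  expect_true(sum(!inp$mask) == 1L)
  # inner coordinates sit exactly d inside the wall
  off1 <- sqrt((inp$values[, , 4] - inp$values[, , 1])^2 +
                 (inp$values[, , 5] - inp$values[, , 2])^2 +
                 (inp$values[, , 6] - inp$values[, , 3])^2)
  off2 <- sqrt((inp$values[, , 7] - inp$values[, , 1])^2 +
                 (inp$values[, , 8] - inp$values[, , 2])^2 +
                 (inp$values[, , 9] - inp$values[, , 3])^2)
  expect_equal(max(abs(off1 - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(off2 - 2)), 0, tolerance = 1e-9)
  # swapped sheet order is rejected
  expect_error(assemble_input(wall, in2, in1, fx$sheet2, fx$sheet1),
               "closer")
})
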