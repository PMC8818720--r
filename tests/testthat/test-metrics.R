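const_series <- function(vec_by_frame, times, shape = c(3, 4), mask = NULL) {
  frames <- lapply(vec_by_frame, function(v) {
    vals <- array(0, c(shape, 3))
    for (k in 1:3) vals[, , k] <- v[k]
    flatmap(vals, mask = mask)
  })
  wss_series(frames, times)
}

test_that("TAWSS integrates piecewise profiles with the trapezoidal rule", {
  # constant |wss| = 2 Pa
  s <- const_series(rep(list(c(0, 0, 2)), 5), seq(0, 800, length.out = 5))
  expect_equal(unique(as.vector(tawss(s)$values)), 2)
  # two equal-duration plateaus at 1 and 3 Pa -> dense sampling averages to 2
  n <- 2001
  tt <- seq(0, 1000, length.out = n)
  vecs <- lapply(tt, function(t) c(0, 0, if (t < 500) 1 else 3))
  s2 <- const_series(vecs, tt)
  expect_equal(unique(as.vector(tawss(s2)$values)), 2, tolerance = 1e-3)
  expect_true(all(tawss(s2)$values >= 0))
  expect_error(wss_series(list(flatmap(array(1, c(2, 2, 3)))), 0), "2 frames")
})

test_that("OSI closed forms: 0 for constant direction, 0.5 for full reversal,
           0.25 for a quarter-cycle reversal", {
  tt <- seq(0, 710, length.out = 102)  # 101 intervals: flip mid-interval
  vecs <- lapply(tt, function(t) c(0, 0, if (t < 355) 1 else -1))
  o <- osi(const_series(vecs, tt))
  expect_equal(max(abs(o$values[o$mask] - 0.5)), 0, tolerance = 1e-9)
  # pulsatile magnitude, fixed direction
  tt2 <- seq(0, 710, length.out = 51)
  vecs2 <- lapply(tt2, function(t) c(0, 0, 1 + sin(2 * pi * t / 710)^2))
  o2 <- osi(const_series(vecs2, tt2))
  expect_equal(max(abs(o2$values)), 0, tolerance = 1e-12)
  # +1 Pa for 3T/4, -1 Pa for T/4
  tt3 <- seq(0, 1000, length.out = 103)  # flip at 750 ms mid-interval
  vecs3 <- lapply(tt3, function(t) c(0, 0, if (t < 750) 1 else -1))
  o3 <- osi(const_series(vecs3, tt3))
  expect_equal(max(abs(o3$values[o3$mask] - 0.25)), 0, tolerance = 1e-9)
})

test_that("OSI stays in [0, 0.5] and the integrals are time-reversal
           symmetric on random series", {
  set.seed(31)
  for (rep in 1:5) {
    tt <- sort(runif(12, 0, 700))
    frames <- lapply(seq_along(tt), function(i)
      flatmap(array(rnorm(3 * 4 * 3), c(3, 4, 3))))
    s <- wss_series(frames, tt)
    o <- osi(s)
    expect_true(all(o$values[o$mask] >= -1e-12))
    expect_true(all(o$values[o$mask] <= 0.5 + 1e-12))
    # reverse time
    sr <- wss_series(rev(frames), sort(max(tt) - tt))
    expect_equal(osi(sr)$values, o$values, tolerance = 1e-12)
    expect_equal(tawss(sr)$values, tawss(s)$values, tolerance = 1e-12)
  }
})

test_that("masked nodes contribute to no metric", {
  set.seed(5)
  mask <- matrix(TRUE, 3, 4); mask[1, 1] <- FALSE
  mk <- function(seed) {
    set.seed(seed)
    flatmap(array(rnorm(36), c(3, 4, 3)), mask = mask)
  }
  a <- mk(1); b <- mk(2)
  fe <- frame_errors(a, b)
  # perturb the masked node wildly
  a2 <- a; a2$values[1, 1, ] <- 1e6
  b2 <- b; b2$values[1, 1, ] <- -1e6
  fe2 <- frame_errors(a2, b2)
  expect_identical(fe, fe2)
  s <- wss_series(list(a, b), c(0, 100))
  s2 <- wss_series(list(a2, b2), c(0, 100))
  expect_equal(tawss(s)$values[mask], tawss(s2)$values[mask])
  expect_equal(osi(s)$values[mask], osi(s2)$values[mask])
})

test_that("frame error metrics match their definitions", {
  set.seed(8)
  ref <- flatmap(array(rnorm(48 * 3, sd = 2), c(4, 12, 3)))
  expect_equal(frame_errors(ref, ref)$mae, 0)
  expect_equal(frame_errors(ref, ref)$pearson, 1)
  expect_equal(frame_errors(ref, ref)$rel_error, 0)
  # uniform +1 Pa shift of the magnitude image: MAE 1, r stays 1
  mag <- wallshear:::flatmap_magnitude(ref)
  shift <- ref
  for (k in 1:3) shift$values[, , k] <- ref$values[, , k] * (mag + 1) / mag
  fe <- frame_errors(shift, ref)
  expect_equal(fe$mae, 1, tolerance = 1e-9)
  expect_equal(fe$pearson, 1, tolerance = 1e-9)
  # rel error: uniform |delta| = 1 with peak 4 -> 25%
  vals <- array(0, c(2, 3, 3)); vals[, , 3] <- c(4, 2, 1, 3, 2, 2)
  r2 <- flatmap(vals)
  p2 <- r2; p2$values[, , 3] <- p2$values[, , 3] + 1
  expect_equal(frame_errors(p2, r2)$rel_error, 25)
  # constant reference magnitude: Pearson undefined
  cst <- flatmap(array(rep(c(1, 0, 0), each = 6), c(2, 3, 3)))
  expect_warning(fe3 <- frame_errors(p2, cst), "undefined")
  expect_true(is.na(fe3$pearson))
})

test_that("ICC(A,1) matches a brute-force two-way ANOVA oracle", {
  # independent oracle: mean squares from aov() on the long-format table
  icc_oracle <- function(x, y) {
    n <- length(x); k <- 2
    df <- data.frame(score = c(x, y),
                     subj = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(score ~ subj + rater, data = df))[[1]]$`Mean Sq`
    MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
    (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  }
  set.seed(13)
  x <- c(2.1, 3.4, 4.4, 5.9, 7.2, 8.0)
  y <- c(2.4, 3.1, 4.9, 5.5, 7.8, 8.3)
  expect_equal(icc_a1(x, y), icc_oracle(x, y), tolerance = 1e-12)
  for (r in 1:4) {
    a <- rnorm(10); b <- a + rnorm(10, sd = 0.3) + 0.2
    expect_equal(icc_a1(a, b), icc_oracle(a, b), tolerance = 1e-10)
  }
  # perfect agreement
  z <- c(1, 2, 3, 4.5)
  expect_equal(icc_a1(z, z), 1)
  # a constant offset lowers ICC below the (perfect) Pearson correlation
  expect_lt(icc_a1(z, z + 10), 1)
  expect_equal(cor(z, z + 10), 1)
})

test_that("Bland-Altman statistics match the two-point closed form", {
  expect_equal(bland_altman(c(1, 2), c(1, 2)),
               list(bias = 0, sd = 0, loa_low = 0, loa_high = 0))
  # diffs {-1, 0}
  ba <- bland_altman(c(1, 2), c(0, 2))
  expect_equal(ba$bias, -0.5)
  expect_equal(ba$sd, sd(c(-1, 0)))
  expect_equal(ba$loa_low, -0.5 - 1.96 * ba$sd)
  expect_equal(ba$loa_high, -0.5 + 1.96 * ba$sd)
  # bias invariant to a common constant
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(bland_altman(x + 7, y + 7)$bias, bland_altman(x, y)$bias,
               tolerance = 1e-12)
})

test_that("OLS summary matches the normal-equation oracle", {
  # independent oracle: closed-form normal equations
  ols_oracle <- function(x, y) {
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    list(slope = beta[2], intercept = beta[1], r_squared = r2)
  }
  x <- c(1, 2, 3, 4, 5, 6.5, 8, 9.1)
  y <- c(1.2, 2.1, 2.8, 4.4, 5.1, 6.2, 8.5, 9.0)
  fit <- linreg_fit(x, y)
  orc <- ols_oracle(x, y)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, orc$r_squared, tolerance = 1e-12)
  # exact line y = 2x
  f2 <- suppressWarnings(linreg_fit(x, 2 * x))  # lm warns on a perfect fit
  expect_equal(f2$slope, 2)
  expect_equal(f2$r_squared, 1)
  # slope consistency under centred noise (seeded simulation)
  set.seed(77)
  xs <- runif(4000, 0, 10)
  ys <- xs + rnorm(4000, sd = 0.5)
  f3 <- linreg_fit(xs, ys)
  expect_equal(f3$slope, 1, tolerance = 0.02)
  expect_true(f3$r_squared >= 0 && f3$r_squared <= 1)
  expect_error(linreg_fit(rep(1, 5), 1:5), "variance")
})
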