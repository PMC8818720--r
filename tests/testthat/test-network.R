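test_that("periodic padding wraps rows and replicates columns", {
  x <- matrix(seq_len(20), 4, 5)
  p <- periodic_pad(x, 1)
  expect_equal(dim(p), c(6L, 7L))
  expect_equal(p[1, 2:6], x[4, ])       # row above top = bottom row
  expect_equal(p[6, 2:6], x[1, ])       # row below bottom = top row
  expect_equal(p[2:5, 1], x[, 1])       # left column duplicated
  expect_equal(p[2:5, 7], x[, 5])       # right column duplicated
  # constant input stays constant
  expect_equal(unique(as.vector(periodic_pad(matrix(3, 4, 4), 1))), 3)
  expect_error(periodic_pad(x, 4), "smaller")
})

test_that("forward pass maps 48x48x15 patches to 48x48x3, deterministically", {
  net <- init_network(net_config(filters = c(2, 3, 4), bottleneck = 4), seed = 1)
  set.seed(2)
  x <- array(rnorm(48 * 48 * 2 * 15), c(48, 48, 2, 15))
  out <- net_forward(net, x)
  expect_equal(dim(out), c(48L, 48L, 2L, 3L))
  # batch of b patches gives b outputs; single-patch input is promoted
  out1 <- net_forward(net, x[, , 1, , drop = TRUE])
  expect_equal(dim(out1), c(48L, 48L, 3L))
  expect_equal(out1, out[, , 1, ], tolerance = 1e-12)
  # eval-mode determinism
  expect_identical(out, net_forward(net, x))
  # same seed, same initialization
  net2 <- init_network(net_config(filters = c(2, 3, 4), bottleneck = 4), seed = 1)
  expect_identical(net$params, net2$params)
  expect_error(net_forward(net, x[, , , 1:14, drop = FALSE]), "channels")
})

test_that("SSIM identities hold", {
  set.seed(3)
  x <- matrix(runif(48 * 48), 48)
  expect_equal(ssim(x, x), 1, tolerance = 1e-6)
  expect_equal(1 - ssim(x, x), 0, tolerance = 1e-6)  # l_SSIM of identical patches
  # constant images follow the luminance closed form
  a <- 0.4; b <- 0.9; L <- 1
  C1 <- (0.01 * L)^2
  expect_equal(ssim(matrix(a, 16, 16), matrix(b, 16, 16), L),
               (2 * a * b + C1) / (a^2 + b^2 + C1), tolerance = 1e-12)
  expect_error(ssim(x, x, L = 0), "positive")
})

test_that("SSIM analytic gradient matches finite differences", {
  set.seed(4)
  x <- matrix(runif(14 * 14), 14)
  y <- matrix(runif(14 * 14), 14)
  g <- wallshear:::ssim_grad_x(x, y, L = 1, window = 11)
  eps <- 1e-6
  idx <- rbind(c(1, 1), c(7, 7), c(14, 14), c(3, 12), c(10, 2))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    xp <- x; xp[i, j] <- xp[i, j] + eps
    xm <- x; xm[i, j] <- xm[i, j] - eps
    fd <- (ssim(xp, y, 1) - ssim(xm, y, 1)) / (2 * eps)
    expect_equal(g[i, j], fd, tolerance = 1e-6)
  }
})

test_that("loss identities: zero at truth, exact L2 term, mask invariance", {
  set.seed(5)
  truth <- array(rnorm(48 * 48 * 3, sd = 0.5), c(48, 48, 3))
  mask <- matrix(runif(48 * 48) > 0.15, 48, 48)
  ls0 <- net_loss(truth, truth, mask, lambda = 0)
  expect_equal(ls0$loss, 0, tolerance = 1e-9)
  # lambda > 0: loss = lambda/(2m) * sum(w^2) exactly
  net <- init_network(net_config(filters = c(2, 3, 4), bottleneck = 4), seed = 1)
  lsw <- net_loss(truth, truth, mask, lambda = 1e-2, m = 16,
                  params = net$params)
  w2 <- sum(vapply(net$params, function(p) sum(p$W^2), numeric(1)))
  expect_equal(lsw$loss, 1e-2 / (2 * 16) * w2, tolerance = 1e-9)
  # perturbing only masked pixels leaves the loss unchanged
  pred <- truth + array(rnorm(length(truth), sd = 0.2), dim(truth))
  ls1 <- net_loss(pred, truth, mask, lambda = 0)
  pred2 <- pred; truth2 <- truth
  bad <- which(!mask, arr.ind = TRUE)
  for (r in seq_len(nrow(bad))) {
    pred2[bad[r, 1], bad[r, 2], ] <- 1e5
    truth2[bad[r, 1], bad[r, 2], ] <- -1e5
  }
  ls2 <- net_loss(pred2, truth2, mask, lambda = 0)
  expect_equal(ls1$loss, ls2$loss, tolerance = 1e-12)
  expect_error(net_loss(pred, truth, mask & FALSE), "empty")
})

test_that("network loss gradient matches finite differences end to end", {
  set.seed(6)
  cfg <- net_config(filters = c(2, 3, 4), bottleneck = 4, patch = 16)
  net <- init_network(cfg, seed = 3)
  x <- array(rnorm(16 * 16 * 2 * 15), c(16, 16, 2, 15))
  y <- array(rnorm(16 * 16 * 2 * 3, sd = 0.5), c(16, 16, 2, 3))
  msk <- array(runif(16 * 16 * 2) > 0.2, c(16, 16, 2))
  fw <- net_forward(net, x, train = TRUE, keep_cache = TRUE)
  ls <- net_loss(fw$out, y, msk, omega = 1.5, lambda = 0, m = 2,
                 want_grad = TRUE)
  g <- wallshear:::net_backward(net, fw$cache, ls$grad)
  lossfun <- function(net)
    net_loss(net_forward(net, x, train = TRUE), y, msk,
             omega = 1.5, lambda = 0, m = 2)$loss
  eps <- 1e-5
  for (nm in c("conv1", "conv6", "conv10", "out")) {
    np <- net; np$params[[nm]]$W[2] <- np$params[[nm]]$W[2] + eps
    nn <- net; nn$params[[nm]]$W[2] <- nn$params[[nm]]$W[2] - eps
    fd <- (lossfun(np) - lossfun(nn)) / (2 * eps)
    expect_equal(g[[nm]]$W[2], fd, tolerance = 1e-4)
  }
  for (nm in c("bn1", "bn7")) {
    np <- net; np$bn[[nm]]$gamma[1] <- np$bn[[nm]]$gamma[1] + eps
    nn <- net; nn$bn[[nm]]$gamma[1] <- nn$bn[[nm]]$gamma[1] - eps
    fd <- (lossfun(np) - lossfun(nn)) / (2 * eps)
    expect_equal(g[[nm]]$ggamma[1], fd, tolerance = 1e-4)
  }
})

test_that("augmentations act consistently on coordinates, vectors and labels", {
  ds <- small_dataset()
  smp <- wallshear:::case_sample(ds$cases[[1]], 2, c(5, 6))
  patch <- list(input = smp$input[, 1:48, ], label = smp$label[, 1:48, ],
                mask = smp$mask[, 1:48])
  # rotation preserves magnitudes of all vector triplets
  set.seed(9)
  cfg <- augment_config(translate = FALSE, max_roll = 0, noise_prob = 0)
  aug <- augment_sample(patch, cfg)
  for (ch in list(1:3, 10:12, 13:15)) {
    m0 <- sqrt(patch$input[, , ch[1]]^2 + patch$input[, , ch[2]]^2 +
                 patch$input[, , ch[3]]^2)
    m1 <- sqrt(aug$input[, , ch[1]]^2 + aug$input[, , ch[2]]^2 +
                 aug$input[, , ch[3]]^2)
    expect_equal(m1, m0, tolerance = 1e-9)
  }
  lm0 <- sqrt(patch$label[, , 1]^2 + patch$label[, , 2]^2 +
                patch$label[, , 3]^2)
  lm1 <- sqrt(aug$label[, , 1]^2 + aug$label[, , 2]^2 + aug$label[, , 3]^2)
  expect_equal(lm1, lm0, tolerance = 1e-9)
  # translation leaves velocities and labels bit-identical
  set.seed(10)
  cfgt <- augment_config(rotate = FALSE, max_roll = 0, noise_prob = 0)
  augt <- augment_sample(patch, cfgt)
  expect_identical(augt$input[, , 10:15], patch$input[, , 10:15])
  expect_identical(augt$label, patch$label)
  # pairwise wall-to-inner offsets survive translation
  expect_equal(augt$input[, , 4] - augt$input[, , 1],
               patch$input[, , 4] - patch$input[, , 1])
  # rolling shift by k then -k restores the sample
  r5 <- wallshear:::roll_rows(patch$input, 5)
  expect_identical(wallshear:::roll_rows(r5, -5), patch$input)
})

test_that("cosine annealing cycles between the configured bounds", {
  tc <- train_config(epochs = 30)
  expect_equal(cosine_lr(0, tc), 1e-4)
  expect_equal(cosine_lr(10, tc), 1e-4)   # cycle restart
  expect_lt(cosine_lr(9, tc), 1e-5)       # near the floor at cycle end
  expect_gt(cosine_lr(9, tc), 1e-7)
  lrs <- sapply(0:9, cosine_lr, cfg = tc)
  expect_true(all(diff(lrs) < 0))
})

test_that("sliding-window stitching covers the flatmap and respects masks", {
  net <- init_network(net_config(filters = c(2, 3, 4), bottleneck = 4), seed = 2)
  set.seed(11)
  mask <- matrix(runif(48 * 93) > 0.1, 48, 93)
  inp <- flatmap(array(rnorm(48 * 93 * 15), c(48, 93, 15)), mask = mask)
  out <- predict_flatmap(net, inp)
  expect_equal(dim(out), c(48L, 93L, 3L))
  expect_identical(out$mask, mask)
  # constant input: every window sees identical content, so the stride can
  # only matter through zero-padding edge effects inside each window; the
  # stitched results must agree to within 5% of the mean magnitude
  cst <- flatmap(array(rep(seq_len(15), each = 48 * 93) / 15,
                       c(48, 93, 15)))
  o1 <- predict_flatmap(net, cst, stride = 45)
  o2 <- predict_flatmap(net, cst, stride = 15)
  expect_lt(mean(abs(o1$values - o2$values)),
            0.05 * mean(abs(o2$values)))
  short <- flatmap(array(0, c(48, 40, 15)))
  expect_error(predict_flatmap(net, short), "smaller")
})

test_that("a short training run is seeded-deterministic and lowers the loss", {
  ds <- small_dataset()
  cfg <- net_config(filters = c(4, 6, 8), bottleneck = 8)
  tc <- train_config(epochs = 2, batch = 8, n_patches = 48, n_val = 8,
                     seed = 21)
  n1 <- train_network(ds, init_network(cfg, seed = 2), tc)
  n2 <- train_network(ds, init_network(cfg, seed = 2), tc)
  expect_equal(n1$history$train_loss[1], n2$history$train_loss[1])
  expect_identical(n1$params, n2$params)
  expect_lt(n1$history$train_loss[2], n1$history$train_loss[1])
})
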