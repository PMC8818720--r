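#' Network architecture configuration
#'
#' A U-Net-style patch estimator mapping the 15-channel geometry+velocity
#' input to the 3-channel WSS vector output. Three encoder and three decoder
#' blocks, each of two 3x3 convolutions with ReLU followed by batch
#' normalization at the block end; 2x2 max pooling downsamples, bilinear
#' interpolation upsamples, and skip connections concatenate encoder
#' features. Periodic padding (circumferential wrap, longitudinal edge
#' replication) is applied before the first two convolutions; interior
#' convolutions use zero padding. Patch height equals the 48-node template
#' circumference.
#'
#' Coordinate channels are scaled by a fixed factor (default 0.1, mm -> cm)
#' inside the model for numerical conditioning; the constants are part of the
#' configuration and stored with checkpoints.
#'
#' @param filters encoder filter counts per block (decoder mirrors them).
#' @param bottleneck filter count of the bottom block.
#' @param in_channels,out_channels input/output channel counts.
#' @param patch patch edge length (must equal the template circumference).
#' @param input_scale per-channel input scaling constants.
#' @return list of class `net_config`.
#' @export
net_config <- function(filters = c(64, 128, 256), bottleneck = 512,
                       in_channels = 15, out_channels = 3, patch = 48,
                       input_scale = c(rep(0.05, 9), rep(8, 6))) {
  stopifnot(length(filters) == 3, all(filters > 0), bottleneck > 0,
            length(input_scale) == in_channels, patch %% 8 == 0)
  structure(list(filters = filters, bottleneck = bottleneck,
                 in_channels = in_channels, out_channels = out_channels,
                 patch = patch, input_scale = input_scale),
            class = "net_config")
}

#' Reduced configuration for CPU-scale experiments
#'
#' Same architecture with small filter counts, suitable for training on a
#' single CPU within minutes.
#' @export
net_config_reduced <- function() {
  net_config(filters = c(8, 16, 32), bottleneck = 32)
}

#' Periodic padding of a flatmap patch
#'
#' Pads the circumferential (row, U) axis by wrapping -- the row above the
#' top row is the bottom row and vice versa -- and the longitudinal (column,
#' V) axis by replicating the first/last column. Accepts an `(H, W)` matrix
#' or an array whose first two dimensions are spatial.
#'
#' @param x matrix or array with spatial dimensions first.
#' @param p pad width (must be smaller than the patch height).
#' @return padded matrix/array, spatial dims `(H + 2p, W + 2p)`.
#' @export
periodic_pad <- function(x, p = 1) {
  d <- if (is.matrix(x)) dim(x) else dim(x)[1:2]
  H <- d[1]; W <- d[2]
  if (p >= H) stop("pad width must be smaller than the patch height")
  ri <- c((H - p + 1):H, 1:H, 1:p)
  ci <- c(rep(1L, p), 1:W, rep(W, p))
  if (is.matrix(x)) return(x[ri, ci, drop = FALSE])
  nd <- length(dim(x))
  if (nd == 3L) x[ri, ci, , drop = FALSE]
  else x[ri, ci, , , drop = FALSE]
}

zero_pad <- function(x, p = 1) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[-(1:2)]))
  if (length(d) == 3L) out[p + 1:d[1], p + 1:d[2], ] <- x
  else out[p + 1:d[1], p + 1:d[2], , ] <- x
  out
}

# ---- low-level layer ops on (H, W, N, C) arrays --------------------------

# cache of im2col gather indices and upsampling matrices, keyed by shape
.op_cache <- new.env(parent = emptyenv())

# linear indices so that xpad[idx] is the (H*W*N) x (k*k*cin) column matrix
# with column order (ci inner, di, dj outer), matching aperm(W, c(3,1,2,4))
im2col_idx <- function(d, k) {
  key <- paste0("i2c_", paste(d, collapse = "_"), "_", k)
  idx <- .op_cache[[key]]
  if (!is.null(idx)) return(idx)
  Hp <- d[1]; Wp <- d[2]; N <- d[3]; cin <- d[4]
  H <- Hp - k + 1L; W <- Wp - k + 1L
  rowbase <- outer(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"),
                   (seq_len(N) - 1L) * Hp * Wp, "+")
  dim(rowbase) <- NULL
  off <- integer(k * k * cin)
  p <- 1L
  for (dj in seq_len(k)) for (di in seq_len(k)) for (ci in seq_len(cin)) {
    off[p] <- (di - 1L) + (dj - 1L) * Hp + (ci - 1L) * Hp * Wp * N
    p <- p + 1L
  }
  idx <- outer(as.integer(rowbase), off, "+")
  .op_cache[[key]] <- idx
  idx
}

# He-style uniform fan-in init; small positive bias keeps ReLUs alive
# through the short, high-rate training schedules used on CPU.
conv_init <- function(cin, cout, k = 3, rng = stats::runif) {
  lim <- sqrt(6 / (k * k * cin))
  list(W = array(rng(k * k * cin * cout, -lim, lim), c(k, k, cin, cout)),
       b = rep(0.1, cout))
}

# x must already be padded; returns (H, W, N, Cout) with H = Hp - k + 1.
# im2col + one BLAS product; with keep_cols = TRUE the column matrix is
# returned for reuse in the backward pass.
conv_fwd <- function(x, par, keep_cols = FALSE) {
  k <- dim(par$W)[1]
  d <- dim(x); H <- d[1] - k + 1L; W <- d[2] - k + 1L
  N <- d[3]; cin <- d[4]; cout <- dim(par$W)[4]
  if (k == 1L) {
    Xc <- x
    dim(Xc) <- c(H * W * N, cin)
  } else {
    Xc <- x[im2col_idx(d, k)]
    dim(Xc) <- c(H * W * N, k * k * cin)
  }
  # column order is (di, dj) outer, cin inner -> rows of W permuted to match
  Wm <- aperm(par$W, c(3, 1, 2, 4))
  dim(Wm) <- c(k * k * cin, cout)
  acc <- Xc %*% Wm
  acc <- acc + rep(par$b, each = H * W * N)
  dim(acc) <- c(H, W, N, cout)
  if (keep_cols) list(out = acc, cols = Xc, dim_in = d) else acc
}

# backward: grad wrt padded input, W, b. The input gradient is itself a
# convolution of the (zero-padded) output gradient with the flipped kernel,
# which keeps all accumulation inside BLAS products.
conv_bwd <- function(cols, dim_in, par, gout) {
  k <- dim(par$W)[1]
  d <- dim(gout)
  cin <- dim(par$W)[3]; cout <- d[4]
  G <- gout
  dim(G) <- c(prod(d[1:3]), cout)
  gW <- crossprod(cols, G)                 # (k*k*cin) x cout, (cin,di,dj) rows
  dim(gW) <- c(cin, k, k, cout)
  gW <- aperm(gW, c(2, 3, 1, 4))
  Wf <- par$W[k:1, k:1, , , drop = FALSE]
  Wf <- aperm(Wf, c(1, 2, 4, 3))           # flipped, cin/cout swapped
  gp <- if (k > 1) zero_pad(gout, k - 1L) else gout
  gx <- conv_fwd(gp, list(W = Wf, b = numeric(cin)))
  list(gx = gx, gW = gW, gb = colSums(G))
}

# fold gradients at padded borders back onto the source pixels (p = 1)
unpad_grad <- function(gxp, type = c("zero", "periodic"), p = 1) {
  type <- match.arg(type)
  d <- dim(gxp); H <- d[1] - 2 * p; W <- d[2] - 2 * p
  if (type == "zero")
    return(gxp[p + 1:H, p + 1:W, , , drop = FALSE])
  # columns first: edge-replicated columns fold onto first/last column
  g <- gxp[, p + 1:W, , , drop = FALSE]
  g[, 1, , ] <- g[, 1, , ] + gxp[, 1, , ]
  g[, W, , ] <- g[, W, , ] + gxp[, W + 2 * p, , ]
  # rows: circular wrap
  out <- g[p + 1:H, , , , drop = FALSE]
  out[H, , , ] <- out[H, , , ] + g[1, , , ]
  out[1, , , ] <- out[1, , , ] + g[H + 2 * p, , , ]
  out
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  i1 <- seq(1, H, by = 2); i2 <- i1 + 1
  j1 <- seq(1, W, by = 2); j2 <- j1 + 1
  s <- list(x[i1, j1, , , drop = FALSE], x[i2, j1, , , drop = FALSE],
            x[i1, j2, , , drop = FALSE], x[i2, j2, , , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  which4 <- (s[[1]] == out) * 1L
  which4[which4 == 0 & s[[2]] == out] <- 2L
  which4[which4 == 0 & s[[3]] == out] <- 3L
  which4[which4 == 0] <- 4L
  list(out = out, which = which4, dim_in = d)
}

maxpool_bwd <- function(cache, gout) {
  d <- cache$dim_in
  gx <- array(0, d)
  i1 <- seq(1, d[1], by = 2); j1 <- seq(1, d[2], by = 2)
  for (q in 1:4) {
    sel <- cache$which == q
    gq <- gout * sel
    di <- if (q %in% c(2, 4)) 1L else 0L
    dj <- if (q %in% c(3, 4)) 1L else 0L
    gx[i1 + di, j1 + dj, , ] <- gx[i1 + di, j1 + dj, , ] + gq
  }
  gx
}

# bilinear x2 interpolation matrix (half-pixel convention, edge-clamped)
upsample_mat <- function(n_in) {
  key <- paste0("up_", n_in)
  U <- .op_cache[[key]]
  if (!is.null(U)) return(U)
  n_out <- 2L * n_in
  src <- (seq_len(n_out) - 0.5) / 2 + 0.5
  src <- pmin(pmax(src, 1), n_in)
  i0 <- pmin(floor(src), n_in - 1L)
  w1 <- src - i0
  U <- matrix(0, n_out, n_in)
  U[cbind(seq_len(n_out), i0)] <- 1 - w1
  U[cbind(seq_len(n_out), i0 + 1L)] <- U[cbind(seq_len(n_out), i0 + 1L)] + w1
  .op_cache[[key]] <- U
  U
}

# apply M (m x d1) along the first dimension of a 4D array
contract_dim1 <- function(M, x) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  y <- M %*% x
  dim(y) <- c(nrow(M), d[-1])
  y
}

# apply M (m x d2) along the second dimension of a 4D array
contract_dim2 <- function(M, x) {
  d <- dim(x)
  x <- aperm(x, c(2, 1, 3, 4))
  dim(x) <- c(d[2], d[1] * d[3] * d[4])
  y <- M %*% x
  dim(y) <- c(nrow(M), d[1], d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}

upsample_fwd <- function(x) {
  d <- dim(x)
  contract_dim2(upsample_mat(d[2]), contract_dim1(upsample_mat(d[1]), x))
}

upsample_bwd <- function(gout, dim_in) {
  contract_dim2(t(upsample_mat(dim_in[2])),
                contract_dim1(t(upsample_mat(dim_in[1])), gout))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

bn_fwd <- function(x, par, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(x); C <- d[4]
  xm <- matrix(x, ncol = C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    par$run_mean <- momentum * par$run_mean + (1 - momentum) * mu
    par$run_var <- momentum * par$run_var + (1 - momentum) * v
  } else {
    mu <- par$run_mean; v <- par$run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  y <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  list(out = array(y, d), par = par,
       cache = list(xhat = xhat, istd = istd, dim = d))
}

bn_bwd <- function(par, cache, gout) {
  d <- cache$dim; C <- d[4]
  m <- prod(d[1:3])
  gy <- matrix(gout, ncol = C)
  ggamma <- colSums(gy * cache$xhat)
  gbeta <- colSums(gy)
  gxhat <- sweep(gy, 2, par$gamma, "*")
  gx <- sweep(gxhat -
                matrix(colSums(gxhat) / m, m, C, byrow = TRUE) -
                cache$xhat * matrix(colSums(gxhat * cache$xhat) / m, m, C,
                                    byrow = TRUE),
              2, cache$istd, "*")
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

# ---- network assembly ----------------------------------------------------

#' Initialize the WSS estimator network
#'
#' @param config a [net_config()].
#' @param seed RNG seed for the (uniform fan-based) weight initialization.
#' @return list of class `wss_net` holding parameters and configuration.
#' @export
init_network <- function(config = net_config_reduced(), seed = 1) {
  f <- config$filters; fb <- config$bottleneck
  cin <- config$in_channels
  widths <- list(
    c(cin, f[1]), c(f[1], f[1]),           # enc1 (periodic-padded convs)
    c(f[1], f[2]), c(f[2], f[2]),          # enc2
    c(f[2], f[3]), c(f[3], f[3]),          # enc3
    c(f[3], fb), c(fb, fb),                # bottleneck
    c(fb + f[3], f[3]), c(f[3], f[3]),     # dec3
    c(f[3] + f[2], f[2]), c(f[2], f[2]),   # dec2
    c(f[2] + f[1], f[1]), c(f[1], f[1]))   # dec1
  params <- with_seed(seed, {
    p <- lapply(widths, function(w) conv_init(w[1], w[2]))
    p$out <- conv_init(f[1], config$out_channels, k = 1)
    p
  })
  names(params)[1:14] <- paste0("conv", 1:14)
  bn <- lapply(c(f[1], f[2], f[3], fb, f[3], f[2], f[1]), bn_init)
  names(bn) <- paste0("bn", 1:7)
  structure(list(config = config, params = params, bn = bn),
            class = "wss_net")
}

#' @export
print.wss_net <- function(x, ...) {
  cat(sprintf("<wss_net: filters %s | bottleneck %d | %d parameters>\n",
              paste(x$config$filters, collapse = "/"),
              x$config$bottleneck, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param net a `wss_net`.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, function(p) length(p$W) + length(p$b), numeric(1))) +
    sum(vapply(net$bn, function(b) 2 * length(b$gamma), numeric(1)))
}

# one conv (+ optional relu) with the given padding; returns out + cache
conv_block_fwd <- function(x, par, pad, relu = TRUE, keep_cache = TRUE) {
  xp <- if (pad == "periodic") periodic_pad(x, 1)
  else if (pad == "zero") zero_pad(x, 1) else x
  cf <- conv_fwd(xp, par, keep_cols = keep_cache)
  if (!keep_cache) cf <- list(out = cf)
  a <- if (relu) relu_fwd(cf$out) else cf$out
  list(out = a,
       cache = list(cols = cf$cols, dim_in = cf$dim_in, z = cf$out,
                    pad = pad, relu = relu))
}

conv_block_bwd <- function(par, cache, gout) {
  if (cache$relu) gout <- gout * (cache$z > 0)
  bw <- conv_bwd(cache$cols, cache$dim_in, par, gout)
  gx <- if (cache$pad == "none") bw$gx else unpad_grad(bw$gx, cache$pad)
  list(gx = gx, gW = bw$gW, gb = bw$gb)
}

#' Forward pass of the WSS estimator
#'
#' @param net a `wss_net` from [init_network()] or [train_network()].
#' @param x input array `(H, W, N, 15)` (a batch of flatmap patches; H and W
#'   must be divisible by 8) or `(H, W, 15)` for a single patch.
#' @param train logical: training mode (batch statistics) or evaluation mode
#'   (running statistics; deterministic).
#' @param keep_cache keep intermediate activations for the backward pass.
#' @return In evaluation mode, the `(H, W, N, 3)` prediction (Pa); with
#'   `keep_cache = TRUE`, a list `(out, cache, net)` (the net carries updated
#'   batch-norm running statistics in training mode).
#' @export
net_forward <- function(net, x, train = FALSE, keep_cache = FALSE) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3])
  d <- dim(x)
  if (d[4] != net$config$in_channels)
    stop(sprintf("expected %d input channels, got %d",
                 net$config$in_channels, d[4]))
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("spatial dims must be divisible by 8")
  if (!all(is.finite(x))) stop("input contains non-finite values")
  sc <- net$config$input_scale
  x <- x * rep(sc, each = prod(d[1:3]))
  P <- net$params; BN <- net$bn
  cc <- list()
  cbf <- function(x, par, pad, relu = TRUE)
    conv_block_fwd(x, par, pad, relu, keep_cache = keep_cache)
  pads <- c("periodic", "periodic", rep("zero", 12))
  # encoder
  b1a <- cbf(x, P$conv1, pads[1]); cc$c1 <- b1a$cache
  b1b <- cbf(b1a$out, P$conv2, pads[2]); cc$c2 <- b1b$cache
  n1 <- bn_fwd(b1b$out, BN$bn1, train); BN$bn1 <- n1$par; cc$n1 <- n1$cache
  p1 <- maxpool_fwd(n1$out); cc$p1 <- p1
  b2a <- cbf(p1$out, P$conv3, "zero"); cc$c3 <- b2a$cache
  b2b <- cbf(b2a$out, P$conv4, "zero"); cc$c4 <- b2b$cache
  n2 <- bn_fwd(b2b$out, BN$bn2, train); BN$bn2 <- n2$par; cc$n2 <- n2$cache
  p2 <- maxpool_fwd(n2$out); cc$p2 <- p2
  b3a <- cbf(p2$out, P$conv5, "zero"); cc$c5 <- b3a$cache
  b3b <- cbf(b3a$out, P$conv6, "zero"); cc$c6 <- b3b$cache
  n3 <- bn_fwd(b3b$out, BN$bn3, train); BN$bn3 <- n3$par; cc$n3 <- n3$cache
  p3 <- maxpool_fwd(n3$out); cc$p3 <- p3
  # bottleneck
  b4a <- cbf(p3$out, P$conv7, "zero"); cc$c7 <- b4a$cache
  b4b <- cbf(b4a$out, P$conv8, "zero"); cc$c8 <- b4b$cache
  n4 <- bn_fwd(b4b$out, BN$bn4, train); BN$bn4 <- n4$par; cc$n4 <- n4$cache
  # decoder
  u3 <- upsample_fwd(n4$out); cc$u3_dim <- dim(n4$out)
  cat3 <- abind4(u3, n3$out); cc$cat3 <- c(dim(u3)[4], dim(n3$out)[4])
  b5a <- cbf(cat3, P$conv9, "zero"); cc$c9 <- b5a$cache
  b5b <- cbf(b5a$out, P$conv10, "zero"); cc$c10 <- b5b$cache
  n5 <- bn_fwd(b5b$out, BN$bn5, train); BN$bn5 <- n5$par; cc$n5 <- n5$cache
  u2 <- upsample_fwd(n5$out); cc$u2_dim <- dim(n5$out)
  cat2 <- abind4(u2, n2$out); cc$cat2 <- c(dim(u2)[4], dim(n2$out)[4])
  b6a <- cbf(cat2, P$conv11, "zero"); cc$c11 <- b6a$cache
  b6b <- cbf(b6a$out, P$conv12, "zero"); cc$c12 <- b6b$cache
  n6 <- bn_fwd(b6b$out, BN$bn6, train); BN$bn6 <- n6$par; cc$n6 <- n6$cache
  u1 <- upsample_fwd(n6$out); cc$u1_dim <- dim(n6$out)
  cat1 <- abind4(u1, n1$out); cc$cat1 <- c(dim(u1)[4], dim(n1$out)[4])
  b7a <- cbf(cat1, P$conv13, "zero"); cc$c13 <- b7a$cache
  b7b <- cbf(b7a$out, P$conv14, "zero"); cc$c14 <- b7b$cache
  n7 <- bn_fwd(b7b$out, BN$bn7, train); BN$bn7 <- n7$par; cc$n7 <- n7$cache
  fin <- cbf(n7$out, P$out, "none", relu = FALSE)
  cc$cout <- fin$cache
  out <- fin$out
  if (single) dim(out) <- dim(out)[c(1, 2, 4)]
  net$bn <- BN
  if (!keep_cache) return(out)
  list(out = out, cache = cc, net = net)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# backward pass: gradient of scalar loss wrt all parameters
net_backward <- function(net, cache, gout) {
  P <- net$params; BN <- net$bn
  g <- list()
  bo <- conv_block_bwd(P$out, cache$cout, gout)
  g$out <- list(W = bo$gW, b = bo$gb)
  bn7 <- bn_bwd(BN$bn7, cache$n7, bo$gx)
  g$bn7 <- bn7[c("ggamma", "gbeta")]
  b14 <- conv_block_bwd(P$conv14, cache$c14, bn7$gx)
  g$conv14 <- list(W = b14$gW, b = b14$gb)
  b13 <- conv_block_bwd(P$conv13, cache$c13, b14$gx)
  g$conv13 <- list(W = b13$gW, b = b13$gb)
  s <- cache$cat1
  gu1 <- b13$gx[, , , seq_len(s[1]), drop = FALSE]
  gn1skip <- b13$gx[, , , s[1] + seq_len(s[2]), drop = FALSE]
  bn6g <- upsample_bwd(gu1, cache$u1_dim)
  bn6 <- bn_bwd(BN$bn6, cache$n6, bn6g)
  g$bn6 <- bn6[c("ggamma", "gbeta")]
  b12 <- conv_block_bwd(P$conv12, cache$c12, bn6$gx)
  g$conv12 <- list(W = b12$gW, b = b12$gb)
  b11 <- conv_block_bwd(P$conv11, cache$c11, b12$gx)
  g$conv11 <- list(W = b11$gW, b = b11$gb)
  s <- cache$cat2
  gu2 <- b11$gx[, , , seq_len(s[1]), drop = FALSE]
  gn2skip <- b11$gx[, , , s[1] + seq_len(s[2]), drop = FALSE]
  bn5g <- upsample_bwd(gu2, cache$u2_dim)
  bn5 <- bn_bwd(BN$bn5, cache$n5, bn5g)
  g$bn5 <- bn5[c("ggamma", "gbeta")]
  b10 <- conv_block_bwd(P$conv10, cache$c10, bn5$gx)
  g$conv10 <- list(W = b10$gW, b = b10$gb)
  b9 <- conv_block_bwd(P$conv9, cache$c9, b10$gx)
  g$conv9 <- list(W = b9$gW, b = b9$gb)
  s <- cache$cat3
  gu3 <- b9$gx[, , , seq_len(s[1]), drop = FALSE]
  gn3skip <- b9$gx[, , , s[1] + seq_len(s[2]), drop = FALSE]
  bn4g <- upsample_bwd(gu3, cache$u3_dim)
  bn4 <- bn_bwd(BN$bn4, cache$n4, bn4g)
  g$bn4 <- bn4[c("ggamma", "gbeta")]
  b8 <- conv_block_bwd(P$conv8, cache$c8, bn4$gx)
  g$conv8 <- list(W = b8$gW, b = b8$gb)
  b7 <- conv_block_bwd(P$conv7, cache$c7, b8$gx)
  g$conv7 <- list(W = b7$gW, b = b7$gb)
  gp3 <- maxpool_bwd(cache$p3, b7$gx)
  bn3 <- bn_bwd(BN$bn3, cache$n3, gp3 + gn3skip)
  g$bn3 <- bn3[c("ggamma", "gbeta")]
  b6 <- conv_block_bwd(P$conv6, cache$c6, bn3$gx)
  g$conv6 <- list(W = b6$gW, b = b6$gb)
  b5 <- conv_block_bwd(P$conv5, cache$c5, b6$gx)
  g$conv5 <- list(W = b5$gW, b = b5$gb)
  gp2 <- maxpool_bwd(cache$p2, b5$gx)
  bn2 <- bn_bwd(BN$bn2, cache$n2, gp2 + gn2skip)
  g$bn2 <- bn2[c("ggamma", "gbeta")]
  b4 <- conv_block_bwd(P$conv4, cache$c4, bn2$gx)
  g$conv4 <- list(W = b4$gW, b = b4$gb)
  b3 <- conv_block_bwd(P$conv3, cache$c3, b4$gx)
  g$conv3 <- list(W = b3$gW, b = b3$gb)
  gp1 <- maxpool_bwd(cache$p1, b3$gx)
  bn1 <- bn_bwd(BN$bn1, cache$n1, gp1 + gn1skip)
  g$bn1 <- bn1[c("ggamma", "gbeta")]
  b2 <- conv_block_bwd(P$conv2, cache$c2, bn1$gx)
  g$conv2 <- list(W = b2$gW, b = b2$gb)
  b1 <- conv_block_bwd(P$conv1, cache$c1, b2$gx)
  g$conv1 <- list(W = b1$gW, b = b1$gb)
  g
}

#' Predict a full WSS flatmap with sliding windows
#'
#' Slides 48x48 windows along the longitudinal axis with a fixed stride,
#' averages predictions in overlapping regions, and returns a 3-channel WSS
#' flatmap carrying the input's validity mask. Invalid input pixels are
#' zeroed before prediction.
#'
#' @param net a trained `wss_net`.
#' @param input a 15-channel [flatmap()] (e.g. `48 x 93`).
#' @param stride window stride along V (default 15, covering 93 columns with
#'   whole windows).
#' @return 3-channel WSS [flatmap()] in Pa.
#' @export
predict_flatmap <- function(net, input, stride = 15) {
  stopifnot(inherits(input, "flatmap"))
  d <- dim(input$values)
  W <- net$config$patch
  if (d[2] < W) stop("flatmap length (V) is smaller than the patch size")
  vals <- input$values
  vals[array(!input$mask, d)] <- 0
  starts <- unique(c(seq(1L, d[2] - W + 1L, by = stride), d[2] - W + 1L))
  x <- array(0, c(d[1], W, length(starts), d[3]))
  for (i in seq_along(starts))
    x[, , i, ] <- vals[, starts[i]:(starts[i] + W - 1L), ]
  pred <- net_forward(net, x, train = FALSE)
  acc <- array(0, c(d[1], d[2], 3))
  cnt <- matrix(0, d[1], d[2])
  for (i in seq_along(starts)) {
    cols <- starts[i]:(starts[i] + W - 1L)
    acc[, cols, ] <- acc[, cols, ] + pred[, , i, ]
    cnt[, cols] <- cnt[, cols] + 1
  }
  acc <- acc / array(cnt, c(d[1], d[2], 3))
  flatmap(acc, mask = input$mask,
          channel_names = c("wss_x", "wss_y", "wss_z"))
}
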