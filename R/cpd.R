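#' Coherent point drift configuration
#'
#' Parameters of one CPD registration stage. `alpha` trades off goodness of
#' fit against motion-field regularity and `beta` is the width of the Gaussian
#' smoothing kernel (both dimensionless in the deformable stage; `beta` acts
#' in the units of the point coordinates, mm here). The aortic pipeline uses
#' `alpha = 3, beta = 15` on the coarse template and `alpha = 3, beta = 7`
#' for the refinement pass.
#'
#' @param stage one of `"rigid"`, `"affine"`, `"deformable"`.
#' @param alpha regularization weight (> 0), deformable stage only.
#' @param beta Gaussian kernel width (> 0), deformable stage only.
#' @param max_iters maximum EM iterations.
#' @param tolerance relative change of the negative log-likelihood at which
#'   iteration stops.
#' @param outlier_weight uniform-component weight `w` in `[0, 1)`.
#' @return list of class `cpd_config`.
#' @export
cpd_config <- function(stage = c("rigid", "affine", "deformable"),
                       alpha = 3, beta = 15, max_iters = 100,
                       tolerance = 1e-5, outlier_weight = 0) {
  stage <- match.arg(stage)
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  structure(list(stage = stage, alpha = alpha, beta = beta,
                 max_iters = max_iters, tolerance = tolerance,
                 outlier_weight = outlier_weight),
            class = "cpd_config")
}

# E-step: responsibilities of source (rows of Ty) for target points X.
cpd_estep <- function(X, Ty, sigma2, w) {
  N <- nrow(X); M <- nrow(Ty); D <- ncol(X)
  d2 <- outer(rowSums(Ty^2), rowSums(X^2), "+") - 2 * Ty %*% t(X)  # M x N
  K <- exp(-d2 / (2 * sigma2))
  c0 <- if (w > 0) (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N else 0
  den <- colSums(K) + c0
  den[den < .Machine$double.xmin] <- .Machine$double.xmin
  P <- sweep(K, 2, den, "/")
  nll <- -sum(log(den)) + N * D / 2 * log(2 * pi * sigma2)
  list(P = P, nll = nll)
}

init_sigma2 <- function(X, Y) {
  N <- nrow(X); M <- nrow(Y); D <- ncol(X)
  d2 <- outer(rowSums(Y^2), rowSums(X^2), "+") - 2 * Y %*% t(X)
  sum(d2) / (D * N * M)
}

#' Register a point set with coherent point drift
#'
#' One CPD stage (Myronenko & Song 2010): a Gaussian mixture centred on the
#' moving source points is fit to the target cloud by EM, with the M-step
#' constrained to a rigid, affine, or Gaussian-kernel deformable motion model.
#'
#' @param source `M x 3` matrix of moving points (mm).
#' @param target `N x 3` matrix of fixed points (mm).
#' @param config a [cpd_config()].
#' @return list with `points` (transformed source), `transform` (stage
#'   parameters: `R`, `s`, `t` for rigid; `B`, `t` for affine; `G`, `W` for
#'   deformable), `sigma2`, `iterations`, `nll`.
#' @export
register_cpd <- function(source, target, config = cpd_config()) {
  Y <- as.matrix(source); X <- as.matrix(target)
  if (nrow(Y) < 1L || nrow(X) < 1L) stop("point sets must be non-empty")
  if (!all(is.finite(Y)) || !all(is.finite(X))) stop("points must be finite")
  D <- ncol(X)
  if (config$stage == "affine") {
    Xc <- sweep(X, 2, colMeans(X))
    if (nrow(X) < 4L || qr(Xc)$rank < 3L)
      stop("affine stage needs at least 4 non-coplanar target points")
  }
  w <- config$outlier_weight
  sigma2 <- init_sigma2(X, Y)
  Ty <- Y
  G <- W <- NULL
  if (config$stage == "deformable") {
    d2 <- outer(rowSums(Y^2), rowSums(Y^2), "+") - 2 * Y %*% t(Y)
    G <- exp(-d2 / (2 * config$beta^2))
  }
  transform <- NULL
  nll_prev <- Inf; nll <- Inf; it <- 0L
  while (it < config$max_iters) {
    it <- it + 1L
    es <- cpd_estep(X, Ty, sigma2, w)
    P <- es$P; nll <- es$nll
    P1 <- rowSums(P)              # M
    Pt1 <- colSums(P)             # N
    Np <- sum(P1)
    PX <- P %*% X                 # M x D
    if (config$stage == "rigid") {
      mu_x <- colSums(X * Pt1) / Np
      mu_y <- colSums(Y * P1) / Np
      Xc <- sweep(X, 2, mu_x); Yc <- sweep(Y, 2, mu_y)
      A <- t(PX) %*% Y - Np * (mu_x %o% mu_y)
      sv <- svd(A)
      Cd <- diag(c(rep(1, D - 1), det(sv$u %*% t(sv$v))))
      R <- sv$u %*% Cd %*% t(sv$v)
      s <- sum(diag(Cd) * sv$d) / sum(P1 * rowSums(Yc^2))
      tvec <- mu_x - s * as.vector(R %*% mu_y)
      Ty <- s * Y %*% t(R) + matrix(tvec, nrow(Y), D, byrow = TRUE)
      sigma2 <- max((sum(Pt1 * rowSums(Xc^2)) -
                       s * sum(diag(Cd) * sv$d)) / (Np * D), 1e-12)
      transform <- list(R = R, s = s, t = tvec)
    } else if (config$stage == "affine") {
      mu_x <- colSums(X * Pt1) / Np
      mu_y <- colSums(Y * P1) / Np
      Xc <- sweep(X, 2, mu_x); Yc <- sweep(Y, 2, mu_y)
      A <- t(PX) %*% Y - Np * (mu_x %o% mu_y)
      YPY <- crossprod(Yc * P1, Yc)
      B <- A %*% solve(YPY)
      tvec <- mu_x - as.vector(B %*% mu_y)
      Ty <- Y %*% t(B) + matrix(tvec, nrow(Y), D, byrow = TRUE)
      sigma2 <- max((sum(Pt1 * rowSums(Xc^2)) -
                       sum(A * B)) / (Np * D), 1e-12)
      transform <- list(B = B, t = tvec)
    } else {
      lhs <- G * P1 + diag(config$alpha * sigma2, nrow(Y))
      rhs <- PX - Y * P1
      W <- solve(lhs, rhs)
      Ty <- Y + G %*% W
      xPx <- sum(Pt1 * rowSums(X^2))
      trPXT <- sum(PX * Ty)
      trTPT <- sum(P1 * rowSums(Ty^2))
      sigma2 <- max((xPx - 2 * trPXT + trTPT) / (Np * D), 1e-12)
      transform <- list(G = G, W = W, beta = config$beta)
    }
    if (is.finite(nll_prev) &&
        abs(nll_prev - nll) < config$tolerance * (abs(nll_prev) + 1e-12)) break
    nll_prev <- nll
    if (sigma2 < 1e-10) break
  }
  list(points = Ty, transform = transform, sigma2 = sigma2,
       iterations = it, nll = nll)
}

#' Two-stage template-to-surface registration
#'
#' Registers the coarse quad template to a target vessel point cloud with a
#' rigid, then affine, then deformable CPD pass (`alpha1`, `beta1`), refines
#' the result with two midpoint subdivisions to the full `48 x 93` grid, and
#' runs a second deformable pass (`alpha2`, `beta2`) to recover detail lost by
#' subdivision. Grid topology (U/V node ordering) is preserved throughout.
#' The coarse stage can be skipped, in which case all three transformations
#' run directly on the subdivided template.
#'
#' @param coarse coarse template [quad_surface()] (typically `12 x 24`).
#' @param target `N x 3` matrix (mm) or a `quad_surface` to take points from.
#' @param alpha1,beta1 deformable parameters for the coarse pass.
#' @param alpha2,beta2 deformable parameters for the fine refinement pass.
#' @param skip_coarse if `TRUE`, subdivide first and register only the fine
#'   grid.
#' @param coarse_iters,fine_iters EM iteration caps for the two deformable
#'   passes (the rigid/affine passes use `coarse_iters`).
#' @param tolerance relative NLL stopping tolerance.
#' @return The registered fine [quad_surface()], with the per-stage CPD fits
#'   attached as attribute `"stages"`.
#' @export
register_pipeline <- function(coarse, target,
                              alpha1 = 3, beta1 = 15,
                              alpha2 = 3, beta2 = 7,
                              skip_coarse = FALSE,
                              coarse_iters = 50, fine_iters = 15,
                              tolerance = 1e-5) {
  stopifnot(inherits(coarse, "quad_surface"))
  if (inherits(target, "quad_surface"))
    target <- matrix(target$nodes, prod(dim(target$nodes)[1:2]), 3)
  target <- as.matrix(target)
  stages <- list()
  as_points <- function(s) matrix(s$nodes, prod(dim(s$nodes)[1:2]), 3)
  set_points <- function(s, p) {
    s$nodes <- array(p, dim(s$nodes)); s
  }
  surf <- coarse
  run <- function(surf, stage, alpha, beta, iters) {
    fit <- register_cpd(as_points(surf), target,
                        cpd_config(stage, alpha, beta, iters, tolerance))
    stages[[length(stages) + 1L]] <<- fit[c("sigma2", "iterations", "nll")]
    set_points(surf, fit$points)
  }
  if (!skip_coarse) {
    surf <- run(surf, "rigid", alpha1, beta1, coarse_iters)
    surf <- run(surf, "affine", alpha1, beta1, coarse_iters)
    surf <- run(surf, "deformable", alpha1, beta1, coarse_iters)
    surf <- subdivide(subdivide(surf))
    surf <- run(surf, "deformable", alpha2, beta2, fine_iters)
  } else {
    surf <- subdivide(subdivide(surf))
    surf <- run(surf, "rigid", alpha2, beta2, coarse_iters)
    surf <- run(surf, "affine", alpha2, beta2, coarse_iters)
    surf <- run(surf, "deformable", alpha2, beta2, fine_iters)
  }
  attr(surf, "stages") <- stages
  surf
}
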