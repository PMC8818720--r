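#' Parabolic-fitting wall shear stress estimate
#'
#' The classical velocity-based WSS estimator: per component, a parabola
#' `v(d) = a d + b d^2` is fitted through the wall (zero velocity, no-slip)
#' and two near-wall velocity samples at inward distances `d1 < d2`. The
#' wall shear rate is the derivative at the wall,
#' `a = (v1 d2^2 - v2 d1^2) / (d1 d2 (d2 - d1))` (converted 1/ms -> 1/s via
#' mm -> m), and the WSS vector is `mu` times the component of `a`
#' tangential to the wall (the normal component of the shear-rate vector is
#' removed, as shear stress is tangential by definition). Exact for any
#' velocity profile quadratic in the wall distance.
#'
#' @param v1,v2 velocity vectors at `d1` and `d2` (length 3 or `n x 3`), m/s.
#' @param d1,d2 inward distances, mm (`0 < d1 < d2`).
#' @param normal inward unit normal(s), same shape as `v1`.
#' @param mu dynamic viscosity, Pa.s.
#' @return WSS vector(s) in Pa, same shape as `v1`.
#' @export
parabolic_wss <- function(v1, v2, d1, d2, normal, mu = 4e-3) {
  if (d1 <= 0 || d2 <= d1) stop("need 0 < d1 < d2")
  v1 <- matrix(v1, ncol = 3)
  v2 <- matrix(v2, ncol = 3)
  normal <- matrix(normal, ncol = 3)
  a <- (v1 * d2^2 - v2 * d1^2) / (d1 * d2 * (d2 - d1)) * 1e3  # 1/s
  an <- rowSums(a * normal)
  tang <- a - an * normal
  wss <- mu * tang
  if (nrow(wss) == 1L) drop(wss) else wss
}

#' Parabolic-baseline WSS flatmap
#'
#' Node-wise application of [parabolic_wss()] over two velocity sheets,
#' using each node's inward normal. Nodes invalid in either sheet, or with
#' non-finite velocities, stay masked.
#'
#' @param surface a [quad_surface()].
#' @param sheet1,sheet2 velocity sheets from [sample_velocity_sheet()] with
#'   attributes `distance` (`d1 < d2`).
#' @param mu dynamic viscosity, Pa.s.
#' @param normals optional precomputed [inward_normals()].
#' @return 3-channel WSS [flatmap()] in Pa.
#' @export
parabolic_flatmap <- function(surface, sheet1, sheet2, mu = 4e-3,
                              normals = NULL) {
  d1 <- attr(sheet1, "distance"); d2 <- attr(sheet2, "distance")
  if (is.null(d1) || is.null(d2)) stop("sheets must carry distance attributes")
  if (d1 == d2) stop("sheet distances must differ")
  if (d1 > d2) stop("sheet1 must be closer to the wall than sheet2")
  if (is.null(normals)) normals <- inward_normals(surface)
  dm <- dim(surface$nodes)
  np <- dm[1] * dm[2]
  v1 <- matrix(sheet1$values, np, 3)
  v2 <- matrix(sheet2$values, np, 3)
  nn <- matrix(normals$values, np, 3)
  finite <- rowSums(!is.finite(v1) | !is.finite(v2)) == 0
  v1[!finite, ] <- 0; v2[!finite, ] <- 0
  wss <- parabolic_wss(v1, v2, d1, d2, nn, mu)
  mask <- sheet1$mask & sheet2$mask & normals$mask &
    matrix(finite, dm[1], dm[2])
  flatmap(array(wss, c(dm[1], dm[2], 3)), mask = mask,
          channel_names = c("wss_x", "wss_y", "wss_z"))
}
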