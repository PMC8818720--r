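#' Flatmap: the 2D unwrapped representation of a vessel surface
#'
#' A flatmap stores one value per template node on the `(U, V)` grid obtained
#' by unwrapping the quad template along its cut-line: U runs around the
#' circumference (periodic), V along the vessel. `values` holds `C` channels
#' (1 for scalar maps, 3 for coordinate/velocity/WSS vector maps) and `mask`
#' flags valid nodes; invalid nodes are ignored by every loss and metric.
#'
#' @param values numeric `(U, V, C)` array (a `(U, V)` matrix is promoted to
#'   one channel).
#' @param mask logical `(U, V)` matrix, `TRUE` = valid. Default: all valid.
#' @param channel_names optional character vector of length `C`.
#' @return object of class `flatmap`.
#' @export
flatmap <- function(values, mask = NULL, channel_names = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  d <- dim(values)
  if (length(d) != 3L) stop("`values` must be a (U, V, C) array")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  mask <- as.matrix(mask)
  if (!all(dim(mask) == d[1:2])) stop("mask dimensions must match values")
  if (!is.null(channel_names) && length(channel_names) != d[3])
    stop("channel_names length must equal the channel count")
  structure(list(values = values, mask = mask,
                 channel_names = channel_names),
            class = "flatmap")
}

#' @export
print.flatmap <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<flatmap %d x %d, %d channel(s), %d/%d valid>\n",
              d[1], d[2], d[3], sum(x$mask), d[1] * d[2]))
  invisible(x)
}

#' @export
dim.flatmap <- function(x) dim(x$values)

# magnitude image of a vector flatmap (invalid nodes set to 0)
flatmap_magnitude <- function(fm) {
  m <- sqrt(apply(fm$values^2, c(1, 2), sum))
  m[!fm$mask] <- 0
  m
}

#' Node coordinates of a surface as a 3-channel flatmap
#'
#' @param surface a [quad_surface()].
#' @return [flatmap()] with channels `x`, `y`, `z` (mm).
#' @export
coordinate_flatmap <- function(surface) {
  flatmap(surface$nodes, channel_names = c("x", "y", "z"))
}

#' Inward unit normals of a vessel surface
#'
#' Per-node surface normal oriented into the lumen. Normals are the
#' area-weighted average of the (up to four) adjacent quad-face normals, with
#' the sign fixed so each normal points from the node toward the centroid of
#' its circumferential ring. Nodes with a degenerate neighbourhood (zero-area
#' faces all around) are marked invalid.
#'
#' @param surface a [quad_surface()].
#' @return [flatmap()] with 3 channels holding unit vectors.
#' @export
inward_normals <- function(surface) {
  nodes <- surface$nodes
  nU <- dim(nodes)[1]; nV <- dim(nodes)[2]
  up1 <- c(2:nU, 1L)
  # face f(u,v): corners (u,v),(u+1,v),(u+1,v+1),(u,v+1); u periodic, v=1..nV-1
  # face normal = 0.5 * cross(diag1, diag2): magnitude = area (weighting)
  a <- nodes[, 1:(nV - 1), , drop = FALSE]
  b <- nodes[up1, 1:(nV - 1), , drop = FALSE]
  cc <- nodes[up1, 2:nV, , drop = FALSE]
  dd <- nodes[, 2:nV, , drop = FALSE]
  d1 <- cc - a; d2 <- dd - b
  fn <- array(0, dim(d1))
  fn[, , 1] <- d1[, , 2] * d2[, , 3] - d1[, , 3] * d2[, , 2]
  fn[, , 2] <- d1[, , 3] * d2[, , 1] - d1[, , 1] * d2[, , 3]
  fn[, , 3] <- d1[, , 1] * d2[, , 2] - d1[, , 2] * d2[, , 1]
  fn <- fn / 2
  dn1 <- c(nU, 2:nU - 1L)  # u-1 with wrap
  nrm <- array(0, c(nU, nV, 3))
  vf <- function(v) if (v >= 1 && v <= nV - 1) v else NA_integer_
  for (k in 1:3) {
    acc <- matrix(0, nU, nV)
    for (v in 1:nV) {
      for (dv in c(v - 1L, v)) {
        if (!is.na(vf(dv))) {
          acc[, v] <- acc[, v] + fn[, dv, k] + fn[dn1, dv, k]
        }
      }
    }
    nrm[, , k] <- acc
  }
  # orient toward ring centroid
  cent <- apply(nodes, c(2, 3), mean)  # nV x 3
  inward <- array(0, c(nU, nV, 3))
  for (k in 1:3) inward[, , k] <- matrix(cent[, k], nU, nV, byrow = TRUE) -
    nodes[, , k]
  sgn <- sign(apply(nrm * inward, c(1, 2), sum))
  sgn[sgn == 0] <- 1
  for (k in 1:3) nrm[, , k] <- nrm[, , k] * sgn
  len <- sqrt(apply(nrm^2, c(1, 2), sum))
  valid <- len > 1e-12
  len[!valid] <- 1
  for (k in 1:3) nrm[, , k] <- nrm[, , k] / len
  flatmap(nrm, mask = valid, channel_names = c("nx", "ny", "nz"))
}

#' Velocity sources
#'
#' A `velocity_source` provides velocity vectors (m/s) at arbitrary 3D
#' positions (mm), abstracting over the three data representations used in
#' the pipeline: scattered point clouds (CFD-like), uniform voxel grids
#' (MRI-like), and closed-form analytic fields.
#'
#' * `velocity_source_grid()`: trilinear interpolation on a uniform grid.
#'   `values` is an `(nx, ny, nz, 3)` array; `dx` the voxel spacing in mm
#'   (scalar or length 3); `origin` the coordinate of the centre of voxel
#'   `[1,1,1]`.
#' * `velocity_source_points()`: inverse-distance weighting over the `k`
#'   nearest cloud points within `cutoff` mm.
#' * `velocity_source_analytic()`: wraps `fun(points, t)` returning `n x 3`.
#'
#' @param values `(nx, ny, nz, 3)` velocity array, m/s.
#' @param dx voxel spacing, mm.
#' @param origin centre of the first voxel, mm.
#' @param venc velocity-encoding limit, m/s (metadata; sets noise scales).
#' @param points `n x 3` matrix of sample positions, mm.
#' @param velocities `n x 3` matrix of velocities, m/s.
#' @param k,cutoff IDW neighbourhood size and radius (mm).
#' @param fun function `(points, t)` returning an `n x 3` velocity matrix.
#' @return object of class `velocity_source`.
#' @name velocity_source
NULL

#' @rdname velocity_source
#' @export
velocity_source_grid <- function(values, dx, origin = c(0, 0, 0), venc = 1.5) {
  d <- dim(values)
  if (length(d) != 4L || d[4] != 3L)
    stop("grid values must be an (nx, ny, nz, 3) array")
  dx <- rep_len(dx, 3)
  if (any(dx <= 0)) stop("grid spacing must be positive")
  if (!all(is.finite(values))) stop("velocities must be finite")
  structure(list(kind = "uniform_grid", values = values, dx = dx,
                 origin = origin, venc = venc), class = "velocity_source")
}

#' @rdname velocity_source
#' @export
velocity_source_points <- function(points, velocities, venc = 1.5,
                                   k = 8, cutoff = 5) {
  points <- as.matrix(points); velocities <- as.matrix(velocities)
  stopifnot(nrow(points) == nrow(velocities), ncol(points) == 3)
  structure(list(kind = "point_cloud", points = points,
                 velocities = velocities, venc = venc, k = k,
                 cutoff = cutoff), class = "velocity_source")
}

#' @rdname velocity_source
#' @export
velocity_source_analytic <- function(fun, venc = 1.5) {
  stopifnot(is.function(fun))
  structure(list(kind = "analytic", fun = fun, venc = venc),
            class = "velocity_source")
}

# vectorized trilinear interpolation of an (nx,ny,nz) array at query points
trilinear <- function(arr, dx, origin, q) {
  d <- dim(arr)
  fx <- (q[, 1] - origin[1]) / dx[1] + 1
  fy <- (q[, 2] - origin[2]) / dx[2] + 1
  fz <- (q[, 3] - origin[3]) / dx[3] + 1
  inside <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  out <- rep(NA_real_, nrow(q))
  if (!any(inside)) return(list(values = out, inside = inside))
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  i0 <- pmin(floor(fx), d[1] - 1); j0 <- pmin(floor(fy), d[2] - 1)
  k0 <- pmin(floor(fz), d[3] - 1)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- at(i0, j0, k0) * (1 - tx) * (1 - ty) * (1 - tz) +
    at(i0 + 1, j0, k0) * tx * (1 - ty) * (1 - tz) +
    at(i0, j0 + 1, k0) * (1 - tx) * ty * (1 - tz) +
    at(i0, j0, k0 + 1) * (1 - tx) * (1 - ty) * tz +
    at(i0 + 1, j0 + 1, k0) * tx * ty * (1 - tz) +
    at(i0 + 1, j0, k0 + 1) * tx * (1 - ty) * tz +
    at(i0, j0 + 1, k0 + 1) * (1 - tx) * ty * tz +
    at(i0 + 1, j0 + 1, k0 + 1) * tx * ty * tz
  out[inside] <- v
  list(values = out, inside = inside)
}

# evaluate a velocity source at query points (n x 3, mm) and time t (ms)
eval_velocity <- function(src, q, t = 0) {
  stopifnot(inherits(src, "velocity_source"))
  n <- nrow(q)
  V <- matrix(NA_real_, n, 3)
  ok <- rep(TRUE, n)
  if (src$kind == "analytic") {
    V <- src$fun(q, t)
  } else if (src$kind == "uniform_grid") {
    for (c in 1:3) {
      ti <- trilinear(src$values[, , , c], src$dx, src$origin, q)
      V[, c] <- ti$values
      ok <- ok & ti$inside
    }
    if (any(!ok))
      warning(sprintf("%d query point(s) outside the velocity grid; masked",
                      sum(!ok)))
    V[!ok, ] <- 0
  } else {
    kn <- knn_query(q, src$points, src$k)
    for (i in seq_len(n)) {
      sel <- kn$dist[i, ] <= src$cutoff
      if (!any(sel)) { ok[i] <- FALSE; V[i, ] <- 0; next }
      dd <- kn$dist[i, sel]; id <- kn$index[i, sel]
      if (dd[1] < 1e-9) {
        V[i, ] <- src$velocities[id[1], ]
      } else {
        wgt <- 1 / dd^2
        V[i, ] <- colSums(src$velocities[id, , drop = FALSE] * wgt) / sum(wgt)
      }
    }
  }
  list(velocities = V, valid = ok)
}

#' Sample a velocity sheet at an inward distance from the wall
#'
#' Evaluates the velocity source at `p = node + d * inward_normal` for every
#' template node, producing a 3-channel velocity flatmap ("velocity sheet")
#' at distance `d` from the wall. The wall itself (d = 0) is never sampled:
#' by the no-slip condition the velocity there is zero. Nodes whose query
#' point is not covered by the source are masked.
#'
#' @param src a [velocity_source].
#' @param surface a [quad_surface()].
#' @param d inward-normal distance in mm (> 0).
#' @param t time in ms (passed to analytic sources).
#' @param normals optional precomputed [inward_normals()] flatmap.
#' @return [flatmap()] with channels `vx`, `vy`, `vz` (m/s) and attribute
#'   `distance` = `d`.
#' @export
sample_velocity_sheet <- function(src, surface, d, t = 0, normals = NULL) {
  if (d <= 0) stop("sheet distance must be positive (no-slip wall at d = 0)")
  if (is.null(normals)) normals <- inward_normals(surface)
  dm <- dim(surface$nodes)
  pts <- matrix(surface$nodes, dm[1] * dm[2], 3) +
    d * matrix(normals$values, dm[1] * dm[2], 3)
  ev <- eval_velocity(src, pts, t)
  vals <- array(ev$velocities, c(dm[1], dm[2], 3))
  mask <- matrix(ev$valid, dm[1], dm[2]) & normals$mask
  fm <- flatmap(vals, mask, channel_names = c("vx", "vy", "vz"))
  attr(fm, "distance") <- d
  fm
}

#' Transfer WSS labels from a point cloud to the template grid
#'
#' Each template node takes the WSS vector of its nearest source point,
#' provided that point lies within `radius` mm; nodes with no source point in
#' range are masked invalid. This is the label-transfer step that pairs a
#' registered surface with reference wall shear stress samples.
#'
#' @param src_points `n x 3` matrix of source positions, mm.
#' @param src_wss `n x 3` matrix of WSS vectors, Pa.
#' @param surface a [quad_surface()].
#' @param radius search radius in mm (default 5).
#' @return [flatmap()] with channels `wss_x`, `wss_y`, `wss_z` (Pa).
#' @export
transfer_wss_labels <- function(src_points, src_wss, surface, radius = 5) {
  src_points <- as.matrix(src_points); src_wss <- as.matrix(src_wss)
  if (nrow(src_points) < 1L) stop("source point set is empty")
  dm <- dim(surface$nodes)
  pts <- matrix(surface$nodes, dm[1] * dm[2], 3)
  nn <- nn_query(pts, src_points)
  ok <- nn$dist <= radius
  vals <- src_wss[nn$index, , drop = FALSE]
  vals[!ok, ] <- 0
  flatmap(array(vals, c(dm[1], dm[2], 3)),
          mask = matrix(ok, dm[1], dm[2]),
          channel_names = c("wss_x", "wss_y", "wss_z"))
}

#' Validity mask for branch ostia and the inlet boundary
#'
#' Marks template nodes invalid where the wall is interrupted: nodes strictly
#' inside a branch ostium exclusion zone (per-ostium centre + radius; a node
#' exactly on the zone boundary stays valid), and the first `exclude_inlet`
#' longitudinal rings from the inlet, which carry boundary artefacts and are
#' excluded during training.
#'
#' @param surface a [quad_surface()].
#' @param branch_ostia list of `list(center = c(x, y, z), radius = r)` in mm;
#'   may be empty.
#' @param exclude_inlet number of inlet rings (V columns) to invalidate
#'   (default 3).
#' @return logical `(U, V)` matrix, `TRUE` = valid.
#' @export
build_branch_mask <- function(surface, branch_ostia = list(),
                              exclude_inlet = 3) {
  dm <- dim(surface$nodes)
  mask <- matrix(TRUE, dm[1], dm[2])
  pts <- matrix(surface$nodes, dm[1] * dm[2], 3)
  for (ost in branch_ostia) {
    d <- sqrt(colSums((t(pts) - ost$center)^2))
    mask[matrix(d < ost$radius, dm[1], dm[2])] <- FALSE
  }
  if (exclude_inlet > 0)
    mask[, seq_len(min(exclude_inlet, dm[2]))] <- FALSE
  mask
}

#' Assemble the 15-channel network input
#'
#' Stacks the wall coordinate flatmap, two inner-surface coordinate flatmaps
#' and two velocity sheets into the network's 15-channel input, in the fixed
#' order `(x0,y0,z0, x1,y1,z1, x2,y2,z2, vx1,vy1,vz1, vx2,vy2,vz2)`. The
#' first sheet must be the one closer to the wall (`d1 < d2`). The output
#' mask is the conjunction of all input masks.
#'
#' @param wall wall coordinate [flatmap()] (3 channels).
#' @param inner1,inner2 inner-surface coordinate flatmaps at distances
#'   `d1 < d2`.
#' @param sheet1,sheet2 velocity sheets from [sample_velocity_sheet()] at the
#'   same distances.
#' @return 15-channel [flatmap()]; attribute `distances` records `c(d1, d2)`.
#' @export
assemble_input <- function(wall, inner1, inner2, sheet1, sheet2) {
  d1 <- attr(sheet1, "distance"); d2 <- attr(sheet2, "distance")
  if (is.null(d1) || is.null(d2)) stop("sheets must carry a distance attribute")
  if (d1 >= d2) stop("sheet1 must be closer to the wall than sheet2 (d1 < d2)")
  parts <- list(wall, inner1, inner2, sheet1, sheet2)
  dm <- dim(wall$values)[1:2]
  for (p in parts) stopifnot(all(dim(p$values)[1:2] == dm),
                             dim(p$values)[3] == 3L)
  vals <- array(0, c(dm, 15L))
  mask <- matrix(TRUE, dm[1], dm[2])
  for (i in seq_along(parts)) {
    vals[, , (3 * i - 2):(3 * i)] <- parts[[i]]$values
    mask <- mask & parts[[i]]$mask
  }
  fm <- flatmap(vals, mask, channel_names = c(
    "x0", "y0", "z0", "x1", "y1", "z1", "x2", "y2", "z2",
    "vx1", "vy1", "vz1", "vx2", "vy2", "vz2"))
  attr(fm, "distances") <- c(d1, d2)
  fm
}

#' Inner-surface coordinate flatmap at an inward distance
#'
#' @param surface a [quad_surface()].
#' @param d inward-normal distance, mm.
#' @param normals optional precomputed [inward_normals()].
#' @return 3-channel coordinate [flatmap()] with attribute `distance`.
#' @export
inner_coordinates <- function(surface, d, normals = NULL) {
  if (is.null(normals)) normals <- inward_normals(surface)
  fm <- flatmap(surface$nodes + d * normals$values, mask = normals$mask,
                channel_names = c("x", "y", "z"))
  attr(fm, "distance") <- d
  fm
}
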