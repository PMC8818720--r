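#' Structured quadrilateral vessel surface
#'
#' A `quad_surface` is a grid of 3D nodes describing a tubular vessel wall.
#' The first grid axis (U) runs around the circumference and is periodic for
#' vessel templates; the second axis (V) runs along the vessel and is open.
#' Coordinates are in millimetres.
#'
#' @param nodes numeric array of dimension `(n_U, n_V, 3)` with node
#'   coordinates in mm.
#' @param periodic_U logical; whether the U axis wraps around (default `TRUE`).
#' @return An object of class `quad_surface`.
#' @examples
#' surf <- build_coarse_template(12, 24, centerline_straight(100), 10)
#' dim(surf$nodes)
#' @export
quad_surface <- function(nodes, periodic_U = TRUE) {
  nodes <- as.array(nodes)
  d <- dim(nodes)
  if (length(d) != 3L || d[3] != 3L)
    stop("`nodes` must be an (n_U x n_V x 3) array")
  if (d[1] < 3L || d[2] < 2L)
    stop("quad surface needs n_U >= 3 and n_V >= 2")
  if (!all(is.finite(nodes)))
    stop("all nodes must be finite")
  structure(list(nodes = nodes, periodic_U = isTRUE(periodic_U)),
            class = "quad_surface")
}

#' @export
print.quad_surface <- function(x, ...) {
  d <- dim(x$nodes)
  cat(sprintf("<quad_surface %d x %d (%s U)>\n", d[1], d[2],
              if (x$periodic_U) "periodic" else "open"))
  invisible(x)
}

#' @export
dim.quad_surface <- function(x) dim(x$nodes)[1:2]

#' Straight and curved centerlines
#'
#' Convenience constructors for synthetic vessel centerlines: a straight
#' segment along the z axis, and a circular arc (a torus section) in the x-z
#' plane. Both return an `n x 3` matrix of points in mm ordered from inlet to
#' outlet.
#'
#' @param length segment length in mm.
#' @param n number of stations.
#' @param bend_radius arc radius in mm.
#' @param angle arc angle in radians (default a quarter turn).
#' @return `n x 3` numeric matrix.
#' @export
centerline_straight <- function(length = 120, n = 50) {
  cbind(0, 0, seq(0, length, length.out = n))
}

#' @rdname centerline_straight
#' @export
centerline_arc <- function(bend_radius = 40, angle = pi / 2, n = 50) {
  th <- seq(0, angle, length.out = n)
  cbind(bend_radius * (1 - cos(th)), 0, bend_radius * sin(th))
}

# Resample a polyline to n stations uniformly in arc length.
resample_centerline <- function(centerline, n) {
  centerline <- as.matrix(centerline)
  seg <- sqrt(rowSums(diff(centerline)^2))
  if (any(seg <= .Machine$double.eps))
    stop("degenerate centerline: repeated points")
  s <- c(0, cumsum(seg))
  si <- seq(0, s[length(s)], length.out = n)
  vapply(1:3, function(k) stats::approx(s, centerline[, k], xout = si)$y,
         numeric(n))
}

# Unit tangents (central differences) and a parallel-transported normal frame.
centerline_frames <- function(cl) {
  n <- nrow(cl)
  tg <- rbind(cl[2, ] - cl[1, ],
              cl[3:n, , drop = FALSE] - cl[1:(n - 2), , drop = FALSE],
              cl[n, ] - cl[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  e1 <- matrix(0, n, 3)
  e2 <- matrix(0, n, 3)
  # initial normal: axis least aligned with the first tangent
  ax <- diag(3)[which.min(abs(tg[1, ])), ]
  v <- ax - sum(ax * tg[1, ]) * tg[1, ]
  e1[1, ] <- v / sqrt(sum(v^2))
  e2[1, ] <- crossprod3(tg[1, ], e1[1, ])
  for (i in 2:n) {
    v <- e1[i - 1, ] - sum(e1[i - 1, ] * tg[i, ]) * tg[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) v <- e2[i - 1, ] - sum(e2[i - 1, ] * tg[i, ]) * tg[i, ]
    e1[i, ] <- v / sqrt(sum(v^2))
    e2[i, ] <- crossprod3(tg[i, ], e1[i, ])
  }
  list(tangent = tg, e1 = e1, e2 = e2)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a tubular quad template over a centerline
#'
#' Constructs a periodic-U tube surface procedurally: each longitudinal
#' station v carries a circular ring of `n_U` nodes lying in the plane normal
#' to the centerline, with the requested radius. The ring frame is parallel
#' transported along the centerline so the U = 1 generator line (the cut-line
#' of the flatmap) does not twist. The default `12 x 24` grid is the coarse
#' registration template; two midpoint subdivisions take it to `48 x 93`.
#'
#' @param n_U circumferential node count (periodic), default 12.
#' @param n_V longitudinal node count (open), default 24.
#' @param centerline `m x 3` matrix of centerline points in mm, `m >= n_V`.
#' @param radius_profile tube radius in mm: a scalar or a vector of length
#'   `n_V` (per-station radii).
#' @return A [quad_surface()].
#' @export
build_coarse_template <- function(n_U = 12, n_V = 24,
                                  centerline = centerline_straight(),
                                  radius_profile = 10) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < n_V)
    stop("centerline must have at least n_V stations")
  r <- rep_len(radius_profile, n_V)
  if (any(r <= 0)) stop("radii must be positive")
  cl <- resample_centerline(centerline, n_V)
  fr <- centerline_frames(cl)
  th <- 2 * pi * (seq_len(n_U) - 1) / n_U
  nodes <- array(0, c(n_U, n_V, 3))
  for (v in seq_len(n_V)) {
    ring <- outer(cos(th), fr$e1[v, ]) + outer(sin(th), fr$e2[v, ])
    nodes[, v, ] <- matrix(cl[v, ], n_U, 3, byrow = TRUE) + r[v] * ring
  }
  quad_surface(nodes)
}

#' Midpoint subdivision matrices for a quad grid
#'
#' Linear operators refining an `(n_U, n_V)` node grid to
#' `(2 n_U, 2 n_V - 1)`: the U pass wraps (periodic circumference, n -> 2n),
#' the V pass is open with interpolating endpoints (n -> 2n - 1). Every new
#' node is a convex combination of old nodes (rows sum to 1); original nodes
#' are kept exactly, so two passes map `(12, 24)` to `(48, 93)`.
#'
#' @param n_U,n_V input grid dimensions.
#' @return list with matrices `U` (`2 n_U x n_U`) and `V` (`(2 n_V - 1) x n_V`).
#' @export
subdivision_matrices <- function(n_U, n_V) {
  MU <- matrix(0, 2 * n_U, n_U)
  for (k in seq_len(n_U)) {
    MU[2 * k - 1, k] <- 1
    MU[2 * k, k] <- 0.5
    MU[2 * k, if (k == n_U) 1L else k + 1L] <- 0.5
  }
  MV <- matrix(0, 2 * n_V - 1, n_V)
  for (k in seq_len(n_V)) MV[2 * k - 1, k] <- 1
  for (k in seq_len(n_V - 1)) MV[2 * k, c(k, k + 1)] <- 0.5
  list(U = MU, V = MV)
}

#' Refine a quad surface with subdivision matrices
#'
#' @param surface a [quad_surface()].
#' @param mats subdivision matrices from [subdivision_matrices()] matching the
#'   surface dimensions.
#' @return The refined [quad_surface()] of dimension `(2 n_U, 2 n_V - 1)`.
#' @export
subdivide <- function(surface, mats = NULL) {
  stopifnot(inherits(surface, "quad_surface"))
  d <- dim(surface$nodes)
  if (is.null(mats)) mats <- subdivision_matrices(d[1], d[2])
  if (ncol(mats$U) != d[1] || ncol(mats$V) != d[2])
    stop("subdivision matrix dimensions do not match the surface grid")
  out <- array(0, c(nrow(mats$U), nrow(mats$V), 3))
  for (k in 1:3) out[, , k] <- mats$U %*% surface$nodes[, , k] %*% t(mats$V)
  quad_surface(out, surface$periodic_U)
}

#' Per-node distance from a surface to a target point set
#'
#' Nearest-point (point-to-point) distance of every grid node to the target
#' cloud, returned as a 1-channel flatmap in mm. The mean +/- SD of this map
#' is the usual registration quality summary.
#'
#' @param registered a [quad_surface()] (or an `n x 3` matrix of points).
#' @param target `m x 3` matrix of target points, mm.
#' @return A [flatmap()] with one channel (`"dist_mm"`) when given a surface,
#'   otherwise a numeric vector of distances.
#' @export
surface_distance <- function(registered, target) {
  target <- as.matrix(target)
  if (nrow(target) < 1L) stop("target point set is empty")
  if (inherits(registered, "quad_surface")) {
    d <- dim(registered$nodes)
    pts <- matrix(registered$nodes, d[1] * d[2], 3)
    dist <- nn_dist(pts, target)
    flatmap(array(dist, c(d[1], d[2], 1)), channel_names = "dist_mm")
  } else {
    nn_dist(as.matrix(registered), target)
  }
}

# chunked brute-force nearest neighbour: returns list(index, dist) or dist only
nn_query <- function(query, ref, chunk = 2048L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  n <- nrow(query)
  idx <- integer(n); dst <- numeric(n)
  rs <- rowSums(ref^2)
  for (a in seq(1L, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    q <- query[a:b, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rs, "+") - 2 * q %*% t(ref)
    j <- max.col(-d2, ties.method = "first")
    idx[a:b] <- j
    dst[a:b] <- sqrt(pmax(d2[cbind(seq_len(nrow(q)), j)], 0))
  }
  list(index = idx, dist = dst)
}

nn_dist <- function(query, ref) nn_query(query, ref)$dist

# k-nearest neighbours (small k, brute force, chunked)
knn_query <- function(query, ref, k, chunk = 1024L) {
  query <- as.matrix(query); ref <- as.matrix(ref)
  n <- nrow(query); k <- min(k, nrow(ref))
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  rs <- rowSums(ref^2)
  for (a in seq(1L, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    q <- query[a:b, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rs, "+") - 2 * q %*% t(ref)
    for (i in seq_len(nrow(q))) {
      o <- order(d2[i, ])[seq_len(k)]
      idx[a + i - 1L, ] <- o
      dst[a + i - 1L, ] <- sqrt(pmax(d2[i, o], 0))
    }
  }
  list(index = idx, dist = dst)
}

#' Convert a quad surface to an indexed mesh
#'
#' @param surface a [quad_surface()].
#' @return list with `vertices` (`n x 3`) and `faces` (list of integer vectors,
#'   1-based, counter-clockwise quads; the periodic seam is closed).
#' @export
surface_to_mesh <- function(surface) {
  d <- dim(surface$nodes)
  nU <- d[1]; nV <- d[2]
  verts <- matrix(surface$nodes, nU * nV, 3)
  id <- function(u, v) (v - 1L) * nU + u
  faces <- list()
  umax <- if (surface$periodic_U) nU else nU - 1L
  f <- 1L
  for (v in seq_len(nV - 1L)) {
    for (u in seq_len(umax)) {
      u2 <- if (u == nU) 1L else u + 1L
      faces[[f]] <- c(id(u, v), id(u2, v), id(u2, v + 1L), id(u, v + 1L))
      f <- f + 1L
    }
  }
  list(vertices = verts, faces = faces)
}

#' Read and write surface meshes (ASCII PLY / OBJ)
#'
#' Minimal mesh I/O for triangulated or quad-faced surfaces. `write_ply()`
#' and `write_obj()` accept either a [quad_surface()] or a
#' `list(vertices, faces)` mesh; the readers return a `list(vertices, faces)`.
#'
#' @param mesh a [quad_surface()] or `list(vertices, faces)`.
#' @param path file path.
#' @return readers: `list(vertices, faces)`; writers: `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  if (inherits(mesh, "quad_surface")) mesh <- surface_to_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", length(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  writeLines(vapply(f, function(fi)
    paste(c(length(fi), fi - 1L), collapse = " "), character(1)), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  if (is.na(nf)) nf <- 0L
  vlines <- lines[(hdr_end + 1):(hdr_end + nv)]
  verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- list()
  if (nf > 0) {
    flines <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
    faces <- lapply(strsplit(flines, "\\s+"), function(x) {
      n <- as.integer(x[1]); as.integer(x[2:(1 + n)]) + 1L
    })
  }
  list(vertices = verts, faces = faces)
}

#' @rdname write_ply
#' @export
write_obj <- function(mesh, path) {
  if (inherits(mesh, "quad_surface")) mesh <- surface_to_mesh(mesh)
  v <- mesh$vertices
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", v[, 1], v[, 2], v[, 3]), con)
  writeLines(vapply(mesh$faces, function(fi)
    paste(c("f", fi), collapse = " "), character(1)), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^v ", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  flines <- grep("^f ", lines, value = TRUE)
  faces <- lapply(strsplit(flines, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[-1])))
  list(vertices = verts, faces = faces)
}
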