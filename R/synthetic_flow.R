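#' Analytic pulsatile flow model
#'
#' Physical and acquisition parameters for the analytic tube-flow generator
#' used as the source of training and ground-truth data. Defaults follow
#' standard blood-flow modelling: dynamic viscosity 4e-3 Pa.s, density
#' 1060 kg/m^3, velocity-encoding limit 1.5 m/s, and a 710 ms cardiac cycle.
#'
#' @param mu dynamic viscosity, Pa.s.
#' @param rho density, kg/m^3.
#' @param venc velocity-encoding limit, m/s.
#' @param R tube radius, mm.
#' @param Vmax_peak peak-systolic centreline velocity, m/s.
#' @param cycle cardiac cycle length T, ms.
#' @param waveform periodic scale function `s(t)` (t in ms, `s(t) >= 0`,
#'   period `cycle`). Default: a raised-cosine systolic pulse over a small
#'   diastolic baseline, see [waveform_raised_cosine()].
#' @return list of class `flow_model`.
#' @export
flow_model <- function(mu = 4e-3, rho = 1060, venc = 1.5, R = 10,
                       Vmax_peak = 1, cycle = 710,
                       waveform = waveform_raised_cosine(cycle)) {
  stopifnot(mu > 0, rho > 0, venc > 0, R > 0, Vmax_peak > 0, cycle > 0)
  structure(list(mu = mu, rho = rho, venc = venc, R = R,
                 Vmax_peak = Vmax_peak, cycle = cycle, waveform = waveform),
            class = "flow_model")
}

#' Raised-cosine systolic waveform
#'
#' Periodic flow-rate scale `s(t)`: a raised-cosine pulse of the given width
#' centred at `t_peak`, on top of a constant diastolic baseline. `s` peaks at
#' exactly 1 (so `Vmax_peak` is attained at `t = t_peak`) and never drops
#' below `baseline`.
#'
#' @param cycle cycle length T, ms.
#' @param t_peak time of peak systole, ms.
#' @param width pulse width, ms.
#' @param baseline diastolic scale in `[0, 1)`.
#' @return function `s(t)` accepting a numeric vector of times in ms.
#' @export
waveform_raised_cosine <- function(cycle = 710, t_peak = 150, width = 300,
                                   baseline = 0.1) {
  force(cycle); force(t_peak); force(width); force(baseline)
  function(t) {
    tm <- t %% cycle
    pulse <- ifelse(abs(tm - t_peak) <= width / 2,
                    0.5 * (1 + cos(2 * pi * (tm - t_peak) / width)), 0)
    baseline + (1 - baseline) * pulse
  }
}

# generic tube flow field along a (possibly curved, possibly tapered)
# centerline; exponent p gives u = s(t) Vmax (1 - (r/R)^p), wall shear
# mu * p * s(t) * Vmax / R  (R converted mm -> m).
tube_flow_field <- function(model, centerline, radius, exponent = 2,
                            direction_sign = function(t) 1) {
  centerline <- as.matrix(centerline)
  m <- nrow(centerline)
  radius <- rep_len(radius, m)
  fr <- centerline_frames(centerline)
  fun <- function(points, t = 0) {
    points <- as.matrix(points)
    nn <- nn_query(points, centerline)
    st <- nn$index
    rel <- points - centerline[st, , drop = FALSE]
    tg <- fr$tangent[st, , drop = FALSE]
    # radial distance: remove the axial component of the offset
    ax <- rowSums(rel * tg)
    r <- sqrt(pmax(rowSums(rel^2) - ax^2, 0))
    Rl <- radius[st]
    s <- model$waveform(t) * direction_sign(t)
    u <- s * model$Vmax_peak * pmax(1 - (r / Rl)^exponent, 0)
    u[r > Rl] <- 0
    u * tg
  }
  structure(list(model = model, centerline = centerline, radius = radius,
                 exponent = exponent, frames = fr,
                 direction_sign = direction_sign,
                 source = velocity_source_analytic(fun, venc = model$venc),
                 fun = fun),
            class = "flow_field")
}

#' Analytic Poiseuille tube flow with closed-form wall shear stress
#'
#' Laminar parabolic profile `u(r, t) = s(t) Vmax (1 - r^2/R^2)` along the
#' tube axis, with exact wall WSS magnitude `2 mu s(t) Vmax / R` (SI units;
#' R is converted from mm to m). `power_law_field()` generalises the profile
#' to `u = s(t) Vmax (1 - (r/R)^p)`; large `p` (e.g. 9) gives a blunt,
#' plug-like profile with a steep near-wall gradient and wall WSS
#' `p mu s(t) Vmax / R`, used to probe resolution-driven underestimation of
#' classical estimators.
#'
#' @param model a [flow_model()].
#' @param centerline centerline points, mm (default: straight 120 mm tube
#'   along z).
#' @param radius tube radius per centerline station, mm (default `model$R`).
#' @param exponent profile exponent `p` (2 = Poiseuille).
#' @return A `flow_field` object: `$source` is an analytic
#'   [velocity_source], `$wall_wss(t, R)` the closed-form wall WSS in Pa.
#' @export
poiseuille_field <- function(model, centerline = centerline_straight(120, 60),
                             radius = model$R) {
  tube_flow_field(model, centerline, radius, exponent = 2)
}

#' @rdname poiseuille_field
#' @export
power_law_field <- function(model, centerline = centerline_straight(120, 60),
                            radius = model$R, exponent = 9) {
  tube_flow_field(model, centerline, radius, exponent = exponent)
}

#' Closed-form wall WSS of a flow field
#'
#' @param field a `flow_field`.
#' @param t time, ms.
#' @param R radius in mm (defaults to the field's station radii mean).
#' @return WSS magnitude in Pa.
#' @export
wall_wss <- function(field, t = 0, R = NULL) {
  if (is.null(R)) R <- field$radius
  m <- field$model
  m$mu * field$exponent * m$waveform(t) * m$Vmax_peak / (R * 1e-3) *
    field$direction_sign(t)
}

#' Analytic WSS label flatmap for a tube surface
#'
#' Evaluates the generator's closed-form wall shear stress at every template
#' node of a tube surface built over the field's centerline: magnitude
#' `p mu s(t) Vmax / R(v)` with the local station radius, directed along the
#' local centerline tangent (the flow direction). For curved tubes this is
#' the per-cross-section straight-tube formula, i.e. an approximation.
#'
#' @param field a `flow_field`.
#' @param surface the [quad_surface()] the labels live on.
#' @param t time, ms.
#' @param mask optional validity mask.
#' @return 3-channel WSS [flatmap()] in Pa.
#' @export
analytic_wss_flatmap <- function(field, surface, t = 0, mask = NULL) {
  dm <- dim(surface$nodes)
  pts <- matrix(surface$nodes, dm[1] * dm[2], 3)
  nn <- nn_query(pts, field$centerline)
  st <- nn$index
  mag <- wall_wss(field, t, R = field$radius[st])
  vals <- mag * field$frames$tangent[st, , drop = FALSE]
  flatmap(array(vals, c(dm[1], dm[2], 3)), mask = mask,
          channel_names = c("wss_x", "wss_y", "wss_z"))
}

#' Oscillating tube flow for exercising the oscillatory shear index
#'
#' A constant-magnitude Poiseuille field whose axial direction reverses by
#' 180 degrees for a fraction `f` of the cycle: the flow (and hence the wall
#' WSS vector) points along +axis for `t < (1 - f) T` and along -axis for
#' the remainder. With equal magnitudes the resulting OSI is exactly
#' `0.5 (1 - |1 - 2 f|)`, i.e. `f` for `f <= 0.5`.
#'
#' `oscillating_wss_series()` builds the corresponding closed-form WSS series
#' directly on a small flatmap grid. Note that the trapezoidal rule
#' reproduces the closed-form OSI exactly only when the sign change falls
#' half-way between two consecutive frames; choose `n_frames` accordingly
#' (an even `n_frames`, i.e. an odd number of intervals, is exact for
#' `f = 0.5`).
#'
#' @param model a [flow_model()].
#' @param reversal_fraction fraction `f` of the cycle with reversed flow,
#'   in `[0, 0.5]`.
#' @param n_frames number of time samples spanning `[0, T]`.
#' @param shape `(U, V)` grid of the generated flatmaps.
#' @return `oscillating_field()`: a `flow_field`; `oscillating_wss_series()`:
#'   a [wss_series()].
#' @export
oscillating_field <- function(model, reversal_fraction = 0.5) {
  f <- reversal_fraction
  stopifnot(f >= 0, f <= 0.5)
  model$waveform <- function(t) rep_len(1, length(t))  # constant magnitude
  sign_fun <- function(t) {
    if (f == 0) return(rep_len(1, length(t)))
    tm <- t %% model$cycle
    tm[t > 0 & tm == 0] <- model$cycle  # t = T belongs to the cycle end
    ifelse(tm < (1 - f) * model$cycle, 1, -1)
  }
  tube_flow_field(model, centerline_straight(120, 60), model$R,
                  exponent = 2, direction_sign = sign_fun)
}

#' @rdname oscillating_field
#' @export
oscillating_wss_series <- function(model = flow_model(),
                                   reversal_fraction = 0.5,
                                   n_frames = 102, shape = c(4, 4)) {
  field <- oscillating_field(model, reversal_fraction)
  times <- seq(0, model$cycle, length.out = n_frames)
  mag <- 2 * model$mu * model$Vmax_peak / (model$R * 1e-3)
  frames <- lapply(times, function(t) {
    w <- mag * field$direction_sign(t)
    vals <- array(0, c(shape, 3))
    vals[, , 3] <- w
    flatmap(vals, channel_names = c("wss_x", "wss_y", "wss_z"))
  })
  wss_series(frames, times)
}

#' Synthetic-MRI grid specification
#'
#' @param dx isotropic voxel spacing, mm (2.4 mimics clinical 4D Flow; 1.2 a
#'   high-resolution protocol).
#' @param dt frame spacing, ms.
#' @param noise_sd_frac Gaussian noise SD as a fraction of venc (0.02 mimics
#'   4D Flow noise).
#' @param seed RNG seed for the noise draw.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(dx = 2.4, dt = 40, noise_sd_frac = 0, seed = NULL) {
  stopifnot(dx > 0, dt > 0, noise_sd_frac >= 0)
  structure(list(dx = dx, dt = dt, noise_sd_frac = noise_sd_frac,
                 seed = seed), class = "grid_spec")
}

# run code with a temporary RNG state seeded by `seed` (restores afterwards)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Voxelize an analytic velocity field onto a uniform grid
#'
#' Samples the field at voxel centres over a bounding box (synthetic-MRI
#' downsampling); voxels outside the lumen are zero by construction of the
#' analytic field. Gaussian noise with SD `noise_sd_frac * venc` is then
#' added independently per component, reproducibly under `spec$seed`.
#'
#' @param field a `flow_field` (or analytic [velocity_source]).
#' @param spec a [grid_spec()].
#' @param bbox `2 x 3` matrix: rows are the min and max corner, mm.
#' @param t time, ms.
#' @return a `uniform_grid` [velocity_source].
#' @export
voxelize <- function(field, spec, bbox, t = 0) {
  src <- if (inherits(field, "flow_field")) field$source else field
  stopifnot(inherits(src, "velocity_source"), src$kind == "analytic")
  bbox <- as.matrix(bbox)
  if (any(bbox[2, ] - bbox[1, ] <= 0)) stop("degenerate bounding box")
  ax <- lapply(1:3, function(k)
    seq(bbox[1, k] + spec$dx / 2, bbox[2, k], by = spec$dx))
  nd <- vapply(ax, length, integer(1))
  q <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  V <- src$fun(q, t)
  vals <- array(V, c(nd, 3))
  if (spec$noise_sd_frac > 0) {
    sd <- spec$noise_sd_frac * src$venc
    vals <- vals + with_seed(spec$seed,
                             array(stats::rnorm(length(vals), 0, sd),
                                   dim(vals)))
  }
  velocity_source_grid(vals, dx = spec$dx,
                       origin = bbox[1, ] + spec$dx / 2, venc = src$venc)
}

#' Generate a synthetic training dataset of tube geometries
#'
#' Builds `n_geometries` tube cases with randomly varied radius, taper,
#' curvature and peak velocity, each carrying: the `(n_U, n_V)` wall surface,
#' inward normals, validity mask (first 3 inlet rings excluded), analytic
#' velocity sheets at all requested inward distances for every time frame,
#' and exact closed-form WSS label flatmaps. Cases are split by geometry into
#' train/validation/test so no geometry is shared across splits.
#'
#' @param n_geometries number of cases (>= 3; the last two become validation
#'   and test).
#' @param radius_range range of the mean tube radius, mm.
#' @param vmax_range range of peak centreline velocity, m/s.
#' @param taper_range range of the linear radius taper fraction over the
#'   tube length.
#' @param curved_fraction fraction of cases built on an arc centerline
#'   (labels on curved tubes use the per-cross-section formula and are
#'   approximate).
#' @param n_frames time frames per cycle.
#' @param sheet_distances inward sheet distances, mm.
#' @param n_U,n_V template grid size.
#' @param tube_length tube length, mm.
#' @param seed RNG seed.
#' @return list of class `wss_dataset` with elements `cases`, `split`,
#'   `distances`, `times`.
#' @export
make_dataset <- function(n_geometries = 7,
                         radius_range = c(8, 13),
                         vmax_range = c(0.8, 1.4),
                         taper_range = c(-0.25, 0.25),
                         curved_fraction = 0,
                         n_frames = 8,
                         sheet_distances = c(0.3, 0.5, 0.6, 0.8, 1.0, 2.0),
                         n_U = 48, n_V = 93, tube_length = 120,
                         seed = 1) {
  stopifnot(n_geometries >= 3,
            diff(radius_range) > 0, diff(vmax_range) > 0)
  cases <- with_seed(seed, {
    lapply(seq_len(n_geometries), function(g) {
      R0 <- stats::runif(1, radius_range[1], radius_range[2])
      Vmax <- stats::runif(1, vmax_range[1], vmax_range[2])
      tap <- stats::runif(1, taper_range[1], taper_range[2])
      wob <- stats::runif(1, 0, 0.06)
      curved <- stats::runif(1) < curved_fraction
      n_cl <- max(120, n_V)
      cl <- if (curved) centerline_arc(bend_radius = tube_length / (pi / 2),
                                       n = n_cl)
            else centerline_straight(tube_length, n_cl)
      zrel <- seq(0, 1, length.out = n_cl)
      rad <- R0 * (1 + tap * (zrel - 0.5) + wob * sin(2 * pi * zrel))
      model <- flow_model(R = R0, Vmax_peak = Vmax)
      field <- tube_flow_field(model, cl, rad, exponent = 2)
      cl_s <- resample_centerline(cl, n_V)
      rad_s <- R0 * (1 + tap * (seq(0, 1, length.out = n_V) - 0.5) +
                       wob * sin(2 * pi * seq(0, 1, length.out = n_V)))
      surface <- build_coarse_template(n_U, n_V, cl, rad_s)
      normals <- inward_normals(surface)
      mask <- build_branch_mask(surface) & normals$mask
      times <- seq(0, model$cycle, length.out = n_frames)
      sheets <- lapply(times, function(t)
        lapply(sheet_distances, function(d) {
          sh <- sample_velocity_sheet(field$source, surface, d, t, normals)
          sh$mask <- sh$mask & mask
          sh
        }))
      labels <- lapply(times, function(t)
        analytic_wss_flatmap(field, surface, t, mask = mask))
      list(id = g, model = model, field = field, surface = surface,
           normals = normals, mask = mask, times = times,
           distances = sheet_distances, sheets = sheets, labels = labels,
           curved = curved)
    })
  })
  split <- list(train = seq_len(n_geometries - 2),
                val = n_geometries - 1L, test = n_geometries)
  structure(list(cases = cases, split = split,
                 distances = sheet_distances,
                 times = cases[[1]]$times),
            class = "wss_dataset")
}

#' @export
print.wss_dataset <- function(x, ...) {
  cat(sprintf("<wss_dataset: %d cases (%d train / %d val / %d test), %d frames>\n",
              length(x$cases), length(x$split$train), length(x$split$val),
              length(x$split$test), length(x$times)))
  invisible(x)
}
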