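# Shared fixtures, built once per test run.

# steady (s = 1) flow model for closed-form checks
steady_model <- function(R = 10, Vmax = 1) {
  flow_model(R = R, Vmax_peak = Vmax, waveform = function(t) rep(1, length(t)))
}

# fine cylinder template built directly (rings exactly circular, radius R)
cylinder_surface <- local({
  cache <- list()
  function(R = 10, n_U = 48, n_V = 93, length = 120) {
    key <- paste(R, n_U, n_V, length)
    if (is.null(cache[[key]]))
      cache[[key]] <<- build_coarse_template(
        n_U, n_V, centerline_straight(length, max(120, n_V)), R)
    cache[[key]]
  }
})

# steady Poiseuille field + sheets on the cylinder (memoized)
poiseuille_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      surf <- cylinder_surface()
      model <- steady_model()
      field <- poiseuille_field(model, centerline_straight(120, 120), 10)
      normals <- inward_normals(surf)
      s1 <- sample_velocity_sheet(field$source, surf, 1.0, 0, normals)
      s2 <- sample_velocity_sheet(field$source, surf, 2.0, 0, normals)
      cache <<- list(surface = surf, model = model, field = field,
                     normals = normals, sheet1 = s1, sheet2 = s2)
    }
    cache
  }
})

# small synthetic dataset shared across network tests (5 train geometries)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_dataset(n_geometries = 7, n_frames = 6, seed = 11)
    cache
  }
})

# a random valid WSS flatmap pair for metric tests
random_wss_flatmap <- function(U = 8, V = 10, seed = 1, mask = NULL) {
  set.seed(seed)
  vals <- array(rnorm(U * V * 3), c(U, V, 3))
  flatmap(vals, mask = mask)
}
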