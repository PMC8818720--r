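#' Configuration for the end-to-end inference workflow
#'
#' Collects the inputs of [run_inference_workflow()]: the vessel surface
#' (a registered `quad_surface`, or a coarse template plus a target surface
#' to register it to), the velocity volume, the trained network, sheet
#' distances and output location. All referenced files must exist.
#'
#' @param surface a registered [quad_surface()] or a path to a PLY/OBJ mesh
#'   whose vertices are a registered `48 x 93` grid.
#' @param template optional coarse template [quad_surface()]; when given
#'   together with `target`, registration is performed.
#' @param target optional target surface point set (`n x 3` or PLY/OBJ path).
#' @param volume a [velocity_source] or a NIfTI path.
#' @param net a `wss_net` or an RDS checkpoint path.
#' @param distances inward sheet distances in mm (default `c(1, 2)`, the
#'   MRI-resolution choice).
#' @param times frame times (ms) at which to run inference.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   persistence.
#' @param stride sliding-window stride for [predict_flatmap()].
#' @param seed seed recorded in output provenance.
#' @return list of class `run_config`.
#' @export
run_config <- function(surface = NULL, template = NULL, target = NULL,
                       volume = NULL, net = NULL,
                       distances = c(1, 2), times = 0,
                       out_dir = NULL, stride = 15, seed = 1) {
  for (p in list(surface, target, volume, net))
    if (is.character(p) && !file.exists(p)) stop("missing file: ", p)
  structure(list(surface = surface, template = template, target = target,
                 volume = volume, net = net, distances = distances,
                 times = times, out_dir = out_dir, stride = stride,
                 seed = seed),
            class = "run_config")
}

workflow_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("workflow stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full inference workflow
#'
#' Registration (optional) -> inward normals -> velocity-sheet extraction at
#' the configured distances -> 15-channel input assembly -> network
#' prediction -> per-frame WSS flatmaps, plus TAWSS/OSI when more than one
#' frame is requested. Every stage logs a message; any failure aborts naming
#' the stage. Outputs (when `out_dir` is set) are flatmap NIfTI files with
#' provenance sidecars (seed + configuration hash), so a rerun with the same
#' configuration is bit-identical.
#'
#' @param config a [run_config()].
#' @return list with `surface`, `predictions` (list of WSS flatmaps),
#'   `times`, and (for multi-frame runs) `tawss` and `osi` flatmaps.
#' @export
run_inference_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config[c("distances", "times", "stride", "seed")])
  prov <- list(seed = config$seed, config = hash)
  surface <- workflow_stage("surface", {
    s <- config$surface
    if (is.character(s)) {
      mesh <- if (grepl("\\.obj$", s)) read_obj(s) else read_ply(s)
      # vertices of a structured grid written by write_ply(quad_surface)
      nU <- 48L
      quad_surface(array(mesh$vertices, c(nU, nrow(mesh$vertices) / nU, 3)))
    } else if (!is.null(config$template) && !is.null(config$target)) {
      tg <- config$target
      if (is.character(tg)) {
        mesh <- if (grepl("\\.obj$", tg)) read_obj(tg) else read_ply(tg)
        tg <- mesh$vertices
      }
      message("* registering template (CPD rigid/affine/deformable)")
      register_pipeline(config$template, tg)
    } else if (inherits(s, "quad_surface")) s
    else stop("no surface or template+target provided")
  })
  volume <- workflow_stage("volume", {
    v <- config$volume
    if (is.character(v)) read_velocity_volume(v) else v
  })
  net <- workflow_stage("weights", {
    w <- config$net
    if (is.character(w)) load_network(w) else w
  })
  message(sprintf("* extracting sheets at %s mm",
                  paste(config$distances, collapse = ", ")))
  normals <- workflow_stage("normals", inward_normals(surface))
  wall <- coordinate_flatmap(surface)
  d1 <- config$distances[1]; d2 <- config$distances[2]
  preds <- vector("list", length(config$times))
  for (i in seq_along(config$times)) {
    t <- config$times[i]
    inp <- workflow_stage("extract", {
      s1 <- sample_velocity_sheet(volume, surface, d1, t, normals)
      s2 <- sample_velocity_sheet(volume, surface, d2, t, normals)
      assemble_input(wall, inner_coordinates(surface, d1, normals),
                     inner_coordinates(surface, d2, normals), s1, s2)
    })
    preds[[i]] <- workflow_stage("predict",
                                 predict_flatmap(net, inp, config$stride))
  }
  out <- list(surface = surface, predictions = preds, times = config$times)
  if (length(preds) >= 2) {
    series <- wss_series(preds, config$times)
    out$tawss <- tawss(series)
    out$osi <- osi(series)
  }
  if (!is.null(config$out_dir)) {
    workflow_stage("persist", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(preds))
        write_flatmap(preds[[i]],
                      file.path(config$out_dir,
                                sprintf("wss_frame%03d.nii", i)),
                      provenance = prov)
      if (!is.null(out$tawss)) {
        write_flatmap(out$tawss, file.path(config$out_dir, "tawss.nii"),
                      provenance = prov)
        write_flatmap(out$osi, file.path(config$out_dir, "osi.nii"),
                      provenance = prov)
      }
      write_ply(surface, file.path(config$out_dir, "surface.ply"))
    })
    message("* outputs written to ", config$out_dir)
  }
  out
}
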