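#' Read and write 3D+t velocity volumes (NIfTI)
#'
#' A velocity volume is stored as a 4D NIfTI image `(nx, ny, nz, 3)` holding
#' the three Cartesian velocity components in m/s, with the voxel spacing in
#' the NIfTI header (mm; anisotropic spacing is preserved) and a JSON
#' sidecar (`<path>.json`) carrying `venc` and the grid origin. Reading
#' fails loudly if the header spacing is missing or non-positive.
#'
#' @param src a `uniform_grid` [velocity_source].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `read_velocity_volume()`: a `uniform_grid` [velocity_source];
#'   `write_velocity_volume()`: `path`, invisibly.
#' @export
write_velocity_volume <- function(src, path) {
  stopifnot(inherits(src, "velocity_source"), src$kind == "uniform_grid")
  img <- RNifti::asNifti(src$values)
  RNifti::pixdim(img) <- c(src$dx, 1)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(venc = src$venc, origin = src$origin,
                            components = c("vx", "vy", "vz"),
                            units = "m/s"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_velocity_volume
#' @export
read_velocity_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 3L)
    stop("velocity volume must be 4D with 3 components")
  arr <- array(as.numeric(img), dim(img))
  pd <- RNifti::pixdim(img)
  dx <- pd[1:3]
  if (any(!is.finite(dx)) || any(dx <= 0))
    stop("missing or invalid voxel spacing 'dx' in NIfTI header")
  meta <- list(venc = 1.5, origin = c(0, 0, 0))
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    js <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(js$venc)) meta$venc <- js$venc
    if (!is.null(js$origin)) meta$origin <- js$origin
  }
  velocity_source_grid(arr, dx = dx, origin = meta$origin, venc = meta$venc)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Read and write flatmaps (NIfTI + JSON sidecar)
#'
#' Flatmap values are stored as a 3D NIfTI `(U, V, C)`; the sidecar JSON
#' carries the validity mask, channel names, and provenance (seed and
#' configuration hash) so outputs are self-describing and reruns can be
#' checked for bit-identity.
#'
#' @param fm a [flatmap()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param provenance optional named list (e.g. seed, config hash) embedded
#'   in the sidecar.
#' @return `read_flatmap()`: a [flatmap()]; `write_flatmap()`: `path`,
#'   invisibly.
#' @export
write_flatmap <- function(fm, path, provenance = NULL) {
  stopifnot(inherits(fm, "flatmap"))
  RNifti::writeNifti(RNifti::asNifti(fm$values), path)
  jsonlite::write_json(
    list(mask = as.integer(fm$mask), dim = dim(fm$values),
         channel_names = fm$channel_names, provenance = provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flatmap
#' @export
read_flatmap <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  sp <- sidecar_path(path)
  mask <- NULL; cn <- NULL
  if (file.exists(sp)) {
    js <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!is.null(js$mask))
      mask <- matrix(as.logical(js$mask), dim(vals)[1], dim(vals)[2])
    cn <- js$channel_names
  }
  flatmap(vals, mask = mask, channel_names = cn)
}

#' Save and load trained networks
#'
#' Checkpoints are written as RDS (the parameters and batch-norm state) with
#' a JSON sidecar describing the architecture configuration.
#'
#' @param net a `wss_net`.
#' @param path checkpoint path (`.rds`).
#' @return `load_network()`: a `wss_net`; `save_network()`: `path`,
#'   invisibly.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "wss_net"))
  saveRDS(net, path)
  jsonlite::write_json(unclass(net$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "wss_net"))
  net
}

# small stable polynomial hash of a serialized R object (provenance tags)
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
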