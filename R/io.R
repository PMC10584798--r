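# File interchange: NIfTI-1 volumes, YAML phantom specifications and a
# projection container (RDS payload plus JSON metadata sidecar).

#' Write a volume as NIfTI-1
#'
#' Stores the voxel array with mm spacing in the header.  Works for
#' `recon_volume`, [activity_map()], [mu_map()] or a plain array (then
#' `spacing` is required).  Logical masks are stored as 0/1 label maps.
#'
#' @param vol Volume object or array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing (mm) for plain arrays.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, c("recon_volume", "activity_map", "mu_map"))) {
    spacing <- vol$grid$spacing
    values <- vol$values
  } else {
    if (is.null(spacing)) stop("spacing required for plain arrays")
    values <- vol
  }
  if (is.logical(values)) values <- array(as.integer(values), dim(values))
  img <- RNifti::asNifti(values)
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file path.
#' @return List with `values` (array) and `grid` (a centred [voxel_grid()]
#'   with the header spacing).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  list(values = values,
       grid = voxel_grid(dim(values), spacing))
}

#' Persist a projection set
#'
#' Writes the count arrays as a compressed RDS payload and the acquisition
#' metadata (geometry, windows, detector model, seed, timestamps) as a JSON
#' sidecar next to it.
#'
#' @param proj A [projection_set][forward_project()].
#' @param path Output path (conventionally `.luq`).
#' @return The path, invisibly.
#' @export
write_projections <- function(proj, path) {
  stopifnot(inherits(proj, "projection_set"))
  saveRDS(proj, path, compress = "gzip")
  meta <- list(n_views = proj$geometry$n_views,
               angular_step = proj$geometry$angular_step,
               detector_radius = proj$geometry$detector_radius,
               duration = proj$geometry$duration,
               windows = unclass(proj$windows),
               detector = unclass(proj$detector),
               acq_start = proj$acq_start,
               noiseless = proj$noiseless,
               seed = proj$seed,
               dims = dim(proj$photopeak))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a projection set written by [write_projections()]
#'
#' @param path Container path.
#' @return The `projection_set`.
#' @export
read_projections <- function(path) {
  proj <- readRDS(path)
  if (!inherits(proj, "projection_set")) stop("not a projection container")
  proj
}

#' Write a phantom specification as YAML
#'
#' @param spec Named list describing a phantom (see [read_phantom_spec()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read a phantom specification from YAML
#'
#' The specification is a named list with a `type` field (`"cylinder"`,
#' `"nema"` or `"patient"`) plus the arguments of the corresponding
#' `make_*_phantom()` constructor; [build_phantom()] renders it on a grid.
#'
#' @param path YAML file path.
#' @return The specification list.
#' @export
read_phantom_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$type)) stop("phantom spec lacks a `type` field")
  spec
}

#' Render a phantom specification on a grid
#'
#' @param spec Specification list (see [read_phantom_spec()]).
#' @param grid A [voxel_grid()].
#' @return The phantom list produced by the matching constructor.
#' @export
build_phantom <- function(spec, grid) {
  type <- spec$type
  if (is.null(type)) stop("phantom spec lacks a `type` field")
  spec$type <- NULL
  spec$grid <- grid
  switch(type,
         cylinder = do.call(make_cylinder_phantom, spec),
         nema = do.call(make_nema_phantom, spec),
         patient = do.call(make_patient_phantom, spec),
         stop("unknown phantom type: ", type))
}
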