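#' Read a 3D NIfTI volume
#'
#' Accepts plain or gzipped NIfTI-1/2; voxel spacing is taken from the
#' header `pixdim`.
#'
#' @param path file path.
#' @return A [cf_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D payload in ", path)
  cf_volume(array(as.numeric(img), d), RNifti::pixdim(img)[1:3])
}

#' Write a 3D volume as NIfTI
#'
#' @param volume a [cf_volume()] (logical data is written as 0/1).
#' @param path output path; `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  volume <- as_volume(volume)
  dat <- volume$data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim(dat))
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a 2D deformation field as NIfTI
#'
#' Fields are stored as a two-component volume `(h, w, 2)` with
#' displacements in pixels.
#'
#' @param field `(h, w, 2)` displacement array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `write_field_2d()`: invisibly, `path`; `read_field_2d()`: a
#'   `cf_field2d` array.
#' @export
write_field_2d <- function(field, path) {
  fd <- dim(field)
  if (length(fd) != 3L || fd[3] != 2L)
    stop("expected a (h, w, 2) displacement array")
  RNifti::writeNifti(RNifti::asNifti(unclass(field)), path)
  invisible(path)
}

#' @rdname write_field_2d
#' @export
read_field_2d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 2L)
    stop("expected a (h, w, 2) displacement field, got dims ",
         paste(d, collapse = "x"))
  structure(array(as.numeric(img), d), class = c("cf_field2d", "array"))
}

#' Save a trained model checkpoint
#'
#' Single-file archive holding the weights, the training configuration, the
#' seed and the package version.
#'
#' @param model a `cf_reorient_model` or `cf_sdn_model`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, c("cf_reorient_model", "cf_sdn_model")))
    stop("not a cardiofuse model")
  saveRDS(list(class = class(model)[1], params = model$params,
               config = model$config, seed = model$config$seed,
               version = model$version), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @return The restored model.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  x <- readRDS(path)
  structure(list(params = x$params, config = x$config, version = x$version),
            class = x$class)
}
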