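#' 3D scalar volume with voxel spacing
#'
#' A minimal container for a 3D image: a numeric (or logical) array plus the
#' per-axis voxel spacing in millimetres. Axis roles follow the package-wide
#' convention: index 1 = axial (S-I), 2 = coronal (A-P), 3 = sagittal (R-L).
#'
#' @param data 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @return A `cf_volume` object.
#' @export
cf_volume <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stop("cf_volume expects a 3D array, got ", length(dim(data)),
         " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  structure(list(data = data, spacing = spacing), class = "cf_volume")
}

#' @export
print.cf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cf_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.cf_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "cf_volume")

as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (is_volume(x)) x else cf_volume(x, spacing)
}

#' Short-axis CMR stack
#'
#' Ordered short-axis 2D frames indexed by slice and time. The first slice is
#' the most basal; frames share one in-plane pixel spacing, slices are
#' separated by `slice_spacing_mm` along the LV long axis.
#'
#' @param frames 4D array `(x, y, slice, time)`.
#' @param slice_spacing_mm inter-slice distance in mm.
#' @param pixel_spacing_mm in-plane pixel size in mm.
#' @return A `cf_cmr_stack` object.
#' @export
cf_cmr_stack <- function(frames, slice_spacing_mm, pixel_spacing_mm = 1) {
  if (length(dim(frames)) != 4L)
    stop("cf_cmr_stack expects a 4D array (x, y, slice, time)")
  if (slice_spacing_mm <= 0 || pixel_spacing_mm <= 0)
    stop("spacings must be positive")
  structure(list(frames = frames,
                 slice_spacing_mm = as.numeric(slice_spacing_mm),
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 n_slices = dim(frames)[3], n_frames = dim(frames)[4]),
            class = "cf_cmr_stack")
}

#' @export
print.cf_cmr_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cf_cmr_stack> %d x %d px, %d slices x %d frames, slice gap %.3g mm, pixel %.3g mm\n",
              d[1], d[2], d[3], d[4], x$slice_spacing_mm, x$pixel_spacing_mm))
  invisible(x)
}

# min-max normalization to [0, 1]; constant input maps to 0.
minmax_norm <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}
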