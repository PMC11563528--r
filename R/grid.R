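#' Shared 3D voxel-grid geometry
#'
#' All volumes belonging to one subject (ASL series, M0, CBF map, lesion and
#' tissue masks) must live on a single grid: same array dimensions, same voxel
#' spacing, same left-right axis. `volume_grid()` builds the descriptor that
#' every other function validates against.
#'
#' @param shape Integer vector of length 3, array dimensions (all positive).
#' @param spacing_mm Numeric vector of length 3, voxel pitch in mm along each
#'   axis (all positive). For a 2D multi-slice acquisition pass the in-plane
#'   voxel size for the first two axes and the slice *thickness* for the
#'   third; a declared `slice_gap_mm` is added to the third axis when volumes
#'   are computed, so thickness 5.5 with gap 0.55 yields an effective slice
#'   pitch of 6.05 mm.
#' @param lr_axis Which array axis runs left-right (1, 2 or 3). Mirroring
#'   reflects indices about the mid-plane of this axis. Default 1.
#' @param slice_gap_mm Interslice gap in mm added to the third axis for
#'   volume computations. Default 0 (contiguous slices).
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(80, 80, 20), c(3, 3, 5.5), slice_gap_mm = 0.55)
#' voxel_volume_ml(g)  # 3 * 3 * 6.05 / 1000
#' @export
volume_grid <- function(shape, spacing_mm, lr_axis = 1L, slice_gap_mm = 0) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive reals")
  lr_axis <- as.integer(lr_axis)
  if (length(lr_axis) != 1L || is.na(lr_axis) || !lr_axis %in% 1:3)
    stop("`lr_axis` must be 1, 2 or 3")
  if (!is.finite(slice_gap_mm) || slice_gap_mm < 0)
    stop("`slice_gap_mm` must be a nonnegative real")
  structure(
    list(shape = shape, spacing_mm = spacing_mm, lr_axis = lr_axis,
         slice_gap_mm = as.numeric(slice_gap_mm)),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, %s mm, lr_axis = %d, slice gap %.3g mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              x$lr_axis, x$slice_gap_mm))
  invisible(x)
}

#' Voxel volume in ml, honouring a declared interslice gap
#'
#' @param grid A [volume_grid()].
#' @return Scalar volume of one voxel in ml (effective pitch product / 1000).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  pitch <- grid$spacing_mm
  pitch[3] <- pitch[3] + grid$slice_gap_mm
  prod(pitch) / 1000
}

#' Test whether two grids are identical
#'
#' @param a,b [volume_grid()] objects.
#' @return Logical scalar.
#' @export
grids_match <- function(a, b) {
  inherits(a, "volume_grid") && inherits(b, "volume_grid") &&
    identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm)) &&
    identical(a$lr_axis, b$lr_axis) &&
    isTRUE(all.equal(a$slice_gap_mm, b$slice_gap_mm))
}

# internal: stop with the offending stage when an array does not sit on `grid`
check_on_grid <- function(vol, grid, what = "volume") {
  if (!identical(dim(vol), grid$shape))
    stop(sprintf("grid mismatch: %s has dims %s, grid expects %s", what,
                 paste(dim(vol), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  invisible(TRUE)
}
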