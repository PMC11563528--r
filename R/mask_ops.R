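#' Binary mask on a voxel grid
#'
#' Wraps a 3D 0/1 array together with its [volume_grid()] and a free-text
#' label. All mask algebra in the package (thresholding, mirroring, hematoma
#' exclusion, intersection, volume in ml) operates on these objects.
#'
#' @param data 3D array coercible to 0/1 (logical or numeric in \{0,1\}).
#' @param grid The [volume_grid()] the mask lives on.
#' @param label Free-text label carried through for error messages and logs.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, grid, label = "mask") {
  stopifnot(inherits(grid, "volume_grid"))
  check_on_grid(data, grid, label)
  v <- as.numeric(data)
  if (any(is.na(v)) || !all(v %in% c(0, 1)))
    stop(sprintf("mask '%s' must contain only 0/1 values", label))
  arr <- array(v, dim = grid$shape)
  structure(list(data = arr, grid = grid, label = label), class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("mask_volume '%s': %d of %d voxels set (%.2f ml)\n",
              x$label, sum(x$data), length(x$data), mask_volume_ml(x)))
  invisible(x)
}

#' Threshold a gray-matter probability map into a binary GM mask
#'
#' A voxel enters the mask when its GM probability is greater than or equal
#' to the threshold (boundary inclusive). The default threshold of 0.6
#' restricts perfusion readout to cortical gray matter, limiting intravascular
#' signal spill-over from sulcal vessels and low white-matter signal.
#'
#' @param gm_prob 3D array of probabilities in \[0, 1\].
#' @param grid The [volume_grid()].
#' @param threshold Inclusion threshold in (0, 1); default 0.6.
#' @return A `mask_volume` labelled "gm".
#' @export
threshold_gm <- function(gm_prob, grid, threshold = 0.6) {
  stopifnot(inherits(grid, "volume_grid"))
  check_on_grid(gm_prob, grid, "gm_prob")
  if (any(!is.finite(gm_prob)) || any(gm_prob < 0) || any(gm_prob > 1))
    stop("`gm_prob` must lie in [0, 1] everywhere")
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)")
  mask_volume(gm_prob >= threshold, grid, label = "gm")
}

#' Mirror a mask across the grid mid-plane of the left-right axis
#'
#' Pure voxel-grid reflection: index i on the left-right axis maps to
#' N - 1 - i (0-based), all other axes untouched. On an odd-extent axis the
#' central slice is its own image. This realizes the contralateral
#' homologous-region construction used to reference infarct perfusion against
#' the unaffected hemisphere; inputs must already be approximately
#' grid-symmetric (anatomical midline estimation is out of scope and the
#' phantom generator guarantees symmetry by construction).
#'
#' @param mask A `mask_volume`.
#' @return The mirrored `mask_volume`.
#' @export
mirror_mask <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  out <- mask
  out$data <- flip_axis(mask$data, mask$grid$lr_axis)
  out$label <- paste0("mirror(", mask$label, ")")
  out
}

# internal: reverse an array along one axis
flip_axis <- function(arr, axis) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(arr)[axis]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Remove hematoma voxels from an infarct mask
#'
#' ASL perfusion readout is T2*-sensitive, so voxels with visible bleeding
#' corrupt the CBF signal; they are excluded from the infarct mask before any
#' readout (set difference infarct \\ hematoma).
#'
#' @param infarct,hematoma `mask_volume`s on the same grid.
#' @return A `mask_volume` disjoint from `hematoma`.
#' @export
exclude_hematoma <- function(infarct, hematoma) {
  stopifnot(inherits(infarct, "mask_volume"), inherits(hematoma, "mask_volume"))
  if (!grids_match(infarct$grid, hematoma$grid))
    stop("grid mismatch between infarct and hematoma masks")
  out <- infarct
  out$data <- infarct$data * (1 - hematoma$data)
  out$label <- paste0(infarct$label, " \\ ", hematoma$label)
  out
}

#' Voxelwise intersection (logical AND) of two masks
#'
#' @param a,b `mask_volume`s on the same grid.
#' @return A `mask_volume`.
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "mask_volume"), inherits(b, "mask_volume"))
  if (!grids_match(a$grid, b$grid))
    stop(sprintf("grid mismatch between masks '%s' and '%s'", a$label, b$label))
  out <- a
  out$data <- a$data * b$data
  out$label <- paste0(a$label, " & ", b$label)
  out
}

#' Mask volume in ml
#'
#' Voxel count times the voxel volume (effective pitch product, including any
#' declared interslice gap) divided by 1000.
#'
#' @param mask A `mask_volume`.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  sum(mask$data) * voxel_volume_ml(mask$grid)
}

#' Number of voxels set in a mask
#' @param mask A `mask_volume`.
#' @return Integer count.
#' @export
mask_count <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  as.integer(sum(mask$data))
}
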