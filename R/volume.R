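#' 3-D scalar voxel volume
#'
#' A synthetic CT image: a 3-D array of intensities with per-axis voxel
#' spacing and a world origin. The world coordinate of voxel `(i,j,k)`
#' (1-based R indices) is `origin + (c(i,j,k) - 1) * spacing` — the
#' voxel-centre convention, which keeps marching-cubes output aligned with
#' distance-map geometry.
#'
#' @param values 3-D numeric array.
#' @param spacing per-axis voxel size in mm, length 3, all > 0.
#' @param origin world coordinate (mm) of the centre of voxel (1,1,1).
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3)
    stop("voxel_volume: values must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel_volume: spacing must be 3 positive values")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("voxel_volume: origin must be 3 finite values")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "voxel_volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' World coordinates of voxel centres
#' @param volume a `voxel_volume`.
#' @param index integer matrix or vector of 1-based voxel indices (i,j,k).
#' @return matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(volume, index) {
  if (is.null(dim(index))) index <- matrix(index, ncol = 3)
  sweep(sweep(index - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Binary voxel mask
#'
#' Same grid semantics as [voxel_volume()] but with logical values; the
#' intermediate of the segmentation chain.
#'
#' @param values 3-D logical array.
#' @param spacing,origin as in [voxel_volume()].
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.logical(values)) stop("binary_mask: values must be logical")
  v <- voxel_volume(array(values, dim(values)), spacing, origin)
  class(v) <- c("binary_mask", "voxel_volume")
  v
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "binary_mask: %d x %d x %d voxels, %d foreground, spacing (%g, %g, %g) mm\n",
    d[1], d[2], d[3], sum(x$values), x$spacing[1], x$spacing[2],
    x$spacing[3]))
  invisible(x)
}
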