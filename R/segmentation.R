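#' Threshold-connected region growing
#'
#' The 6-connected component of the voxels whose intensity lies in
#' `[lower, upper]` that contains the seed voxel. Face connectivity matches
#' the standard threshold-connected flood fill used in semi-automatic bone
#' segmentation.
#'
#' @param volume a [voxel_volume()].
#' @param seed_voxel 1-based voxel index triple `c(i, j, k)`.
#' @param lower,upper intensity bounds.
#' @return a [binary_mask()].
#' @export
region_grow <- function(volume, seed_voxel, lower, upper) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$values)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3 || any(seed_voxel < 1) ||
      any(seed_voxel > d))
    stop("region_grow: seed voxel outside the grid")
  sval <- volume$values[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
  if (sval < lower || sval > upper)
    stop(sprintf(
      "region_grow: seed intensity %g outside threshold band [%g, %g]",
      sval, lower, upper))
  m <- .region_grow_cpp(as.numeric(volume$values), d, seed_voxel - 1L,
                        lower, upper)
  binary_mask(array(m, d), volume$spacing, volume$origin)
}

#' Morphological closing with a Euclidean ball
#'
#' Dilation then erosion with a ball of the given physical radius,
#' implemented exactly through the Euclidean distance transform (so the
#' structuring element respects anisotropic spacing): dilation keeps voxels
#' within `radius` of the foreground, erosion keeps voxels farther than
#' `radius` from the dilated background. Fills holes and closes gaps
#' narrower than twice the radius.
#'
#' @param mask a [binary_mask()].
#' @param radius ball radius in mm, >= 0; 0 is the identity.
#' @export
binary_close <- function(mask, radius) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius < 0) stop("binary_close: radius must be >= 0")
  if (radius == 0) return(mask)
  d <- dim(mask$values)
  tol <- 1e-9
  dil <- .edt_sq_cpp(as.logical(mask$values), d, mask$spacing) <=
    (radius + tol)^2
  ero <- .edt_sq_cpp(!dil, d, mask$spacing) > (radius + tol)^2
  binary_mask(array(ero, d), mask$spacing, mask$origin)
}

#' Fill enclosed cavities of a binary mask
#'
#' Background components not 6-connected to the grid border become
#' foreground. Idempotent.
#'
#' @param mask a [binary_mask()].
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$values)
  reach <- .border_background_cpp(as.logical(mask$values), d)
  binary_mask(array(!reach, d), mask$spacing, mask$origin)
}

#' Signed Euclidean distance map of a binary mask
#'
#' Exact Euclidean distance in mm to the opposite phase, negative inside
#' the mask and positive outside: `d(x) = dist(x, foreground) -
#' dist(x, background)`. The zero crossing lies on the mid-plane between
#' adjacent foreground and background voxel centres (half-voxel
#' convention), which is where the iso-surface extractor places the mesh.
#'
#' @param mask a [binary_mask()] with both phases present.
#' @return a [voxel_volume()] of signed distances.
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  v <- as.logical(mask$values)
  if (all(v)) stop("signed_distance: mask is all foreground")
  if (!any(v)) stop("signed_distance: mask is all background")
  d <- dim(mask$values)
  dout <- sqrt(.edt_sq_cpp(v, d, mask$spacing))
  din <- sqrt(.edt_sq_cpp(!v, d, mask$spacing))
  voxel_volume(array(dout - din, d), mask$spacing, mask$origin)
}

#' Smooth a distance map
#'
#' Gaussian smoothing of the signed distance map, standing in for the
#' boundary-refining level-set step of interactive segmentation tools: it
#' removes voxel-scale ripples from the zero level while moving the
#' enclosed volume of convex shapes by well under 1% for
#' `sigma_mm <= spacing`.
#'
#' @param distance a [voxel_volume()] of signed distances.
#' @param sigma_mm Gaussian SD in mm, >= 0; 0 returns the input unchanged.
#' @export
smooth_refine <- function(distance, sigma_mm) {
  stopifnot(inherits(distance, "voxel_volume"))
  if (sigma_mm < 0) stop("smooth_refine: sigma must be >= 0")
  if (sigma_mm == 0) return(distance)
  d <- dim(distance$values)
  vals <- .gauss_blur_cpp(as.numeric(distance$values), d,
                          sigma_mm / distance$spacing)
  voxel_volume(array(vals, d), distance$spacing, distance$origin)
}

#' Extract the iso-surface of a volume as a triangle mesh
#'
#' Marching tetrahedra on the voxel grid: every cube is split into six
#' tetrahedra around a fixed body diagonal, so the triangulation is
#' watertight and unambiguous; vertices are interpolated on grid edges in
#' world coordinates (mm) and normals point outward under the
#' negative-inside sign convention.
#'
#' @param distance a [voxel_volume()] (typically a signed distance map).
#' @param level iso value, default 0; must lie strictly inside the data
#'   range.
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(distance, level = 0) {
  stopifnot(inherits(distance, "voxel_volume"))
  rng <- range(distance$values)
  if (level <= rng[1] || level >= rng[2])
    stop(sprintf(
      "extract_surface: level %g outside data range (%g, %g); empty surface",
      level, rng[1], rng[2]))
  res <- .mtet_cpp(as.numeric(distance$values), dim(distance$values),
                   distance$spacing, distance$origin, level)
  if (nrow(res$vertices) == 0)
    stop("extract_surface: empty surface at the requested level")
  surface_mesh(res$vertices, res$faces)
}

#' Full segmentation chain: volume to surface mesh
#'
#' Composition of the semi-automatic bone segmentation pipeline:
#' threshold-connected region growing, binary closing, hole filling,
#' signed distance map, Gaussian refinement, and zero-level iso-surface
#' extraction. Deterministic; all parameters are recorded in the
#' `"segmentation_log"` attribute of the result.
#'
#' @param volume a [voxel_volume()].
#' @param lower,upper region-growing intensity band.
#' @param seed_voxel 1-based seed index triple; defaults to the voxel with
#'   maximal intensity.
#' @param close_radius closing ball radius in mm.
#' @param smooth_sigma distance-map smoothing SD in mm.
#' @param level iso level for surface extraction (default 0).
#' @return a [surface_mesh()] with a `segmentation_log` attribute.
#' @export
segment <- function(volume, lower, upper, seed_voxel = NULL,
                    close_radius = 0, smooth_sigma = 0, level = 0) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (is.null(seed_voxel)) {
    ix <- which.max(volume$values)
    seed_voxel <- arrayInd(ix, dim(volume$values))[1, ]
  }
  mask <- region_grow(volume, seed_voxel, lower, upper)
  mask <- binary_close(mask, close_radius)
  mask <- fill_holes(mask)
  dist <- signed_distance(mask)
  dist <- smooth_refine(dist, smooth_sigma)
  mesh <- extract_surface(dist, level)
  attr(mesh, "segmentation_log") <- list(
    lower = lower, upper = upper, seed_voxel = as.integer(seed_voxel),
    close_radius = close_radius, smooth_sigma = smooth_sigma, level = level,
    grid = dim(volume$values), spacing = volume$spacing,
    origin = volume$origin)
  mesh
}
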