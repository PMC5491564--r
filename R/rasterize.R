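#' CT imaging condition specification
#'
#' The synthetic counterpart of a scanner protocol. Image noise follows
#' photon (Poisson) statistics in the Gaussian approximation: halving the
#' exposure (mAs) multiplies the noise SD by sqrt(2), i.e.
#' `SD = noise_sigma_ref / sqrt(exposure_fraction)`. Slice thickness acts
#' as axial partial-volume blur with the stated full width at half maximum;
#' in-plane blur has FWHM equal to the voxel spacing.
#'
#' @param spacing isotropic voxel size in mm (> 0).
#' @param slice_thickness axial blur FWHM in mm (> 0); 0.9 mm is a typical
#'   bone protocol, 3.0 mm a typical abdominal protocol.
#' @param exposure_fraction relative exposure in (0, 1].
#' @param hu_bone,hu_background tissue intensities (HU-like units).
#' @param noise_sigma_ref image noise SD at full exposure.
#' @param seed integer seed for the noise realisation.
#' @export
imaging_spec <- function(spacing = 0.5, slice_thickness = 0.9,
                         exposure_fraction = 1, hu_bone = 400,
                         hu_background = 0, noise_sigma_ref = 0,
                         seed = 1L) {
  if (spacing <= 0 || slice_thickness <= 0)
    stop("imaging_spec: spacing and slice_thickness must be > 0")
  if (exposure_fraction <= 0 || exposure_fraction > 1)
    stop("imaging_spec: exposure_fraction must be in (0, 1]")
  if (noise_sigma_ref < 0) stop("imaging_spec: noise_sigma_ref must be >= 0")
  structure(list(spacing = spacing, slice_thickness = slice_thickness,
                 exposure_fraction = exposure_fraction, hu_bone = hu_bone,
                 hu_background = hu_background,
                 noise_sigma_ref = noise_sigma_ref, seed = as.integer(seed)),
            class = "imaging_spec")
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Rasterize a closed mesh into a synthetic CT volume
#'
#' Voxel centres inside the mesh receive `hu_bone`, outside
#' `hu_background`; the binary image is then blurred (axial FWHM =
#' `slice_thickness`, in-plane FWHM = `spacing`) and Gaussian noise with
#' SD `noise_sigma_ref / sqrt(exposure_fraction)` is added under the
#' spec's seed.
#'
#' @param base a closed [surface_mesh()].
#' @param imaging an [imaging_spec()].
#' @param margin padding around the mesh bounding box in mm; defaults to
#'   `2 * slice_thickness + 3 * spacing`.
#' @return a [voxel_volume()].
#' @export
rasterize_volume <- function(base, imaging, margin = NULL) {
  stopifnot(inherits(imaging, "imaging_spec"))
  if (!is_closed_mesh(base))
    stop("rasterize_volume: mesh is not closed; inside test undefined")
  if (is.null(margin))
    margin <- 2 * imaging$slice_thickness + 3 * imaging$spacing
  h <- imaging$spacing
  lo <- apply(base$vertices, 2, min) - margin
  hi <- apply(base$vertices, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  origin <- lo
  inside <- .voxelize_cpp(base$vertices, base$faces, dims, rep(h, 3), origin)
  vals <- imaging$hu_background +
    (imaging$hu_bone - imaging$hu_background) * as.numeric(inside)
  sig_inplane <- fwhm_to_sigma(imaging$spacing) / h
  sig_axial <- fwhm_to_sigma(imaging$slice_thickness) / h
  vals <- .gauss_blur_cpp(vals, dims, c(sig_inplane, sig_inplane, sig_axial))
  if (imaging$noise_sigma_ref > 0) {
    sd_noise <- imaging$noise_sigma_ref / sqrt(imaging$exposure_fraction)
    vals <- vals + with_seed(imaging$seed,
                             rnorm(length(vals), 0, sd_noise))
  }
  voxel_volume(array(vals, dims), rep(h, 3), origin)
}
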