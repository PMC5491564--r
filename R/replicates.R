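#' Surface noise specification for replicate meshes
#'
#' Models segmentation uncertainty as displacement of each vertex along its
#' outward normal by an independent draw from Normal(0, sigma(x)^2). The
#' field sigma(x) is `global_sigma` everywhere except inside spherical
#' patches, which emulate locally elevated variability (joint surfaces,
#' osteophyte-prone regions). Optional resampling (random edge collapse)
#' gives replicates differing vertex counts, as real repeated segmentations
#' produce meshes with different numbers of points.
#'
#' @param global_sigma background normal-displacement SD in mm, >= 0.
#' @param patches list of patches, each `list(centre = c(x, y, z), radius,
#'   sigma)` in mm, overriding `global_sigma` locally (later patches win).
#' @param resample_fraction per-replicate vertex-count jitter in \[0, 0.3\]:
#'   each replicate is decimated to between `(1 - resample_fraction)` and 1
#'   times the base vertex count.
#' @param seed master integer seed; replicate i uses a derived substream.
#' @export
noise_spec <- function(global_sigma = 0, patches = list(),
                       resample_fraction = 0, seed = 1L) {
  if (!is.finite(global_sigma) || global_sigma < 0)
    stop("noise_spec: global_sigma must be >= 0")
  for (p in patches) {
    if (is.null(p$centre) || length(p$centre) != 3)
      stop("noise_spec: patch centre must have 3 coordinates")
    if (is.null(p$radius) || p$radius <= 0)
      stop("noise_spec: patch radius must be > 0")
    if (is.null(p$sigma) || p$sigma < 0)
      stop("noise_spec: patch sigma must be >= 0")
  }
  if (resample_fraction < 0 || resample_fraction > 0.3)
    stop("noise_spec: resample_fraction must be in [0, 0.3]")
  structure(list(global_sigma = global_sigma, patches = patches,
                 resample_fraction = resample_fraction,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Set of replicate meshes of one physical object
#'
#' @param meshes list of at least two [surface_mesh()] objects; vertex
#'   counts may differ.
#' @param label condition name (e.g. `"Philips 0.9 mm"`).
#' @export
replicate_set <- function(meshes, label = "") {
  if (length(meshes) < 2)
    stop("replicate_set: at least two replicates are required")
  for (m in meshes) {
    if (!inherits(m, "surface_mesh")) stop("replicate_set: not a mesh")
    if (nrow(m$vertices) == 0) stop("replicate_set: empty mesh")
  }
  structure(list(meshes = meshes, label = label), class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set '%s': %d replicates, %s vertices\n", x$label,
              length(x$meshes),
              paste(vapply(x$meshes, n_vertices, 0L), collapse = "/")))
  invisible(x)
}

#' Generate noise-perturbed replicate meshes
#'
#' Emulates repeated scans/segmentations of one object without
#' repositioning: each replicate is the base mesh displaced independently
#' along vertex normals under the [noise_spec()]. Fully reproducible:
#' replicate i draws from a fixed substream of the master seed.
#'
#' @param base a closed [surface_mesh()].
#' @param n number of replicates (>= 2; quintuplicate scans use 5).
#' @param noise a [noise_spec()].
#' @param label condition label for the resulting [replicate_set()].
#' @export
perturb_replicates <- function(base, n, noise, label = "") {
  if (n < 2) stop("perturb_replicates: n must be >= 2")
  stopifnot(inherits(noise, "noise_spec"))
  nrm <- vertex_normals(base)
  sigma <- vertex_sigma(base$vertices, noise)
  meshes <- lapply(seq_len(n), function(i) {
    with_seed(derive_seed(noise$seed, i), {
      offs <- rnorm(nrow(base$vertices)) * sigma
      v <- base$vertices + offs * nrm
      m <- surface_mesh(v, base$faces)
      if (noise$resample_fraction > 0) {
        frac <- runif(1, 0, noise$resample_fraction)
        target <- max(4L, as.integer(round((1 - frac) * nrow(v))))
        res <- .edge_collapse_cpp(m$vertices, m$faces, target)
        m <- surface_mesh(res$vertices, res$faces)
      }
      m
    })
  })
  replicate_set(meshes, label)
}

# Per-vertex noise SD: global sigma overridden inside patches.
vertex_sigma <- function(vertices, noise) {
  sigma <- rep(noise$global_sigma, nrow(vertices))
  for (p in noise$patches) {
    d2 <- (vertices[, 1] - p$centre[1])^2 + (vertices[, 2] - p$centre[2])^2 +
      (vertices[, 3] - p$centre[3])^2
    sigma[d2 <= p$radius^2] <- p$sigma
  }
  sigma
}
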