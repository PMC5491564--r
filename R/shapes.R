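#' Generate a closed phantom surface mesh
#'
#' Deterministic stand-ins for the physical bone that replicate scans would
#' image. `sphere` and `ellipsoid` are subdivided icosahedra (resolution =
#' subdivision level); `capsule` and `pelvis_phantom` are zero level sets
#' of implicit functions extracted by marching tetrahedra (resolution =
#' number of grid cells across the largest dimension). `pelvis_phantom` is
#' a union of ellipsoids with a ridge and a thin joint-like gap, giving the
#' multifaceted morphology (smooth cortical shell, crest, narrow joint
#' space) that drives spatially varying segmentation variability.
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"capsule"`,
#'   `"pelvis_phantom"`.
#' @param dimensions kind-specific lengths in mm: sphere `radius`;
#'   ellipsoid semi-axes `c(a, b, c)`; capsule `c(radius, length)` (length
#'   of the cylindrical part); pelvis_phantom overall `c(width, height,
#'   depth)`.
#' @param resolution subdivision level (sphere/ellipsoid, default 4) or
#'   grid cells across the largest extent (implicit shapes, default 80).
#' @return a closed, outward-oriented [surface_mesh()].
#' @export
make_base_shape <- function(kind, dimensions, resolution = NULL) {
  if (any(!is.finite(dimensions)) || any(dimensions <= 0))
    stop("make_base_shape: dimensions must be positive")
  mesh <- switch(kind,
    sphere = {
      if (length(dimensions) != 1)
        stop("make_base_shape: sphere takes a single radius")
      icosphere(dimensions, if (is.null(resolution)) 4L else resolution)
    },
    ellipsoid = {
      if (length(dimensions) != 3)
        stop("make_base_shape: ellipsoid takes three semi-axes")
      s <- icosphere(1, if (is.null(resolution)) 4L else resolution)
      surface_mesh(sweep(s$vertices, 2, dimensions, "*"), s$faces)
    },
    capsule = implicit_shape(capsule_field(dimensions), capsule_bbox(dimensions),
                             if (is.null(resolution)) 80L else resolution),
    pelvis_phantom = implicit_shape(pelvis_field(dimensions),
                                    pelvis_bbox(dimensions),
                                    if (is.null(resolution)) 80L else resolution),
    stop(sprintf("make_base_shape: unknown kind '%s'", kind)))
  if (nrow(mesh$vertices) < 100)
    stop("make_base_shape: resolution yields fewer than 100 vertices")
  mesh
}

# Subdivided icosahedron projected onto the sphere of given radius.
icosphere <- function(radius, subdivisions = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
    ukey <- unique(key)
    mid_id <- nv + match(key, ukey)
    first <- match(ukey, key)
    mids <- (v[e[first, 1], , drop = FALSE] + v[e[first, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  surface_mesh(v * radius, f)
}

# Zero level set of a scalar field (negative inside) on a regular grid.
implicit_shape <- function(field, bbox, resolution) {
  ext <- bbox[2, ] - bbox[1, ]
  h <- max(ext) / resolution
  dims <- pmax(4L, as.integer(ceiling(ext / h)) + 5L)
  origin <- bbox[1, ] - 2 * h
  ax <- lapply(1:3, function(c) origin[c] + (seq_len(dims[c]) - 1) * h)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  vals <- array(field(as.matrix(g)), dims)
  res <- .mtet_cpp(as.numeric(vals), dims, rep(h, 3), origin, 0)
  surface_mesh(res$vertices, res$faces)
}

capsule_field <- function(dimensions) {
  r <- dimensions[1]
  half <- dimensions[2] / 2
  function(p) {
    zc <- pmin(pmax(p[, 3], -half), half)
    sqrt(p[, 1]^2 + p[, 2]^2 + (p[, 3] - zc)^2) - r
  }
}

capsule_bbox <- function(dimensions) {
  r <- dimensions[1]
  half <- dimensions[2] / 2
  rbind(c(-r, -r, -half - r), c(r, r, half + r))
}

ellipsoid_field <- function(centre, semi) {
  function(p) {
    q <- sweep(p, 2, centre)
    # approximate signed distance: scaled radial residual
    rr <- sqrt((q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 +
                 (q[, 3] / semi[3])^2)
    (rr - 1) * min(semi)
  }
}

# Union of ellipsoids with a crest-like ridge and a narrow carved gap.
pelvis_field <- function(dimensions) {
  w <- dimensions[1]; h <- dimensions[2]; d <- dimensions[3]
  blade_l <- ellipsoid_field(c(-0.28 * w, 0.1 * h, 0), # left "blade"
                             c(0.22 * w, 0.32 * h, 0.18 * d))
  blade_r <- ellipsoid_field(c(0.28 * w, 0.1 * h, 0),
                             c(0.22 * w, 0.32 * h, 0.18 * d))
  body <- ellipsoid_field(c(0, -0.15 * h, 0), # central "sacral" body
                          c(0.18 * w, 0.28 * h, 0.22 * d))
  function(p) {
    ridge <- 0.02 * h * cos(10 * pi * p[, 1] / w) *
      exp(-((p[, 2] - 0.35 * h) / (0.12 * h))^2)  # crest undulation
    f <- pmin(blade_l(p), blade_r(p), body(p)) - ridge
    # thin joint-like gaps where blades meet the body
    gap_l <- pmax(abs(p[, 1] + 0.13 * w) - 0.012 * w,
                  abs(p[, 2] - 0.02 * h) - 0.22 * h)
    gap_r <- pmax(abs(p[, 1] - 0.13 * w) - 0.012 * w,
                  abs(p[, 2] - 0.02 * h) - 0.22 * h)
    pmax(f, -gap_l, -gap_r)
  }
}

pelvis_bbox <- function(dimensions) {
  w <- dimensions[1]; h <- dimensions[2]; d <- dimensions[3]
  rbind(c(-0.55 * w, -0.5 * h, -0.3 * d), c(0.55 * w, 0.5 * h, 0.3 * d))
}
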