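#' Triangle surface mesh in millimetre world coordinates
#'
#' The basic container for a virtual bone model: a vertex matrix, a
#' triangle index matrix, and optional per-vertex scalar values (e.g.
#' single-point SD in mm) and per-vertex RGB colours.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param vertex_scalar optional numeric vector of length n.
#' @param vertex_colour optional integer matrix n x 3 with values in 0..255.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, vertex_scalar = NULL,
                         vertex_colour = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces,
                         vertex_scalar = vertex_scalar,
                         vertex_colour = vertex_colour),
                    class = "surface_mesh")
  validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3)
    stop("surface_mesh: vertices must be an n x 3 matrix")
  if (nrow(v) == 0)
    stop("surface_mesh: mesh has zero vertices")
  if (!all(is.finite(v)))
    stop("surface_mesh: non-finite vertex coordinate")
  if (!is.matrix(f) || ncol(f) != 3)
    stop("surface_mesh: faces must be an m x 3 matrix")
  if (nrow(f) > 0) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop(sprintf("surface_mesh: face index out of range [1, %d]", nrow(v)))
    rep_ix <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(rep_ix))
      stop(sprintf("surface_mesh: face %d has repeated vertex indices",
                   which(rep_ix)[1]))
  }
  if (!is.null(mesh$vertex_scalar)) {
    if (length(mesh$vertex_scalar) != nrow(v))
      stop("surface_mesh: vertex_scalar length differs from vertex count")
    if (!all(is.finite(mesh$vertex_scalar)))
      stop("surface_mesh: non-finite vertex_scalar")
  }
  if (!is.null(mesh$vertex_colour)) {
    cc <- mesh$vertex_colour
    if (!is.matrix(cc) || nrow(cc) != nrow(v) || ncol(cc) != 3)
      stop("surface_mesh: vertex_colour must be an n x 3 matrix")
    if (min(cc) < 0 || max(cc) > 255)
      stop("surface_mesh: vertex_colour outside 0..255")
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$vertex_scalar)) ", per-vertex scalar" else "",
              if (!is.null(x$vertex_colour)) ", per-vertex colour" else ""))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Vertex and face counts
#' @param mesh a `surface_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) {
  cr <- face_cross(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed mesh (mm^3), by the divergence theorem
#'
#' Positive for consistently outward-oriented closed meshes.
#' @param mesh a `surface_mesh`.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Per-vertex outward normals (area-weighted average of face normals)
#' @param mesh a `surface_mesh`.
#' @return numeric matrix n x 3 of unit normals.
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # face normal scaled by 2*area
  n <- matrix(0, nrow(mesh$vertices), 3)
  f <- mesh$faces
  for (c in 1:3) {
    n[, 1] <- n[, 1] + tabulate_weighted(f[, c], cr[, 1], nrow(n))
    n[, 2] <- n[, 2] + tabulate_weighted(f[, c], cr[, 2], nrow(n))
    n[, 3] <- n[, 3] + tabulate_weighted(f[, c], cr[, 3], nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

edge_key <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  lo * (max(hi) + 1) + hi
}

#' Is the mesh closed (every edge shared by exactly two faces)?
#' @param mesh a `surface_mesh`.
#' @export
is_closed_mesh <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(table(edge_key(mesh$faces)) == 2)
}

#' Euler characteristic V - E + F
#' @param mesh a `surface_mesh`.
#' @export
euler_characteristic <- function(mesh) {
  ne <- length(unique(edge_key(mesh$faces)))
  nrow(mesh$vertices) - ne + nrow(mesh$faces)
}

#' Merge vertices that coincide within a tolerance
#'
#' STL files store each facet independently; welding reconstructs the
#' shared-vertex mesh. Coordinates are snapped to a `tol`-spaced grid.
#'
#' @param mesh a `surface_mesh`.
#' @param tol welding tolerance in mm (default 1e-9).
#' @export
weld_vertices <- function(mesh, tol = 1e-9) {
  v <- round(mesh$vertices / tol)
  key <- paste(v[, 1], v[, 2], v[, 3])
  first <- !duplicated(key)
  newid <- match(key, key[first])
  keep <- mesh$vertices[first, , drop = FALSE]
  f <- matrix(newid[mesh$faces], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  surface_mesh(keep, f[ok, , drop = FALSE])
}
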