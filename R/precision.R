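#' Per-vertex nearest-neighbour distances between two meshes
#'
#' For each vertex of `reference`, the Euclidean distance (mm) to the
#' nearest vertex of `other`. Correspondence is vertex-to-vertex — the
#' nearest *point* of the other replicate's polygon mesh — with distance
#' ties resolved to the lowest vertex index. Because the nearest neighbour
#' of a displaced point can never be farther than its true counterpart,
#' these distances underestimate the true displacement (see the package
#' vignette).
#'
#' @param reference,other [surface_mesh()] objects (nonempty).
#' @param return_index also return the index of the nearest vertex.
#' @return numeric vector of distances, or a list with `distance` and
#'   `index` when `return_index = TRUE`.
#' @export
nn_distances <- function(reference, other, return_index = FALSE) {
  if (nrow(reference$vertices) == 0 || nrow(other$vertices) == 0)
    stop("nn_distances: empty mesh")
  res <- .nn_cpp(reference$vertices, other$vertices)
  if (return_index) res else res$distance
}

#' Per-vertex SD field attached to a reference mesh
#'
#' @param reference a [surface_mesh()].
#' @param sd numeric vector of per-vertex SD values (mm, >= 0, finite).
#' @param estimator tag recording the SD convention (`"rms"` or
#'   `"sample_sd"`).
#' @export
point_sd_field <- function(reference, sd, estimator = "rms") {
  if (length(sd) != nrow(reference$vertices))
    stop("point_sd_field: sd length differs from vertex count")
  if (any(!is.finite(sd)) || any(sd < 0))
    stop("point_sd_field: sd values must be finite and >= 0")
  structure(list(reference = reference, sd = as.numeric(sd),
                 estimator = estimator),
            class = "point_sd_field")
}

#' @export
print.point_sd_field <- function(x, ...) {
  cat(sprintf(
    "point_sd_field (%s): %d vertices, mean %.4f mm, max %.4f mm\n",
    x$estimator, length(x$sd), mean(x$sd), max(x$sd)))
  invisible(x)
}

#' Single-point SD of one reference mesh against other replicates
#'
#' For each reference vertex, the nearest-neighbour distances to each of
#' the other replicate meshes are pooled into a per-vertex SD. The default
#' `"rms"` estimator treats the m distances as deviations from the
#' reference point itself: `sd = sqrt(sum(d_i^2) / m)`. The alternative
#' `"sample_sd"` is the standard deviation of the distances about their
#' mean (requires m >= 2); it vanishes whenever all deviations share the
#' same magnitude, so `"rms"` is the default reading of per-point
#' variability.
#'
#' @param reference a [surface_mesh()].
#' @param others list of at least one other [surface_mesh()].
#' @param estimator `"rms"` or `"sample_sd"`.
#' @return a [point_sd_field()] on `reference`.
#' @export
single_point_sd <- function(reference, others, estimator = c("rms",
                                                             "sample_sd")) {
  estimator <- match.arg(estimator)
  if (length(others) < 1) stop("single_point_sd: empty others list")
  d <- vapply(others, function(o) nn_distances(reference, o),
              numeric(nrow(reference$vertices)))
  d <- matrix(d, nrow = nrow(reference$vertices))
  sdv <- if (estimator == "rms") sqrt(rowMeans(d^2))
  else {
    if (ncol(d) < 2)
      stop("single_point_sd: sample_sd needs at least two other meshes")
    apply(d, 1, sd)
  }
  point_sd_field(reference, sdv, estimator)
}

#' Balanced single-point SD over all replicates
#'
#' The single-point SD is computed once with every replicate acting as the
#' reference, removing reference-choice bias. The per-replicate fields are
#' transferred onto the first replicate by nearest-vertex lookup (the same
#' correspondence machinery as the distances themselves) and averaged per
#' vertex; the result is attached to replicate 1, which is also the
#' conventional visualization reference.
#'
#' @param replicates a [replicate_set()].
#' @param estimator `"rms"` (default) or `"sample_sd"`.
#' @return a [point_sd_field()] on the first replicate.
#' @export
balanced_sd <- function(replicates, estimator = c("rms", "sample_sd")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(replicates, "replicate_set"))
  meshes <- replicates$meshes
  n <- length(meshes)
  ref1 <- meshes[[1]]
  acc <- numeric(nrow(ref1$vertices))
  for (r in seq_len(n)) {
    field <- single_point_sd(meshes[[r]], meshes[-r], estimator)
    if (r == 1) acc <- acc + field$sd
    else {
      ix <- nn_distances(ref1, meshes[[r]], return_index = TRUE)$index
      acc <- acc + field$sd[ix]
    }
  }
  point_sd_field(ref1, acc / n, estimator)
}

#' Fraction of SD values below each threshold
#'
#' The row of the precision table for one condition: the fraction of
#' vertices with SD strictly below each threshold, plus the fraction
#' strictly above the largest (the `<0.07 mm ... >0.7 mm` table layout).
#'
#' @param field a [point_sd_field()] (or a bare numeric vector of SDs).
#' @param thresholds an [sd_thresholds()].
#' @return named numeric vector of length `length(thresholds) + 1`.
#' @export
fraction_table <- function(field, thresholds = sd_thresholds()) {
  sdv <- if (inherits(field, "point_sd_field")) field$sd
         else as.numeric(field)
  if (length(sdv) == 0) stop("fraction_table: empty field")
  thr <- as.numeric(thresholds)
  below <- vapply(thr, function(t) mean(sdv < t), 0)
  above <- mean(sdv > max(thr))
  out <- c(below, above)
  names(out) <- c(sprintf("below_%g", thr), sprintf("above_%g", max(thr)))
  out
}

#' Convert a single-point SD to the 95% CI of a point-to-point distance
#'
#' A distance is measured between two mesh points; if each point varies
#' independently with the same per-point SD, the difference of the two
#' measurements has SD `sqrt(2) * sd`, and a 2-SD ("95%") interval on it
#' spans `2 * sqrt(2) * sd`. The inverse [ci95_to_sd()] is exact: a 2 mm
#' CI — the classical acceptable osteometric measurement error — maps to a
#' per-point SD of 0.707 mm, the ceiling usually quoted as 0.7 mm.
#'
#' @param sd per-point SD in mm, >= 0.
#' @export
sd_to_ci95 <- function(sd) {
  if (any(sd < 0)) stop("sd_to_ci95: sd must be >= 0")
  2 * sqrt(2) * sd
}

#' @rdname sd_to_ci95
#' @param ci 95% CI width of a point-to-point distance in mm, >= 0.
#' @export
ci95_to_sd <- function(ci) {
  if (any(ci < 0)) stop("ci95_to_sd: ci must be >= 0")
  ci / (2 * sqrt(2))
}

#' Two-sample Kolmogorov-Smirnov comparison of SD distributions
#'
#' The D statistic is the largest vertical distance between the empirical
#' cumulative distributions of the two pooled per-vertex SD samples;
#' `sd_at_max` is the SD value (mm) at which that largest gap occurs
#' (smallest such value on ties). The p-value uses the asymptotic
#' two-sample Kolmogorov distribution; with ~1e4-1e5 mesh vertices treated
#' as independent samples it is anti-conservative under spatial
#' correlation and should be read qualitatively.
#'
#' @param field_a,field_b [point_sd_field()] objects or numeric vectors.
#' @return a `ks_result` with elements `D`, `p`, `sd_at_max`, `n_a`, `n_b`.
#' @export
ks_compare <- function(field_a, field_b) {
  a <- if (inherits(field_a, "point_sd_field")) field_a$sd
       else as.numeric(field_a)
  b <- if (inherits(field_b, "point_sd_field")) field_b$sd
       else as.numeric(field_b)
  if (length(a) == 0 || length(b) == 0) stop("ks_compare: empty field")
  x <- sort(unique(c(a, b)))
  fa <- ecdf(a)(x)
  fb <- ecdf(b)(x)
  gap <- abs(fa - fb)
  D <- max(gap)
  # ties (within float round-off of the sup) resolve to the smallest SD
  sd_at_max <- x[which(gap >= D - 1e-12)[1]]
  n <- length(a)
  m <- length(b)
  lambda <- sqrt(n * m / (n + m)) * D
  structure(list(D = D, p = kolmogorov_sf(lambda), sd_at_max = sd_at_max,
                 n_a = n, n_b = m),
            class = "ks_result")
}

# Survival function of the Kolmogorov distribution, 1 - K(lambda).
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-12) return(1)
  if (lambda < 0.3) {
    # small-lambda representation of K itself
    k <- 1:5
    K <- sqrt(2 * pi) / lambda *
      sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
    return(min(1, max(0, 1 - K)))
  }
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "Two-sample KS: D = %.4f at SD = %.4f mm, p = %.3g (n = %d vs %d)\n",
    x$D, x$sd_at_max, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Default 5-band SD colour palette (blue to red)
#' @export
sd_palette <- function() {
  rbind(c(0L, 90L, 200L),    # < first threshold
        c(0L, 180L, 90L),
        c(250L, 220L, 0L),
        c(255L, 140L, 0L),
        c(220L, 30L, 30L))   # > last threshold
}

#' Colour a mesh by SD band
#'
#' Each vertex is assigned the colour of its SD band; band k collects SD
#' values in `[thresholds[k-1], thresholds[k])`, the last band everything
#' at or above the largest threshold. Band populations therefore equal the
#' successive differences of the [fraction_table()] entries.
#'
#' @param field a [point_sd_field()].
#' @param thresholds an [sd_thresholds()].
#' @param palette integer matrix of RGB rows, `length(thresholds) + 1` of
#'   them.
#' @return the reference [surface_mesh()] with `vertex_colour` set and the
#'   SD values as `vertex_scalar`.
#' @export
colour_map <- function(field, thresholds = sd_thresholds(),
                       palette = sd_palette()) {
  stopifnot(inherits(field, "point_sd_field"))
  thr <- as.numeric(thresholds)
  palette <- as.matrix(palette)
  if (nrow(palette) != length(thr) + 1)
    stop(sprintf("colour_map: palette must have %d colours for %d thresholds",
                 length(thr) + 1, length(thr)))
  band <- findInterval(field$sd, thr) + 1L
  mesh <- field$reference
  mesh$vertex_colour <- palette[band, , drop = FALSE]
  mesh$vertex_scalar <- field$sd
  validate_mesh(mesh)
  mesh
}
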