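# Fixtures and independent oracles used across the suite.

# mesh with vertices only (valid for nearest-neighbour statistics)
point_mesh <- function(coords) {
  surface_mesh(matrix(coords, ncol = 3), matrix(integer(0), 0, 3))
}

# axis-aligned closed cuboid (12 triangles) spanning lo..hi
cuboid_mesh <- function(lo, hi) {
  v <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                             c(lo[3], hi[3])))
  # vertices: 1:(---),2:(+--),3:(-+-),4:(++-),5:(--+),6:(+-+),7:(-++),8:(+++)
  f <- rbind(c(1, 3, 2), c(2, 3, 4),    # bottom (z = lo)
             c(5, 6, 7), c(6, 8, 7),    # top (z = hi)
             c(1, 2, 5), c(2, 6, 5),    # y = lo
             c(3, 7, 4), c(4, 7, 8),    # y = hi
             c(1, 5, 3), c(3, 5, 7),    # x = lo
             c(2, 4, 6), c(4, 8, 6))    # x = hi
  surface_mesh(v, f)
}

# brute-force nearest-neighbour oracle: exhaustive all-pairs minimum with
# ties resolved to the lowest index
nn_brute <- function(query, target) {
  t(apply(query, 1, function(p) {
    d <- sqrt(colSums((t(target) - p)^2))
    i <- which(d == min(d))[1]
    c(d[i], i)
  }))
}

# exhaustive two-sample ECDF scan oracle for the KS statistic
ks_brute <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  gaps <- vapply(xs, function(x) abs(mean(a <= x) - mean(b <= x)), 0)
  D <- max(gaps)
  list(D = D, at = xs[which(gaps >= D - 1e-12)[1]])
}

# brute-force signed distance oracle on a small grid (mm)
signed_distance_brute <- function(mask_arr, spacing) {
  d <- dim(mask_arr)
  idx <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  world <- sweep(idx - 1, 2, spacing, "*")
  fg <- world[as.vector(mask_arr), , drop = FALSE]
  bg <- world[!as.vector(mask_arr), , drop = FALSE]
  mind <- function(p, set) min(sqrt(colSums((t(set) - p)^2)))
  out <- numeric(nrow(world))
  for (i in seq_len(nrow(world))) {
    out[i] <- if (mask_arr[idx[i, 1], idx[i, 2], idx[i, 3]])
      -mind(world[i, ], bg) else mind(world[i, ], fg)
  }
  array(out, d)
}

# point-to-surface (triangle) distance, for Hausdorff-style bounds
point_to_mesh_dist <- function(points, mesh) {
  # adequate for tests: vertex distance upper-bounds are too loose, so
  # compute exact point-triangle distances by brute force
  v <- mesh$vertices
  f <- mesh$faces
  apply(points, 1, function(p) {
    dmin <- Inf
    for (i in seq_len(nrow(f))) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
      dmin <- min(dmin, point_triangle_dist(p, a, b, cc))
    }
    dmin
  })
}

point_triangle_dist <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + t * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + t * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + t * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  w1 <- vb * denom; w2 <- vc * denom
  sqrt(sum((p - (a + ab * w1 + ac * w2))^2))
}
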