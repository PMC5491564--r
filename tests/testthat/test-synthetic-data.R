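test_that("phantom shapes are closed and match analytic geometry", {
  s <- make_base_shape("sphere", 50, 4)
  rr <- sqrt(rowSums(s$vertices^2))
  expect_true(all(rr <= 50 + 1e-9))
  expect_true(all(rr >= 50 - 50 * (1 - cos(pi / 2^4))))  # chord-sagitta bound
  expect_true(is_closed_mesh(s))

  # area converges to 4*pi*r^2 from below under refinement
  areas <- vapply(2:4, function(k)
    mesh_area(make_base_shape("sphere", 50, k)), 0)
  exact <- 4 * pi * 50^2
  expect_true(all(diff(areas) > 0))
  expect_lt(abs(areas[3] / exact - 1), 0.01)

  e <- make_base_shape("ellipsoid", c(30, 20, 10), 3)
  q <- sweep(e$vertices, 2, c(30, 20, 10), "/")
  expect_equal(max(abs(rowSums(q^2) - 1)), 0, tolerance = 1e-9)

  cp <- make_base_shape("capsule", c(10, 30), 40)
  expect_true(is_closed_mesh(cp))
  expect_equal(euler_characteristic(cp), 2)

  pv <- make_base_shape("pelvis_phantom", c(120, 100, 80), 60)
  expect_true(is_closed_mesh(pv))
  expect_gt(n_vertices(pv), 100)

  expect_error(make_base_shape("cube", 10), "unknown kind")
  expect_error(make_base_shape("sphere", -1), "positive")
})

test_that("replicate perturbation realises the declared noise model", {
  s <- make_base_shape("sphere", 50, 5)  # >= 1e4 vertices

  # zero noise, no resampling: replicates are bit-identical to the base
  rs0 <- perturb_replicates(s, 3, noise_spec(0, seed = 1))
  for (m in rs0$meshes) expect_identical(m$vertices, s$vertices)

  # pooled signed normal offsets recover sigma within 3%
  rs <- perturb_replicates(s, 5, noise_spec(0.2, seed = 2))
  nrm <- vertex_normals(s)
  offs <- unlist(lapply(rs$meshes, function(m)
    rowSums((m$vertices - s$vertices) * nrm)))
  expect_lt(abs(sd(offs) / 0.2 - 1), 0.03)

  # patch sigma dominates the background field
  ns <- noise_spec(0.1, patches = list(list(centre = c(0, 0, 50),
                                            radius = 20, sigma = 1)),
                   seed = 3)
  rsp <- perturb_replicates(s, 5, ns)
  d2 <- rowSums(sweep(s$vertices, 2, c(0, 0, 50))^2)
  inside <- d2 <= 20^2
  m1 <- rsp$meshes[[1]]
  disp <- sqrt(rowSums((m1$vertices - s$vertices)^2))
  expect_gt(mean(disp[inside]), 5 * mean(disp[!inside]))
})

test_that("replicate generation is seed-deterministic with substreams", {
  s <- make_base_shape("sphere", 30, 3)
  a <- perturb_replicates(s, 4, noise_spec(0.1, seed = 9))
  b <- perturb_replicates(s, 4, noise_spec(0.1, seed = 9))
  c <- perturb_replicates(s, 4, noise_spec(0.1, seed = 10))
  expect_identical(a$meshes, b$meshes)
  expect_false(identical(a$meshes[[1]]$vertices, c$meshes[[1]]$vertices))
  # replicates use independent substreams
  expect_false(identical(a$meshes[[1]]$vertices, a$meshes[[2]]$vertices))
  # sigma -> 0 converges to the base mesh
  for (sg in c(0.1, 0.01, 0.001)) {
    r <- perturb_replicates(s, 2, noise_spec(sg, seed = 5))
    expect_lt(max(abs(r$meshes[[1]]$vertices - s$vertices)), 6 * sg)
  }
  expect_error(perturb_replicates(s, 1, noise_spec(0.1)), ">= 2")
  expect_error(noise_spec(-1), ">= 0")
})

test_that("resampling yields differing vertex counts but preserves shape", {
  s <- make_base_shape("sphere", 30, 4)
  rs <- perturb_replicates(s, 5, noise_spec(0.05, resample_fraction = 0.2,
                                            seed = 4))
  counts <- vapply(rs$meshes, n_vertices, 0L)
  expect_gt(length(unique(counts)), 1)
  expect_true(all(counts <= n_vertices(s)))
  expect_true(all(counts >= 0.8 * n_vertices(s) - 1))
  # decimated vertices stay near the sphere
  for (m in rs$meshes)
    expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 30)), 1.5)
})

test_that("synthetic CT realises the exposure and slice-thickness laws", {
  s <- make_base_shape("sphere", 15, 3)
  # noise SD scales as 1/sqrt(exposure): variance ratio 2 at half exposure.
  # hu_bone = hu_background = 0 leaves the whole grid as pure noise.
  vA <- rasterize_volume(s, imaging_spec(0.6, 0.9, exposure_fraction = 1,
                                         hu_bone = 0,
                                         noise_sigma_ref = 25, seed = 5))
  vB <- rasterize_volume(s, imaging_spec(0.6, 0.9, exposure_fraction = 0.5,
                                         hu_bone = 0,
                                         noise_sigma_ref = 25, seed = 6))
  expect_lt(abs(var(as.numeric(vB$values)) /
                  var(as.numeric(vA$values)) - 2), 0.1)

  # noiseless deep-interior voxels keep the exact bone intensity
  v0 <- rasterize_volume(s, imaging_spec(0.6, 0.9, noise_sigma_ref = 0))
  ctr <- round(dim(v0$values) / 2)
  expect_equal(v0$values[ctr[1], ctr[2], ctr[3]], 400)

  # determinism of the seeded noise
  vA2 <- rasterize_volume(s, imaging_spec(0.6, 0.9, exposure_fraction = 1,
                                          hu_bone = 0,
                                          noise_sigma_ref = 25, seed = 5))
  expect_identical(vA$values, vA2$values)
})

test_that("axial edge width grows with slice thickness (1-D oracle)", {
  box <- cuboid_mesh(c(-15, -15, -10), c(15, 15, 10))
  # first downward crossing of `target` along the profile, by linear interp
  edge_cross <- function(z, prof, target) {
    i <- which(prof[-length(prof)] >= target & prof[-1] < target)[1]
    z[i] + (prof[i] - target) / (prof[i] - prof[i + 1]) * (z[i + 1] - z[i])
  }
  widths <- vapply(c(0.9, 3.0), function(th) {
    v <- rasterize_volume(box, imaging_spec(0.6, th))
    ctr <- round(dim(v$values) / 2)
    prof <- as.numeric(v$values[ctr[1], ctr[2], ])
    z <- v$origin[3] + (seq_along(prof) - 1) * v$spacing[3]
    # 10-90% width of the descending edge at the top face (z = 10)
    edge_cross(z, prof, 0.1 * 400) - edge_cross(z, prof, 0.9 * 400)
  }, 0)
  expect_gt(widths[2], widths[1])
  # oracle: the 1-D Gaussian-blurred step in closed form
  oracle <- vapply(c(0.9, 3.0), function(th) {
    sigma <- th / (2 * sqrt(2 * log(2)))
    z <- seq(5, 15, by = 0.001)
    step <- 400 * pnorm((10 - z) / sigma)
    edge_cross(z, step, 0.1 * 400) - edge_cross(z, step, 0.9 * 400)
  }, 0)
  expect_equal(widths, oracle, tolerance = 0.35)  # grid-sampling slack

  # topology is conserved: half-intensity surface of the blurred noiseless
  # volume is closed with the sphere's Euler characteristic
  s <- make_base_shape("sphere", 12, 3)
  v <- rasterize_volume(s, imaging_spec(0.6, 0.9))
  iso <- extract_surface(voxel_volume(200 - v$values, v$spacing, v$origin), 0)
  expect_true(is_closed_mesh(iso))
  expect_equal(euler_characteristic(iso), 2)
})
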