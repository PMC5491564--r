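test_that("region growing selects the seeded connected component", {
  arr <- array(0, c(20, 20, 20))
  arr[4:9, 4:9, 4:9] <- 400          # blob A
  arr[13:18, 13:18, 13:18] <- 400    # blob B, not 6-connected to A
  v <- voxel_volume(arr, c(1, 1, 1))

  mA <- region_grow(v, c(6, 6, 6), 200, 600)
  expect_identical(mA$values, arr == 400 &
                     slice.index(arr, 1) <= 9)
  expect_equal(sum(mA$values), 6^3)
  mB <- region_grow(v, c(15, 15, 15), 200, 600)
  expect_equal(sum(mB$values), 6^3)
  expect_false(any(mA$values & mB$values))

  expect_error(region_grow(v, c(0, 6, 6), 200, 600), "outside the grid")
  expect_error(region_grow(v, c(10, 10, 10), 200, 600), "threshold band")

  # widening the band can only grow the region
  set.seed(11)
  arr2 <- arr + array(rnorm(length(arr), 0, 40), dim(arr))
  v2 <- voxel_volume(arr2, c(1, 1, 1))
  narrow <- region_grow(v2, c(6, 6, 6), 300, 500)
  wide <- region_grow(v2, c(6, 6, 6), 250, 550)
  expect_true(all(wide$values[narrow$values]))
})

test_that("closing fills holes and bridges gaps narrower than 2r", {
  arr <- array(FALSE, c(14, 14, 14))
  arr[3:12, 3:12, 3:12] <- TRUE
  arr[7, 7, 7] <- FALSE              # one-voxel cavity
  m <- binary_mask(arr, c(1, 1, 1))
  expect_identical(binary_close(m, 0), m)            # identity at r = 0
  closed <- binary_close(m, 1)
  expect_true(closed$values[7, 7, 7])
  expect_true(all(closed$values[arr]))               # closing is extensive

  # two slabs with a 3 mm gap: bridged at r = 2, not at r = 1
  slab <- array(FALSE, c(24, 5, 5))
  slab[1:10, , ] <- TRUE
  slab[14:24, , ] <- TRUE
  sm <- binary_mask(slab, c(1, 1, 1))
  expect_true(binary_close(sm, 2)$values[12, 3, 3])
  expect_false(binary_close(sm, 1)$values[12, 3, 3])
  expect_error(binary_close(sm, -1), ">= 0")
})

test_that("fill_holes closes cavities, is idempotent, keeps open masks", {
  shell <- array(FALSE, c(12, 12, 12))
  shell[3:10, 3:10, 3:10] <- TRUE
  solid <- shell
  shell[4:9, 4:9, 4:9] <- FALSE      # hollow interior
  filled <- fill_holes(binary_mask(shell, c(1, 1, 1)))
  expect_identical(filled$values, solid)
  expect_identical(fill_holes(filled)$values, filled$values)

  open <- array(FALSE, c(8, 8, 8))
  open[2:5, 2:5, 2:5] <- TRUE
  expect_identical(fill_holes(binary_mask(open, c(1, 1, 1)))$values, open)
})

test_that("signed distance matches the brute-force oracle", {
  set.seed(21)
  arr <- array(runif(7 * 6 * 5) < 0.4, c(7, 6, 5))
  arr[4, 3, 3] <- TRUE
  arr[1, 1, 1] <- FALSE              # guarantee both phases
  sp <- c(0.7, 1.0, 1.3)             # anisotropic spacing
  m <- binary_mask(arr, sp)
  got <- signed_distance(m)$values
  expect_equal(got, signed_distance_brute(arr, sp), tolerance = 1e-9)

  # centre of a 9-voxel cube at unit spacing is 5 mm from background
  cube <- array(FALSE, c(11, 11, 11))
  cube[2:10, 2:10, 2:10] <- TRUE
  sd3 <- signed_distance(binary_mask(cube, c(1, 1, 1)))$values
  expect_equal(sd3[6, 6, 6], -5)
  # phase swap is an exact negation
  swap <- signed_distance(binary_mask(!cube, c(1, 1, 1)))$values
  expect_identical(swap, -sd3)

  expect_error(signed_distance(binary_mask(array(TRUE, c(3, 3, 3)),
                                           c(1, 1, 1))), "all foreground")
  expect_error(signed_distance(binary_mask(array(FALSE, c(3, 3, 3)),
                                           c(1, 1, 1))), "all background")
})

test_that("smoothing removes ripples but conserves enclosed volume", {
  h <- 0.5
  ax <- seq(-14, 14, by = h)
  g <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt(g$x^2 + g$y^2 + g$z^2)
  ripple <- 0.3 * sin(2 * pi * g$x / 1.5) * sin(2 * pi * g$y / 1.5)
  d <- length(ax)
  vol <- voxel_volume(array(r - 10 + ripple, c(d, d, d)), rep(h, 3),
                      rep(-14, 3))
  expect_identical(smooth_refine(vol, 0), vol)
  expect_error(smooth_refine(vol, -0.1), ">= 0")

  rough <- extract_surface(vol, 0)
  smoothed <- extract_surface(smooth_refine(vol, h), 0)
  expect_lt(mesh_area(smoothed), mesh_area(rough))
  expect_lt(abs(mesh_volume(smoothed) / (4 / 3 * pi * 1000) - 1), 0.02)
})

test_that("iso-surface of an analytic sphere field is faithful", {
  h <- 0.5
  ax <- seq(-13, 13, by = h)
  g <- expand.grid(x = ax, y = ax, z = ax)
  d <- length(ax)
  vol <- voxel_volume(array(sqrt(g$x^2 + g$y^2 + g$z^2) - 10, c(d, d, d)),
                      rep(h, 3), rep(-13, 3))
  s <- extract_surface(vol, 0)
  expect_true(is_closed_mesh(s))
  expect_equal(euler_characteristic(s), 2)
  rr <- sqrt(rowSums(s$vertices^2))
  expect_lt(max(abs(rr - 10)), 0.3)  # well under one voxel
  expect_error(extract_surface(vol, 1e9), "level")
})

test_that("end-to-end segmentation recovers the phantom within a voxel", {
  sph <- make_base_shape("sphere", 12, 3)
  v <- rasterize_volume(sph, imaging_spec(0.6, 0.9))
  m <- segment(v, lower = 200, upper = 1000,
               close_radius = 1.2, smooth_sigma = 0.6)
  expect_true(is_closed_mesh(m))
  rr <- sqrt(rowSums(m$vertices^2))
  expect_lt(max(abs(rr - 12)), sqrt(3) * 0.6)  # within a voxel diagonal
  expect_lt(abs(mean(rr) - 12), 0.3)           # within half a voxel

  log <- attr(m, "segmentation_log")
  expect_equal(log$lower, 200)
  expect_equal(log$close_radius, 1.2)

  # deterministic: repeated runs are bit-identical
  m2 <- segment(v, lower = 200, upper = 1000,
                close_radius = 1.2, smooth_sigma = 0.6)
  expect_identical(m$vertices, m2$vertices)

  # a different operator threshold yields a measurably different surface
  m3 <- segment(v, lower = 280, upper = 1000,
                close_radius = 1.2, smooth_sigma = 0.6)
  expect_false(isTRUE(all.equal(mean(rr),
                                mean(sqrt(rowSums(m3$vertices^2))))))
})
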