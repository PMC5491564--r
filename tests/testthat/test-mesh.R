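test_that("surface_mesh validates its invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- surface_mesh(v, rbind(c(1, 2, 3)))
  expect_equal(n_vertices(m), 3)
  expect_equal(n_faces(m), 1)

  expect_error(surface_mesh(v, rbind(c(1, 2, 99))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 1, 2))), "repeated")
  expect_error(surface_mesh(matrix(0, 0, 3), matrix(integer(0), 0, 3)),
               "zero vertices")
  expect_error(surface_mesh(rbind(c(0, 0, NA)), matrix(integer(0), 0, 3)),
               "finite")
  expect_error(surface_mesh(v, rbind(c(1, 2, 3)), vertex_scalar = 1:2),
               "length")
  expect_error(surface_mesh(v, rbind(c(1, 2, 3)),
                            vertex_colour = matrix(300L, 3, 3)), "0..255")
})

test_that("area, volume and Euler characteristic match closed-form values", {
  box <- cuboid_mesh(c(0, 0, 0), c(2, 3, 4))
  expect_true(is_closed_mesh(box))
  expect_equal(euler_characteristic(box), 2)
  expect_equal(mesh_area(box), 2 * (2 * 3 + 2 * 4 + 3 * 4))
  expect_equal(mesh_volume(box), 24)
})

test_that("vertex normals of a sphere point radially outward", {
  s <- make_base_shape("sphere", 10, 3)
  nrm <- vertex_normals(s)
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  expect_gt(min(rowSums(nrm * radial)), 0.99)
})

test_that("welding merges coincident vertices and drops slivers", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))  # duplicated edge pair
  m <- surface_mesh(v, rbind(c(1, 2, 3), c(4, 6, 5)))
  w <- weld_vertices(m)
  expect_equal(n_vertices(w), 4)
  expect_equal(n_faces(w), 2)
})
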