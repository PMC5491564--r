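test_that("nearest-neighbour distances match the exhaustive oracle", {
  set.seed(31)
  q <- matrix(runif(300, -10, 10), ncol = 3)
  t0 <- matrix(runif(450, -10, 10), ncol = 3)
  res <- nn_distances(point_mesh(q), point_mesh(t0), return_index = TRUE)
  oracle <- nn_brute(q, t0)
  expect_equal(res$distance, oracle[, 1], tolerance = 1e-12)
  expect_equal(res$index, oracle[, 2])

  # identity and rigid translation
  expect_equal(nn_distances(point_mesh(q), point_mesh(q)), rep(0, 100))
  shifted <- sweep(q, 2, c(0.3, 0, 0), "+")
  d <- nn_distances(point_mesh(q[1, , drop = FALSE]), point_mesh(shifted))
  expect_lte(d, 0.3 + 1e-12)  # NN never exceeds the true displacement

  # distance ties resolve to the lowest index
  tie <- rbind(c(1, 0, 0), c(-1, 0, 0))
  res2 <- nn_distances(point_mesh(c(0, 0, 0)), point_mesh(tie),
                       return_index = TRUE)
  expect_equal(res2$index, 1)
})

test_that("per-point SD estimators reproduce hand-computed values", {
  ref <- point_mesh(c(0, 0, 0))
  at <- function(x) point_mesh(c(x, 0, 0))
  others <- lapply(c(1, 2, 3, 4), at)

  rms <- single_point_sd(ref, others, "rms")
  expect_equal(rms$sd, sqrt((1 + 4 + 9 + 16) / 4))   # 2.7386...
  ss <- single_point_sd(ref, others, "sample_sd")
  expect_equal(ss$sd, sd(c(1, 2, 3, 4)))             # 1.2909...

  # equal-magnitude deviations: rms keeps them, sample_sd annihilates them
  eq <- single_point_sd(ref, lapply(c(2, 2, 2), at))
  expect_equal(eq$sd, 2)
  eq2 <- single_point_sd(ref, lapply(c(2, 2, 2), at), "sample_sd")
  expect_equal(eq2$sd, 0)

  expect_error(single_point_sd(ref, list()), "empty")
  expect_error(single_point_sd(ref, others[1], "sample_sd"), "at least two")
  expect_error(point_sd_field(ref, c(1, 2)), "length")
  expect_error(point_sd_field(ref, -1), ">= 0")
})

test_that("balanced SD is zero for identical replicates and symmetric", {
  s <- make_base_shape("sphere", 20, 3)
  idset <- replicate_set(list(s, s, s, s))
  f0 <- balanced_sd(idset)
  expect_equal(f0$sd, rep(0, n_vertices(s)))
  expect_equal(unname(fraction_table(f0)), c(1, 1, 1, 1, 0))

  # invariant under permutation of the non-reference replicates
  reps <- perturb_replicates(s, 4, noise_spec(0.1, seed = 8))
  f1 <- balanced_sd(reps)
  perm <- replicate_set(reps$meshes[c(1, 4, 2, 3)])
  f2 <- balanced_sd(perm)
  expect_equal(f1$sd, f2$sd, tolerance = 1e-12)
})

test_that("fraction tables follow the strict-threshold convention", {
  thr <- sd_thresholds()
  sds <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  ft <- fraction_table(sds, thr)
  expect_equal(unname(ft), c(0.2, 0.4, 0.6, 0.8, 0.2))
  expect_equal(names(ft),
               c("below_0.07", "below_0.175", "below_0.35", "below_0.7",
                 "above_0.7"))
  # boundary value 0.07 is neither below nor above 0.07
  expect_equal(unname(fraction_table(0.07, thr)), c(0, 1, 1, 1, 0))
  # monotone: below-fractions never decrease along thresholds
  set.seed(41)
  for (i in 1:5) {
    f <- fraction_table(abs(rnorm(200, 0, 0.3)), thr)
    expect_true(all(diff(f[1:4]) >= 0))
    expect_equal(unname(f[5]), 1 - unname(f[4]))
  }
  expect_error(fraction_table(numeric(0)), "empty")
})

test_that("the 2*sqrt(2) propagation law and its inverse are exact", {
  expect_equal(sd_to_ci95(0.7071), 2 * sqrt(2) * 0.7071)
  expect_equal(ci95_to_sd(2.0), 2 / (2 * sqrt(2)))
  expect_equal(ci95_to_sd(sd_to_ci95(c(0, 0.07, 0.35, 1.3))),
               c(0, 0.07, 0.35, 1.3))
  expect_error(sd_to_ci95(-0.1), ">= 0")
  expect_error(ci95_to_sd(-0.1), ">= 0")
})

test_that("KS comparison matches hand values and independent oracles", {
  self <- ks_compare(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(self$D, 0)
  expect_equal(self$p, 1)
  disjoint <- ks_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disjoint$D, 1)

  # all three gaps are 1/3; the reported location is the smallest SD
  hand <- ks_compare(c(0.1, 0.2, 0.3), c(0.15, 0.25, 0.35))
  expect_equal(hand$D, 1 / 3, tolerance = 1e-12)
  expect_equal(hand$sd_at_max, 0.1)

  set.seed(51)
  for (i in 1:10) {
    a <- abs(rnorm(sample(20:400, 1), 0, 0.2))
    b <- abs(rnorm(sample(20:400, 1), 0, sample(c(0.2, 0.35), 1)))
    got <- ks_compare(a, b)
    ora <- ks_brute(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b))
    expect_equal(got$D, ora$D, tolerance = 1e-12)
    expect_equal(got$sd_at_max, ora$at)
    expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
  }
  # asymptotic p agrees with stats::ks.test on large samples
  set.seed(52)
  a <- rnorm(4000)
  b <- rnorm(4000, 0.08)
  got <- ks_compare(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(got$p, ref$p.value, tolerance = 1e-3)
  expect_error(ks_compare(numeric(0), 1), "empty")
})

test_that("colour bands partition vertices consistently with fractions", {
  s <- make_base_shape("sphere", 10, 2)
  n <- n_vertices(s)
  f <- point_sd_field(s, rep(0, n))
  cm <- colour_map(f)
  expect_equal(unique(cm$vertex_colour), sd_palette()[1, , drop = FALSE])

  sds <- rep(c(0.05, 0.1, 0.2, 0.4, 0.8), length.out = n)
  f2 <- point_sd_field(s, sds)
  cm2 <- colour_map(f2)
  band <- match(apply(cm2$vertex_colour, 1, paste, collapse = ","),
                apply(sd_palette(), 1, paste, collapse = ","))
  ft <- fraction_table(f2)
  # cumulative band populations equal the below-fractions
  for (k in 1:4)
    expect_equal(mean(band <= k), unname(ft[k]))
  expect_equal(cm2$vertex_scalar, sds)
  expect_error(colour_map(f2, palette = sd_palette()[1:3, ]),
               "palette")
})
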