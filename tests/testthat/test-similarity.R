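test_that("skin mask equals a brute-force distance scan for one atom", {
  atom <- ion_structure(q = -1, radius = 1.5, pos = c(0.1, 0.2, -0.1))
  gs <- grid_spec(c(21, 21, 21), 1, center = c(0, 0, 0))
  spec <- skin_spec(probe_radius = 2, skin_thickness = 3,
                    sphere_radius = 100, center = c(0.1, 0.2, -0.1))
  m <- skin_mask(atom, gs, spec)
  ax <- grid_axes(gs)
  pts <- expand.grid(x = ax$x, y = ax$y, z = ax$z)
  d <- sqrt((pts$x - 0.1)^2 + (pts$y - 0.2)^2 + (pts$z + 0.1)^2) - 1.5
  expect_identical(as.vector(m), d > 2 & d <= 5)
  # vanishing sphere radius gives the empty mask
  m0 <- skin_mask(atom, gs, skin_spec(sphere_radius = 1e-9))
  expect_false(any(m0))
  # defaults echo the standard parameters
  expect_equal(skin_spec()$probe_radius, 2)
  expect_equal(skin_spec()$skin_thickness, 3)
})

test_that("Hodgkin index algebra: identity, antisymmetry, orthogonality", {
  set.seed(31)
  g <- random_grid(c(5, 5, 5), f32 = FALSE)
  neg <- g; neg$values <- -g$values
  mask <- array(TRUE, c(5, 5, 5))
  expect_equal(hodgkin_index(g, g, mask), 1)
  expect_equal(hodgkin_index(g, neg, mask), -1)
  # two-voxel mask with disjoint support: (1,0) vs (0,1)
  a <- const_grid(0); b <- const_grid(0)
  a$values[1, 1, 1] <- 1; b$values[2, 1, 1] <- 1
  m2 <- array(FALSE, c(4, 4, 4)); m2[1:2, 1, 1] <- TRUE
  expect_equal(hodgkin_index(a, b, m2), 0)
  expect_error(hodgkin_index(a, b, array(FALSE, c(4, 4, 4))), "empty")
  z <- const_grid(0)
  expect_error(hodgkin_index(z, z, m2), "zero")
})

test_that("electrostatic distance maps SI to [0,2] monotonically", {
  expect_equal(electrostatic_distance(1), 0)
  expect_equal(electrostatic_distance(-1), 2)
  expect_equal(electrostatic_distance(0), sqrt(2), tolerance = 1e-12)
  si <- seq(-1, 1, by = 0.05)
  d <- electrostatic_distance(si)
  expect_true(all(diff(d) < 0))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("pairwise matrix equals the entry-by-entry loop oracle", {
  set.seed(32)
  spec <- bilayer_spec(lipids_per_leaflet = 4, seed = 7)
  s <- generate_bilayer(spec)
  gs <- grid_spec(c(13, 13, 13), 2, center = c(0, 0, 22))
  man <- perturb_ensemble(s, 3, gs, spec)
  dm <- pairwise_distances(man, s, skin_spec(sphere_radius = 12))
  mask <- skin_mask(s, gs, skin_spec(sphere_radius = 12))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    si <- hodgkin_index(man$grid[[i]], man$grid[[j]], mask)
    expect_equal(dm$D[i, j], electrostatic_distance(si), tolerance = 1e-12)
  }
  expect_true(isSymmetric(dm$D))
  expect_true(all(diag(dm$D) == 0))
  # identical grids: all-zero matrix
  dm0 <- pairwise_distances(list(man$grid[[1]], man$grid[[1]]), s,
                            skin_spec(sphere_radius = 12))
  expect_equal(max(dm0$D), 0, tolerance = 1e-7)
})

test_that("D satisfies the triangle inequality on random masked triples", {
  set.seed(33)
  mask <- array(runif(64) < 0.5, c(4, 4, 4))
  for (rep in 1:200) {
    gs <- lapply(1:3, function(i) random_grid(c(4, 4, 4), f32 = FALSE))
    dm <- pairwise_distances(gs, mask = mask)
    d <- dm$D
    expect_lte(d[1, 2], d[1, 3] + d[3, 2] + 1e-12)
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
    expect_lte(d[2, 3], d[2, 1] + d[1, 3] + 1e-12)
  }
})

test_that("scaling both grids preserves SI; scaling one follows the formula", {
  set.seed(34)
  a <- random_grid(c(4, 4, 4), f32 = FALSE)
  b <- random_grid(c(4, 4, 4), f32 = FALSE)
  mask <- array(TRUE, c(4, 4, 4))
  si <- hodgkin_index(a, b, mask)
  a2 <- a; a2$values <- 3 * a$values
  b2 <- b; b2$values <- 3 * b$values
  expect_equal(hodgkin_index(a2, b2, mask), si, tolerance = 1e-12)
  # one-sided scaling: direct evaluation of the definition
  va <- a$values; vb <- b$values; c <- 3
  si_one <- 2 * sum(c * va * vb) / (sum((c * va)^2) + sum(vb^2))
  expect_equal(hodgkin_index(a2, b, mask), si_one, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(si_one, si)))
})

test_that("restricting the sphere is reproduced exactly by recomputation", {
  spec <- bilayer_spec(lipids_per_leaflet = 9, seed = 3)
  s <- generate_bilayer(spec)
  gs <- grid_spec(c(17, 17, 17), 2, center = c(0, 0, 22))
  man <- perturb_ensemble(s, 3, gs, spec)
  d14 <- pairwise_distances(man, s, skin_spec(sphere_radius = 14))
  d10 <- pairwise_distances(man, s, skin_spec(sphere_radius = 10))
  m10 <- skin_mask(s, gs, skin_spec(sphere_radius = 10))
  si_direct <- hodgkin_index(man$grid[[1]], man$grid[[2]], m10)
  expect_equal(d10$D[1, 2], electrostatic_distance(si_direct),
               tolerance = 1e-12)
  expect_lt(d10$n_mask_voxels, d14$n_mask_voxels)
})

test_that("distance statistics summarize the strict upper triangle", {
  D <- matrix(0, 3, 3); D[upper.tri(D)] <- 1; D <- D + t(D)
  s <- distance_stats(D)
  expect_equal(s$mean, 1); expect_equal(s$sd, 0); expect_equal(s$n_pairs, 3)
  z <- distance_stats(matrix(0, 4, 4))
  expect_equal(z$mean, 0); expect_equal(z$sd, 0)
  set.seed(35)
  M <- matrix(0, 6, 6); M[upper.tri(M)] <- runif(15); M <- M + t(M)
  s2 <- distance_stats(M)
  expect_equal(s2$mean, mean(M[upper.tri(M)]))
  expect_equal(s2$sd, sd(M[upper.tri(M)]))
  expect_equal(sum(s2$histogram$count), 15)
})

test_that("distance ACF: lag 0 is 1, i.i.d. is flat, drift and period show", {
  set.seed(36)
  dims <- c(4, 4, 4); mask <- array(TRUE, dims)
  # i.i.d. ensemble: all lags within the white-noise band
  gs <- lapply(1:40, function(i) random_grid(dims, f32 = FALSE))
  dm <- pairwise_distances(gs, mask = mask)
  dm$time_ns <- seq_along(gs)
  a <- distance_autocorrelation(dm, max_lag = 10)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf[-1]) < 3 / sqrt(a$n_pairs[-1])))
  # slow drift: short-lag correlation exceeds long-lag
  base <- array(rnorm(prod(dims)), dims)
  drift <- lapply(1:30, function(i)
    potential_grid(base + i * 0.2 + array(rnorm(prod(dims), sd = 0.05), dims),
                   1))
  dmd <- pairwise_distances(drift, mask = mask)
  dmd$time_ns <- 1:30
  ad <- distance_autocorrelation(dmd, max_lag = 6)
  expect_gt(ad$acf[ad$lag == 1], ad$acf[ad$lag == 5])
  # strict two-grid alternation: the ACF alternates sign
  A <- random_grid(dims, f32 = FALSE); B <- random_grid(dims, f32 = FALSE)
  alt <- rep(list(A, B), 8)
  dma <- pairwise_distances(alt, mask = mask)
  dma$time_ns <- seq_along(alt)
  aa <- distance_autocorrelation(dma, max_lag = 5)
  expect_true(all(sign(aa$acf) == c(1, -1, 1, -1, 1, -1)))
  # degenerate: identical snapshots have no defined ACF
  dmz <- pairwise_distances(rep(list(A), 4), mask = mask)
  dmz$time_ns <- 1:4
  expect_error(distance_autocorrelation(dmz), "zero-variance")
})

test_that("tidy and glance expose the pair table and summary row", {
  set.seed(37)
  gs <- lapply(1:4, function(i) random_grid(c(4, 4, 4), f32 = FALSE,
                                            label = paste0("s", i)))
  dm <- pairwise_distances(gs, mask = array(TRUE, c(4, 4, 4)))
  td <- tidy(dm)
  expect_identical(nrow(td), 6L)
  expect_named(td, c("a", "b", "si", "distance"))
  expect_equal(td$distance, electrostatic_distance(td$si))
  gl <- glance(dm)
  expect_identical(gl$n_grids, 4L)
  expect_equal(gl$mean_distance, mean(td$distance))
})
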