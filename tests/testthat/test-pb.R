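test_that("media maps: empty structure gives uniform solvent everywhere", {
  cfg <- pb_config()
  gs <- grid_spec(c(9, 9, 9), 1)
  empty <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 0))[0, ]
  maps <- build_media_maps(empty, gs, cfg)
  expect_true(all(maps$eps == 80))
  ka <- ORACLE$kappa(0.1, 80, 296)
  expect_equal(unique(as.vector(maps$kbar2)), 80 * ka^2, tolerance = 1e-9)
  expect_true(all(maps$charge == 0))
})

test_that("solute voxel count matches brute-force point-in-sphere", {
  cfg <- pb_config()
  gs <- grid_spec(c(17, 17, 17), 0.75, center = c(0, 0, 0))
  atom <- ion_structure(q = -1, radius = 2, pos = c(0.2, -0.3, 0.1))
  maps <- build_media_maps(atom, gs, cfg)
  ax <- grid_axes(gs)
  pts <- expand.grid(x = ax$x, y = ax$y, z = ax$z)
  inside <- (pts$x - 0.2)^2 + (pts$y + 0.3)^2 + (pts$z - 0.1)^2 <= 2^2
  expect_identical(sum(maps$eps == cfg$eps_solute), sum(inside))
  # Stern layer: kbar2 zeroed inside radius + ion exclusion
  stern <- (pts$x - 0.2)^2 + (pts$y + 0.3)^2 + (pts$z - 0.1)^2 <= (2 + 2)^2
  expect_identical(sum(maps$kbar2 == 0), sum(stern))
})

test_that("trilinear charge spreading conserves total charge", {
  cfg <- pb_config()
  gs <- grid_spec(c(11, 11, 11), 1, center = c(0, 0, 0))
  set.seed(21)
  s <- tibble::tibble(atom = "A", role = NA_character_, lipid = 1:5,
                      leaflet = 1L, is_phosphate = FALSE,
                      x = runif(5, -3, 3), y = runif(5, -3, 3),
                      z = runif(5, -3, 3),
                      charge = c(-3, 1.2, -0.4, 2, 0.7), radius = 1.5)
  maps <- build_media_maps(s, gs, cfg)
  expect_equal(sum(maps$charge), sum(s$charge), tolerance = 1e-9)
  expect_error(
    build_media_maps(dplyr::mutate(s, radius = 0), gs, cfg), "radius")
  expect_warning(
    build_media_maps(dplyr::mutate(s, x = x + 100), gs, cfg), "outside")
})

test_that("zero charges with zero boundary give the zero potential", {
  cfg <- pb_config()
  gs <- grid_spec(c(9, 9, 9), 1)
  empty <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 0))[0, ]
  maps <- build_media_maps(empty, gs, cfg)
  phi <- pb_solve(maps, cfg, boundary = array(0, gs$dims))
  expect_true(all(phi$values == 0))
})

test_that("single-ion solve matches the Debye-Hueckel closed form", {
  ion <- ion_structure(q = -1, radius = 2)
  cfg <- pb_config(eps_solute = 80, tol = 1e-7)  # uniform solvent dielectric
  gs <- grid_spec(c(65, 65, 65), 0.5)
  phi <- pb_solve(build_media_maps(ion, gs, cfg), cfg, ion)
  ka <- ORACLE$kappa(0.1, 80, 296)
  ax <- grid_axes(gs)
  ic <- 33L
  sel <- which(ax$x >= 2 & ax$x <= 12)   # 2 A out to the boundary margin
  num <- phi$values[sel, ic, ic]
  an <- oracle_dh(ax$x[sel], -1, 80, ka, b = 4)
  rel <- abs(num - an) / abs(an)
  expect_lt(max(rel), 0.05)
  # refinement: halving the spacing shrinks the error
  gs2 <- grid_spec(c(33, 33, 33), 1)
  phi2 <- pb_solve(build_media_maps(ion, gs2, cfg), cfg, ion)
  ax2 <- grid_axes(gs2)
  probe_r <- c(5, 6, 8, 10)
  e_coarse <- max(abs(phi2$values[match(probe_r, ax2$x), 17, 17] -
                        oracle_dh(probe_r, -1, 80, ka, 4)) /
                    abs(oracle_dh(probe_r, -1, 80, ka, 4)))
  e_fine <- max(abs(phi$values[match(probe_r, ax$x), ic, ic] -
                      oracle_dh(probe_r, -1, 80, ka, 4)) /
                  abs(oracle_dh(probe_r, -1, 80, ka, 4)))
  expect_lt(e_fine, e_coarse / 2)
})

test_that("linear solve obeys superposition and sign-flip symmetry", {
  base <- tibble::tibble(atom = c("A", "B"), role = NA_character_,
                         lipid = 1:2, leaflet = 1L, is_phosphate = FALSE,
                         x = c(0, 3), y = 0, z = 0, charge = c(-1, 0.5),
                         radius = c(2, 1.5))
  gs <- grid_spec(c(25, 25, 25), 1)
  cfg <- pb_config(tol = 1e-8)
  solve_q <- function(q) {
    s <- dplyr::mutate(base, charge = q)
    pb_solve(build_media_maps(s, gs, cfg), cfg, s)
  }
  pA <- solve_q(c(-1, 0)); pB <- solve_q(c(0, 0.5))
  pAB <- solve_q(c(-1, 0.5)); pneg <- solve_q(c(1, -0.5))
  scale <- max(abs(pAB$values))
  expect_lt(max(abs(pAB$values - pA$values - pB$values)) / scale, 1e-6)
  expect_equal(pneg$values, -pAB$values)  # exact: same sweeps, negated data
})

test_that("nonlinear mode agrees with linear where the potential is small", {
  ion <- ion_structure(q = -1, radius = 2)
  gs <- grid_spec(c(33, 33, 33), 1)
  lin <- pb_solve(build_media_maps(ion, gs, pb_config(tol = 1e-8)),
                  pb_config(tol = 1e-8), ion)
  nl_cfg <- pb_config(tol = 1e-8, nonlinear = TRUE)
  nl <- pb_solve(build_media_maps(ion, gs, nl_cfg), nl_cfg, ion)
  small <- abs(lin$values) < 0.5 & abs(lin$values) > 0.01
  rel <- abs(nl$values[small] - lin$values[small]) / abs(lin$values[small])
  expect_lt(max(rel), 0.02)
})

test_that("focusing reproduces a direct fine solve in the interior", {
  ion <- ion_structure(q = -1, radius = 2)
  cfg <- pb_config(outer_grid = grid_spec(c(65, 65, 65), 2),
                   inner_grid = grid_spec(c(65, 65, 65), 0.5),
                   tol = 1e-7)
  foc <- focus_solve(ion, cfg)
  direct <- pb_solve(build_media_maps(ion, cfg$inner_grid, cfg), cfg, ion)
  q <- 17:49  # interior half of the inner grid
  mad <- mean(abs(foc$values[q, q, q] - direct$values[q, q, q]))
  expect_lt(mad, 0.05)
  # degenerate: a zero problem stays zero through focusing
  empty <- ion_structure(q = 0, radius = 2)
  z <- focus_solve(empty, pb_config(
    outer_grid = grid_spec(c(17, 17, 17), 2),
    inner_grid = grid_spec(c(17, 17, 17), 0.5)))
  expect_lt(max(abs(z$values)), 1e-12)
  # inner grid escaping the outer is refused
  bad <- pb_config(outer_grid = grid_spec(c(9, 9, 9), 1),
                   inner_grid = grid_spec(c(65, 65, 65), 0.5))
  expect_error(focus_solve(ion, bad), "inside")
})

test_that("default focusing protocol echoes the standard membrane grids", {
  cfg <- pb_config()
  expect_identical(cfg$outer_grid$dims, c(271L, 271L, 222L))
  expect_equal(cfg$outer_grid$spacing, 2)
  expect_identical(cfg$inner_grid$dims, c(201L, 201L, 201L))
  expect_equal(cfg$inner_grid$spacing, 0.5)
  expect_equal(cfg$eps_solute, 2)
  expect_equal(cfg$eps_solvent, 80)
  expect_equal(cfg$ionic_strength, 0.1)
  expect_equal(cfg$ion_radius, 2)
  expect_equal(cfg$temperature, 296)
})
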