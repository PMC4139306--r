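test_that("generated bilayer keeps exact charge bookkeeping", {
  # dipoles are neutral: total system charge is the probe's
  for (q in c(-3, -4)) {
    s <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 12,
                                       probe_charge = q))
    expect_equal(sum(s$charge), q)
    expect_equal(sum(s$role == "P1", na.rm = TRUE), 1L)
  }
  # no lattice lipids: only the probe's four atoms remain
  s0 <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 0))
  expect_identical(nrow(s0), 4L)
  expect_equal(sum(s0$charge), -3)
  expect_setequal(s0$role, c("P1", "C3", "C4", "C5"))
})

test_that("hexagonal lattice has area per lipid (sqrt(3)/2) a^2", {
  a <- 8
  s <- generate_bilayer(bilayer_spec(lattice_constant = a,
                                     lipids_per_leaflet = 64))
  ph <- s[s$is_phosphate & is.na(s$role) & s$leaflet == 1, ]
  pts <- cbind(ph$x, ph$y)
  # brute-force Voronoi cell area of an interior site by dense sampling
  ctr <- pts[which.min(rowSums(sweep(pts, 2, colMeans(pts))^2)), ]
  box <- a * 1.2
  gx <- seq(ctr[1] - box, ctr[1] + box, length.out = 141)
  gy <- seq(ctr[2] - box, ctr[2] + box, length.out = 141)
  sample_pts <- as.matrix(expand.grid(gx, gy))
  # include the probe site (it occupies a lattice position too)
  all_sites <- rbind(pts, c(role_position(s, "P1")[1:2]))
  d2_ctr <- rowSums(sweep(sample_pts, 2, ctr)^2)
  nearest_is_ctr <- vapply(seq_len(nrow(sample_pts)), function(i) {
    d2 <- (all_sites[, 1] - sample_pts[i, 1])^2 +
      (all_sites[, 2] - sample_pts[i, 2])^2
    d2_ctr[i] <= min(d2) + 1e-9
  }, logical(1))
  cell_area <- mean(nearest_is_ctr) * (2 * box)^2
  expect_equal(cell_area, sqrt(3) / 2 * a^2, tolerance = 0.02)
})

test_that("analytic potential matches constants-only Coulomb and Debye formulas", {
  # unscreened: phi at 10 A from a -1e charge in eps=80
  chg <- ion_structure(q = -1, radius = 2)
  p0 <- dh_params(ionic_strength = 0)
  gs <- grid_spec(c(2, 2, 2), 10, origin = c(0, 0, 0))
  g <- analytic_potential(chg, gs, p0)
  expect_equal(g$values[2, 1, 1], -ORACLE$coulomb_k / (80 * 10),
               tolerance = 1e-12)
  # screening constant against the independently assembled formula
  expect_equal(debye_kappa(0.1, 80, 296), ORACLE$kappa(0.1, 80, 296),
               tolerance = 1e-12)
  # screened value at 10 A carries the (1 + kappa a) ion-size factor
  p1 <- dh_params(0.1, 80, 296, ion_radius = 2)
  ka <- ORACLE$kappa(0.1, 80, 296)
  g1 <- analytic_potential(chg, gs, p1)
  expect_equal(g1$values[2, 1, 1],
               -ORACLE$coulomb_k * exp(-ka * (10 - 2)) /
                 (80 * (1 + ka * 2) * 10),
               tolerance = 1e-12)
})

test_that("analytic potential is linear in charges and zero for no charges", {
  set.seed(3)
  gs <- grid_spec(c(6, 6, 6), 2, center = c(0, 0, 0))
  mk <- function(n, qs) tibble::tibble(
    atom = "A", role = NA_character_, lipid = seq_len(n), leaflet = 1L,
    is_phosphate = FALSE, x = runif(n, -4, 4), y = runif(n, -4, 4),
    z = runif(n, -4, 4), charge = qs, radius = 1.5)
  A <- mk(3, c(-1, 2, 0.5)); B <- mk(2, c(1.5, -0.7))
  gA <- analytic_potential(A, gs); gB <- analytic_potential(B, gs)
  gAB <- analytic_potential(dplyr::bind_rows(A, B), gs)
  expect_equal(gAB$values, gA$values + gB$values, tolerance = 1e-12)
  z <- analytic_potential(dplyr::mutate(A, charge = 0), gs)
  expect_true(all(z$values == 0))
})

test_that("ensemble generation is deterministic and degenerates correctly", {
  spec <- bilayer_spec(lipids_per_leaflet = 4, fluctuation_sigma = 0,
                       outlier_rate = 0, seed = 9)
  s <- generate_bilayer(spec)
  gs <- grid_spec(c(5, 5, 5), 3, center = c(0, 0, 24))
  man <- perturb_ensemble(s, 4, gs, spec)
  base <- analytic_potential(s, gs)
  for (i in 1:4)
    expect_equal(man$grid[[i]]$values, base$values, tolerance = 1e-14)
  # fixed seed reproduces bit-identically, with jitter and outliers on
  spec2 <- bilayer_spec(lipids_per_leaflet = 4, fluctuation_sigma = 0.7,
                        outlier_rate = 0.5, seed = 31)
  m1 <- perturb_ensemble(s, 6, gs, spec2)
  m2 <- perturb_ensemble(s, 6, gs, spec2)
  expect_identical(lapply(m1$grid, `[[`, "values"),
                   lapply(m2$grid, `[[`, "values"))
  expect_identical(m1$outlier, m2$outlier)
})

test_that("sample mean of a jittered ensemble converges to the smooth-region truth", {
  spec <- bilayer_spec(lipids_per_leaflet = 9, fluctuation_sigma = 0.15,
                       outlier_rate = 0, seed = 17)
  s <- generate_bilayer(spec)
  # solvent-region grid, where the potential is locally near-linear in the
  # atom displacements so the jitter averages out
  gs <- grid_spec(c(7, 7, 5), 2, center = c(0, 0, 34))
  man <- perturb_ensemble(s, 200, gs, spec)
  clean <- analytic_potential(s, gs)
  vals <- vapply(man$grid, function(g) as.vector(g$values),
                 numeric(prod(gs$dims)))
  m <- rowMeans(vals)
  se <- apply(vals, 1, sd) / sqrt(ncol(vals))
  frac_within <- mean(abs(m - as.vector(clean$values)) <= 3 * se)
  expect_gte(frac_within, 0.95)
})

test_that("probe z-offset pushes the isopotential contour further into solvent", {
  # measured against the fixed membrane frame (the POPC plane reference),
  # the bulge apex must rise strictly with the probe's protrusion
  apex_z <- vapply(c(0, 1.5, 3), function(dz) {
    spec <- bilayer_spec(lipids_per_leaflet = 9, probe_z_offset = dz)
    s <- generate_bilayer(spec)
    g <- analytic_potential(s, grid_spec(c(25, 25, 41), 1,
                                         center = c(0, 0, 30)))
    p1 <- role_position(s, "P1")
    bulge_height(g, p1) + p1[3]
  }, numeric(1))
  expect_true(all(diff(apex_z) > 0))
})
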