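# Synthetic pseudo-bilayer: a planar hexagonal lattice of neutral two-point
# dipoles (pseudo-phosphatidylcholine headgroups) on two leaflets, with one
# lipid of the upper leaflet replaced by a charged probe headgroup (net -3e
# by default) whose phosphate protrudes a configurable z-offset into the
# solvent.  Structures are tibbles of atoms; potentials come from the
# closed-form screened-Coulomb superposition, so every downstream metric can
# be validated against analytic expectations without MD data.

#' Specification of a synthetic bilayer ensemble
#'
#' Defaults are the study conditions the package's validation suite uses: a
#' hexagonal lattice with area/lipid of \eqn{(\sqrt3/2) a^2 \approx 62.6}
#' square angstrom (a = 8.5 A), a -3e probe headgroup protruding 1.5 A, 1 A
#' positional jitter per snapshot, and rare large-magnitude grid spikes
#' (rate 0.05, amplitude -50 kcal/mol/e on 1% of voxels) that exercise the
#' robustness of the remedian average.
#'
#' @param lattice_constant hexagonal lattice constant a (A), > 0.
#' @param lipids_per_leaflet number of pseudo-lipid sites per leaflet
#'   (the probe replaces one upper-leaflet site).
#' @param leaflet_separation distance between the two phosphate planes (A).
#' @param dipole_charge magnitude (e) of the +/- pseudo-headgroup dipole.
#' @param dipole_separation distance (A) between the dipole charges, along z.
#' @param probe_charge net charge (e) of the probe headgroup; <= 0 for the
#'   modeled anionic phosphoinositide.
#' @param probe_z_offset signed protrusion (A) of the probe P1 phosphate
#'   above the upper phosphate plane (+ = toward solvent).
#' @param probe_theta,probe_phi planted headgroup tilt angles (degrees): the
#'   P1->C4 axis makes `probe_theta` with +z; the C3->C5 axis makes
#'   `|probe_phi|` with +z, signed by the convention of [tilt_angles()].
#' @param fluctuation_sigma per-atom Gaussian jitter per snapshot (A).
#' @param outlier_rate probability in `[0, 1)` that a snapshot grid receives
#'   additive spikes.
#' @param outlier_amplitude spike value added (kcal/mol/e).
#' @param outlier_voxel_fraction fraction of voxels spiked in an outlier grid.
#' @param seed integer random seed for ensemble generation.
#' @return a `bilayer_spec` list.
#' @export
bilayer_spec <- function(lattice_constant = 8.5,
                         lipids_per_leaflet = 36,
                         leaflet_separation = 38,
                         dipole_charge = 1.0,
                         dipole_separation = 4.5,
                         probe_charge = -3,
                         probe_z_offset = 1.5,
                         probe_theta = 44.3,
                         probe_phi = -26.9,
                         fluctuation_sigma = 1.0,
                         outlier_rate = 0.05,
                         outlier_amplitude = -50,
                         outlier_voxel_fraction = 0.01,
                         seed = 1L) {
  stopifnot(lattice_constant > 0, lipids_per_leaflet >= 0,
            leaflet_separation > 0, dipole_separation > 0,
            outlier_rate >= 0, outlier_rate < 1,
            outlier_voxel_fraction >= 0, outlier_voxel_fraction <= 1)
  if (probe_charge > 0)
    abort("`probe_charge` must be <= 0 for the modeled anionic headgroup.")
  structure(as.list(environment()), class = "bilayer_spec")
}

#' Debye-Hueckel medium parameters
#'
#' @param ionic_strength ionic strength (mol/L).
#' @param epsilon solvent relative dielectric constant.
#' @param temperature temperature (K).
#' @param ion_radius ion exclusion radius a (A); enters the closed form
#'   through the `exp(kappa a) / (1 + kappa a)` Debye-Hueckel factor.
#' @return a `dh_params` list with the derived `kappa` (1/A).
#' @export
dh_params <- function(ionic_strength = 0.1, epsilon = 80,
                      temperature = 296, ion_radius = 2.0) {
  stopifnot(ionic_strength >= 0, epsilon > 0, temperature > 0, ion_radius >= 0)
  p <- list(ionic_strength = ionic_strength, epsilon = epsilon,
            temperature = temperature, ion_radius = ion_radius,
            kappa = debye_kappa(ionic_strength, epsilon, temperature))
  structure(p, class = "dh_params")
}

# hexagonal lattice sites, centered near the origin, ordered by distance
# from the patch centroid so site 1 is the central one
hex_sites <- function(n, a) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  side <- ceiling(sqrt(n)) + 2
  ij <- expand.grid(i = seq(-side, side), j = seq(-side, side))
  x <- a * (ij$i + 0.5 * (ij$j %% 2))
  y <- a * (sqrt(3) / 2) * ij$j
  ord <- order(x^2 + y^2)
  unname(cbind(x[ord][seq_len(n)], y[ord][seq_len(n)]))
}

#' Generate a synthetic bilayer structure
#'
#' Two leaflets of neutral pseudo-lipid dipoles (a phosphate-like "-" atom on
#' the phosphate plane, a choline-like "+" atom `dipole_separation` further
#' toward the solvent), plus exactly one probe headgroup on the upper leaflet
#' carrying the net probe charge on its `P1` atom, with neutral `C3`, `C4`,
#' `C5` ring atoms placed to realize the planted tilt angles.
#'
#' @param spec a [bilayer_spec].
#' @return a tibble with columns `atom`, `role` (`P1`, `C3`, `C4`, `C5` or
#'   `NA`), `lipid`, `leaflet` (+1 upper / -1 lower), `is_phosphate`,
#'   `x`, `y`, `z` (A), `charge` (e), `radius` (A).
#' @examples
#' b <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 9))
#' sum(b$charge)  # net charge = probe charge
#' @export
generate_bilayer <- function(spec = bilayer_spec()) {
  stopifnot(inherits(spec, "bilayer_spec"))
  zs <- spec$leaflet_separation / 2
  rows <- list()
  sites <- hex_sites(spec$lipids_per_leaflet, spec$lattice_constant)
  lipid_id <- 0L
  for (leaflet in c(1L, -1L)) {
    for (s in seq_len(nrow(sites))) {
      if (leaflet == 1L && s == 1L) next  # replaced by the probe
      lipid_id <- lipid_id + 1L
      zp <- leaflet * zs
      zn <- leaflet * (zs + spec$dipole_separation)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        atom = c("P", "N"), role = NA_character_, lipid = lipid_id,
        leaflet = leaflet, is_phosphate = c(TRUE, FALSE),
        x = sites[s, 1], y = sites[s, 2], z = c(zp, zn),
        charge = c(-1, 1) * spec$dipole_charge, radius = c(1.9, 1.7))
    }
  }
  # probe headgroup at the central upper-leaflet site (or origin if no lattice)
  px <- if (nrow(sites)) sites[1, 1] else 0
  py <- if (nrow(sites)) sites[1, 2] else 0
  p1 <- c(px, py, zs + spec$probe_z_offset)
  th <- spec$probe_theta * pi / 180
  ph <- spec$probe_phi * pi / 180
  # frame with the P1->C4 axis in the xz-plane (positive x), matching the
  # phi sign convention of tilt_angles()
  L_pc4 <- 4.9
  L_c35 <- 2.5
  c4 <- p1 + L_pc4 * c(sin(th), 0, cos(th))
  u <- c(sin(abs(ph)) * sign(ph + (ph == 0)), 0, cos(abs(ph)))
  c3 <- c4 - (L_c35 / 2) * u
  c5 <- c4 + (L_c35 / 2) * u
  probe <- tibble::tibble(
    atom = c("P1", "C3", "C4", "C5"),
    role = c("P1", "C3", "C4", "C5"),
    lipid = lipid_id + 1L, leaflet = 1L,
    is_phosphate = c(TRUE, FALSE, FALSE, FALSE),
    x = c(p1[1], c3[1], c4[1], c5[1]),
    y = c(p1[2], c3[2], c4[2], c5[2]),
    z = c(p1[3], c3[3], c4[3], c5[3]),
    charge = c(spec$probe_charge, 0, 0, 0),
    radius = c(2.0, 1.7, 1.7, 1.7))
  dplyr::bind_rows(c(rows, list(probe)))
}

structure_coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Resolve a role-tagged atom position
#'
#' @param structure an atom tibble with a `role` column.
#' @param role role tag, e.g. `"P1"`.
#' @return numeric length-3 position (A).
#' @export
role_position <- function(structure, role = "P1") {
  hit <- which(structure$role == role)
  if (!length(hit))
    abort(sprintf("no atom with role '%s' in the structure.", role))
  as.numeric(structure[hit[1], c("x", "y", "z")])
}

#' Analytic screened-Coulomb potential of a structure
#'
#' Closed-form Debye-Hueckel superposition
#' \deqn{\phi(r) = \sum_i q_i k_C e^{-\kappa (r_i - a)} /
#'   (\epsilon (1 + \kappa a) r_i)}
#' in kcal/mol/e, exact to floating precision; the oracle for the
#' finite-difference solver and for all downstream metrics. Voxels closer
#' than `r_min` to a charge are clamped and flagged in the
#' `clamped_voxels` attribute.
#'
#' @param structure atom tibble with `x`, `y`, `z`, `charge`.
#' @param grid a [grid_spec] (or `potential_grid` whose geometry is reused).
#' @param params a [dh_params].
#' @param r_min clamp radius (A).
#' @return a [potential_grid].
#' @export
analytic_potential <- function(structure, grid, params = dh_params(),
                               r_min = 1e-3) {
  gs <- as_grid_spec(grid)
  keep <- structure$charge != 0
  if (!any(keep)) {
    g <- potential_grid(array(0, gs$dims), gs$spacing, gs$origin,
                        label = "analytic potential")
    attr(g, "clamped_voxels") <- integer(0)
    return(g)
  }
  res <- cpp_analytic_potential(
    structure_coords(structure[keep, ]), structure$charge[keep],
    gs$dims, gs$origin, gs$spacing,
    params$kappa, params$epsilon, .const$coulomb_kcal, params$ion_radius,
    r_min)
  g <- potential_grid(res$values, gs$spacing, gs$origin,
                      label = "analytic potential")
  attr(g, "clamped_voxels") <- res$clamped
  g
}

#' Generate a fluctuating grid ensemble from a structure
#'
#' Each snapshot jitters every atom by isotropic Gaussian noise of sd
#' `spec$fluctuation_sigma`, computes the analytic potential, and with
#' probability `spec$outlier_rate` adds `spec$outlier_amplitude` to a random
#' `spec$outlier_voxel_fraction` of voxels (the rare large-magnitude spikes
#' the remedian average is designed to resist). Fully reproducible from
#' `spec$seed`.
#'
#' @param structure atom tibble, the unperturbed reference.
#' @param n number of snapshots (>= 1).
#' @param grid a [grid_spec].
#' @param spec a [bilayer_spec] (fluctuation/outlier/seed fields are used).
#' @param params a [dh_params].
#' @param dt_ns time between snapshots in ns (default 0.1, i.e. 100 ps).
#' @return an ensemble manifest: tibble with `snapshot`, `time_ns`,
#'   `outlier` (logical) and a `grid` list-column of [potential_grid]s.
#' @export
perturb_ensemble <- function(structure, n, grid, spec = bilayer_spec(),
                             params = dh_params(), dt_ns = 0.1) {
  stopifnot(n >= 1)
  gs <- as_grid_spec(grid)
  nvox <- prod(gs$dims)
  n_spike <- max(1L, round(spec$outlier_voxel_fraction * nvox))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  grids <- vector("list", n)
  is_out <- logical(n)
  coords <- structure_coords(structure)
  for (s in seq_len(n)) {
    jit <- structure
    if (spec$fluctuation_sigma > 0) {
      d <- matrix(rnorm(length(coords), sd = spec$fluctuation_sigma),
                  ncol = 3)
      jit$x <- coords[, 1] + d[, 1]
      jit$y <- coords[, 2] + d[, 2]
      jit$z <- coords[, 3] + d[, 3]
    }
    g <- analytic_potential(jit, gs, params)
    if (spec$outlier_rate > 0 && runif(1) < spec$outlier_rate) {
      vox <- sample.int(nvox, n_spike)
      g$values[vox] <- g$values[vox] + spec$outlier_amplitude
      is_out[s] <- TRUE
    }
    g$label <- sprintf("snapshot %d", s)
    grids[[s]] <- g
  }
  tibble::tibble(snapshot = seq_len(n), time_ns = seq_len(n) * dt_ns,
                 outlier = is_out, grid = grids)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
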