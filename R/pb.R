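# Finite-difference Poisson-Boltzmann solver.  Linearized form by default:
#   div( eps grad phi ) - kbar2 phi = -4 pi k_C rho
# on a uniform grid (kcal/mol/e, angstrom, e), 7-point variable-coefficient
# stencil, face dielectrics by harmonic mean, damped red-black SOR.
# kbar2 = eps_solvent * kappa^2 outside the ion-accessible surface (solute
# vdW spheres inflated by the ion exclusion radius), zero inside.  Dirichlet
# boundary from the screened-Coulomb superposition unless values are given.

#' Poisson-Boltzmann solver configuration
#'
#' Defaults mirror the membrane protocol this package targets: solute
#' dielectric 2, solvent 80, 100 mM ionic strength, 2 A ion exclusion
#' radius, 296 K, an outer focusing grid of 271 x 271 x 222 points at 2 A
#' and an inner grid of 201^3 points at 0.5 A centered on the probe P1
#' phosphate.
#'
#' @param eps_solute solute relative dielectric (default 2).
#' @param eps_solvent solvent relative dielectric (default 80).
#' @param ionic_strength mol/L (default 0.1).
#' @param ion_radius ion exclusion radius (A, default 2).
#' @param temperature K (default 296).
#' @param outer_grid,inner_grid [grid_spec]s for the two focusing levels;
#'   `inner_grid` may omit a center, in which case it is centered on P1 at
#'   solve time.
#' @param tol relative residual convergence tolerance.
#' @param maxit maximum SOR iterations.
#' @param omega SOR over-relaxation factor; `NULL` chooses
#'   `2 / (1 + sin(pi / max(dims)))`.
#' @param nonlinear solve the nonlinear form (damped Picard on the
#'   effective screening coefficient) instead of the linearized one.
#' @return a `pb_config` list.
#' @export
pb_config <- function(eps_solute = 2, eps_solvent = 80,
                      ionic_strength = 0.1, ion_radius = 2.0,
                      temperature = 296,
                      outer_grid = grid_spec(c(271, 271, 222), 2),
                      inner_grid = grid_spec(c(201, 201, 201), 0.5),
                      tol = 1e-6, maxit = 10000, omega = NULL,
                      nonlinear = FALSE) {
  stopifnot(eps_solute > 0, eps_solvent > 0, tol > 0, maxit >= 1)
  structure(list(eps_solute = eps_solute, eps_solvent = eps_solvent,
                 ionic_strength = ionic_strength, ion_radius = ion_radius,
                 temperature = temperature, outer_grid = outer_grid,
                 inner_grid = inner_grid, tol = tol, maxit = maxit,
                 omega = omega, nonlinear = isTRUE(nonlinear)),
            class = "pb_config")
}

pb_dh_params <- function(config) {
  dh_params(config$ionic_strength, config$eps_solvent, config$temperature,
            config$ion_radius)
}

# mark voxels whose centers fall inside any sphere (coords, radii + inflate)
mark_inside <- function(gs, coords, radii, inflate = 0) {
  ax <- grid_axes(gs)
  inside <- array(FALSE, gs$dims)
  clipped <- FALSE
  for (a in seq_len(nrow(coords))) {
    r <- radii[a] + inflate
    ir <- lapply(1:3, function(d) {
      which(abs(ax[[d]] - coords[a, d]) <= r)
    })
    if (!all(lengths(ir) > 0)) { clipped <- TRUE; next }
    dx2 <- (ax$x[ir[[1]]] - coords[a, 1])^2
    dy2 <- (ax$y[ir[[2]]] - coords[a, 2])^2
    dz2 <- (ax$z[ir[[3]]] - coords[a, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    inside[ir[[1]], ir[[2]], ir[[3]]] <-
      inside[ir[[1]], ir[[2]], ir[[3]]] | (d2 <= r^2)
  }
  attr(inside, "clipped") <- clipped
  inside
}

#' Build dielectric, screening and source maps for a structure on a grid
#'
#' Voxel dielectric is `eps_solute` inside any atom's vdW sphere and
#' `eps_solvent` outside (the vdW dielectric boundary); face values are the
#' harmonic means of the two adjacent voxels. The modified screening map
#' \eqn{\bar\kappa^2 = \epsilon_{solv} \kappa^2} is zeroed inside the vdW
#' surface inflated by the ion exclusion radius. Charges are spread to the
#' 8 surrounding voxel corners with trilinear weights (conserving total
#' charge exactly).
#'
#' @param structure atom tibble with `x`, `y`, `z`, `charge`, `radius`
#'   (all radii > 0); may be empty (uniform solvent).
#' @param grid a [grid_spec].
#' @param config a [pb_config].
#' @return a `pb_media` list: `eps` (voxel array), `eps_x/y/z` (face
#'   arrays), `kbar2`, `charge` (e per voxel), `spec`.
#' @export
build_media_maps <- function(structure, grid, config = pb_config()) {
  gs <- as_grid_spec(grid)
  if (nrow(structure) && any(structure$radius <= 0))
    abort("zero-radius atom: every atom needs a positive vdW radius.")
  dh <- pb_dh_params(config)
  eps <- array(config$eps_solvent, gs$dims)
  kb <- array(config$eps_solvent * dh$kappa^2, gs$dims)
  qv <- array(0, gs$dims)
  if (nrow(structure)) {
    coords <- structure_coords(structure)
    vdw <- mark_inside(gs, coords, structure$radius, 0)
    stern <- mark_inside(gs, coords, structure$radius, config$ion_radius)
    eps[vdw] <- config$eps_solute
    kb[stern] <- 0
    # trilinear charge spreading
    clipped <- FALSE
    for (a in which(structure$charge != 0)) {
      f <- (coords[a, ] - gs$origin) / gs$spacing
      i0 <- floor(f)
      if (any(i0 < 0) || any(i0 > gs$dims - 2)) {
        clipped <- TRUE
        i0 <- pmin(pmax(i0, 0), gs$dims - 2)
        f <- pmin(pmax(f, 0), gs$dims - 1)
      }
      t <- f - i0
      for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
        w <- (if (di) t[1] else 1 - t[1]) * (if (dj) t[2] else 1 - t[2]) *
          (if (dk) t[3] else 1 - t[3])
        qv[i0[1] + di + 1, i0[2] + dj + 1, i0[3] + dk + 1] <-
          qv[i0[1] + di + 1, i0[2] + dj + 1, i0[3] + dk + 1] +
          w * structure$charge[a]
      }
    }
    if (clipped || isTRUE(attr(vdw, "clipped")))
      warn("atom(s) outside the grid: spreading/marking was clipped to the grid.")
  }
  nx <- gs$dims[1]; ny <- gs$dims[2]; nz <- gs$dims[3]
  hm <- function(a, b) 2 * a * b / (a + b)
  structure(list(
    eps = eps,
    eps_x = hm(eps[-nx, , , drop = FALSE], eps[-1, , , drop = FALSE]),
    eps_y = hm(eps[, -ny, , drop = FALSE], eps[, -1, , drop = FALSE]),
    eps_z = hm(eps[, , -nz, drop = FALSE], eps[, , -1, drop = FALSE]),
    kbar2 = kb, charge = qv, spec = gs), class = "pb_media")
}

# Dirichlet boundary values from the screened-Coulomb closed form; each
# atom's ion exclusion is its vdW radius plus the ion radius (the
# Debye-Hueckel sphere consistent with the kbar2 Stern layer)
dh_boundary <- function(structure, gs, params) {
  phi <- array(0, gs$dims)
  keep <- structure$charge != 0
  if (!any(keep)) return(phi)
  faces <- boundary_points(gs)
  vals <- cpp_analytic_potential(
    structure_coords(structure[keep, ]), structure$charge[keep],
    gs$dims, gs$origin, gs$spacing, params$kappa, params$epsilon,
    .const$coulomb_kcal, structure$radius[keep] + params$ion_radius)$values
  phi[faces] <- vals[faces]
  phi
}

boundary_points <- function(gs) {
  m <- array(FALSE, gs$dims)
  m[c(1, gs$dims[1]), , ] <- TRUE
  m[, c(1, gs$dims[2]), ] <- TRUE
  m[, , c(1, gs$dims[3])] <- TRUE
  m
}

#' Solve the (linearized) Poisson-Boltzmann equation on one grid
#'
#' @param maps a `pb_media` from [build_media_maps()].
#' @param config a [pb_config].
#' @param structure atom tibble; needed when `boundary = "dh_analytic"`.
#' @param boundary `"dh_analytic"` (screened-Coulomb Dirichlet values), or a
#'   numeric array of the grid's dims providing boundary values (interior
#'   entries are ignored).
#' @return a [potential_grid] with `iterations` and `residual` attributes.
#' @export
pb_solve <- function(maps, config = pb_config(), structure = NULL,
                     boundary = "dh_analytic") {
  stopifnot(inherits(maps, "pb_media"))
  gs <- maps$spec
  if (is.character(boundary) && boundary == "dh_analytic") {
    if (is.null(structure)) abort("`structure` needed for the analytic boundary.")
    phi0 <- dh_boundary(structure, gs, pb_dh_params(config))
  } else {
    phi0 <- array(as.numeric(boundary), gs$dims)
    phi0[!boundary_points(gs)] <- 0
  }
  omega <- config$omega
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(gs$dims)))
  src <- 4 * pi * .const$coulomb_kcal * maps$charge / gs$spacing^3
  run_linear <- function(kb, phi_init) {
    cpp_sor_solve(phi_init, maps$eps_x, maps$eps_y, maps$eps_z, kb, src,
                  gs$dims, gs$spacing, omega, config$tol, config$maxit)
  }
  if (!config$nonlinear) {
    res <- run_linear(maps$kbar2, phi0)
  } else {
    # damped Picard: effective coefficient kbar2 * sinh(u)/u, u = phi/kT'
    kTe <- esp_units(config$temperature)$kT_per_e_kcal
    res <- run_linear(maps$kbar2, phi0)
    phi <- res$phi
    for (outer_it in 1:30) {
      u <- phi / kTe
      fac <- ifelse(abs(u) < 1e-8, 1, sinh(pmin(pmax(u, -30), 30)) / u)
      res <- run_linear(maps$kbar2 * array(fac, gs$dims), phi)
      phi_new <- 0.6 * res$phi + 0.4 * phi
      delta <- max(abs(phi_new - phi)) / max(max(abs(phi_new)), 1e-12)
      phi <- phi_new
      if (delta < 10 * config$tol) break
    }
    res$phi <- phi
  }
  if (!res$converged)
    abort(sprintf(
      "PB solve did not converge: residual %.3g after %d iterations (tol %g).",
      res$residual, res$iterations, config$tol))
  g <- potential_grid(res$phi, gs$spacing, gs$origin,
                      label = if (config$nonlinear) "PB potential (nonlinear)"
                              else "PB potential (linear)")
  attr(g, "iterations") <- res$iterations
  attr(g, "residual") <- res$residual
  g
}

#' Two-level focusing solve
#'
#' Solves the outer grid with the analytic screened-Coulomb boundary, then
#' the inner grid with boundary values interpolated trilinearly from the
#' outer solution. The inner grid is centered on the structure's P1 atom
#' when `center_on_p1` is `TRUE` (the default), and must lie fully inside
#' the outer grid.
#'
#' @param structure atom tibble (with a `P1` role when centering on P1).
#' @param config a [pb_config].
#' @param center_on_p1 recenter the inner grid on the P1 atom.
#' @return the inner [potential_grid], labeled with focusing provenance.
#' @export
focus_solve <- function(structure, config = pb_config(),
                        center_on_p1 = TRUE) {
  outer_gs <- config$outer_grid
  inner_gs <- config$inner_grid
  if (center_on_p1)
    inner_gs <- grid_spec(inner_gs$dims, inner_gs$spacing,
                          center = role_position(structure, "P1"))
  lo_ok <- all(inner_gs$origin >= outer_gs$origin - 1e-9)
  hi_ok <- all(inner_gs$origin + (inner_gs$dims - 1) * inner_gs$spacing <=
                 outer_gs$origin + (outer_gs$dims - 1) * outer_gs$spacing + 1e-9)
  if (!lo_ok || !hi_ok)
    abort("inner grid is not fully inside the outer grid.")
  outer_maps <- build_media_maps(structure, outer_gs, config)
  outer_phi <- pb_solve(outer_maps, config, structure, "dh_analytic")
  inner_maps <- build_media_maps(structure, inner_gs, config)
  bd <- boundary_points(inner_gs)
  ax <- grid_axes(inner_gs)
  nx <- inner_gs$dims[1]; ny <- inner_gs$dims[2]; nz <- inner_gs$dims[3]
  pts <- cbind(rep(ax$x, times = ny * nz),
               rep(rep(ax$y, each = nx), times = nz),
               rep(ax$z, each = nx * ny))[as.vector(bd), , drop = FALSE]
  phi_bd <- array(0, inner_gs$dims)
  phi_bd[bd] <- interp_grid(outer_phi, pts)
  inner <- pb_solve(inner_maps, config, structure, boundary = phi_bd)
  inner$label <- sprintf("PB potential (focused: outer %s @ %g A)",
                         paste(outer_gs$dims, collapse = "x"),
                         outer_gs$spacing)
  attr(inner, "outer_iterations") <- attr(outer_phi, "iterations")
  inner
}
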