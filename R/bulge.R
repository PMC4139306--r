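# Isopotential bulge height: how far the (negative) potential contour
# protrudes into the solvent above the probe phosphate.  Operationalized as
# the topmost threshold crossing on the vertical line(s) through P1, with
# linear interpolation between the bracketing z-planes.

#' Bulge measurement specification
#'
#' @param threshold isopotential threshold in kcal/mol/e (negative for the
#'   anionic systems analyzed here); default -0.6 (about 1 kT/e at 296 K).
#' @param reference `"P1"` (height above the probe phosphate) or
#'   `"popc_plane"` (height above the mean far-field phosphate plane, see
#'   [bulge_height_popc_ref()]).
#' @param surface_offset offset (A) above the P1 z at which the upward scan
#'   starts; default 0.05.
#' @param lateral_radius search radius (A) around the P1 x,y position; 0
#'   scans only the vertical line through P1.
#' @return a `bulge_spec` list.
#' @export
bulge_spec <- function(threshold = -0.6, reference = c("P1", "popc_plane"),
                       surface_offset = 0.05, lateral_radius = 0) {
  if (threshold >= 0)
    abort("`threshold` must be negative for this system.")
  stopifnot(surface_offset >= 0, lateral_radius >= 0)
  structure(list(threshold = threshold, reference = match.arg(reference),
                 surface_offset = surface_offset,
                 lateral_radius = lateral_radius),
            class = "bulge_spec")
}

# topmost threshold crossing along one vertical line at (x, y): largest z
# with phi <= threshold, linearly interpolated toward the plane above where
# phi rises back through the threshold.  NA when no plane qualifies.
column_top_crossing <- function(grid, x, y, z_min, threshold) {
  ax <- grid_axes(grid)
  zs <- ax$z[ax$z >= z_min]
  if (!length(zs)) return(NA_real_)
  phi <- interp_grid(grid, cbind(x, y, zs))
  below <- which(phi <= threshold)
  if (!length(below)) return(NA_real_)
  j <- max(below)
  if (j == length(zs)) return(zs[j])  # contour leaves through the grid top
  # interpolate between (zs[j], phi<=thr) and (zs[j+1], phi>thr)
  zs[j] + (threshold - phi[j]) / (phi[j + 1] - phi[j]) * (zs[j + 1] - zs[j])
}

#' Isopotential bulge height above the probe phosphate
#'
#' Scans upward (+z, the solvent direction) from just above `p1` and returns
#' the largest z at which the potential is at or below the threshold, minus
#' the reference z (`p1`'s z), with linear interpolation between bracketing
#' z-planes. With `lateral_radius > 0`, all grid columns within that radius
#' of p1 are scanned and the maximum crossing is returned.
#'
#' @param grid a [potential_grid].
#' @param p1 numeric length-3: the probe phosphate position (A), inside the
#'   grid.
#' @param spec a [bulge_spec].
#' @return signed height (A), or `NA` when the potential never reaches the
#'   threshold above p1.
#' @export
bulge_height <- function(grid, p1, spec = bulge_spec()) {
  stopifnot(is_potential_grid(grid), length(p1) == 3)
  ax <- grid_axes(grid)
  if (p1[1] < ax$x[1] || p1[1] > ax$x[length(ax$x)] ||
      p1[2] < ax$y[1] || p1[2] > ax$y[length(ax$y)] ||
      p1[3] < ax$z[1] || p1[3] > ax$z[length(ax$z)])
    abort("`p1` lies outside the grid.")
  z_min <- p1[3] + spec$surface_offset
  if (spec$lateral_radius <= 0) {
    zc <- column_top_crossing(grid, p1[1], p1[2], z_min, spec$threshold)
    return(if (is.na(zc)) NA_real_ else zc - p1[3])
  }
  xin <- ax$x[abs(ax$x - p1[1]) <= spec$lateral_radius]
  yin <- ax$y[abs(ax$y - p1[2]) <= spec$lateral_radius]
  cols <- expand.grid(x = xin, y = yin)
  cols <- cols[(cols$x - p1[1])^2 + (cols$y - p1[2])^2 <=
                 spec$lateral_radius^2, , drop = FALSE]
  cols <- rbind(cols, data.frame(x = p1[1], y = p1[2]))
  best <- NA_real_
  for (r in seq_len(nrow(cols))) {
    zc <- column_top_crossing(grid, cols$x[r], cols$y[r], z_min,
                              spec$threshold)
    if (!is.na(zc) && (is.na(best) || zc > best)) best <- zc
  }
  if (is.na(best)) NA_real_ else best - p1[3]
}

#' Bulge height relative to the far-field phosphate plane
#'
#' As [bulge_height()], but reported relative to the mean z of same-leaflet
#' flagged phosphates beyond the lateral exclusion radius (see
#' [popc_reference_z()]); the distribution convention of ensemble analyses
#' that reference the membrane surface rather than the probe atom. Heights
#' are signed: an apex below the reference plane is negative.
#'
#' @param grid a [potential_grid].
#' @param structure atom tibble with a `P1` role and phosphate flags.
#' @param spec a [bulge_spec].
#' @param geometry a [geometry_spec()] controlling the exclusion radius.
#' @return signed height (A) or `NA`.
#' @export
bulge_height_popc_ref <- function(grid, structure, spec = bulge_spec(),
                                  geometry = geometry_spec()) {
  p1 <- role_position(structure, "P1")
  h <- bulge_height(grid, p1, spec)
  if (is.na(h)) return(NA_real_)
  zref <- popc_reference_z(structure, geometry)
  h + (p1[3] - zref)
}

#' Bulge heights over an ensemble
#'
#' @param manifest ensemble tibble with a `grid` list-column (see
#'   [perturb_ensemble()]).
#' @param structure reference structure (per-snapshot jitter is not needed:
#'   the measurement references the unperturbed P1 column unless
#'   `reference = "popc_plane"`).
#' @param spec a [bulge_spec].
#' @param geometry a [geometry_spec()] (popc_plane reference only).
#' @return the manifest with a `bulge_height` column appended.
#' @export
bulge_heights <- function(manifest, structure, spec = bulge_spec(),
                          geometry = geometry_spec()) {
  f <- if (spec$reference == "popc_plane")
    function(g) bulge_height_popc_ref(g, structure, spec, geometry)
  else {
    p1 <- role_position(structure, "P1")
    function(g) bulge_height(g, p1, spec)
  }
  dplyr::mutate(manifest,
                bulge_height = purrr::map_dbl(.data$grid, f))
}

#' Sample the potential on a shell just outside the molecular surface
#'
#' Places quasi-uniform points on each atom's sphere of radius
#' `radius + offset`, discards points buried inside any other atom's
#' inflated sphere, and interpolates the grid trilinearly at the survivors.
#'
#' @param grid a [potential_grid].
#' @param structure atom tibble with `x`, `y`, `z`, `radius`.
#' @param offset shell offset above the vdW surface (A), default 0.05.
#' @param n_per_atom points per atom sphere before burial pruning.
#' @return tibble with `atom_index`, `x`, `y`, `z`, `phi`.
#' @export
surface_shell_values <- function(grid, structure, offset = 0.05,
                                 n_per_atom = 64) {
  stopifnot(is_potential_grid(grid), offset >= 0)
  # Fibonacci sphere directions
  i <- seq_len(n_per_atom) - 0.5
  ga <- pi * (3 - sqrt(5))
  dirs <- cbind(cos(ga * i) * sqrt(1 - (1 - 2 * i / n_per_atom)^2),
                sin(ga * i) * sqrt(1 - (1 - 2 * i / n_per_atom)^2),
                1 - 2 * i / n_per_atom)
  out <- vector("list", nrow(structure))
  for (a in seq_len(nrow(structure))) {
    r <- structure$radius[a] + offset
    pts <- sweep(dirs * r, 2,
                 as.numeric(structure[a, c("x", "y", "z")]), "+")
    keep <- rep(TRUE, nrow(pts))
    for (b in seq_len(nrow(structure))) {
      if (b == a) next
      rb <- structure$radius[b] + offset
      d2 <- (pts[, 1] - structure$x[b])^2 + (pts[, 2] - structure$y[b])^2 +
        (pts[, 3] - structure$z[b])^2
      keep <- keep & d2 >= (rb - 1e-9)^2
    }
    if (!any(keep)) next
    out[[a]] <- tibble::tibble(atom_index = a, x = pts[keep, 1],
                               y = pts[keep, 2], z = pts[keep, 3])
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(tibble::tibble(atom_index = integer(), x = double(),
                                        y = double(), z = double(),
                                        phi = double()))
  res$phi <- interp_grid(grid, res[, c("x", "y", "z")])
  res
}
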