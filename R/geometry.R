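# Headgroup geometry: the z-height of the probe phosphate relative to the
# surrounding membrane surface, and the inositol-ring tilt angles.

#' Geometry analysis specification
#'
#' @param exclusion_radius lateral (xy) exclusion radius (A) around the
#'   probe P1 phosphate: only flagged phosphates farther than this define
#'   the membrane reference plane. Default 15.
#' @param leaflet which leaflet's phosphates to use: `+1` (upper), `-1`
#'   (lower), or `NULL` to use the probe's leaflet.
#' @param subtract_90 alternative tilt convention: report the angles minus
#'   90 degrees (see [tilt_angles()]).
#' @return a `geometry_spec` list.
#' @export
geometry_spec <- function(exclusion_radius = 15, leaflet = NULL,
                          subtract_90 = FALSE) {
  stopifnot(exclusion_radius >= 0)
  structure(list(exclusion_radius = exclusion_radius, leaflet = leaflet,
                 subtract_90 = isTRUE(subtract_90)),
            class = "geometry_spec")
}

#' Mean z of far-field membrane phosphates
#'
#' Arithmetic mean z of same-leaflet flagged phosphates whose lateral (xy)
#' distance from the probe P1 exceeds the exclusion radius.
#'
#' @param structure atom tibble with `role`, `is_phosphate`, `leaflet`.
#' @param spec a [geometry_spec()].
#' @return reference plane z (A).
#' @export
popc_reference_z <- function(structure, spec = geometry_spec()) {
  p1 <- role_position(structure, "P1")
  leaflet <- spec$leaflet
  if (is.null(leaflet))
    leaflet <- structure$leaflet[which(structure$role == "P1")[1]]
  cand <- structure$is_phosphate & is.na(structure$role) &
    structure$leaflet == leaflet
  lat <- sqrt((structure$x - p1[1])^2 + (structure$y - p1[2])^2)
  sel <- cand & lat > spec$exclusion_radius
  if (!any(sel))
    abort(sprintf(
      "no flagged phosphates beyond the %g A exclusion radius.",
      spec$exclusion_radius))
  mean(structure$z[sel])
}

#' Probe phosphate z-height relative to the membrane surface
#'
#' `z(P1) - popc_reference_z`, sign-corrected so that positive always means
#' "toward the solvent" (the sign is flipped on the lower leaflet).
#'
#' @inheritParams popc_reference_z
#' @return signed height (A).
#' @export
p1_relative_z <- function(structure, spec = geometry_spec()) {
  p1 <- role_position(structure, "P1")
  leaflet <- spec$leaflet
  if (is.null(leaflet))
    leaflet <- structure$leaflet[which(structure$role == "P1")[1]]
  (p1[3] - popc_reference_z(structure, spec)) * sign(leaflet)
}

angle_with_z <- function(v) {
  acos(pmin(pmax(v[3] / sqrt(sum(v^2)), -1), 1)) * 180 / pi
}

#' Headgroup tilt angles
#'
#' Theta is the angle between the P1->C4 vector and +z (in `[0, 180]`);
#' Phi is the angle between the C3->C5 vector and +z, signed by the
#' x-component of C3->C5 after rotating the frame about z so that P1->C4
#' lies in the xz-plane with positive x (a deterministic, z-rotation
#' invariant sign). With `spec$subtract_90`, both angles are reported minus
#' 90 degrees (the alternative convention in which an in-plane vector reads
#' 0 degrees).
#'
#' @param structure atom tibble carrying `P1`, `C3`, `C4`, `C5` role tags.
#' @param spec a [geometry_spec()].
#' @return list with `theta` and `phi` (degrees).
#' @export
tilt_angles <- function(structure, spec = geometry_spec()) {
  p1 <- role_position(structure, "P1")
  c3 <- role_position(structure, "C3")
  c4 <- role_position(structure, "C4")
  c5 <- role_position(structure, "C5")
  vt <- c4 - p1
  vp <- c5 - c3
  theta <- angle_with_z(vt)
  # rotate about z so vt points into the xz-plane with positive x
  psi <- atan2(vt[2], vt[1])
  rot <- function(v) c(cos(-psi) * v[1] - sin(-psi) * v[2],
                       sin(-psi) * v[1] + cos(-psi) * v[2], v[3])
  vpr <- rot(vp)
  s <- if (vpr[1] < 0) -1 else 1
  phi <- s * angle_with_z(vp)
  if (spec$subtract_90) {
    theta <- theta - 90
    phi <- phi - 90
  }
  list(theta = theta, phi = phi)
}

#' Geometry table for a structure ensemble
#'
#' Applies [p1_relative_z()] and [tilt_angles()] to jittered copies of the
#' structure matching an ensemble manifest's snapshots (regenerated from the
#' manifest's generating spec), or to a list of structures.
#'
#' @param structures list of atom tibbles.
#' @param spec a [geometry_spec()].
#' @return tibble with `snapshot`, `p1_dz`, `theta`, `phi`.
#' @export
geometry_table <- function(structures, spec = geometry_spec()) {
  purrr::map_dfr(seq_along(structures), function(i) {
    s <- structures[[i]]
    ang <- tilt_angles(s, spec)
    tibble::tibble(snapshot = i,
                   p1_dz = p1_relative_z(s, spec),
                   theta = ang$theta, phi = ang$phi)
  })
}

#' Jittered copies of a structure
#'
#' The positional-fluctuation model of [perturb_ensemble()], exposed at the
#' structure level for geometry analyses.
#'
#' @param structure atom tibble.
#' @param n number of copies.
#' @param sigma per-atom Gaussian jitter sd (A).
#' @param seed random seed.
#' @return list of `n` atom tibbles.
#' @export
jitter_structures <- function(structure, n, sigma, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  coords <- structure_coords(structure)
  lapply(seq_len(n), function(s) {
    out <- structure
    d <- matrix(rnorm(length(coords), sd = sigma), ncol = 3)
    out$x <- coords[, 1] + d[, 1]
    out$y <- coords[, 2] + d[, 2]
    out$z <- coords[, 3] + d[, 3]
    out
  })
}
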