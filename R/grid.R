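# The voxel convention used everywhere in this package:
#   - uniform spacing, axis-aligned, voxel *centers* at
#       origin + c(i, j, k) * spacing, 0-based indices i < nx, j < ny, k < nz;
#   - values are stored in an [nx, ny, nz] array, so the x index varies
#     fastest in the linearized order, matching the on-disk plane order of the
#     UHBD dialects (x fastest, then y, plane-by-plane in z).

#' Construct a 3-D potential grid
#'
#' A `potential_grid` is a uniform axis-aligned scalar field of electrostatic
#' potential values in kcal/mol/e, with voxel centers at
#' `origin + index * spacing` (0-based indices).
#'
#' @param values numeric array of dim `dims`, or a vector of length
#'   `prod(dims)` in x-fastest order.
#' @param spacing voxel spacing in angstrom (uniform, scalar, > 0).
#' @param origin numeric length-3: position (A) of the center of voxel (0,0,0).
#' @param dims integer length-3 (nx, ny, nz), each >= 2; inferred from
#'   `values` when it is an array.
#' @param label free-text label carried through averaging and I/O.
#' @return an object of class `potential_grid`.
#' @examples
#' g <- potential_grid(array(0, c(4, 4, 4)), spacing = 1, origin = c(0, 0, 0))
#' g
#' @export
potential_grid <- function(values, spacing, origin = c(0, 0, 0), dims = NULL,
                           label = "") {
  if (is.null(dims)) {
    if (is.null(dim(values)) || length(dim(values)) != 3L)
      abort("`values` must be a 3-D array when `dims` is not given.")
    dims <- dim(values)
  }
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 2L))
    abort("`dims` must be three integers, all >= 2.")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    abort("`spacing` must be a single positive number (angstrom).")
  if (length(origin) != 3L || !all(is.finite(origin)))
    abort("`origin` must be three finite numbers (angstrom).")
  v <- as.double(values)
  if (length(v) != prod(dims))
    abort(sprintf("value count %d does not equal nx*ny*nz = %d.",
                  length(v), prod(dims)))
  if (!all(is.finite(v)))
    abort("all grid values must be finite.")
  dim(v) <- dims
  structure(
    list(dims = dims, spacing = as.double(spacing),
         origin = as.double(origin), values = v,
         label = as.character(label)[1]),
    class = "potential_grid"
  )
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf(
    "<potential_grid> %dx%dx%d @ %.4g A, origin (%.3g, %.3g, %.3g) A\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing,
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values [kcal/mol/e]: min %.4g, max %.4g%s\n",
              min(x$values), max(x$values),
              if (nzchar(x$label)) paste0("  label: ", x$label) else ""))
  invisible(x)
}

is_potential_grid <- function(x) inherits(x, "potential_grid")

#' Grid geometry specification
#'
#' Describes grid geometry without values; used to request a grid from the
#' analytic potential or the Poisson-Boltzmann solver. Either `origin` or
#' `center` may be given (`center` is the geometric center of the voxel
#' lattice).
#'
#' @param dims integer length-3, all >= 2.
#' @param spacing voxel spacing (A).
#' @param origin position of voxel (0,0,0) center (A).
#' @param center alternative to `origin`: lattice center (A).
#' @return a `grid_spec` list with `dims`, `spacing`, `origin`.
#' @export
grid_spec <- function(dims, spacing, origin = NULL, center = NULL) {
  dims <- as.integer(rep(dims, length.out = 3))
  stopifnot(all(dims >= 2L), spacing > 0)
  if (is.null(origin)) {
    if (is.null(center)) center <- c(0, 0, 0)
    origin <- center - (dims - 1) / 2 * spacing
  } else if (!is.null(center)) {
    abort("give either `origin` or `center`, not both.")
  }
  structure(list(dims = dims, spacing = as.double(spacing),
                 origin = as.double(origin)),
            class = "grid_spec")
}

as_grid_spec <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (is_potential_grid(x))
    return(grid_spec(x$dims, x$spacing, origin = x$origin))
  abort("cannot interpret object as a grid specification.")
}

#' Voxel-center coordinates along each axis
#'
#' @param g a `potential_grid` or `grid_spec`.
#' @return list of numeric vectors `x`, `y`, `z` (angstrom).
#' @export
grid_axes <- function(g) {
  g <- as_grid_spec(g)
  list(x = g$origin[1] + (seq_len(g$dims[1]) - 1) * g$spacing,
       y = g$origin[2] + (seq_len(g$dims[2]) - 1) * g$spacing,
       z = g$origin[3] + (seq_len(g$dims[3]) - 1) * g$spacing)
}

#' Trilinear interpolation of grid values at arbitrary points
#'
#' Points outside the grid hull are clamped to the hull faces.
#'
#' @param grid a `potential_grid`.
#' @param points numeric matrix (n x 3) or data frame with columns x, y, z (A).
#' @return numeric vector of interpolated potentials (kcal/mol/e).
#' @export
interp_grid <- function(grid, points) {
  stopifnot(is_potential_grid(grid))
  pts <- as.matrix(as.data.frame(points)[, 1:3])
  storage.mode(pts) <- "double"
  cpp_trilinear(grid$values, grid$origin, grid$spacing, pts)
}

#' Convert a grid to a long tibble of voxels
#'
#' @param x a `potential_grid`.
#' @param ... unused.
#' @return tibble with columns `x`, `y`, `z` (A) and `phi` (kcal/mol/e).
#' @export
as_tibble.potential_grid <- function(x, ...) {
  ax <- grid_axes(x)
  tibble::tibble(
    x = rep(ax$x, times = x$dims[2] * x$dims[3]),
    y = rep(rep(ax$y, each = x$dims[1]), times = x$dims[3]),
    z = rep(ax$z, each = x$dims[1] * x$dims[2]),
    phi = as.vector(x$values)
  )
}

#' Check that an ensemble of grids shares one geometry
#'
#' Dims must be identical; spacing and origin equal within `tol` angstrom.
#' On success returns the list of grids invisibly as an aligned ensemble;
#' on failure the error names the first offending grid and field.
#'
#' @param grids list of `potential_grid` objects (>= 2).
#' @param tol geometric tolerance in angstrom.
#' @return the input list, invisibly, classed `grid_ensemble`.
#' @export
assert_coincident <- function(grids, tol = 1e-6) {
  stopifnot(is.list(grids), length(grids) >= 2)
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    g <- grids[[i]]
    if (!identical(g$dims, ref$dims))
      abort(sprintf("grid %d: dims (%s) differ from grid 1 (%s).",
                    i, paste(g$dims, collapse = ","),
                    paste(ref$dims, collapse = ",")))
    if (abs(g$spacing - ref$spacing) > tol)
      abort(sprintf("grid %d: spacing %.8g differs from grid 1 (%.8g).",
                    i, g$spacing, ref$spacing))
    if (any(abs(g$origin - ref$origin) > tol))
      abort(sprintf("grid %d: origin differs from grid 1 beyond %g A.",
                    i, tol))
  }
  invisible(structure(grids, class = "grid_ensemble"))
}
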