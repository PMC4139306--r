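# PIPSA-style comparison of potentials over solvent "skin" regions: the
# shell of voxels between the probe-inflated and (probe+skin)-inflated van
# der Waals surfaces, restricted to a sphere around the probe phosphate.

#' Skin-region specification
#'
#' @param probe_radius solvent probe radius (A), default 2.0.
#' @param skin_thickness skin shell thickness (A), default 3.0.
#' @param sphere_radius radius (A) of the comparison sphere (10 or 14 in the
#'   analyses this package targets).
#' @param center role tag resolved against the structure (default `"P1"`),
#'   or an explicit numeric length-3 point (A).
#' @return a `skin_spec` list.
#' @export
skin_spec <- function(probe_radius = 2.0, skin_thickness = 3.0,
                      sphere_radius = 14.0, center = "P1") {
  stopifnot(probe_radius > 0, skin_thickness > 0, sphere_radius >= 0)
  structure(list(probe_radius = probe_radius,
                 skin_thickness = skin_thickness,
                 sphere_radius = sphere_radius, center = center),
            class = "skin_spec")
}

#' Build a skin mask over a grid
#'
#' A voxel is selected iff its center lies outside every atom's vdW sphere
#' inflated by the probe radius, inside at least one sphere inflated by
#' probe + skin (i.e. surface distance in `(probe, probe + skin]`), and
#' within `sphere_radius` of the center point.
#'
#' @param structure atom tibble with `x`, `y`, `z`, `radius` (and `role` if
#'   the center is a role tag).
#' @param grid a [grid_spec] or [potential_grid].
#' @param spec a [skin_spec].
#' @return logical array of the grid's dims, classed `skin_mask`, with the
#'   resolved `center` and `spec` as attributes.
#' @export
skin_mask <- function(structure, grid, spec = skin_spec()) {
  stopifnot(nrow(structure) >= 1)
  gs <- as_grid_spec(grid)
  ctr <- if (is.character(spec$center)) role_position(structure, spec$center)
         else as.numeric(spec$center)
  ax <- grid_axes(gs)
  nx <- gs$dims[1]; ny <- gs$dims[2]; nz <- gs$dims[3]
  X <- rep(ax$x, times = ny * nz)
  Y <- rep(rep(ax$y, each = nx), times = nz)
  Z <- rep(ax$z, each = nx * ny)
  inside_sphere <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <=
    spec$sphere_radius^2
  surf <- rep(Inf, length(X))
  idx <- which(inside_sphere)
  if (length(idx)) {
    for (a in seq_len(nrow(structure))) {
      d <- sqrt((X[idx] - structure$x[a])^2 + (Y[idx] - structure$y[a])^2 +
                (Z[idx] - structure$z[a])^2) - structure$radius[a]
      surf[idx] <- pmin(surf[idx], d)
    }
  }
  m <- inside_sphere & surf > spec$probe_radius &
    surf <= spec$probe_radius + spec$skin_thickness
  dim(m) <- gs$dims
  structure(m, class = "skin_mask", center = ctr, spec = spec)
}

#' Hodgkin similarity index of two potentials over a mask
#'
#' \deqn{SI = 2 \sum_i a_i b_i / (\sum_i a_i^2 + \sum_i b_i^2)} over the
#' masked voxels; SI is 1 for identical fields, -1 for sign-flipped ones.
#'
#' @param a,b coincident [potential_grid]s.
#' @param mask logical array (e.g. a [skin_mask()]) of the grids' dims.
#' @return SI in `[-1, 1]`.
#' @export
hodgkin_index <- function(a, b, mask) {
  assert_coincident(list(a, b))
  if (!identical(dim(mask), a$dims))
    abort("mask dims do not match the grids.")
  va <- a$values[mask]; vb <- b$values[mask]
  if (!length(va)) abort("empty skin mask: no voxels selected.")
  den <- sum(va * va) + sum(vb * vb)
  if (den == 0)
    abort("Hodgkin index undefined: both potentials are zero on the mask.")
  2 * sum(va * vb) / den
}

#' Electrostatic distance from a similarity index
#'
#' \eqn{D = \sqrt{2 - 2 SI}}: 0 for perfectly correlated potentials, 2 for
#' anti-correlated ones.
#'
#' @param si Hodgkin similarity in `[-1, 1]`.
#' @return D in `[0, 2]`.
#' @export
electrostatic_distance <- function(si) {
  stopifnot(all(si >= -1 - 1e-12), all(si <= 1 + 1e-12))
  sqrt(pmax(2 - 2 * si, 0))
}

#' All-against-all electrostatic distance matrix
#'
#' Computes \eqn{D_{ab}} for every grid pair over a shared skin mask. The
#' default mask policy builds one mask from the reference structure (the
#' ensemble's designated member), keeping D a metric over a fixed voxel set;
#' `mask` may instead be any logical array, e.g. an intersection mask.
#'
#' @param grids list of coincident [potential_grid]s or an ensemble manifest
#'   tibble (see [perturb_ensemble()]); a `time_ns` column or attribute is
#'   carried into the result.
#' @param structure reference structure used to build the mask (ignored when
#'   `mask` is given).
#' @param spec a [skin_spec].
#' @param mask optional explicit logical mask array.
#' @param labels optional character labels (default grid labels or indices).
#' @return an `esp_distmat`: list with the symmetric `D` matrix, `SI`
#'   matrix, `labels`, `time_ns` and the mask voxel count.
#' @export
pairwise_distances <- function(grids, structure = NULL, spec = skin_spec(),
                               mask = NULL, labels = NULL) {
  time_ns <- NULL
  if (tibble::is_tibble(grids) && "grid" %in% names(grids)) {
    if ("time_ns" %in% names(grids)) time_ns <- grids$time_ns
    grids <- grids$grid
  }
  if (length(grids) < 2) abort("need at least two grids.")
  assert_coincident(grids)
  if (is.null(mask)) {
    if (is.null(structure))
      abort("give either a reference `structure` or an explicit `mask`.")
    mask <- skin_mask(structure, grids[[1]], spec)
  }
  if (!any(mask)) abort("empty skin mask: no voxels selected.")
  V <- vapply(grids, function(g) g$values[mask], numeric(sum(mask)))
  sq <- colSums(V * V)
  G <- crossprod(V)                       # pairwise inner products
  SI <- 2 * G / outer(sq, sq, "+")
  diag(SI) <- 1
  D <- electrostatic_distance(SI)
  if (is.null(labels)) {
    labels <- vapply(seq_along(grids), function(i) {
      lb <- grids[[i]]$label
      if (nzchar(lb)) lb else sprintf("grid %d", i)
    }, character(1))
  }
  dimnames(D) <- dimnames(SI) <- list(labels, labels)
  structure(list(D = D, SI = SI, labels = labels, time_ns = time_ns,
                 n_mask_voxels = sum(mask)),
            class = "esp_distmat")
}

#' @export
print.esp_distmat <- function(x, ...) {
  s <- distance_stats(x)
  cat(sprintf("<esp_distmat> %d grids, %d skin voxels; pairwise D: mean %.3f, sd %.3f\n",
              nrow(x$D), x$n_mask_voxels, s$mean, s$sd))
  invisible(x)
}

upper_tri_values <- function(m) m[upper.tri(m)]

#' Summary statistics of a distance matrix
#'
#' Mean, standard deviation and a histogram of the strict upper triangle.
#'
#' @param m an `esp_distmat` (or bare symmetric matrix).
#' @param breaks passed to [graphics::hist()] binning via [base::cut()];
#'   number of histogram bins.
#' @return list with `mean`, `sd`, `n_pairs` and a `histogram` tibble
#'   (`mid`, `count`).
#' @export
distance_stats <- function(m, breaks = 20) {
  D <- if (inherits(m, "esp_distmat")) m$D else as.matrix(m)
  stopifnot(nrow(D) >= 2)
  v <- upper_tri_values(D)
  edges <- seq(min(v), max(v), length.out = breaks + 1)
  if (min(v) == max(v)) edges <- c(min(v) - 1e-9, max(v) + 1e-9)
  cnt <- tabulate(cut(v, edges, include.lowest = TRUE), length(edges) - 1)
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n_pairs = length(v),
       histogram = tibble::tibble(mid = (head(edges, -1) + tail(edges, -1)) / 2,
                                  count = cnt))
}

#' Time-autocorrelation of the electrostatic distance
#'
#' For snapshots at uniform time spacing, converts the distance matrix back
#' to similarities (\eqn{SI = 1 - D^2/2}) and estimates, per lag \eqn{\tau},
#' \deqn{ACF(\tau) = (\overline{SI(t, t+\tau)} - \overline{SI}_{all}) /
#'   (1 - \overline{SI}_{all})}
#' where \eqn{\overline{SI}_{all}} is the mean over all distinct pairs. Lag 0
#' is 1 by construction; an ensemble of mutually indistinguishable snapshots
#' (zero variance in D) has no defined ACF and raises an error.
#'
#' @param m an `esp_distmat` with `time_ns` (uniformly spaced) or a matrix
#'   plus `time_ns`.
#' @param time_ns snapshot times (ns), required if `m` is a bare matrix.
#' @param max_lag largest lag (in steps) to report; default n - 2.
#' @return tibble with `lag`, `lag_ns`, `acf`, `n_pairs`.
#' @export
distance_autocorrelation <- function(m, time_ns = NULL, max_lag = NULL) {
  D <- if (inherits(m, "esp_distmat")) m$D else as.matrix(m)
  if (is.null(time_ns) && inherits(m, "esp_distmat")) time_ns <- m$time_ns
  n <- nrow(D)
  if (n < 3) abort("need at least 3 snapshots for an autocorrelation.")
  if (is.null(time_ns)) time_ns <- seq_len(n)
  dt <- diff(time_ns)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt))))
    abort("timestamps must be uniformly spaced.")
  SI <- 1 - D^2 / 2
  si_all <- mean(upper_tri_values(SI))
  if (abs(1 - si_all) < 1e-12)
    abort("zero-variance distance series: autocorrelation undefined.")
  if (is.null(max_lag)) max_lag <- n - 2L
  max_lag <- min(max_lag, n - 1L)
  lags <- 0:max_lag
  acf_v <- vapply(lags, function(L) {
    if (L == 0) return(1)
    t1 <- seq_len(n - L)
    s <- mean(SI[cbind(t1, t1 + L)])
    (s - si_all) / (1 - si_all)
  }, numeric(1))
  tibble::tibble(lag = lags, lag_ns = lags * dt[1], acf = acf_v,
                 n_pairs = n - lags)
}
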