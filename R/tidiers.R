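#' Tidy an electrostatic distance matrix into pair rows
#'
#' @param x an `esp_distmat` from [pairwise_distances()].
#' @param ... unused.
#' @return tibble with one row per unordered pair: `a`, `b`, `si`,
#'   `distance`, and `lag_ns` when timestamps are present.
#' @export
tidy.esp_distmat <- function(x, ...) {
  n <- nrow(x$D)
  ij <- which(upper.tri(x$D), arr.ind = TRUE)
  out <- tibble::tibble(
    a = x$labels[ij[, 1]], b = x$labels[ij[, 2]],
    si = x$SI[ij], distance = x$D[ij])
  if (!is.null(x$time_ns))
    out$lag_ns <- x$time_ns[ij[, 2]] - x$time_ns[ij[, 1]]
  out
}

#' One-row summary of an electrostatic distance matrix
#'
#' @inheritParams tidy.esp_distmat
#' @return tibble with `n_grids`, `n_pairs`, `n_mask_voxels`,
#'   `mean_distance`, `sd_distance`, `min_distance`, `max_distance`.
#' @export
glance.esp_distmat <- function(x, ...) {
  s <- distance_stats(x)
  v <- upper_tri_values(x$D)
  tibble::tibble(n_grids = nrow(x$D), n_pairs = s$n_pairs,
                 n_mask_voxels = x$n_mask_voxels,
                 mean_distance = s$mean, sd_distance = s$sd,
                 min_distance = min(v), max_distance = max(v))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
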