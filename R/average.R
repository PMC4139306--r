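# Voxel-wise ensemble averaging.  The remedian (Rousseeuw & Bassett) keeps k
# cascading buffers of b values per voxel: a full buffer collapses to its
# median, which is pushed one level up, so a stream of up to b^k grids is
# summarized in k*b values per voxel.  Because every update touches every
# voxel, buffer occupancy is identical across voxels and is tracked once, as
# the base-b digits of the stream length n.

#' Create a streaming remedian accumulator for grids
#'
#' @param b buffer size (odd, >= 3); the default 9 with `k = 3` gives
#'   capacity \eqn{9^3 = 729} grids.
#' @param k number of cascading buffer levels (>= 1).
#' @return a `remedian_accumulator` (mutable; update with
#'   [update_remedian()], read out with [finalize_remedian()]).
#' @references Rousseeuw, P. J. and Bassett, G. W. (1990) The remedian: a
#'   robust averaging method for large data sets. JASA 85, 97-104.
#' @export
remedian_accumulator <- function(b = 9, k = 3) {
  b <- as.integer(b); k <- as.integer(k)
  if (b < 3L || b %% 2L == 0L) abort("`b` must be an odd integer >= 3.")
  if (k < 1L) abort("`k` must be >= 1.")
  acc <- new.env(parent = emptyenv())
  acc$b <- b; acc$k <- k
  acc$n <- 0L
  acc$counts <- integer(k)       # occupancy of each level's buffer
  acc$bufs <- NULL               # list of nvox x b matrices, made lazily
  acc$spec <- NULL
  acc$label <- "remedian potential"
  class(acc) <- "remedian_accumulator"
  acc
}

#' @export
print.remedian_accumulator <- function(x, ...) {
  cat(sprintf("<remedian_accumulator> b=%d k=%d: %d of %d grids%s\n",
              x$b, x$k, x$n, x$b^x$k,
              if (is.null(x$spec)) " (no grid seen yet)" else ""))
  invisible(x)
}

#' Stream one grid into a remedian accumulator
#'
#' The grid's values enter the level-0 buffer; any buffer that fills
#' collapses to its per-voxel median, pushed to the next level. Errors once
#' the capacity \eqn{b^k} is exceeded.
#'
#' @param acc a [remedian_accumulator()].
#' @param grid a [potential_grid], coincident with the first grid streamed.
#' @return `acc`, invisibly (the accumulator is modified in place).
#' @export
update_remedian <- function(acc, grid) {
  stopifnot(inherits(acc, "remedian_accumulator"), is_potential_grid(grid))
  cap <- acc$b^acc$k
  if (acc$n >= cap)
    abort(sprintf(
      "remedian capacity b^k = %d reached; use a larger `b` or `k`.", cap))
  if (is.null(acc$spec)) {
    acc$spec <- as_grid_spec(grid)
    nvox <- prod(acc$spec$dims)
    acc$bufs <- lapply(seq_len(acc$k),
                       function(i) matrix(NA_real_, nvox, acc$b))
  } else {
    sp <- acc$spec
    if (!identical(grid$dims, sp$dims) ||
        abs(grid$spacing - sp$spacing) > 1e-6 ||
        any(abs(grid$origin - sp$origin) > 1e-6))
      abort("grid is not coincident with the accumulator's grid geometry.")
  }
  v <- as.vector(grid$values)
  level <- 1L
  repeat {
    acc$counts[level] <- acc$counts[level] + 1L
    acc$bufs[[level]][, acc$counts[level]] <- v
    # a full buffer collapses to its median, pushed up (the top level keeps
    # its full buffer: at n = b^k it holds the b nested medians)
    if (acc$counts[level] < acc$b || level == acc$k) break
    v <- cpp_row_median(acc$bufs[[level]], acc$b)
    acc$counts[level] <- 0L
    level <- level + 1L
  }
  acc$n <- acc$n + 1L
  invisible(acc)
}

#' Read out the remedian grid from an accumulator
#'
#' At full capacity this is the plain median of the top-level buffer (the
#' exact nested median of the stream). For partial fills the published
#' completion rule is used: a weighted median over all buffered entries,
#' level-i entries weighted \eqn{b^i}.
#'
#' @param acc a [remedian_accumulator()] with `n >= 1`.
#' @return a [potential_grid]; the stream length is recorded in the
#'   `n_grids` attribute.
#' @export
finalize_remedian <- function(acc) {
  stopifnot(inherits(acc, "remedian_accumulator"))
  if (acc$n == 0L) abort("no grids streamed yet (n = 0).")
  counts <- acc$counts
  cap <- acc$b^acc$k
  if (acc$n == cap) {
    # the cascade left the capstone median as a single level-k... at exactly
    # b^k updates the top buffer is full; its median is the nested median
    v <- cpp_row_median(acc$bufs[[acc$k]], acc$b)
  } else {
    v <- cpp_weighted_median(acc$bufs, counts,
                             as.numeric(acc$b)^(seq_len(acc$k) - 1))
  }
  g <- potential_grid(array(v, acc$spec$dims), acc$spec$spacing,
                      acc$spec$origin, label = acc$label)
  attr(g, "n_grids") <- acc$n
  g
}

.as_grid_list <- function(grids) {
  if (tibble::is_tibble(grids) && "grid" %in% names(grids)) grids$grid
  else grids
}

#' Remedian average of a grid ensemble
#'
#' Convenience wrapper: streams `grids` through a fresh accumulator.
#'
#' @param grids list of coincident [potential_grid]s, or an ensemble
#'   manifest tibble with a `grid` list-column (see [perturb_ensemble()]).
#' @inheritParams remedian_accumulator
#' @return a [potential_grid].
#' @export
remedian_grid <- function(grids, b = 9, k = 3) {
  grids <- .as_grid_list(grids)
  acc <- remedian_accumulator(b, k)
  for (g in grids) update_remedian(acc, g)
  finalize_remedian(acc)
}

#' Voxel-wise arithmetic mean of a grid ensemble
#'
#' Single-pass incremental mean (`m += (x - m)/i`), numerically stable for
#' long streams; at most one grid beyond the running state is resident.
#'
#' @inheritParams remedian_grid
#' @return a [potential_grid] with the stream length in `n_grids`.
#' @export
mean_grid <- function(grids) {
  grids <- .as_grid_list(grids)
  if (!length(grids)) abort("empty grid stream.")
  if (length(grids) > 1) assert_coincident(grids)
  m <- as.vector(grids[[1]]$values)
  for (i in seq_along(grids)[-1])
    m <- m + (as.vector(grids[[i]]$values) - m) / i
  g1 <- grids[[1]]
  g <- potential_grid(array(m, g1$dims), g1$spacing, g1$origin,
                      label = "mean potential")
  attr(g, "n_grids") <- length(grids)
  g
}

#' Voxel-wise exact median of a grid ensemble
#'
#' Holds all grids in memory (test/reference scale); even counts use the
#' midpoint of the two central values.
#'
#' @inheritParams remedian_grid
#' @return a [potential_grid] with the stream length in `n_grids`.
#' @export
exact_median_grid <- function(grids) {
  grids <- .as_grid_list(grids)
  if (!length(grids)) abort("empty grid list.")
  if (length(grids) > 1) assert_coincident(grids)
  mat <- vapply(grids, function(g) as.vector(g$values),
                numeric(prod(grids[[1]]$dims)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  v <- cpp_row_median(mat, ncol(mat))
  g1 <- grids[[1]]
  g <- potential_grid(array(v, g1$dims), g1$spacing, g1$origin,
                      label = "median potential")
  attr(g, "n_grids") <- length(grids)
  g
}

#' @describeIn remedian_grid average an ensemble by a chosen method.
#' @param method one of `"mean"`, `"median"`, `"remedian"`.
#' @export
average_grids <- function(grids, method = c("remedian", "mean", "median"),
                          b = 9, k = 3) {
  method <- match.arg(method)
  switch(method,
         remedian = remedian_grid(grids, b = b, k = k),
         mean = mean_grid(grids),
         median = exact_median_grid(grids))
}
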