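#' Build a logarithmic particle-size grid
#'
#' Constructs the contiguous, half-open `[lower, upper)` bin structure used by
#' optical aerosol spectrometers that count particles into a fixed number of
#' intervals per decade of diameter. Edges follow the geometric progression
#' `e_k = d_min * 10^(k / intervals_per_decade)`; the final edge is clipped to
#' exactly `d_max`, so the last bin may be narrower than the nominal ratio.
#' Bin centers are arithmetic midpoints, `x_i = lower_i + width_i / 2`.
#'
#' @param d_min Lower instrument bound, um (default 0.2).
#' @param d_max Upper instrument bound, um (default 10).
#' @param intervals_per_decade Number of bins per decade of diameter
#'   (default 128).
#'
#' @return An object of class `size_grid`: a list with numeric vectors
#'   `lower`, `upper`, `centers`, `widths` (all um) and the scalar
#'   `intervals_per_decade`.
#'
#' @examples
#' g <- build_grid()            # 0.2-10 um, 128 per decade: 218 bins
#' n_bins(g)
#' head(g$centers)
#' @export
build_grid <- function(d_min = 0.2, d_max = 10, intervals_per_decade = 128) {
  if (!is.numeric(d_min) || !is.numeric(d_max) || length(d_min) != 1L ||
      length(d_max) != 1L || !is.finite(d_min) || !is.finite(d_max) ||
      d_min <= 0 || d_max <= d_min) {
    stop("`d_min` and `d_max` must satisfy 0 < d_min < d_max", call. = FALSE)
  }
  if (!is.numeric(intervals_per_decade) || length(intervals_per_decade) != 1L ||
      intervals_per_decade < 1 ||
      intervals_per_decade != round(intervals_per_decade)) {
    stop("`intervals_per_decade` must be a positive integer", call. = FALSE)
  }
  n_dec <- log10(d_max / d_min)
  k <- ceiling(intervals_per_decade * n_dec - 1e-9)
  edges <- d_min * 10^(seq(0L, k) / intervals_per_decade)
  edges[k + 1L] <- d_max          # clip the last edge to the instrument bound
  edges <- pmin(edges, d_max)
  lower <- edges[-(k + 1L)]
  upper <- edges[-1L]
  widths <- upper - lower
  structure(
    list(
      lower = lower,
      upper = upper,
      centers = lower + widths / 2,
      widths = widths,
      intervals_per_decade = as.integer(intervals_per_decade)
    ),
    class = "size_grid"
  )
}

#' Number of bins in a size grid
#'
#' @param grid A `size_grid`.
#' @return Integer bin count.
#' @export
n_bins <- function(grid) {
  stopifnot(inherits(grid, "size_grid"))
  length(grid$lower)
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf(
    "<size_grid> %d bins, %.4g-%.4g um, %d intervals/decade\n",
    n_bins(x), x$lower[1L], x$upper[n_bins(x)], x$intervals_per_decade
  ))
  invisible(x)
}

#' Test two grids for bin-wise equality
#'
#' @param a,b `size_grid` objects.
#' @param tol Relative edge tolerance.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  inherits(a, "size_grid") && inherits(b, "size_grid") &&
    n_bins(a) == n_bins(b) &&
    all(abs(a$lower - b$lower) <= tol * pmax(a$lower, 1e-300)) &&
    all(abs(a$upper - b$upper) <= tol * pmax(a$upper, 1e-300))
}

assert_same_grid <- function(a, b, what = "spectra") {
  if (!same_grid(a, b)) {
    stop("incompatible grids: ", what, " do not share a common size grid",
         call. = FALSE)
  }
  invisible(TRUE)
}
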