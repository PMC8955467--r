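#' Binned particle-count spectrum
#'
#' One optical-spectrometer measurement: particle counts per size bin for one
#' phase of one run, together with the sampling conditions needed to convert
#' counts to number concentrations.
#'
#' @param grid A `size_grid`.
#' @param counts Non-negative particle counts, one per bin.
#' @param phase One of `"inhalation"`, `"exhalation"`, `"background"`.
#' @param duration Measurement time, s (> 0).
#' @param sample_flow Volumetric sampling flow of the spectrometer, L/min
#'   (default 5).
#' @param run_id Free-text run label.
#'
#' @return An object of class `binned_spectrum`.
#' @export
binned_spectrum <- function(grid, counts,
                            phase = c("inhalation", "exhalation", "background"),
                            duration, sample_flow = 5, run_id = "run") {
  stopifnot(inherits(grid, "size_grid"))
  phase <- match.arg(phase)
  if (length(counts) != n_bins(grid)) {
    stop("`counts` must have one entry per grid bin", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a positive scalar (seconds)", call. = FALSE)
  }
  if (!is.numeric(sample_flow) || length(sample_flow) != 1L || sample_flow <= 0) {
    stop("`sample_flow` must be a positive scalar (L/min)", call. = FALSE)
  }
  structure(
    list(grid = grid, counts = as.numeric(counts), phase = phase,
         duration = duration, sample_flow = sample_flow,
         run_id = as.character(run_id)),
    class = "binned_spectrum"
  )
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf(
    "<binned_spectrum> %s/%s: %d bins, %.0f particles, %.3g s at %.3g L/min\n",
    x$run_id, x$phase, n_bins(x$grid), sum(x$counts), x$duration, x$sample_flow
  ))
  invisible(x)
}

#' Differential number distribution q0
#'
#' Converts per-bin counts `n_i` into the differential particle number
#' distribution `q0(x_i) = n_i / (sum(n) * dx_i)` (units 1/um), which
#' integrates to one over the grid. A spectrum with zero total counts yields
#' an all-zero distribution flagged `empty` rather than dividing by zero.
#'
#' @param spec A `binned_spectrum`.
#' @return An object of class `number_distribution` with fields `grid`, `q0`,
#'   `total_count` and `empty`.
#' @export
number_distribution <- function(spec) {
  stopifnot(inherits(spec, "binned_spectrum"))
  total <- sum(spec$counts)
  q0 <- if (total > 0) spec$counts / (total * spec$grid$widths) else
    numeric(n_bins(spec$grid))
  structure(
    list(grid = spec$grid, q0 = q0, total_count = total, empty = total == 0),
    class = "number_distribution"
  )
}

#' Arithmetic mean particle diameter M1
#'
#' First moment of the differential number distribution over the size grid,
#' `M1 = sum(x_i * q0(x_i) * dx_i)`, which equals the count-weighted mean of
#' the arithmetic bin centers.
#'
#' @param dist A `number_distribution`, or any object with a
#'   [mean_diameter()] method.
#' @param ... Passed to methods.
#' @return Mean diameter, um.
#' @export
mean_diameter <- function(dist, ...) UseMethod("mean_diameter")

#' @rdname mean_diameter
#' @export
mean_diameter.number_distribution <- function(dist, ...) {
  if (dist$empty) {
    stop("mean diameter is undefined for an empty distribution", call. = FALSE)
  }
  sum(dist$grid$centers * dist$q0 * dist$grid$widths)
}

#' @rdname mean_diameter
#' @export
mean_diameter.binned_spectrum <- function(dist, ...) {
  mean_diameter(number_distribution(dist))
}

#' @rdname mean_diameter
#' @export
mean_diameter.concentration_spectrum <- function(dist, ...) {
  tot <- sum(dist$dCn)
  if (tot <= 0) {
    stop("mean diameter is undefined for an empty concentration spectrum",
         call. = FALSE)
  }
  sum(dist$grid$centers * dist$dCn) / tot
}

#' Sampled air volume of a measurement
#'
#' `Vm = Q * t`, converting the sampling flow from L/min to cm3/s
#' (1 L/min = 1000/60 cm3/s).
#'
#' @param sample_flow Volumetric sampling flow, L/min.
#' @param duration Measurement time, s.
#' @return Measured volume, cm3.
#' @examples
#' measured_volume(5, 6)    # 500 cm3
#' @export
measured_volume <- function(sample_flow, duration) {
  if (!is.numeric(sample_flow) || any(sample_flow <= 0) ||
      !is.numeric(duration) || any(duration <= 0)) {
    stop("`sample_flow` and `duration` must be positive", call. = FALSE)
  }
  sample_flow * (1000 / 60) * duration
}

#' Per-bin particle number concentration
#'
#' `dCn_i = n_i / Vm` with the measured volume from [measured_volume()];
#' units particles/cm3.
#'
#' @param spec A `binned_spectrum`.
#' @return An object of class `concentration_spectrum` with fields `grid`,
#'   `dCn`, `measured_volume`, `phase`, `run_id`.
#' @export
concentration <- function(spec) {
  stopifnot(inherits(spec, "binned_spectrum"))
  vm <- measured_volume(spec$sample_flow, spec$duration)
  structure(
    list(grid = spec$grid, dCn = spec$counts / vm, measured_volume = vm,
         phase = spec$phase, run_id = spec$run_id),
    class = "concentration_spectrum"
  )
}

#' @export
print.concentration_spectrum <- function(x, ...) {
  cat(sprintf(
    "<concentration_spectrum> %s/%s: total %.4g P/cm3 (Vm = %.4g cm3)\n",
    x$run_id, x$phase, sum(x$dCn), x$measured_volume
  ))
  invisible(x)
}

#' Background correction of a concentration spectrum
#'
#' Subtracts the ambient (background) aerosol concentration bin-wise, clipping
#' at zero so no bin carries a negative concentration.
#'
#' @param spec,background `concentration_spectrum` objects on the same grid.
#' @return A `concentration_spectrum` with the corrected `dCn`.
#' @export
subtract_background <- function(spec, background) {
  stopifnot(inherits(spec, "concentration_spectrum"),
            inherits(background, "concentration_spectrum"))
  assert_same_grid(spec$grid, background$grid)
  out <- spec
  out$dCn <- pmax(spec$dCn - background$dCn, 0)
  out
}
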