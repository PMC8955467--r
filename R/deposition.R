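#' Average concentration spectra of one phase
#'
#' Per-bin arithmetic mean of the selected spectra across runs. Used to pool
#' the repeated inhalation (or exhalation) cycles of one device before the
#' deposition fractions are formed.
#'
#' @param spectra List of `concentration_spectrum` objects.
#' @param phase Phase to select (`"inhalation"`, `"exhalation"`,
#'   `"background"`), or `NULL` to average all supplied spectra.
#' @return A `concentration_spectrum` whose `dCn` is the per-bin mean; its
#'   `measured_volume` is the mean of the selected volumes and its `run_id`
#'   records the number of runs pooled.
#' @export
phase_average <- function(spectra, phase = NULL) {
  if (!length(spectra)) stop("no spectra supplied", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, TRUE, "concentration_spectrum")))
  if (!is.null(phase)) {
    spectra <- Filter(function(s) s$phase == phase, spectra)
    if (!length(spectra)) {
      stop("no spectra with phase '", phase, "'", call. = FALSE)
    }
  }
  g <- spectra[[1L]]$grid
  for (s in spectra[-1L]) assert_same_grid(g, s$grid)
  m <- rowMeans(vapply(spectra, function(s) s$dCn, numeric(n_bins(g))))
  structure(
    list(grid = g, dCn = m,
         measured_volume = mean(vapply(spectra, `[[`, 0, "measured_volume")),
         phase = spectra[[1L]]$phase,
         run_id = sprintf("mean_of_%d", length(spectra))),
    class = "concentration_spectrum"
  )
}

#' Lung deposition and exhaled fraction from paired spectra
#'
#' The number concentration lost between the inhaled and the exhaled
#' airstream is attributed to deposition downstream of the sampling point
#' (the lung equivalent). The exhaled fraction is
#' `100 * sum(C_ex) / sum(C_in)` and the overall deposition its complement.
#' Per-bin deposition `100 * (C_in - C_ex) / C_in` is reported where the
#' inhaled concentration is positive (`NA` otherwise) and clipped to
#' `[0, 100]` so counting noise cannot produce a nominal negative deposition.
#'
#' @param inhaled,exhaled Background-corrected `concentration_spectrum`
#'   objects on a common grid.
#' @param n_runs Number of runs the spectra were averaged over (metadata).
#' @return An object of class `deposition_result`: list with `grid`,
#'   `per_bin_deposition` (vector, percent or `NA`), `overall_deposition`
#'   (percent), `exhaled_fraction` (percent), `mean_diameter_in`,
#'   `mean_diameter_ex` (um), `n_runs`.
#' @export
deposition <- function(inhaled, exhaled, n_runs = 1L) {
  stopifnot(inherits(inhaled, "concentration_spectrum"),
            inherits(exhaled, "concentration_spectrum"))
  assert_same_grid(inhaled$grid, exhaled$grid)
  cin <- sum(inhaled$dCn)
  if (cin <= 0) {
    stop("deposition is undefined: total inhaled concentration is zero",
         call. = FALSE)
  }
  ef <- 100 * sum(exhaled$dCn) / cin
  per_bin <- rep(NA_real_, n_bins(inhaled$grid))
  pos <- inhaled$dCn > 0
  per_bin[pos] <- pmin(pmax(
    100 * (inhaled$dCn[pos] - exhaled$dCn[pos]) / inhaled$dCn[pos], 0), 100)
  structure(
    list(grid = inhaled$grid,
         per_bin_deposition = per_bin,
         overall_deposition = 100 - ef,
         exhaled_fraction = ef,
         mean_diameter_in = mean_diameter(inhaled),
         mean_diameter_ex = if (sum(exhaled$dCn) > 0)
           mean_diameter(exhaled) else NA_real_,
         n_runs = as.integer(n_runs)),
    class = "deposition_result"
  )
}

#' @export
print.deposition_result <- function(x, ...) {
  cat(sprintf(
    paste0("<deposition_result> deposition %.2f%%, exhaled %.2f%% ",
           "(M1 in %.3g um -> ex %.3g um, n = %d)\n"),
    x$overall_deposition, x$exhaled_fraction,
    x$mean_diameter_in, x$mean_diameter_ex, x$n_runs
  ))
  invisible(x)
}

#' Summarize deposition results across devices
#'
#' @param results Named list of `deposition_result` objects (one per device),
#'   or a list with a `device` field on each element.
#' @param per_run Optional data frame of per-run quantities with columns
#'   `device`, `exhaled_fraction`, `mean_diameter_in`, `mean_diameter_ex`;
#'   when supplied, run-level dispersion (median and IQR of the per-run
#'   exhaled fractions) is added.
#' @return Data frame, one row per device, sorted by device name: overall
#'   deposition and exhaled fraction (percent), inhaled and exhaled mean
#'   diameters (um), number of runs, and optional run-level dispersion.
#' @export
summarize_devices <- function(results, per_run = NULL) {
  if (!length(results)) stop("no results supplied", call. = FALSE)
  devs <- names(results)
  if (is.null(devs)) devs <- vapply(results, function(r) r$device %||% NA, "")
  tab <- data.frame(
    device = devs,
    overall_deposition = vapply(results, `[[`, 0, "overall_deposition"),
    exhaled_fraction = vapply(results, `[[`, 0, "exhaled_fraction"),
    mean_diameter_in = vapply(results, `[[`, 0, "mean_diameter_in"),
    mean_diameter_ex = vapply(results, `[[`, 0, "mean_diameter_ex"),
    n_runs = vapply(results, `[[`, 0L, "n_runs"),
    stringsAsFactors = FALSE
  )
  if (!is.null(per_run)) {
    disp <- do.call(rbind, lapply(split(per_run, per_run$device), function(d) {
      data.frame(device = d$device[1L],
                 exhaled_fraction_median = stats::median(d$exhaled_fraction),
                 exhaled_fraction_iqr = stats::IQR(d$exhaled_fraction),
                 stringsAsFactors = FALSE)
    }))
    tab <- merge(tab, disp, by = "device", all.x = TRUE)
  }
  tab <- tab[order(tab$device), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
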