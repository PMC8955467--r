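#' Simulate a maneuver flow trace for one inhaler
#'
#' Emulates one inhalation-hold-exhalation maneuver through a device of
#' resistance `R`: the inspiratory flow ramps up to the peak
#' `Q_peak = sqrt(pressure_target) / R_system` over the preset's inhalation
#' time and terminates at the peak; a zero-flow breath-hold follows, then a
#' rectangular slow exhalation. In `"porcine"` mode the lung equivalent adds
#' `resistance_increment` to the system resistance (lowering the peak flow)
#' and flattens the rising profile (saturating-exponential instead of
#' sinusoidal rise). Capsule devices overlay a seeded rapid flow oscillation
#' ("capsule flutter"). The pressure channel follows the orifice relation
#' `dP = (R_system * Q)^2` during inhalation and is zero elsewhere.
#'
#' @param preset An `inhaler_preset`.
#' @param maneuver A `maneuver_spec`.
#' @param lung `"bag"` (characterization) or `"porcine"` (respiration).
#' @param seed Seed for the flutter overlay; traces are deterministic given
#'   the seed.
#' @param resistance_increment Additional resistance of the breathing system
#'   in porcine mode, kPa^(1/2)/(L/min).
#' @param dt Sampling interval, s.
#' @return A `flow_trace` with phase marks and a pressure channel.
#' @export
simulate_flow <- function(preset, maneuver = maneuver_spec(),
                          lung = c("bag", "porcine"), seed = 1,
                          resistance_increment = 0.003, dt = 0.01) {
  stopifnot(inherits(preset, "inhaler_preset"),
            inherits(maneuver, "maneuver_spec"))
  lung <- match.arg(lung)
  r_sys <- preset$resistance +
    if (lung == "porcine") resistance_increment else 0
  q_peak <- sqrt(maneuver$pressure_target) / r_sys
  t_inh <- preset$t_inh
  t_total <- t_inh + maneuver$hold_duration + maneuver$exhale_duration
  time <- seq(0, t_total, by = dt)
  n <- length(time)
  inh <- time <= t_inh + 1e-9
  hold <- !inh & time <= t_inh + maneuver$hold_duration + 1e-9

  flow <- numeric(n)
  ti <- time[inh] / t_inh                      # normalized inhalation time
  flow[inh] <- if (lung == "porcine") {
    # flattened, prolonged rise of the compliant lung equivalent
    q_peak * (1 - exp(-4 * ti)) / (1 - exp(-4))
  } else {
    q_peak * sin(pi * ti / 2)
  }
  if (preset$capsule_flutter) {
    set.seed(seed)
    amp <- q_peak * stats::runif(1, 0.03, 0.07)
    freq <- stats::runif(1, 30, 45)                       # Hz
    phi <- stats::runif(1, 0, 2 * pi)
    envelope <- sin(pi * ti)                              # zero at both ends
    flow[inh] <- pmax(flow[inh] +
                        amp * envelope * sin(2 * pi * freq * time[inh] + phi),
                      0)
  }
  flow[!inh & !hold] <- maneuver$exhale_flow

  pressure <- numeric(n)
  pressure[inh] <- (r_sys * flow[inh])^2
  marks <- c(max(which(inh)), max(which(inh | hold)))
  flow_trace(time, flow, pressure_drop = pressure, device = preset$name,
             phase_marks = marks)
}

#' Expected emitted aerosol spectrum of a device
#'
#' Integrates the preset's lognormal number density over each grid bin and
#' scales to the emission concentration, yielding the expected per-bin number
#' concentration (particles/cm3) of the aerosol at the sampling point with no
#' filter in the path. Mass falling outside the instrument range is
#' renormalized into the range (the spectrometer only observes 0.2-10 um); a
#' count median diameter outside the grid triggers a warning.
#'
#' @param preset An `inhaler_preset`.
#' @param grid A `size_grid`.
#' @return Numeric vector of expected per-bin concentrations, particles/cm3.
#' @export
emitted_spectrum <- function(preset, grid) {
  stopifnot(inherits(preset, "inhaler_preset"), inherits(grid, "size_grid"))
  if (preset$cmd < grid$lower[1L] || preset$cmd > grid$upper[n_bins(grid)]) {
    warning("count median diameter lies outside the grid; ",
            "truncated mass renormalized", call. = FALSE)
  }
  mu <- log(preset$cmd)
  sig <- log(preset$gsd)
  p <- stats::pnorm(log(grid$upper), mu, sig) -
    stats::pnorm(log(grid$lower), mu, sig)
  p <- p / sum(p)
  preset$emission_concentration * p
}

#' Upper-airway impaction survival
#'
#' Fraction of particles of diameter `d` passing the upper airway model at
#' inhalation flow `flow`: a decreasing logistic in the impaction parameter
#' `d^2 * Q` relative to `uam_cutoff^2 * uam_ref_flow`.
#'
#' @param d Particle diameter(s), um.
#' @param flow Inhalation flow, L/min.
#' @param filter A `filter_model`.
#' @return Survival probabilities in `[0, 1]`.
#' @export
uam_survival <- function(d, flow, filter = filter_model()) {
  x <- (d^2 * flow) / (filter$uam_cutoff^2 * filter$uam_ref_flow)
  1 / (1 + x^filter$uam_steepness)
}

#' Lung retention survival (U-shaped deposition)
#'
#' Fraction of particles of diameter `d` surviving passage through the lung
#' equivalent: maximal (`lung_min_survival`) at the deposition minimum near
#' 0.5 um and decaying as a Gaussian in log-diameter on either side, with the
#' diffusion slope below and the sedimentation slope above the minimum.
#'
#' @inheritParams uam_survival
#' @return Survival probabilities in `[0, 1]`.
#' @export
lung_survival <- function(d, filter = filter_model()) {
  l <- log10(d / filter$lung_min_diameter)
  slope <- ifelse(l < 0, filter$diffusion_slope, filter$sedimentation_slope)
  filter$lung_min_survival * exp(-slope * l^2)
}

#' Apply the airway filters to an expected spectrum
#'
#' @param expected Expected per-bin concentration at the device outlet,
#'   particles/cm3 (as from [emitted_spectrum()]).
#' @param filter A `filter_model`.
#' @param flow Mean inhalation flow carrying the aerosol through the upper
#'   airway, L/min.
#' @param grid The `size_grid` the spectrum lives on.
#' @return List with `post_uam` (after the upper-airway filter; what is
#'   sampled during inhalation) and `post_lung` (after lung retention; what
#'   returns during exhalation), both per-bin concentrations.
#' @export
apply_filters <- function(expected, filter, flow, grid) {
  stopifnot(inherits(filter, "filter_model"), inherits(grid, "size_grid"),
            length(expected) == n_bins(grid))
  if (any(expected < 0)) stop("`expected` must be non-negative", call. = FALSE)
  su <- uam_survival(grid$centers, flow, filter)
  sl <- lung_survival(grid$centers, filter)
  post_uam <- expected * su
  list(post_uam = post_uam, post_lung = post_uam * sl)
}

#' Draw a counted spectrum from an expected concentration
#'
#' Particle counting is Poisson: each bin's count is drawn with mean
#' `(expected + background) * Vm`, the sampled volume `Vm` coming from
#' [measured_volume()].
#'
#' @param expected Expected per-bin concentration, particles/cm3.
#' @param grid The `size_grid`.
#' @param sample_flow Spectrometer sampling flow, L/min.
#' @param duration Sampling time, s.
#' @param background Per-bin (or scalar) ambient concentration added to the
#'   expectation, particles/cm3.
#' @param seed Random seed (deterministic counts for a fixed seed).
#' @param phase,run_id Metadata for the resulting spectrum.
#' @return A `binned_spectrum`.
#' @export
sample_counts <- function(expected, grid, sample_flow = 5, duration,
                          background = 0, seed = 1, phase = "inhalation",
                          run_id = "run") {
  stopifnot(inherits(grid, "size_grid"), length(expected) == n_bins(grid))
  if (any(expected < 0) || any(background < 0)) {
    stop("expected concentrations must be non-negative", call. = FALSE)
  }
  vm <- measured_volume(sample_flow, duration)
  set.seed(seed)
  counts <- stats::rpois(n_bins(grid), (expected + background) * vm)
  binned_spectrum(grid, counts, phase = phase, duration = duration,
                  sample_flow = sample_flow, run_id = run_id)
}

# Expected per-bin background concentration of a design (lognormal ambient
# aerosol scaled to the configured total).
background_expected <- function(design) {
  g <- design$grid
  mu <- log(design$background_cmd)
  sig <- log(design$background_gsd)
  p <- stats::pnorm(log(g$upper), mu, sig) - stats::pnorm(log(g$lower), mu, sig)
  design$background_concentration * p / sum(p)
}

# Noise-free expectations of one device's measurement chain. The flow seen by
# the upper-airway filter is the mean inspiratory flow of the porcine-mode
# trace; this same path is used by the calibration that produced the shipped
# presets.
expected_device_chain <- function(preset, design) {
  trace <- simulate_flow(preset, design$maneuver, lung = "porcine", seed = 1,
                         resistance_increment = design$lung_resistance_increment)
  marks <- segment_phases(trace)
  mean_flow <- mean(trace$flow[seq_len(marks[1L])])
  emitted <- emitted_spectrum(preset, design$grid)
  filt <- design$filter
  filt$lung_min_survival <- preset$lung_min_survival
  filtered <- apply_filters(emitted, filt, mean_flow, design$grid)
  list(emitted = emitted, post_uam = filtered$post_uam,
       post_lung = filtered$post_lung, mean_flow = mean_flow)
}

#' Generate a complete synthetic study tree
#'
#' Writes, for every device and run: a characterization flow trace and
#' spectrum (no airway filter in the path), a respiration (porcine-mode) flow
#' trace, the inhalation spectrum sampled below the upper airway model, and
#' the exhalation spectrum after lung retention; plus one shared ambient
#' background spectrum per run. All files use the package's delimited-text
#' formats, indexed by `manifest.csv`. Output is byte-identical for a fixed
#' design seed.
#'
#' @param design A `study_design`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame (columns `device`, `run_id`, `mode`,
#'   `phase`, `kind`, `path`), invisibly; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_study <- function(design, dir) {
  stopifnot(inherits(design, "study_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bg_exp <- background_expected(design)
  rows <- list()
  add <- function(device, run_id, mode, phase, kind, path) {
    rows[[length(rows) + 1L]] <<- data.frame(
      device = device, run_id = run_id, mode = mode, phase = phase,
      kind = kind, path = path, stringsAsFactors = FALSE)
  }
  # deterministic per-file seeds derived from the design seed
  seed_of <- function(i_dev, i_run, slot) {
    # double arithmetic: exact below 2^53, avoids 32-bit overflow
    as.integer((as.numeric(design$seed) * 100003 + i_dev * 1009 +
                  i_run * 101 + slot) %% 2147483629)
  }

  dir.create(file.path(dir, "background"), showWarnings = FALSE)
  for (r in seq_len(design$n_runs)) {
    run_id <- sprintf("run%02d", r)
    spec <- sample_counts(rep(0, n_bins(design$grid)), design$grid,
                          duration = design$background_duration,
                          background = bg_exp, seed = seed_of(0L, r, 1L),
                          phase = "background", run_id = run_id)
    rel <- file.path("background", paste0(run_id, "_background.csv"))
    write_spectrum(spec, file.path(dir, rel))
    add("__ambient__", run_id, "ambient", "background", "spectrum", rel)
  }

  for (i in seq_along(design$devices)) {
    preset <- design$devices[[i]]
    ddir <- file.path(dir, preset$name)
    dir.create(ddir, showWarnings = FALSE)
    chain <- expected_device_chain(preset, design)
    for (r in seq_len(design$n_runs)) {
      run_id <- sprintf("run%02d", r)
      base <- file.path(preset$name, run_id)

      tr_char <- simulate_flow(preset, design$maneuver, lung = "bag",
                               seed = seed_of(i, r, 2L))
      rel <- paste0(base, "_char_flow.csv")
      write_flow_trace(tr_char, file.path(dir, rel))
      add(preset$name, run_id, "characterization", "inhalation", "flow", rel)

      sp_char <- sample_counts(chain$emitted, design$grid,
                               duration = preset$t_inh, background = bg_exp,
                               seed = seed_of(i, r, 3L), phase = "inhalation",
                               run_id = run_id)
      rel <- paste0(base, "_char_spectrum.csv")
      write_spectrum(sp_char, file.path(dir, rel))
      add(preset$name, run_id, "characterization", "inhalation", "spectrum",
          rel)

      tr_resp <- simulate_flow(preset, design$maneuver, lung = "porcine",
                               seed = seed_of(i, r, 4L),
                               resistance_increment =
                                 design$lung_resistance_increment)
      rel <- paste0(base, "_resp_flow.csv")
      write_flow_trace(tr_resp, file.path(dir, rel))
      add(preset$name, run_id, "respiration", "inhalation", "flow", rel)

      sp_in <- sample_counts(chain$post_uam, design$grid,
                             duration = preset$t_inh, background = bg_exp,
                             seed = seed_of(i, r, 5L), phase = "inhalation",
                             run_id = run_id)
      rel <- paste0(base, "_inhalation.csv")
      write_spectrum(sp_in, file.path(dir, rel))
      add(preset$name, run_id, "respiration", "inhalation", "spectrum", rel)

      sp_ex <- sample_counts(chain$post_lung, design$grid,
                             duration = design$maneuver$exhale_duration,
                             background = bg_exp, seed = seed_of(i, r, 6L),
                             phase = "exhalation", run_id = run_id)
      rel <- paste0(base, "_exhalation.csv")
      write_spectrum(sp_ex, file.path(dir, rel))
      add(preset$name, run_id, "respiration", "exhalation", "spectrum", rel)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
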