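#' Dry-powder-inhaler preset
#'
#' Device-level parameters of the synthetic study: the inner airflow
#' resistance (literature values for the four devices studied), the lognormal
#' parameters of the emitted aerosol (count median diameter and geometric
#' standard deviation, calibrated so the pipeline reproduces the published
#' mean-diameter range), the emission concentration at the sampling point,
#' the inhalation time needed to reach the pressure target, whether the
#' device's capsule flutters (oscillatory flow overlay), and the calibrated
#' peak lung survival used by the retention model.
#'
#' @param name Device label.
#' @param resistance Inner resistance, kPa^(1/2)/(L/min), > 0.
#' @param cmd Count median diameter of the emitted aerosol, um, inside the
#'   instrument range.
#' @param gsd Geometric standard deviation, > 1.
#' @param emission_concentration Number concentration at the sampling point
#'   during inhalation, particles/cm3.
#' @param t_inh Inhalation time to reach the pressure target, s.
#' @param capsule_flutter Logical; capsule devices overlay rapid flow
#'   oscillations on the inspiratory ramp.
#' @param lung_min_survival Peak survival probability of the lung retention
#'   curve for this device (calibrated; see [filter_model()]).
#' @param dose_type Free-text dose-type label.
#' @return An object of class `inhaler_preset`.
#' @export
inhaler_preset <- function(name, resistance, cmd, gsd,
                           emission_concentration = 2000, t_inh = 2,
                           capsule_flutter = FALSE, lung_min_survival = 0.2,
                           dose_type = "") {
  if (resistance <= 0) stop("`resistance` must be positive", call. = FALSE)
  if (gsd <= 1) stop("`gsd` must exceed 1", call. = FALSE)
  if (cmd <= 0.2 || cmd >= 10) {
    stop("`cmd` must lie inside the instrument range (0.2, 10) um",
         call. = FALSE)
  }
  if (emission_concentration <= 0 || t_inh <= 0) {
    stop("`emission_concentration` and `t_inh` must be positive",
         call. = FALSE)
  }
  if (lung_min_survival < 0 || lung_min_survival > 1) {
    stop("`lung_min_survival` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = as.character(name), resistance = resistance, cmd = cmd,
         gsd = gsd, emission_concentration = emission_concentration,
         t_inh = t_inh, capsule_flutter = isTRUE(capsule_flutter),
         lung_min_survival = lung_min_survival,
         dose_type = as.character(dose_type)),
    class = "inhaler_preset"
  )
}

#' Size-selective filter model of the airway path
#'
#' Two multiplicative survival curves act on the emitted aerosol. The upper
#' airway model removes large particles by inertial impaction: survival is a
#' decreasing logistic in the impaction parameter `d^2 * Q` with midpoint at
#' `uam_cutoff` (um) at the reference flow. The lung retains particles by a
#' U-shaped deposition curve whose minimum (maximum survival) sits near
#' 0.5 um, between the Brownian-diffusion regime (small particles) and the
#' sedimentation/impaction regime (large particles); survival is
#' `lung_min_survival * exp(-slope * log10(d / lung_min_diameter)^2)` with
#' the diffusion slope below and the sedimentation slope above the minimum.
#'
#' @param uam_cutoff Impaction cut diameter at the reference flow, um.
#' @param uam_steepness Logistic steepness (dimensionless, on the ratio of
#'   impaction parameters).
#' @param uam_ref_flow Reference inhalation flow of the cutoff, L/min.
#' @param lung_min_diameter Diameter of minimum lung deposition, um.
#' @param lung_min_survival Survival probability at that diameter (the
#'   curve's maximum), in `[0, 1]`.
#' @param diffusion_slope Shape parameter of the small-diameter branch
#'   (per squared decade of diameter).
#' @param sedimentation_slope Shape parameter of the large-diameter branch
#'   (per squared decade of diameter).
#' @return An object of class `filter_model`.
#' @export
filter_model <- function(uam_cutoff = 3, uam_steepness = 3, uam_ref_flow = 60,
                         lung_min_diameter = 0.5, lung_min_survival = 0.2,
                         diffusion_slope = 0.8, sedimentation_slope = 70) {
  if (uam_cutoff <= 0 || uam_steepness <= 0 || uam_ref_flow <= 0 ||
      lung_min_diameter <= 0 || diffusion_slope < 0 ||
      sedimentation_slope < 0) {
    stop("filter parameters must be positive", call. = FALSE)
  }
  if (lung_min_survival < 0 || lung_min_survival > 1) {
    stop("`lung_min_survival` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(uam_cutoff = uam_cutoff, uam_steepness = uam_steepness,
         uam_ref_flow = uam_ref_flow, lung_min_diameter = lung_min_diameter,
         lung_min_survival = lung_min_survival,
         diffusion_slope = diffusion_slope,
         sedimentation_slope = sedimentation_slope),
    class = "filter_model"
  )
}

#' Study design of the synthetic experiment
#'
#' Bundles everything the generator needs: the device presets, the number of
#' repeated runs per device, the breathing maneuver, the size grid, the
#' shared filter shape, the ambient background aerosol, the extra flow
#' resistance the breathing system adds in lung (porcine) mode, and the
#' random seed.
#'
#' @param devices Named list of `inhaler_preset` objects.
#' @param n_runs Repeated measurements per device (>= 1).
#' @param maneuver A `maneuver_spec`.
#' @param grid A `size_grid`.
#' @param filter A `filter_model` (its `lung_min_survival` is overridden per
#'   device by the preset's calibrated value).
#' @param background_concentration Total ambient concentration, particles/cm3.
#' @param background_cmd,background_gsd Lognormal shape of the ambient
#'   aerosol.
#' @param background_duration Sampling time of background measurements, s.
#' @param lung_resistance_increment Additional system resistance in porcine
#'   mode, kPa^(1/2)/(L/min).
#' @param seed Base random seed of the study.
#' @return An object of class `study_design`.
#' @export
study_design <- function(devices, n_runs = 12, maneuver = maneuver_spec(),
                         grid = build_grid(), filter = filter_model(),
                         background_concentration = 10,
                         background_cmd = 0.3, background_gsd = 2.0,
                         background_duration = 60,
                         lung_resistance_increment = 0.003, seed = 1) {
  stopifnot(is.list(devices), length(devices) >= 1,
            all(vapply(devices, inherits, TRUE, "inhaler_preset")),
            inherits(maneuver, "maneuver_spec"), inherits(grid, "size_grid"),
            inherits(filter, "filter_model"))
  if (n_runs < 1) stop("`n_runs` must be >= 1", call. = FALSE)
  if (is.null(names(devices))) {
    names(devices) <- vapply(devices, `[[`, "", "name")
  }
  structure(
    list(devices = devices, n_runs = as.integer(n_runs), maneuver = maneuver,
         grid = grid, filter = filter,
         background_concentration = background_concentration,
         background_cmd = background_cmd, background_gsd = background_gsd,
         background_duration = background_duration,
         lung_resistance_increment = lung_resistance_increment,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Load a study configuration file
#'
#' Reads the structured (YAML) configuration holding the grid parameters,
#' maneuver, filter shape, background aerosol, and the calibrated device
#' presets, and assembles a [study_design()].
#'
#' @param path Path to a YAML configuration; defaults to the calibrated
#'   four-device configuration shipped with the package.
#' @param seed Random seed stored in the design (overrides the file's seed
#'   when non-`NULL`).
#' @return A `study_design`.
#' @export
read_study_config <- function(path = default_config_path(), seed = NULL) {
  cfg <- yaml::read_yaml(path)
  grid <- build_grid(cfg$grid$d_min_um, cfg$grid$d_max_um,
                     cfg$grid$intervals_per_decade)
  man <- maneuver_spec(
    pressure_target = cfg$maneuver$pressure_target_kpa,
    pressure_minimum = cfg$maneuver$pressure_minimum_kpa,
    hold_duration = cfg$maneuver$hold_s,
    exhale_flow = cfg$maneuver$exhale_flow_lpm,
    exhale_duration = cfg$maneuver$exhale_s
  )
  filt <- filter_model(
    uam_cutoff = cfg$filter$uam_cutoff_um,
    uam_steepness = cfg$filter$uam_steepness,
    uam_ref_flow = cfg$filter$uam_ref_flow_lpm,
    lung_min_diameter = cfg$filter$lung_min_diameter_um,
    diffusion_slope = cfg$filter$diffusion_slope,
    sedimentation_slope = cfg$filter$sedimentation_slope
  )
  devices <- lapply(cfg$devices, function(d) {
    inhaler_preset(
      name = d$name, resistance = d$resistance, cmd = d$cmd_um, gsd = d$gsd,
      emission_concentration = d$emission_concentration_pcm3,
      t_inh = d$t_inh_s, capsule_flutter = isTRUE(d$capsule_flutter),
      lung_min_survival = d$lung_min_survival, dose_type = d$dose_type %||% ""
    )
  })
  names(devices) <- vapply(devices, `[[`, "", "name")
  study_design(
    devices = devices, n_runs = cfg$study$n_runs, maneuver = man, grid = grid,
    filter = filt,
    background_concentration = cfg$background$concentration_pcm3,
    background_cmd = cfg$background$cmd_um,
    background_gsd = cfg$background$gsd,
    background_duration = cfg$background$duration_s,
    lung_resistance_increment = cfg$study$lung_resistance_increment,
    seed = seed %||% cfg$study$seed
  )
}

#' Path of the shipped calibrated configuration
#' @return File path of the default study configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "study_config.yaml", package = "aerodepo",
              mustWork = TRUE)
}

#' The default four-device study design
#'
#' Convenience wrapper around [read_study_config()] with the shipped
#' calibrated presets.
#'
#' @param seed Random seed.
#' @return A `study_design`.
#' @export
default_study_design <- function(seed = 1) {
  read_study_config(seed = seed)
}
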