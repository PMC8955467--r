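#' Characterize the flow traces of a study
#'
#' Runs [extract_features()] on every flow trace of the requested mode and
#' aggregates per device: mean inhaled volume, peak pressure drop, peak
#' inspiratory flow, inhalation time, and the implied system resistance
#' `sqrt(p_drop)/pif`.
#'
#' @param dir Study directory (with `manifest.csv`).
#' @param mode `"characterization"` (no airway model in the path) or
#'   `"respiration"` (porcine mode).
#' @return List with `per_run` (one row per trace) and `summary` (per-device
#'   means of `v_inh`, `p_drop`, `pif`, `t_inh`, `resistance`).
#' @export
characterize_study <- function(dir, mode = c("characterization",
                                             "respiration")) {
  mode <- match.arg(mode)
  m <- read_manifest(dir)
  m <- m[m$kind == "flow" & m$mode == mode, , drop = FALSE]
  if (!nrow(m)) stop("no ", mode, " flow traces in manifest", call. = FALSE)
  per_run <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    feats <- extract_features(read_flow_trace(m$path[i]))
    feats$run_id <- m$run_id[i]
    feats
  }))
  agg <- stats::aggregate(
    per_run[c("v_inh", "p_drop", "pif", "t_inh")],
    by = list(device = per_run$device), FUN = mean
  )
  agg$resistance <- resistance_from_peak(agg$p_drop, agg$pif)
  agg <- agg[order(agg$device), , drop = FALSE]
  rownames(agg) <- NULL
  list(per_run = per_run, summary = agg)
}

#' Analyze a study end-to-end
#'
#' The full evaluation chain on a study tree: read all spectra, convert
#' counts to number concentrations, subtract the run-averaged ambient
#' background, then per device (a) average the inhalation and exhalation
#' concentration spectra across runs and form the deposition / exhaled
#' fraction, (b) compute per-run mean diameters and exhaled fractions for
#' dispersion, (c) compare per-run inhaled vs exhaled mean diameters with
#' the Kruskal-Wallis test, and (d) summarize the characterization spectra
#' (mean diameter of the unfiltered aerosol).
#'
#' @param dir Study directory (with `manifest.csv`).
#' @param alpha Significance level of the Kruskal-Wallis comparisons.
#' @return List with elements
#'   `summary` (per-device table from [summarize_devices()]),
#'   `deposition` (named list of `deposition_result`),
#'   `per_run` (per-run data frame: device, run, exhaled fraction, inhaled
#'   and exhaled mean diameters),
#'   `characterization` (per-device mean and per-run characterization mean
#'   diameters),
#'   `kw` (named list of `kw_result`, inhaled vs exhaled mean diameter per
#'   device).
#' @export
analyze_study <- function(dir, alpha = 0.05) {
  m <- read_manifest(dir)
  specs <- m[m$kind == "spectrum", , drop = FALSE]

  load_conc <- function(rows) {
    lapply(seq_len(nrow(rows)), function(i) concentration(
      read_spectrum(rows$path[i])))
  }
  bg_rows <- specs[specs$phase == "background", , drop = FALSE]
  if (!nrow(bg_rows)) stop("study has no background spectra", call. = FALSE)
  bg_mean <- phase_average(load_conc(bg_rows))

  devices <- sort(unique(specs$device[specs$mode == "respiration"]))
  dep <- list(); kw <- list(); per_run <- list(); char_rows <- list()

  for (dev in devices) {
    sel <- function(mode, phase) {
      specs[specs$device == dev & specs$mode == mode & specs$phase == phase, ,
            drop = FALSE]
    }
    inh <- lapply(load_conc(sel("respiration", "inhalation")),
                  subtract_background, background = bg_mean)
    exh <- lapply(load_conc(sel("respiration", "exhalation")),
                  subtract_background, background = bg_mean)
    if (!length(inh) || !length(exh)) {
      stop("device ", dev, " lacks paired inhalation/exhalation spectra",
           call. = FALSE)
    }
    dep[[dev]] <- deposition(phase_average(inh), phase_average(exh),
                             n_runs = length(inh))
    m1_in <- vapply(inh, mean_diameter, 0)
    m1_ex <- vapply(exh, mean_diameter, 0)
    ef_run <- 100 * vapply(exh, function(s) sum(s$dCn), 0) /
      vapply(inh, function(s) sum(s$dCn), 0)
    per_run[[dev]] <- data.frame(
      device = dev, run_id = vapply(inh, function(s) s$run_id, ""),
      exhaled_fraction = ef_run, mean_diameter_in = m1_in,
      mean_diameter_ex = m1_ex, stringsAsFactors = FALSE)
    kw[[dev]] <- kruskal_wallis(list(inhaled = m1_in, exhaled = m1_ex),
                                alpha = alpha)

    char <- lapply(load_conc(sel("characterization", "inhalation")),
                   subtract_background, background = bg_mean)
    if (length(char)) {
      char_rows[[dev]] <- data.frame(
        device = dev, run_id = vapply(char, function(s) s$run_id, ""),
        mean_diameter = vapply(char, mean_diameter, 0),
        stringsAsFactors = FALSE)
    }
  }
  per_run <- do.call(rbind, per_run)
  rownames(per_run) <- NULL
  char_per_run <- do.call(rbind, char_rows)
  char_summary <- if (!is.null(char_per_run)) {
    agg <- stats::aggregate(char_per_run["mean_diameter"],
                            by = list(device = char_per_run$device),
                            FUN = mean)
    names(agg)[2L] <- "mean_diameter_char"
    agg
  }
  list(
    summary = summarize_devices(dep, per_run = per_run),
    deposition = dep,
    per_run = per_run,
    characterization = list(summary = char_summary, per_run = char_per_run),
    kw = kw
  )
}

#' Combined human-readable study report
#'
#' Formats the output of [analyze_study()] and [characterize_study()] into a
#' compact per-device table plus the hypothesis-test lines, and optionally
#' writes the tables as CSV.
#'
#' @param analysis Result of [analyze_study()].
#' @param characterization Optional result of [characterize_study()].
#' @param out_dir Optional directory in which CSV tables are written
#'   (`deposition_summary.csv`, `per_run.csv`, `characterization.csv`,
#'   `kw_tests.csv`).
#' @return Data frame of the Kruskal-Wallis lines, invisibly.
#' @export
study_report <- function(analysis, characterization = NULL, out_dir = NULL) {
  s <- analysis$summary
  cat("Per-device deposition summary (concentrations averaged over runs):\n")
  print(s, digits = 4)
  kw_tab <- do.call(rbind, lapply(names(analysis$kw), function(dev) {
    k <- analysis$kw[[dev]]
    data.frame(device = dev, H = k$H, df = k$df, p = k$p,
               significant = k$significant, stringsAsFactors = FALSE)
  }))
  cat("\nInhaled vs exhaled mean diameter (Kruskal-Wallis):\n")
  print(kw_tab, digits = 4)
  if (!is.null(characterization)) {
    cat("\nManeuver characterization (per-device means):\n")
    print(characterization$summary, digits = 4)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(s, file.path(out_dir, "deposition_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$per_run, file.path(out_dir, "per_run.csv"),
                     row.names = FALSE)
    utils::write.csv(kw_tab, file.path(out_dir, "kw_tests.csv"),
                     row.names = FALSE)
    if (!is.null(characterization)) {
      utils::write.csv(characterization$summary,
                       file.path(out_dir, "characterization.csv"),
                       row.names = FALSE)
    }
  }
  invisible(kw_tab)
}
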