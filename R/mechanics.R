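#' Breathing-maneuver parameters
#'
#' The inhalation maneuver used throughout: inhale against the inhaler until a
#' target pressure drop is reached (4 kPa target, 1 kPa accepted minimum for
#' an adequate lung dose), hold the breath, then exhale slowly and steadily.
#'
#' @param pressure_target Target pressure drop across the inhaler, kPa.
#' @param pressure_minimum Minimum adequate pressure drop, kPa.
#' @param hold_duration Breath-hold time, s.
#' @param exhale_flow Exhalation flow, L/min.
#' @param exhale_duration Exhalation time, s.
#' @return An object of class `maneuver_spec`.
#' @export
maneuver_spec <- function(pressure_target = 4, pressure_minimum = 1,
                          hold_duration = 5, exhale_flow = 30,
                          exhale_duration = 6) {
  if (pressure_minimum > pressure_target) {
    stop("`pressure_minimum` must not exceed `pressure_target`", call. = FALSE)
  }
  if (any(c(hold_duration, exhale_duration) <= 0) || exhale_flow <= 0 ||
      pressure_target <= 0 || pressure_minimum <= 0) {
    stop("maneuver parameters must be positive", call. = FALSE)
  }
  structure(
    list(pressure_target = pressure_target, pressure_minimum = pressure_minimum,
         hold_duration = hold_duration, exhale_flow = exhale_flow,
         exhale_duration = exhale_duration),
    class = "maneuver_spec"
  )
}

#' Time-resolved flow (and pressure) trace of one maneuver
#'
#' @param time Sample times, s, strictly increasing.
#' @param flow Flow magnitude, L/min.
#' @param pressure_drop Optional pressure drop across the inhaler, kPa,
#'   sampled at the same times.
#' @param device Device label.
#' @param phase_marks Optional integer vector `c(i, j)`: the last sample index
#'   of the inhalation phase and of the hold phase. When absent, phases are
#'   segmented by threshold crossing (see [segment_phases()]).
#' @return An object of class `flow_trace`.
#' @export
flow_trace <- function(time, flow, pressure_drop = NULL, device = "device",
                       phase_marks = NULL) {
  if (any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (length(flow) != length(time) || any(!is.finite(flow))) {
    stop("`flow` must be finite and match `time` in length", call. = FALSE)
  }
  if (!is.null(pressure_drop) && length(pressure_drop) != length(time)) {
    stop("`pressure_drop` must match `time` in length", call. = FALSE)
  }
  if (!is.null(phase_marks)) {
    phase_marks <- as.integer(phase_marks)
    if (length(phase_marks) != 2L || any(phase_marks < 1L) ||
        phase_marks[2L] < phase_marks[1L] ||
        phase_marks[2L] > length(time)) {
      stop("`phase_marks` must be ordered indices (end of inhalation, end of hold)",
           call. = FALSE)
    }
  }
  structure(
    list(time = as.numeric(time), flow = as.numeric(flow),
         pressure_drop = if (is.null(pressure_drop)) NULL else
           as.numeric(pressure_drop),
         device = as.character(device), phase_marks = phase_marks),
    class = "flow_trace"
  )
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> %s: %d samples over %.3g s, peak flow %.4g L/min\n",
              x$device, length(x$time), max(x$time) - min(x$time),
              max(x$flow)))
  invisible(x)
}

#' Segment a maneuver trace into inhalation / hold / exhalation
#'
#' Explicit `phase_marks` stored on the trace take precedence. Otherwise the
#' inhalation end is found as the last sample before the flow first stays
#' below a 2 L/min threshold (with hysteresis: the flow must first have
#' exceeded twice the threshold, so capsule-flutter oscillations around the
#' threshold do not split the phase), and the exhalation start as the first
#' subsequent sample back above the threshold.
#'
#' @param trace A `flow_trace`.
#' @param threshold Flow threshold, L/min.
#' @return Integer vector of length 3: last inhalation index, last hold
#'   index, last exhalation index.
#' @export
segment_phases <- function(trace, threshold = 2) {
  stopifnot(inherits(trace, "flow_trace"))
  n <- length(trace$time)
  if (!is.null(trace$phase_marks)) {
    return(c(trace$phase_marks, n))
  }
  above <- trace$flow > threshold
  armed <- cumsum(trace$flow > 2 * threshold) > 0      # hysteresis arm
  drop_idx <- which(!above & armed)
  if (!length(drop_idx)) {
    # single-phase trace: all inhalation
    return(c(n, n, n))
  }
  inh_end <- drop_idx[1L] - 1L
  rise <- which(above & seq_len(n) > inh_end)
  hold_end <- if (length(rise)) rise[1L] - 1L else n
  c(inh_end, hold_end, n)
}

#' Airflow resistance from peak pressure drop and peak flow
#'
#' Dry powder inhalers follow the orifice relation `sqrt(dP) = R * Q`, so the
#' device (or whole-system) resistance is `R = sqrt(p_drop) / pif`, in units
#' kPa^(1/2) / (L/min).
#'
#' @param p_drop Peak pressure drop, kPa.
#' @param pif Peak inspiratory flow, L/min.
#' @return Resistance, kPa^(1/2)/(L/min). Vectorized.
#' @examples
#' resistance_from_peak(3.81, 117.28)   # ~0.0166
#' @export
resistance_from_peak <- function(p_drop, pif) {
  if (any(p_drop <= 0) || any(pif <= 0)) {
    stop("`p_drop` and `pif` must be positive", call. = FALSE)
  }
  sqrt(p_drop) / pif
}

#' Pressure drop predicted from resistance and flow
#'
#' Inverse of [resistance_from_peak()]: `dP = (R * Q)^2`.
#'
#' @param resistance Resistance, kPa^(1/2)/(L/min), >= 0.
#' @param flow Flow, L/min, >= 0.
#' @return Pressure drop, kPa. Vectorized.
#' @export
predicted_pressure_drop <- function(resistance, flow) {
  if (any(resistance < 0) || any(flow < 0)) {
    stop("`resistance` and `flow` must be non-negative", call. = FALSE)
  }
  (resistance * flow)^2
}

#' Characterize a maneuver trace
#'
#' Extracts the standard inhalation-maneuver quantities from a flow trace:
#' peak inspiratory flow (global maximum over the inhalation phase),
#' inhalation time, inhaled volume (trapezoidal integral of flow, converted
#' L/min*s -> L), peak pressure drop, and the implied system resistance
#' `sqrt(p_drop)/pif`. When the trace carries no pressure channel, the
#' pressure drop is predicted from `device_resistance`.
#'
#' @param trace A `flow_trace`.
#' @param device_resistance Resistance used to predict the pressure drop when
#'   the trace has no pressure channel, kPa^(1/2)/(L/min).
#' @return One-row data frame with columns `device`, `v_inh` (L), `p_drop`
#'   (kPa), `pif` (L/min), `t_inh` (s), `resistance` (kPa^(1/2)/(L/min)).
#' @export
extract_features <- function(trace, device_resistance = NULL) {
  stopifnot(inherits(trace, "flow_trace"))
  marks <- segment_phases(trace)
  idx <- seq_len(marks[1L])
  if (length(idx) < 2L) {
    stop("invalid trace: inhalation phase has fewer than two samples",
         call. = FALSE)
  }
  t <- trace$time[idx]
  q <- trace$flow[idx]
  pif <- max(q)
  t_inh <- t[length(t)] - t[1L]
  v_inh <- sum(diff(t) * (q[-1L] + q[-length(q)]) / 2) / 60
  p_drop <- if (!is.null(trace$pressure_drop)) {
    max(trace$pressure_drop[idx])
  } else if (!is.null(device_resistance)) {
    predicted_pressure_drop(device_resistance, pif)
  } else {
    stop("trace has no pressure channel and no `device_resistance` was given",
         call. = FALSE)
  }
  data.frame(
    device = trace$device, v_inh = v_inh, p_drop = p_drop, pif = pif,
    t_inh = t_inh, resistance = resistance_from_peak(p_drop, pif),
    stringsAsFactors = FALSE
  )
}

#' Maneuver adequacy flags
#'
#' A pressure drop of at least 1 kPa across a dry powder inhaler suffices for
#' an adequate lung dose; the maneuver additionally aims for a target (4 kPa
#' by default).
#'
#' @param result One-row data frame from [extract_features()] (or any list
#'   with a `p_drop` element, kPa).
#' @param maneuver A `maneuver_spec`.
#' @return Data frame with columns `device`, `p_drop`, `met_minimum`,
#'   `met_target`.
#' @export
adequacy_check <- function(result, maneuver = maneuver_spec()) {
  stopifnot(inherits(maneuver, "maneuver_spec"))
  p <- result$p_drop
  data.frame(
    device = if (!is.null(result$device)) result$device else NA_character_,
    p_drop = p,
    met_minimum = p >= maneuver$pressure_minimum,
    met_target = p >= maneuver$pressure_target,
    stringsAsFactors = FALSE
  )
}
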