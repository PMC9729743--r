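#' Pulsatile inlet waveform over the respiratory cycle
#'
#' Caval return in the Fontan circulation is modulated mainly by respiration;
#' the inlet velocity is modelled as a truncated harmonic series around a
#' mean:
#' \deqn{v(t) = \bar v \left(1 + \sum_m a_m \sin(2\pi h_m t / T + \phi_m)\right)}
#' so the time-mean over one period is exactly `base_mean_velocity` and the
#' waveform stays non-negative whenever `sum(|a_m|) <= 1`.
#'
#' @param port inlet name, `"SVC"` or `"IVC"`.
#' @param base_mean_velocity time-mean inlet velocity, m/s.
#' @param period respiratory cycle length, s (default 2.54).
#' @param modulation list of harmonics, each `list(harmonic=, amplitude=,
#'   phase=)` with relative amplitude; default one respiratory harmonic of
#'   relative amplitude 0.3.
#' @return an object of class `inlet_waveform`.
#' @export
inlet_waveform <- function(port, base_mean_velocity, period = 2.54,
                           modulation = list(list(harmonic = 1,
                                                  amplitude = 0.3,
                                                  phase = 0))) {
  if (!port %in% c("SVC", "IVC"))
    validation_error("inlet port must be SVC or IVC")
  if (base_mean_velocity < 0)
    validation_error("base_mean_velocity must be >= 0")
  if (period <= 0) validation_error("period must be positive")
  amps <- vapply(modulation, function(m) abs(m$amplitude), 0)
  if (length(amps) && sum(amps) > 1 + 1e-12)
    validation_error("sum of |relative amplitudes| must be <= 1 (waveform must stay non-negative)")
  structure(list(port = port, base_mean_velocity = base_mean_velocity,
                 period = period, modulation = modulation),
            class = "inlet_waveform")
}

#' Evaluate an inlet waveform
#'
#' @param w an [inlet_waveform()].
#' @param t time(s), s; vectorised.
#' @return velocity in m/s; periodic and non-negative.
#' @export
waveform_value <- function(w, t) {
  v <- rep(1, length(t))
  for (m in w$modulation)
    v <- v + m$amplitude * sin(2 * pi * m$harmonic * t / w$period +
                                 (m$phase %||% 0))
  w$base_mean_velocity * v
}

PROTOCOL_TABLE <- data.frame(
  level = c("rest", "light", "moderate", "heavy"),
  ivc_flow_multiplier = c(1, 2, 3, 4),
  svc_flow_multiplier = c(1, 1, 1, 1.5),
  resistance_multiplier = c(1.00, 0.95, 0.90, 0.85),
  stringsAsFactors = FALSE
)

#' Exercise boundary-condition protocol
#'
#' Graded exercise is emulated by scaling the rest boundary conditions: the
#' IVC mean inflow velocity is multiplied by 2/3/4 for light/moderate/heavy
#' exercise, the SVC velocity rises 50% at heavy exercise only, and pulmonary
#' outlet resistances drop by 5/10/15%.
#'
#' @param level one of `"rest"`, `"light"`, `"moderate"`, `"heavy"`.
#' @return an object of class `exercise_protocol` with the three multipliers.
#' @examples
#' exercise_protocol("heavy")
#' @export
exercise_protocol <- function(level) {
  i <- match(level, PROTOCOL_TABLE$level)
  if (is.na(i))
    validation_error(sprintf(
      "unknown exercise level '%s' (use rest/light/moderate/heavy)", level))
  structure(as.list(PROTOCOL_TABLE[i, ]), class = "exercise_protocol")
}

#' Lumped resistance outlet
#'
#' Each pulmonary outlet is closed by a linear lumped resistance,
#' `P_port = R * Q_port + P_ref`, standing in for the downstream pulmonary
#' vascular bed. The default corresponds to a total pulmonary vascular
#' resistance of 1.18 Wood units split over two parallel outlets.
#'
#' @param port `"LPA"` or `"RPA"`.
#' @param resistance Pa s/m^3, >= 0.
#' @param reference_pressure distal reference pressure, Pa gauge.
#' @return an object of class `outlet_resistance`.
#' @export
outlet_resistance <- function(port, resistance = 1.888e7,
                              reference_pressure = 0) {
  if (!port %in% c("LPA", "RPA"))
    validation_error("outlet port must be LPA or RPA")
  if (resistance < 0) validation_error("resistance must be >= 0")
  structure(list(port = port, resistance = resistance,
                 reference_pressure = reference_pressure),
            class = "outlet_resistance")
}

#' Bundle inlet waveforms and outlet resistances
#'
#' @param waveforms list of [inlet_waveform()]s, one per inlet port present
#'   in the simulation domain.
#' @param resistances list of [outlet_resistance()]s, one per outlet port.
#' @param protocol optional [exercise_protocol()] already applied (recorded).
#' @return an object of class `boundary_set` keyed by port name.
#' @export
boundary_set <- function(waveforms, resistances, protocol = NULL) {
  wf <- setNames(waveforms, vapply(waveforms, function(w) w$port, ""))
  rs <- setNames(resistances, vapply(resistances, function(r) r$port, ""))
  if (anyDuplicated(names(wf)) || anyDuplicated(names(rs)))
    validation_error("duplicate port in boundary set")
  structure(list(waveforms = wf, resistances = rs,
                 protocol = protocol %||% exercise_protocol("rest")),
            class = "boundary_set")
}

#' Default rest boundary set for the synthetic junction
#'
#' IVC mean 0.30 m/s and SVC mean 0.25 m/s (inside the 0.24-0.41 m/s range
#' of postoperative anastomotic velocities), a single respiratory harmonic of
#' relative amplitude 0.3, and equal outlet resistances totalling 1.18 Wood
#' units.
#'
#' @param period respiratory cycle, s.
#' @param modulation harmonic list passed to [inlet_waveform()].
#' @return a rest [boundary_set()].
#' @export
default_boundaries <- function(period = 2.54,
                               modulation = list(list(harmonic = 1,
                                                      amplitude = 0.3,
                                                      phase = 0))) {
  boundary_set(
    waveforms = list(
      inlet_waveform("IVC", 0.30, period, modulation),
      inlet_waveform("SVC", 0.25, period, modulation)
    ),
    resistances = list(outlet_resistance("LPA"), outlet_resistance("RPA"))
  )
}

#' Apply an exercise protocol to a boundary set
#'
#' Scales the IVC and SVC mean velocities by their flow multipliers and every
#' outlet resistance by the resistance multiplier. The rest protocol is the
#' identity.
#'
#' @param boundaries a [boundary_set()] describing the rest state.
#' @param protocol an [exercise_protocol()] or level name.
#' @return a new [boundary_set()] with the protocol recorded.
#' @export
apply_protocol <- function(boundaries, protocol) {
  if (is.character(protocol)) protocol <- exercise_protocol(protocol)
  wf <- boundaries$waveforms
  for (nm in names(wf)) {
    mult <- switch(nm, IVC = protocol$ivc_flow_multiplier,
                   SVC = protocol$svc_flow_multiplier,
                   validation_error(sprintf("no flow multiplier for port %s", nm)))
    wf[[nm]]$base_mean_velocity <- wf[[nm]]$base_mean_velocity * mult
  }
  rs <- boundaries$resistances
  for (nm in names(rs))
    rs[[nm]]$resistance <- rs[[nm]]$resistance * protocol$resistance_multiplier
  structure(list(waveforms = wf, resistances = rs, protocol = protocol),
            class = "boundary_set")
}
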