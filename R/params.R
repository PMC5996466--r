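#' The seven walk types of a cadence-controlled walking protocol
#'
#' `"Normal"` is self-paced comfortable walking. `NC_80/100/120` play a
#' music tempo of 80/100/120 BPM without asking the walker to follow it;
#' `C_80/100/120` instruct the walker to synchronise steps with the tempo.
#'
#' @return Character vector of the seven walk-type labels.
#' @export
walk_types <- function() {
  c("Normal", "NC_80", "NC_100", "NC_120", "C_80", "C_100", "C_120")
}

# cycle-ordered names of the seven gait periods, starting at toe off
PERIOD_NAMES <- c("initial_swing", "midswing", "terminal_swing",
                  "loading_response", "midstance", "terminal_stance",
                  "preswing")

# period names in conventional reporting order (stance-entry first)
PERIOD_REPORT_ORDER <- c("preswing", "initial_swing", "midswing",
                         "terminal_swing", "loading_response", "midstance",
                         "terminal_stance")

#' Canonical per-cycle gait period fractions
#'
#' The default generative split of the gait cycle, measured from toe off:
#' the swing phase (1 - `stance_fraction`) divided 13:14:13 into initial
#' swing, midswing and terminal swing, and the stance phase divided
#' 10:20:20:10 into loading response, midstance, terminal stance and
#' preswing. At the canonical 60/40 stance/swing split this places initial
#' contact at 40% of the cycle and the opposite toe off at 50%, i.e. the
#' two feet alternate exactly half a cycle apart.
#'
#' @param stance_fraction Fraction of the cycle spent in stance (default 0.60).
#' @return Named numeric vector of seven fractions summing to 1, in cycle
#'   order (initial_swing, midswing, terminal_swing, loading_response,
#'   midstance, terminal_stance, preswing).
#' @export
canonical_period_fractions <- function(stance_fraction = 0.60) {
  swing <- 1 - stance_fraction
  setNames(c(swing * c(13, 14, 13) / 40,
             stance_fraction * c(10, 20, 20, 10) / 60),
           PERIOD_NAMES)
}

#' Parameters for the synthetic gait-signal generator
#'
#' Bundles every knob of the simulator: pacing, gait composition, sensor
#' characteristics and noise. Defaults emulate a foot-worn accelerometer
#' study protocol: 120 Hz sampling, +/-16 g full scale, a 10 s standing
#' still lead used for time synchronisation, and the canonical 60/40
#' stance/swing split.
#'
#' @param cadence_bpm Cadence in steps per minute (two steps = one cycle).
#' @param stance_fraction Fraction of the cycle in stance, in (0, 1).
#' @param period_fractions Named vector of the seven period fractions in
#'   cycle order (see [canonical_period_fractions()]); must sum to 1 and its
#'   stance components must sum to `stance_fraction`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param duration_s Walking duration in seconds (after the lead).
#' @param lead_still_s Standing-still lead duration in seconds.
#' @param noise_sd_g Additive white-noise standard deviation in g per axis.
#' @param amplitude_g Peak signal scale in g (<= 16).
#' @param sway_factor Multiplier on the lateral (y) sway amplitude.
#' @param cadence_effect Optional named list of per-BPM linear slopes applied
#'   multiplicatively to event bump amplitudes relative to 100 BPM, e.g.
#'   `list(vic = 0.01)` makes the V-IC valley 1% deeper per BPM above 100.
#'   Recognised names: `to`, `fa`, `tv`, `vic`, `icp`.
#' @param vic_offset_frac Fraction of the cycle separating V-IC (and IC-P)
#'   from initial contact.
#' @param bump_sigma_frac Width (s.d.) of the Gaussian event bumps as a
#'   fraction of the cycle.
#' @param seed Optional RNG seed for reproducible traces.
#' @return A validated object of class `sim_params`.
#' @export
sim_params <- function(cadence_bpm = 110,
                       stance_fraction = 0.60,
                       period_fractions = canonical_period_fractions(stance_fraction),
                       sample_rate_hz = 120,
                       duration_s = 30,
                       lead_still_s = 10,
                       noise_sd_g = 0.05,
                       amplitude_g = 2,
                       sway_factor = 1,
                       cadence_effect = NULL,
                       vic_offset_frac = 0.04,
                       bump_sigma_frac = 0.030,
                       seed = NULL) {
  p <- structure(
    list(cadence_bpm = cadence_bpm, stance_fraction = stance_fraction,
         period_fractions = period_fractions,
         sample_rate_hz = sample_rate_hz, duration_s = duration_s,
         lead_still_s = lead_still_s, noise_sd_g = noise_sd_g,
         amplitude_g = amplitude_g, sway_factor = sway_factor,
         cadence_effect = cadence_effect,
         vic_offset_frac = vic_offset_frac,
         bump_sigma_frac = bump_sigma_frac, seed = seed),
    class = "sim_params"
  )
  validate_sim_params(p)
}

#' Validate simulator parameters
#'
#' @param p A `sim_params` object (or bare list with the same fields).
#' @return The validated `sim_params`, invisibly classed.
#' @export
validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.numeric(p$cadence_bpm) || p$cadence_bpm <= 0)
    stop("cadence_bpm must be positive", call. = FALSE)
  if (!is.numeric(p$sample_rate_hz) || p$sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive", call. = FALSE)
  if (p$stance_fraction <= 0 || p$stance_fraction >= 1)
    stop("stance_fraction must lie in (0, 1)", call. = FALSE)
  pf <- p$period_fractions
  if (length(pf) != 7L || !all(PERIOD_NAMES %in% names(pf)))
    stop("period_fractions must be the seven named gait periods", call. = FALSE)
  pf <- pf[PERIOD_NAMES]
  if (any(pf <= 0)) stop("period_fractions must be positive", call. = FALSE)
  if (abs(sum(pf) - 1) > 1e-9)
    stop("period_fractions must sum to 1", call. = FALSE)
  stance_sum <- sum(pf[c("loading_response", "midstance",
                         "terminal_stance", "preswing")])
  if (abs(stance_sum - p$stance_fraction) > 1e-9)
    stop("stance period fractions must sum to stance_fraction", call. = FALSE)
  if (p$amplitude_g <= 0 || p$amplitude_g > 16)
    stop("amplitude_g must lie in (0, 16]", call. = FALSE)
  if (p$noise_sd_g < 0) stop("noise_sd_g must be >= 0", call. = FALSE)
  if (p$lead_still_s < 0) stop("lead_still_s must be >= 0", call. = FALSE)
  if (p$duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (pf[["terminal_swing"]] <= p$vic_offset_frac)
    stop("terminal_swing fraction must exceed vic_offset_frac ",
         "(V-IC must fall after tibia vertical)", call. = FALSE)
  p$period_fractions <- pf
  p
}

# cumulative event fractions of the cycle measured from toe off
event_fractions <- function(p) {
  pf <- p$period_fractions
  fa <- pf[["initial_swing"]]
  tv <- fa + pf[["midswing"]]
  ic <- tv + pf[["terminal_swing"]]
  oto <- ic + pf[["loading_response"]]
  hr <- oto + pf[["midstance"]]
  oic <- hr + pf[["terminal_stance"]]
  c(FA = fa, TV = tv, IC = ic, OTO = oto, HR = hr, OIC = oic,
    `V-IC` = ic - p$vic_offset_frac, `IC-P` = ic + p$vic_offset_frac)
}

# nominal cycle length in samples for a two-step stride
nominal_cycle_samples <- function(cadence_bpm, sample_rate_hz) {
  as.integer(round(60 / cadence_bpm * 2 * sample_rate_hz))
}
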