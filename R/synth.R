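#' Generate a two-foot synthetic gait walk with ground truth
#'
#' Builds left- and right-foot longitudinal (x) acceleration signals from a
#' fixed per-cycle template of Gaussian bumps anchored at the gait event
#' positions: a toe-off peak at the cycle start, a small feet-adjacent peak
#' and tibia-vertical dip during swing, the deep V-IC valley immediately
#' before initial contact, and the IC-P peak immediately after it. The
#' valley and peak have equal magnitude, so the rising zero crossing falls
#' exactly at the planted initial-contact sample. The lateral (y) axis
#' carries a sway oscillation at step frequency, the vertical (z) axis only
#' noise. The two feet alternate: the opposite foot's toe off is planted at
#' the cumulative opposite-toe-off fraction of the cycle (exactly half a
#' cycle under the canonical period split). A standing-still lead of
#' `lead_still_s` seconds precedes the walk for time synchronisation.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `gait_walk` with elements `left` and `right`
#'   ([signal_trace]s), `truth` (class `gait_truth`: `$events` data frame
#'   with columns foot, cycle_index, event, sample_index and
#'   `$cycle_boundaries`, toe-off indices per foot), `cycle_samples`,
#'   `realized_cadence_bpm`, and the `params` used.
#' @examples
#' w <- generate_walk(sim_params(cadence_bpm = 120, duration_s = 10, seed = 1))
#' w$cycle_samples  # 120 samples per two-step stride at 120 BPM, 120 Hz
#' @export
generate_walk <- function(params) {
  params <- validate_sim_params(params)
  if (!is.null(params$seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(params$seed)
  }
  fs <- params$sample_rate_hz
  L <- nominal_cycle_samples(params$cadence_bpm, fs)
  lead_n <- as.integer(round(params$lead_still_s * fs))
  n_cycles <- as.integer(floor(params$duration_s * fs / L))
  if (n_cycles < 1L)
    stop("duration_s too short for one full gait cycle", call. = FALSE)

  ef <- event_fractions(params)
  offset <- as.integer(round(ef[["OTO"]] * L))  # right-to-left foot lag
  sigma <- params$bump_sigma_frac * L
  margin <- as.integer(ceiling(6 * sigma)) + 2L
  total_n <- lead_n + (n_cycles + 1L) * L + offset + margin

  amps <- .event_bump_amplitudes(params)

  right <- .synth_foot(total_n, lead_n, L, n_cycles, ef, amps, sigma,
                       params, foot = "right")
  left <- .synth_foot(total_n, lead_n + offset, L, n_cycles, ef, amps, sigma,
                      params, foot = "left")

  events <- rbind(right$events, left$events)
  truth <- structure(
    list(events = events,
         cycle_boundaries = list(left = left$boundaries,
                                 right = right$boundaries)),
    class = "gait_truth"
  )
  structure(
    list(left = left$trace, right = right$trace, truth = truth,
         cycle_samples = L,
         realized_cadence_bpm = 2 * 60 * fs / L,
         params = params),
    class = "gait_walk"
  )
}

# bump amplitudes in g at the five x-axis landmarks, after cadence effects
.event_bump_amplitudes <- function(params) {
  base <- c(TO = 0.55, FA = 0.25, TV = -0.30, `V-IC` = -1, `IC-P` = 1)
  keys <- c(TO = "to", FA = "fa", TV = "tv", `V-IC` = "vic", `IC-P` = "icp")
  ce <- params$cadence_effect
  mult <- vapply(keys, function(k) {
    s <- if (is.null(ce)) NULL else ce[[k]]
    if (is.null(s)) 1 else max(0.1, 1 + s * (params$cadence_bpm - 100))
  }, numeric(1))
  params$amplitude_g * base * mult
}

.synth_foot <- function(total_n, start0, L, n_cycles, ef, amps, sigma,
                        params, foot) {
  x <- numeric(total_n)
  add_bump <- function(x, center0, amp) {
    lo <- max(0L, as.integer(floor(center0 - 6 * sigma)))
    hi <- min(total_n - 1L, as.integer(ceiling(center0 + 6 * sigma)))
    if (lo > hi) return(x)
    i <- lo:hi
    x[i + 1L] <- x[i + 1L] + amp * exp(-((i - center0)^2) / (2 * sigma^2))
    x
  }
  boundaries <- start0 + (0:n_cycles) * L
  ev_list <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    s <- boundaries[k]
    pos <- c(TO = s,
             FA = s + round(ef[["FA"]] * L),
             TV = s + round(ef[["TV"]] * L),
             `V-IC` = s + round(ef[["V-IC"]] * L),
             IC = s + round(ef[["IC"]] * L),
             `IC-P` = s + round(ef[["IC-P"]] * L),
             HR = s + round(ef[["HR"]] * L))
    for (nm in names(amps)) x <- add_bump(x, pos[[nm]], amps[[nm]])
    ev_list[[k]] <- new_events(foot = rep(foot, length(pos)),
                               cycle_index = rep(k, length(pos)),
                               event = names(pos),
                               sample_index = as.integer(pos),
                               flag = rep("ok", length(pos)))
  }
  # closing toe-off bump so the last cycle is delimited on both sides
  x <- add_bump(x, boundaries[n_cycles + 1L], amps[["TO"]])

  fs <- params$sample_rate_hz
  y <- numeric(total_n)
  walk_i <- (start0:(total_n - 1L))
  step_hz <- params$cadence_bpm / 60
  y[walk_i + 1L] <- 0.25 * params$amplitude_g * params$sway_factor *
    sin(2 * pi * step_hz * walk_i / fs)
  if (params$noise_sd_g > 0) {
    x <- x + rnorm(total_n, 0, params$noise_sd_g)
    y <- y + rnorm(total_n, 0, params$noise_sd_g)
    z <- rnorm(total_n, 0, params$noise_sd_g)
    # the still lead is near-zero by contract: sensor-at-rest noise is
    # bounded, so clamp the lead segment to +/- 3 standard deviations
    lead_n <- as.integer(round(params$lead_still_s * fs))
    if (lead_n > 0) {
      lead <- seq_len(min(lead_n, total_n))
      lim <- 3 * params$noise_sd_g
      x[lead] <- pmin(lim, pmax(-lim, x[lead]))
      y[lead] <- pmin(lim, pmax(-lim, y[lead]))
      z[lead] <- pmin(lim, pmax(-lim, z[lead]))
    }
  } else {
    z <- numeric(total_n)
  }
  clip <- function(v) pmin(16, pmax(-16, v))
  trace <- signal_trace(clip(x), clip(y), clip(z), fs, foot)
  list(trace = trace, events = do.call(rbind, ev_list),
       boundaries = as.integer(boundaries))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a cohort of cadence-controlled walk records
#'
#' Produces one walk record per participant and walk type. Each participant
#' receives a reproducible substream of the RNG (derived from the cohort
#' seed and the participant index) from which their personal gait profile
#' is drawn: a natural cadence, a stance fraction, log-normal jitter on the
#' within-phase period composition, and an amplitude factor shared across
#' all of that participant's walks. Cue types (`C_*`) walk at the played
#' tempo; `Normal` and no-cue types walk at the participant's natural
#' cadence. Lateral sway amplitude scales with a per-type sway factor so
#' that cued fast walking sways most and cued slow walking least.
#'
#' @param n_participants Number of participants (>= 1).
#' @param types Walk types to simulate, a subset of [walk_types()].
#' @param base A [sim_params()] giving the shared defaults.
#' @param n_cycles Full gait cycles to simulate per walk (default 21).
#' @param natural_cadence_bpm Mean self-selected cadence (default 110 BPM).
#' @param participant_sd List of variation magnitudes: `fraction`
#'   (log-scale s.d. of within-phase period composition), `amplitude`
#'   (log-scale s.d. of the personal amplitude factor), `stance` (s.d. of
#'   the stance fraction), `cadence` (relative s.d. of cadence).
#' @param sway_factors Named per-type multipliers for lateral sway.
#' @param seed Cohort seed (defaults to `base$seed`, or 1).
#' @return A list of class `gait_cohort`; each element is the [generate_walk()]
#'   result augmented with `participant`, `walk_type`, `tempo_bpm` and
#'   `cadence_bpm` (realised cadence).
#' @export
make_cohort <- function(n_participants,
                        types = walk_types(),
                        base = sim_params(),
                        n_cycles = 21,
                        natural_cadence_bpm = 110,
                        participant_sd = list(fraction = 0.08,
                                              amplitude = 0.10,
                                              stance = 0.01,
                                              cadence = 0.02),
                        sway_factors = c(Normal = 0.8, NC_80 = 1.0,
                                         NC_100 = 1.0, NC_120 = 1.0,
                                         C_80 = 0.6, C_100 = 1.0,
                                         C_120 = 1.4),
                        seed = NULL) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  unknown <- setdiff(types, walk_types())
  if (length(unknown) > 0)
    stop("unknown walk type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(seed)) seed <- if (!is.null(base$seed)) base$seed else 1L
  seed <- as.integer(seed) %% 1000000L

  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)

  records <- list()
  for (p in seq_len(n_participants)) {
    set.seed(seed * 1000L + p)
    profile <- .participant_profile(base, natural_cadence_bpm, participant_sd)
    for (ti in seq_along(types)) {
      type <- types[ti]
      tempo <- .type_tempo(type)
      cadence <- if (startsWith(type, "C_")) {
        tempo * exp(rnorm(1, 0, participant_sd$cadence / 2))
      } else {
        profile$natural_cadence
      }
      params <- base
      params$cadence_bpm <- cadence
      params$stance_fraction <- profile$stance_fraction
      params$period_fractions <- profile$period_fractions
      params$amplitude_g <- min(16, base$amplitude_g * profile$amp_factor)
      params$sway_factor <- base$sway_factor *
        unname(sway_factors[[type]] %||% 1)
      cyc_s <- 120 / cadence
      params$duration_s <- n_cycles * cyc_s + 0.01
      params$seed <- seed * 1000L + p * 10L + ti
      params <- validate_sim_params(params)
      w <- generate_walk(params)
      w$participant <- p
      w$walk_type <- type
      w$tempo_bpm <- tempo
      w$cadence_bpm <- w$realized_cadence_bpm
      records[[length(records) + 1L]] <- w
    }
  }
  structure(records, class = "gait_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.type_tempo <- function(type) {
  if (type == "Normal") return(NA_real_)
  as.numeric(sub("^(NC|C)_", "", type))
}

# draw one participant's gait profile from the current RNG stream
.participant_profile <- function(base, natural_cadence_bpm, psd) {
  natural <- natural_cadence_bpm * exp(rnorm(1, 0, psd$cadence))
  stance <- min(0.68, max(0.52, base$stance_fraction + rnorm(1, 0, psd$stance)))
  pf <- .jitter_fractions(base$period_fractions, stance, psd$fraction,
                          base$vic_offset_frac + 2.5 * base$bump_sigma_frac)
  amp <- exp(rnorm(1, 0, psd$amplitude))
  list(natural_cadence = natural, stance_fraction = stance,
       period_fractions = pf, amp_factor = amp)
}

# jitter the within-phase composition while keeping the profile
# self-consistent with strict half-stride alternation of the feet:
# midstance + terminal stance = swing, so the opposite initial contact
# derived from the other foot matches the planted fractions exactly.
# min_terminal_swing keeps the tibia-vertical dip geometrically clear of
# the V-IC trough (healthy terminal swing stays above ~11% of the cycle).
.jitter_fractions <- function(pf, stance_fraction, sd_log,
                              min_terminal_swing) {
  swing <- 1 - stance_fraction
  for (try in 1:20) {
    sw <- pf[c("initial_swing", "midswing", "terminal_swing")] *
      exp(rnorm(3, 0, sd_log))
    sw <- sw / sum(sw) * swing
    mt <- pf[c("midstance", "terminal_stance")] * exp(rnorm(2, 0, sd_log))
    mt <- mt / sum(mt) * swing
    lp <- pf[c("loading_response", "preswing")] * exp(rnorm(2, 0, sd_log))
    lp <- lp / sum(lp) * (stance_fraction - swing)
    out <- c(sw, loading_response = unname(lp[1]), mt,
             preswing = unname(lp[2]))[PERIOD_NAMES]
    if (out[["terminal_swing"]] > min_terminal_swing) return(out)
  }
  pf  # fall back to the base profile if jitter kept degenerating
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d walk records, %d participant(s), types: %s\n",
              length(x), length(unique(vapply(x, `[[`, 1, "participant"))),
              paste(unique(vapply(x, `[[`, "", "walk_type")), collapse = ", ")))
  invisible(x)
}

#' Write ground-truth / annotation events to CSV
#'
#' @param truth A `gait_truth` object or a bare events data frame with
#'   columns foot, cycle_index, event, sample_index.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  ev <- if (inherits(truth, "gait_truth")) truth$events else truth
  write.csv(ev[c("foot", "cycle_index", "event", "sample_index")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ground-truth / annotation events from CSV
#'
#' @param path CSV with columns foot, cycle_index, event, sample_index.
#' @return An events data frame (columns foot, cycle_index, event,
#'   sample_index, flag).
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("foot", "cycle_index", "event", "sample_index")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  new_events(foot = df$foot, cycle_index = df$cycle_index,
             event = df$event, sample_index = df$sample_index,
             flag = rep("ok", nrow(df)))
}
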