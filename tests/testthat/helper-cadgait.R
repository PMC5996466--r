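# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# clean (noise-free) 100 BPM walk, 20 s
clean_walk <- function() {
  memo("clean_walk", generate_walk(
    sim_params(cadence_bpm = 100, duration_s = 20, noise_sd_g = 0, seed = 5)))
}

# 5%-of-amplitude noise walk (amplitude 2 g -> noise 0.1 g)
noisy_walk <- function() {
  memo("noisy_walk", generate_walk(
    sim_params(cadence_bpm = 100, duration_s = 20, noise_sd_g = 0.1, seed = 5)))
}

# filter, synchronise and segment one foot of a walk
segment_walk <- function(walk, foot, cadence_bpm = 100) {
  tr <- lowpass(walk[[foot]])
  tr <- trim_trace(tr, find_lead_origin(tr, min_still_s = 8))
  list(seg = segment_cycles(tr, cadence_bpm = cadence_bpm), trace = tr)
}

# smallest |detected - truth| for each detected index
truth_errors <- function(detected, truth_idx) {
  vapply(detected, function(i) min(abs(truth_idx - i)), numeric(1))
}

# null cohort (no cadence effect), three cue cadences
null_cohort <- function() {
  memo("null_cohort", make_cohort(
    3, c("C_80", "C_100", "C_120"),
    base = sim_params(noise_sd_g = 0.1), n_cycles = 12, seed = 11))
}

null_analysis <- function() memo("null_analysis", analyze_cohort(null_cohort()))

# cohort with a planted positive cadence -> V-IC depth relation
planted_cohort <- function() {
  memo("planted_cohort", make_cohort(
    5, c("C_80", "C_100", "C_120"),
    base = sim_params(noise_sd_g = 0.1, cadence_effect = list(vic = 0.01)),
    n_cycles = 10, seed = 3))
}

# self-consistent Normal-type generative profile preserving the reference
# left swing periods 13.00/12.89/16.33 exactly (stance subdivision rescaled
# so the profile is realizable under strict half-stride alternation)
normal_profile <- function() {
  swing <- c(13.00, 12.89, 16.33) / 100
  stance <- 1 - sum(swing)
  mt <- c(19.89, 19.11); mt <- mt / sum(mt) * sum(swing)
  lp <- c(9.27, 9.51); lp <- lp / sum(lp) * (stance - sum(swing))
  list(stance_fraction = stance,
       period_fractions = c(initial_swing = swing[1], midswing = swing[2],
                            terminal_swing = swing[3],
                            loading_response = lp[1], midstance = mt[1],
                            terminal_stance = mt[2], preswing = lp[2]))
}
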