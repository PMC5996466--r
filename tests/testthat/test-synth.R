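test_that("cycle length and ground-truth geometry follow the cadence arithmetic", {
  w <- generate_walk(sim_params(cadence_bpm = 120, duration_s = 10,
                                noise_sd_g = 0, seed = 1))
  # two steps per stride: 60/120 min * 2 * 120 Hz
  expect_identical(w$cycle_samples, 120L)

  tru <- w$truth$events
  for (foot in c("left", "right")) {
    ev <- tru[tru$foot == foot, ]
    bnd <- w$truth$cycle_boundaries[[foot]]
    for (k in unique(ev$cycle_index)) {
      e <- setNames(ev$sample_index[ev$cycle_index == k],
                    ev$event[ev$cycle_index == k])
      # IC-to-next-TO spans the stance phase: 60% of the cycle
      expect_equal(bnd[k + 1] - e[["IC"]], 0.60 * w$cycle_samples,
                   tolerance = 1 / w$cycle_samples)
      # within-cycle ordering of the planted landmarks
      expect_true(all(diff(e[c("TO", "FA", "TV", "V-IC", "IC",
                               "IC-P", "HR")]) > 0))
    }
    # stance + swing ground truth equals the cycle length exactly
    expect_true(all(diff(bnd) == w$cycle_samples))
  }
})

test_that("ground-truth event spacing matches the period fractions on noise-free signals", {
  pf <- canonical_period_fractions()
  p <- sim_params(cadence_bpm = 100, duration_s = 10, noise_sd_g = 0, seed = 2)
  w <- generate_walk(p)
  L <- w$cycle_samples
  ev <- w$truth$events
  e1 <- setNames(ev$sample_index[ev$foot == "right" & ev$cycle_index == 1],
                 ev$event[ev$foot == "right" & ev$cycle_index == 1])
  expect_equal(e1[["FA"]] - e1[["TO"]], round(pf[["initial_swing"]] * L))
  expect_equal(e1[["TV"]] - e1[["TO"]],
               round(sum(pf[c("initial_swing", "midswing")]) * L))
  expect_equal(e1[["IC"]] - e1[["TO"]], round(0.40 * L))
  expect_equal(e1[["HR"]] - e1[["TO"]], round(0.70 * L))
  # feet alternate by the opposite-toe-off fraction (half a cycle here)
  expect_equal(w$truth$cycle_boundaries$left[1] -
                 w$truth$cycle_boundaries$right[1], round(0.5 * L))
})

test_that("the waveform carries the landmark topology at the planted positions", {
  w <- clean_walk()
  x <- w$right$ax
  tru <- w$truth$events[w$truth$events$foot == "right", ]
  for (k in 2:5) {
    e <- setNames(tru$sample_index[tru$cycle_index == k],
                  tru$event[tru$cycle_index == k])
    i <- function(kind) e[[kind]] + 1L  # absolute 0-based -> R index
    span <- (e[["TO"]] + 1):(e[["TO"]] + w$cycle_samples)
    # V-IC is the global per-cycle minimum, immediately before IC
    expect_equal(which.min(x[span]) + e[["TO"]], e[["V-IC"]] + 1L)
    expect_lt(e[["IC"]] - e[["V-IC"]], 0.1 * w$cycle_samples)
    # TO and IC-P are local maxima
    for (kind in c("TO", "IC-P")) {
      expect_gte(x[i(kind)], x[i(kind) - 1])
      expect_gte(x[i(kind)], x[i(kind) + 1])
    }
    # rising zero crossing at IC
    expect_lt(x[i("IC") - 2], 0)
    expect_gte(x[i("IC") + 1], 0)
  }
})

test_that("the standing-still lead is quiet relative to the walk", {
  p <- sim_params(cadence_bpm = 100, duration_s = 15, noise_sd_g = 0.05,
                  seed = 9)
  w <- generate_walk(p)
  lead_n <- round(p$lead_still_s * p$sample_rate_hz)
  lead <- abs(w$right$ax[1:lead_n])
  expect_true(all(lead <= 3 * p$noise_sd_g + 1e-12))
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(w$right$ax[1:lead_n]), rms(w$right$ax[-(1:lead_n)]))
})

test_that("generation is deterministic under a fixed seed", {
  p <- sim_params(cadence_bpm = 100, duration_s = 8, seed = 77)
  w1 <- generate_walk(p)
  w2 <- generate_walk(p)
  expect_identical(w1$left$ax, w2$left$ax)
  expect_identical(w1$right$ay, w2$right$ay)
  expect_identical(w1$truth$events, w2$truth$events)
})

test_that("invalid simulator parameters are rejected", {
  expect_error(sim_params(cadence_bpm = 0), "cadence")
  expect_error(sim_params(sample_rate_hz = -120), "sample_rate")
  bad <- canonical_period_fractions()
  bad[["midswing"]] <- bad[["midswing"]] + 0.05
  expect_error(sim_params(period_fractions = bad), "sum to 1")
  expect_error(generate_walk(sim_params(duration_s = 0.5)), "full gait cycle")
})

test_that("make_cohort produces one record per participant and type", {
  co <- make_cohort(25, walk_types(),
                    base = sim_params(duration_s = 4, lead_still_s = 1),
                    n_cycles = 2, seed = 1)
  expect_length(co, 175L)
  expect_length(make_cohort(1, "Normal", n_cycles = 2,
                            base = sim_params(lead_still_s = 1), seed = 1), 1L)
  expect_error(make_cohort(2, c("Normal", "jogging")), "unknown walk type")
})

test_that("a planted cadence effect correlates with cadence by construction", {
  co <- planted_cohort()
  # oracle on the generative rule itself: V-IC signal value at the planted
  # ground-truth sample, no detection involved
  cad <- c(); depth <- c()
  for (rec in co) {
    tru <- rec$truth$events
    vic <- tru$sample_index[tru$foot == "right" & tru$event == "V-IC"]
    cad <- c(cad, rep(rec$cadence_bpm, length(vic)))
    depth <- c(depth, abs(rec$right$ax[vic + 1L]))
  }
  expect_gt(pearson(cad, depth), 0)
})
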