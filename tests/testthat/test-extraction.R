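test_that("FA and TV are located near ground truth on clean cycles", {
  w <- clean_walk()
  sw <- segment_walk(w, "right")
  tru <- w$truth$events[w$truth$events$foot == "right", ]
  for (k in seq_len(nrow(sw$seg$cycles))) {
    ev <- locate_characteristics(sw$seg$cycles[k, ], sw$trace)
    fa <- ev$sample_index[ev$event == "FA"]
    tv <- ev$sample_index[ev$event == "TV"]
    expect_lte(min(abs(tru$sample_index[tru$event == "FA"] - fa)), 3)
    expect_lte(min(abs(tru$sample_index[tru$event == "TV"] - tv)), 3)
    # fraction-of-cycle annotation is attached
    expect_true(all(ev$frac[ev$flag == "ok"] >= 0 &
                      ev$frac[ev$flag == "ok"] <= 1))
  }
})

test_that("opposite-foot events land at their alternation fraction; absence is flagged", {
  w <- clean_walk()
  right <- segment_walk(w, "right")
  left <- segment_walk(w, "left")
  cy <- right$seg$cycles[3, ]
  ev <- locate_characteristics(cy, right$trace, left$seg$events)
  oto <- ev[ev$event == "OTO", ]
  expect_identical(oto$flag, "ok")
  # feet are offset by half a cycle under the canonical split
  expect_lte(abs(oto$frac - 0.5), 0.02)

  # no opposite trace: OTO/OIC flagged missing, FA/TV still returned
  ev2 <- locate_characteristics(cy, right$trace, opposite_events = NULL)
  expect_identical(ev2$flag[ev2$event %in% c("OTO", "OIC")],
                   c("missing", "missing"))
  expect_identical(ev2$flag[ev2$event %in% c("FA", "TV")], c("ok", "ok"))
})

test_that("compute_periods maps canonical event positions to exact percentages", {
  # events placed exactly at the canonical fractions of a 1000-sample cycle
  cycle <- data.frame(foot = "right", cycle_index = 1L, start_to = 0L,
                      vic = 360L, ic = 400L, icp = 440L, end_to = 1000L,
                      cycle_len = 1000L, stance_pct = 60, swing_pct = 40)
  ev <- new_events(foot = rep("right", 5),
                   cycle_index = rep(1L, 5),
                   event = c("FA", "TV", "OTO", "HR", "OIC"),
                   sample_index = c(130L, 270L, 500L, 700L, 900L),
                   flag = rep("ok", 5))
  pd <- compute_periods(ev, cycle)
  expect_identical(pd$flag, "ok")
  expect_equal(pd$initial_swing, 13)
  expect_equal(pd$midswing, 14)
  expect_equal(pd$terminal_swing, 13)
  expect_equal(pd$loading_response, 10)
  expect_equal(pd$midstance, 20)
  expect_equal(pd$terminal_stance, 20)
  expect_equal(pd$preswing, 10)
  # conservation: the seven periods sum to 100, swing parts to swing_pct
  seven <- c(pd$initial_swing, pd$midswing, pd$terminal_swing,
             pd$loading_response, pd$midstance, pd$terminal_stance,
             pd$preswing)
  expect_equal(sum(seven), 100, tolerance = 1e-6)
  expect_equal(pd$initial_swing + pd$midswing + pd$terminal_swing,
               cycle$swing_pct, tolerance = 1e-6)

  # missing heel rise: stance is merged and flagged
  ev_nohr <- ev[ev$event != "HR", ]
  pd2 <- compute_periods(ev_nohr, cycle)
  expect_identical(pd2$flag, "hr-missing")
  expect_equal(pd2$mid_terminal_stance, 40)
  expect_true(is.na(pd2$midstance))
})

test_that("period breakdowns satisfy conservation on segmented noisy data", {
  an <- null_analysis()
  ok <- an$periods[an$periods$flag == "ok", ]
  seven <- ok$initial_swing + ok$midswing + ok$terminal_swing +
    ok$loading_response + ok$midstance + ok$terminal_stance + ok$preswing
  expect_equal(seven, rep(100, nrow(ok)), tolerance = 1e-6)
  # per-cycle swing periods reproduce the cycle's swing phase
  key <- paste(ok$participant, ok$walk_type, ok$foot, ok$cycle_index)
  ph <- an$phases
  pkey <- paste(ph$participant, ph$walk_type, ph$foot, ph$cycle_index)
  m <- match(key, pkey)
  expect_equal(ok$initial_swing + ok$midswing + ok$terminal_swing,
               ph$swing_pct[m], tolerance = 1e-6)
})

test_that("a cohort generated from the reference swing profile is recovered within 1 pp", {
  prof <- normal_profile()
  base <- sim_params(stance_fraction = prof$stance_fraction,
                     period_fractions = prof$period_fractions,
                     noise_sd_g = 0.1)
  co <- make_cohort(10, "Normal", base = base, n_cycles = 21,
                    participant_sd = list(fraction = 0, amplitude = 0.10,
                                          stance = 0, cadence = 0.02),
                    seed = 42)
  an <- analyze_cohort(co)
  pd <- an$periods[an$periods$flag == "ok" & an$periods$foot == "left", ]
  est <- colMeans(pd[c("initial_swing", "midswing", "terminal_swing")])
  expect_true(all(abs(est - c(13.00, 12.89, 16.33)) <= 1))
  # every planted period recovered within 1 pp of generative truth
  all_est <- colMeans(an$periods[an$periods$flag == "ok",
                                 names(prof$period_fractions)])
  expect_true(all(abs(all_est - prof$period_fractions * 100) <= 1))
})

test_that("phase and period tables aggregate symmetric inputs correctly", {
  # hand-built per-cycle phases: identical left and right feet
  ph <- expand.grid(participant = 1:3, walk_type = c("Normal", "C_120"),
                    foot = c("left", "right"), cycle_index = 1:4,
                    stringsAsFactors = FALSE)
  ph$swing_pct <- 40 + ph$participant  # participant effect, foot-symmetric
  ph$stance_pct <- 100 - ph$swing_pct
  tab <- aggregate_phase_table(ph)
  for (ty in c("Normal", "C_120")) {
    expect_equal(tab[[ty]][tab$metric == "swing_diff"], 0)
    expect_equal(tab[[ty]][tab$metric == "stance_diff"], 0)
    expect_equal(tab[[ty]][tab$metric == "left_stance"],
                 100 - tab[[ty]][tab$metric == "left_swing"])
  }
  # permutation invariance in participant order
  tab2 <- aggregate_phase_table(ph[rev(seq_len(nrow(ph))), ])
  expect_equal(tab, tab2)

  # uniform period breakdown aggregates to 100/7 everywhere
  pd <- expand.grid(participant = 1:2, walk_type = "Normal",
                    foot = c("left", "right"), cycle_index = 1:3,
                    stringsAsFactors = FALSE)
  for (nm in c("preswing", "initial_swing", "midswing", "terminal_swing",
               "loading_response", "midstance", "terminal_stance"))
    pd[[nm]] <- 100 / 7
  pd$mid_terminal_stance <- NA_real_
  pd$flag <- "ok"
  ptab <- aggregate_period_table(pd)
  expect_equal(ptab$Normal, rep(100 / 7, 14), tolerance = 1e-9)
})
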