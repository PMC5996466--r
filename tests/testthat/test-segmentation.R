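test_that("detect_vic finds one qualified valley per cycle and discards shallow dips", {
  w <- clean_walk()
  sw <- segment_walk(w, "right")
  tr <- sw$trace
  vics <- detect_vic(tr, cadence_bpm = 100)
  tru <- w$truth$events
  vic_true <- tru$sample_index[tru$foot == "right" & tru$event == "V-IC"]
  # one detection per ground-truth cycle, each within +/- 2 samples
  expect_equal(nrow(vics), length(vic_true))
  expect_true(all(truth_errors(vics$sample_index, vic_true) <= 2))
  expect_true(all(diff(vics$sample_index) > 0))

  # constant signal: no gait detected
  const <- signal_trace(rep(0.3, 500), numeric(500), NULL, 120, "left")
  expect_identical(nrow(detect_vic(const)), 0L)

  # a spurious shallow dip above the threshold line is discarded;
  # brute-force scan of all local minima against the line as oracle
  x <- tr$ax
  j <- .5 * (vic_true[3] + vic_true[4]) - tr$t0_offset  # mid-swing, flat region
  x[j + (-2:2)] <- x[j + (-2:2)] - c(0.05, 0.12, 0.2, 0.12, 0.05)
  tr2 <- signal_trace(x, tr$ay, tr$az, 120, "right", tr$t0_offset)
  det <- detect_vic(tr2, cadence_bpm = 100)
  thr <- mean(x) - 0.5 * (mean(x) - min(x))
  mins <- which(x[2:(length(x) - 1)] < x[1:(length(x) - 2)] &
                  x[2:(length(x) - 1)] <= x[3:length(x)]) + 1L
  oracle_below <- mins[x[mins] < thr] - 1L + tr2$t0_offset
  expect_true(all(det$sample_index %in% oracle_below))
  expect_false((j - 1L + tr2$t0_offset) %in% det$sample_index)
  expect_equal(nrow(det), nrow(vics))
})

test_that("find_ic locates the rising zero crossing between valley and peak", {
  w <- clean_walk()
  sw <- segment_walk(w, "right")
  tr <- sw$trace
  tru <- w$truth$events[w$truth$events$foot == "right", ]
  vic_true <- tru$sample_index[tru$event == "V-IC"]
  ic_true <- tru$sample_index[tru$event == "IC"]
  icp_true <- tru$sample_index[tru$event == "IC-P"]
  for (k in c(2, 8, 14)) {
    r <- find_ic(tr, vic_true[k], cycle_len = 144)
    expect_identical(r$flag, "ok")
    expect_lte(abs(r$ic - ic_true[k]), 2)
    expect_lte(abs(r$icp - icp_true[k]), 2)
  }
  # signal shifted entirely above zero: no crossing exists
  up <- signal_trace(tr$ax - min(tr$ax) + 0.5, tr$ay, tr$az, 120, "right",
                     tr$t0_offset)
  vu <- detect_vic(up, cadence_bpm = 100)
  r <- find_ic(up, vu$sample_index[2], cycle_len = 144)
  expect_identical(r$flag, "IC-undetected")
})

test_that("find_to applies the 60% +/- 5% window with earlier-peak tie-break", {
  w <- clean_walk()
  sw <- segment_walk(w, "right")
  tr <- sw$trace
  tru <- w$truth$events[w$truth$events$foot == "right", ]
  ic_true <- tru$sample_index[tru$event == "IC"]
  to_true <- c(tru$sample_index[tru$event == "TO"],
               w$truth$cycle_boundaries$right)
  for (k in c(2, 8, 14)) {
    r <- find_to(tr, ic_true[k], cycle_len = 144)
    expect_identical(r$flag, "ok")
    expect_lte(min(abs(to_true - r$to)), 2)
  }
  # flat window -> undetected even after widening
  flat <- signal_trace(rep(0.2, 600), numeric(600), NULL, 120, "left")
  expect_identical(find_to(flat, 100, 144)$flag, "TO-undetected")

  # two equal peaks in the window -> the earlier one wins
  x <- numeric(600)
  x[401] <- 1; x[403] <- 0.5; x[420] <- 1  # equal maxima at 400 and 419 (0-based)
  x[419] <- 0; x[421] <- 0
  two <- signal_trace(x, numeric(600), NULL, 120, "left")
  r <- find_to(two, 100, cycle_len = 520, expected_frac = 0.60,
               tol_frac = 0.05)
  expect_identical(r$to, 400L)
})

test_that("segment_cycles recovers count, length and phase split on clean walks", {
  w <- clean_walk()  # 20 s walking at 100 BPM, 120 Hz
  sw <- segment_walk(w, "right")
  s <- sw$seg
  n_truth <- length(w$truth$cycle_boundaries$right) - 1L
  expect_identical(s$qc$n_cycles, n_truth - 1L)  # first cycle lacks a detected start TO
  expect_equal(mean(s$cycles$cycle_len), 144, tolerance = 1 / 144)
  # canonical 60/40 split recovered within 1 percentage point
  expect_true(all(abs(s$cycles$stance_pct - 60) <= 1))
  expect_equal(s$cycles$stance_pct + s$cycles$swing_pct,
               rep(100, nrow(s$cycles)), tolerance = 1e-9)
  # cycles tile without overlap
  expect_true(all(diff(as.vector(rbind(s$cycles$start_to,
                                       s$cycles$end_to))) >= 0))

  w2 <- generate_walk(sim_params(cadence_bpm = 120, duration_s = 15,
                                 noise_sd_g = 0, seed = 8))
  s2 <- segment_walk(w2, "right", cadence_bpm = 120)$seg
  expect_equal(mean(s2$cycles$cycle_len), 120, tolerance = 1 / 120)
})

test_that("segmentation is deterministic and translation-covariant", {
  w <- noisy_walk()
  sw <- segment_walk(w, "right")
  s1 <- segment_cycles(sw$trace, cadence_bpm = 100)
  s2 <- segment_cycles(sw$trace, cadence_bpm = 100)
  expect_identical(s1$cycles, s2$cycles)

  # physically prepending k still samples shifts every event index by k
  k <- 60L
  tr <- sw$trace
  shifted <- signal_trace(c(numeric(k), tr$ax), c(numeric(k), tr$ay),
                          c(numeric(k), tr$az), 120, "right")
  s3 <- segment_cycles(shifted, cadence_bpm = 100)
  expect_identical(s3$cycles$ic, s1$cycles$ic - tr$t0_offset + k)
  expect_identical(s3$cycles$end_to, s1$cycles$end_to - tr$t0_offset + k)
})

test_that("noisy walks are recovered almost completely with small timing errors", {
  w <- noisy_walk()  # noise 5% of the 2 g amplitude
  sw <- segment_walk(w, "right")
  s <- sw$seg
  n_truth <- length(w$truth$cycle_boundaries$right) - 1L
  expect_gte(s$qc$n_cycles / (n_truth - 1L), 0.95)
  tru <- w$truth$events[w$truth$events$foot == "right", ]
  ic_err <- truth_errors(s$cycles$ic, tru$sample_index[tru$event == "IC"])
  to_err <- truth_errors(s$cycles$end_to,
                         c(tru$sample_index[tru$event == "TO"],
                           w$truth$cycle_boundaries$right))
  expect_true(all(ic_err <= 3))
  expect_true(all(to_err <= 3))
})

test_that("degenerate inputs give empty segmentations", {
  const <- signal_trace(rep(0.1, 1000), numeric(1000), NULL, 120, "left")
  s <- segment_cycles(const)
  expect_identical(s$qc$n_cycles, 0L)
  expect_identical(nrow(s$cycles), 0L)
})
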