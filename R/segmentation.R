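#' Detect qualified V-IC valleys on the longitudinal axis
#'
#' The V-IC valley (the deep trough immediately before initial contact) is
#' the anchor landmark of each gait cycle. A threshold line is drawn at
#' `T = mean - threshold_factor * (mean - min)` of the x-axis signal; local
#' minima above the line (shallow dips such as the tibia-vertical feature)
#' are discarded, and qualifying minima closer together than
#' `min_separation` samples are merged keeping the deeper one.
#'
#' @param trace A low-pass filtered [signal_trace].
#' @param threshold_factor Position of the threshold line between the mean
#'   and the global minimum, in (0, 1]; default 0.5.
#' @param cadence_bpm Optional nominal cadence used to derive
#'   `min_separation` as half a nominal cycle; when unknown, half the
#'   median inter-valley gap is used instead.
#' @param min_separation Optional explicit merge distance in samples.
#' @return Events data frame (one `V-IC` row per valley, absolute 0-based
#'   `sample_index`, increasing). Zero rows when no qualified valley exists
#'   ("no gait detected").
#' @export
detect_vic <- function(trace, threshold_factor = 0.5, cadence_bpm = NULL,
                       min_separation = NULL) {
  if (threshold_factor <= 0 || threshold_factor > 1)
    stop("threshold_factor must lie in (0, 1]", call. = FALSE)
  x <- trace$ax
  n <- length(x)
  if (n < 3) return(new_events())
  thr <- mean(x) - threshold_factor * (mean(x) - min(x))
  i <- 2:(n - 1)
  is_min <- x[i] < x[i - 1] & x[i] <= x[i + 1]
  cand <- i[is_min & x[i] < thr]
  if (length(cand) == 0) return(new_events())

  if (is.null(min_separation)) {
    min_separation <- if (!is.null(cadence_bpm)) {
      0.5 * nominal_cycle_samples(cadence_bpm, trace$sample_rate_hz)
    } else if (length(cand) >= 2) {
      0.5 * median(diff(cand))
    } else 0
  }

  keep <- integer(0)
  cur <- cand[1]
  for (c2 in cand[-1]) {
    if (c2 - cur < min_separation) {
      if (x[c2] < x[cur]) cur <- c2  # keep the deeper valley
    } else {
      keep <- c(keep, cur)
      cur <- c2
    }
  }
  keep <- c(keep, cur)
  new_events(foot = rep(trace$foot, length(keep)),
             cycle_index = rep(NA_integer_, length(keep)),
             event = rep("V-IC", length(keep)),
             sample_index = .abs(trace, keep),
             flag = rep("ok", length(keep)))
}

#' Find initial contact (zero crossing) and the IC-P peak after a valley
#'
#' Initial contact is the rising zero crossing of the x-axis signal between
#' the V-IC valley and the IC-P peak. IC-P is taken as the first local
#' maximum after the valley whose height is a set fraction of the valley
#' depth; IC is the first sample with non-negative value between the two
#' (no sub-sample interpolation).
#'
#' @param trace A filtered [signal_trace].
#' @param vic_index Absolute 0-based index of a detected V-IC valley.
#' @param cycle_len Search horizon in samples (nominally one cycle).
#' @param prominence_factor Minimum IC-P height as a fraction of the valley
#'   depth (default 0.5).
#' @return List with `ic`, `icp` (absolute indices, `NA` on failure) and
#'   `flag` (`"ok"`, `"IC-undetected"` or `"ICP-undetected"`).
#' @export
find_ic <- function(trace, vic_index, cycle_len = NULL,
                    prominence_factor = 0.5) {
  x <- trace$ax
  n <- length(x)
  v <- .loc(trace, vic_index)
  if (v < 1 || v > n) stop("vic_index outside trace", call. = FALSE)
  if (is.null(cycle_len)) cycle_len <- round(2 * trace$sample_rate_hz)
  hi <- min(n - 1L, v + as.integer(round(cycle_len)))
  depth <- abs(x[v])

  icp <- NA_integer_
  if (hi >= v + 2) {
    for (j in (v + 1):(hi - 1)) {
      if (x[j] > x[j - 1] && x[j] >= x[j + 1] &&
          x[j] >= prominence_factor * depth) {
        icp <- j
        break
      }
    }
  }
  if (is.na(icp))
    return(list(ic = NA_integer_, icp = NA_integer_, flag = "ICP-undetected"))

  ic <- NA_integer_
  span <- (v + 1):(icp - 1)
  if (length(span) > 0 && icp - 1 >= v + 1) {
    nn <- span[x[span] >= 0]
    if (length(nn) > 0 && x[v] < 0) ic <- nn[1]
  }
  if (is.na(ic))
    return(list(ic = NA_integer_, icp = .abs(trace, icp),
                flag = "IC-undetected"))
  list(ic = .abs(trace, ic), icp = .abs(trace, icp), flag = "ok")
}

#' Find toe off from initial contact via the 60% +/- 5% rule
#'
#' The interval from initial contact to the next toe off spans the stance
#' phase, normally 60% of the cycle; toe off is therefore sought as the
#' highest local maximum of the x-axis signal within the window
#' `ic + (expected_frac +/- tol_frac) * cycle_len`. Ties are broken by the
#' earlier sample. If the window holds no local maximum it is widened once
#' to twice the tolerance before the cycle is declared undetected.
#'
#' @param trace A filtered [signal_trace].
#' @param ic_index Absolute 0-based index of the detected initial contact.
#' @param cycle_len Estimated cycle length in samples.
#' @param expected_frac Expected IC-to-TO fraction of the cycle (default 0.60).
#' @param tol_frac Search half-width as a fraction of the cycle (default 0.05).
#' @return List with `to` (absolute index or `NA`) and `flag`.
#' @export
find_to <- function(trace, ic_index, cycle_len, expected_frac = 0.60,
                    tol_frac = 0.05) {
  x <- trace$ax
  n <- length(x)
  ic <- .loc(trace, ic_index)
  search <- function(tol) {
    lo <- max(2L, ic + as.integer(round((expected_frac - tol) * cycle_len)))
    hi <- min(n - 1L, ic + as.integer(round((expected_frac + tol) * cycle_len)))
    if (lo > hi) return(NA_integer_)
    j <- lo:hi
    is_max <- x[j] > x[j - 1] & x[j] >= x[j + 1]
    peaks <- j[is_max]
    if (length(peaks) == 0) return(NA_integer_)
    peaks[which.max(x[peaks])]  # which.max takes the earlier of equal peaks
  }
  to <- search(tol_frac)
  if (is.na(to)) to <- search(2 * tol_frac)
  if (is.na(to)) return(list(to = NA_integer_, flag = "TO-undetected"))
  list(to = .abs(trace, to), flag = "ok")
}

#' Segment a trace into toe-off-to-toe-off gait cycles
#'
#' Runs the full segmentation chain on a filtered trace: V-IC valley
#' detection, initial-contact zero-crossing detection, and toe-off peak
#' detection, then delimits cycles between consecutive detected toe offs.
#' The stance percentage of a cycle is `(end TO - IC) / cycle length * 100`
#' and swing its complement. Partial first/last cycles, and any cycle whose
#' IC or TO could not be detected, are dropped and counted in the QC report.
#'
#' @param trace A low-pass filtered [signal_trace].
#' @param cadence_bpm Optional nominal cadence (improves valley merging).
#' @param threshold_factor Valley threshold factor, see [detect_vic()].
#' @param expected_frac,tol_frac Toe-off search window, see [find_to()].
#' @param prominence_factor IC-P prominence, see [find_ic()].
#' @return Object of class `gait_segmentation`: list with `cycles` (data
#'   frame: foot, cycle_index, start_to, vic, ic, icp, end_to, cycle_len,
#'   stance_pct, swing_pct), `events` (long events data frame), `qc`
#'   (detection counts) and trace metadata.
#' @export
segment_cycles <- function(trace, cadence_bpm = NULL, threshold_factor = 0.5,
                           expected_frac = 0.60, tol_frac = 0.05,
                           prominence_factor = 0.5) {
  empty <- structure(
    list(cycles = .empty_cycles(), events = new_events(),
         qc = list(n_vic = 0L, n_candidate = 0L, n_cycles = 0L,
                   n_ic_undetected = 0L, n_to_undetected = 0L,
                   n_order_violation = 0L),
         foot = trace$foot, sample_rate_hz = trace$sample_rate_hz,
         cadence_bpm = cadence_bpm),
    class = "gait_segmentation"
  )
  vics <- detect_vic(trace, threshold_factor, cadence_bpm)
  nv <- nrow(vics)
  if (nv < 2) return(empty)
  v_idx <- vics$sample_index
  cycle_len <- median(diff(v_idx))

  ic <- icp <- to <- rep(NA_integer_, nv)
  n_ic_un <- n_to_un <- 0L
  for (j in seq_len(nv)) {
    r <- find_ic(trace, v_idx[j], cycle_len, prominence_factor)
    if (r$flag != "ok") { n_ic_un <- n_ic_un + 1L; next }
    ic[j] <- r$ic; icp[j] <- r$icp
    r2 <- find_to(trace, r$ic, cycle_len, expected_frac, tol_frac)
    if (r2$flag != "ok") { n_to_un <- n_to_un + 1L; next }
    to[j] <- r2$to
  }

  rows <- list()
  n_order <- 0L
  ci <- 0L
  for (j in 2:nv) {
    if (is.na(to[j - 1]) || is.na(ic[j]) || is.na(to[j])) next
    ok <- to[j - 1] < v_idx[j] && v_idx[j] < ic[j] && ic[j] < to[j]
    if (!ok) { n_order <- n_order + 1L; next }
    ci <- ci + 1L
    len <- to[j] - to[j - 1]
    rows[[ci]] <- data.frame(
      foot = trace$foot, cycle_index = ci,
      start_to = to[j - 1], vic = v_idx[j], ic = ic[j], icp = icp[j],
      end_to = to[j], cycle_len = len,
      stance_pct = (to[j] - ic[j]) / len * 100,
      swing_pct = (ic[j] - to[j - 1]) / len * 100,
      stringsAsFactors = FALSE
    )
  }
  if (ci == 0L) {
    empty$qc$n_vic <- nv
    empty$qc$n_candidate <- nv - 1L
    empty$qc$n_ic_undetected <- n_ic_un
    empty$qc$n_to_undetected <- n_to_un
    empty$qc$n_order_violation <- n_order
    return(empty)
  }
  cycles <- do.call(rbind, rows)
  events <- do.call(rbind, lapply(seq_len(nrow(cycles)), function(k) {
    cy <- cycles[k, ]
    new_events(foot = rep(cy$foot, 4L), cycle_index = rep(cy$cycle_index, 4L),
               event = c("TO", "V-IC", "IC", "IC-P"),
               sample_index = c(cy$start_to, cy$vic, cy$ic, cy$icp),
               flag = rep("ok", 4L))
  }))
  structure(
    list(cycles = cycles, events = events,
         qc = list(n_vic = nv, n_candidate = nv - 1L, n_cycles = ci,
                   n_ic_undetected = n_ic_un, n_to_undetected = n_to_un,
                   n_order_violation = n_order),
         foot = trace$foot, sample_rate_hz = trace$sample_rate_hz,
         cadence_bpm = cadence_bpm),
    class = "gait_segmentation"
  )
}

.empty_cycles <- function() {
  data.frame(foot = character(), cycle_index = integer(),
             start_to = integer(), vic = integer(), ic = integer(),
             icp = integer(), end_to = integer(), cycle_len = integer(),
             stance_pct = numeric(), swing_pct = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.gait_segmentation <- function(x, ...) {
  cat(sprintf(
    "<gait_segmentation> %s foot: %d cycles from %d valleys (IC lost %d, TO lost %d)\n",
    x$foot, x$qc$n_cycles, x$qc$n_vic, x$qc$n_ic_undetected,
    x$qc$n_to_undetected))
  if (x$qc$n_cycles > 0)
    cat(sprintf("  mean cycle %.1f samples, mean stance %.2f%% / swing %.2f%%\n",
                mean(x$cycles$cycle_len), mean(x$cycles$stance_pct),
                mean(x$cycles$swing_pct)))
  invisible(x)
}

#' Per-cycle stance/swing phase percentages
#'
#' @param seg A `gait_segmentation`.
#' @return Data frame foot, cycle_index, cycle_len, stance_pct, swing_pct.
#' @export
compute_phases <- function(seg) {
  stopifnot(inherits(seg, "gait_segmentation"))
  seg$cycles[c("foot", "cycle_index", "cycle_len", "stance_pct", "swing_pct")]
}

#' Write segmentation events to CSV
#' @param seg A `gait_segmentation` (or events data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(seg, path) {
  ev <- if (inherits(seg, "gait_segmentation")) seg$events else seg
  write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
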