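#' Locate the remaining gait characteristics of one cycle
#'
#' Uses the neighbouring relationship of gait events along the cycle:
#' feet-adjacent (FA) and tibia-vertical (TV) are sought as the most
#' prominent local extremum of the x-axis signal in windows centred at
#' their canonical fraction of the cycle measured from toe off (FA at the
#' end of initial swing, TV at the end of midswing); opposite toe off (OTO)
#' and opposite initial contact (OIC) are taken from the opposite foot's
#' detected events falling inside the cycle; heel rise (HR) carries no
#' reliable signal feature and is taken from annotation events only. The
#' opposite foot's heel rise (OHR) is also picked up when annotations for
#' the opposite foot are supplied.
#'
#' @param cycle One row of `gait_segmentation$cycles`.
#' @param trace The filtered [signal_trace] the cycle was segmented from.
#' @param opposite_events Optional events data frame of the opposite foot
#'   (detected `TO` and `IC` rows; annotated `HR` rows enable OHR).
#' @param hr_events Optional annotation events data frame holding `HR` rows
#'   for this foot.
#' @param fa_center,tv_center Window centres as fractions of the cycle;
#'   default to the canonical period fractions (0.13 and 0.27 under the
#'   60/40 split).
#' @param half_width Window half-width as a fraction of the cycle.
#' @return Events data frame with rows FA, TV, OTO, OIC, HR, OHR; events
#'   that could not be located carry `flag = "missing"` and `NA` index.
#'   A `frac` column gives each event's fraction-of-cycle position.
#' @export
locate_characteristics <- function(cycle, trace, opposite_events = NULL,
                                   hr_events = NULL,
                                   fa_center = NULL, tv_center = NULL,
                                   half_width = 0.05) {
  canon <- canonical_period_fractions()
  if (is.null(fa_center)) fa_center <- unname(canon[["initial_swing"]])
  if (is.null(tv_center)) tv_center <- fa_center + unname(canon[["midswing"]])
  L <- cycle$cycle_len
  s <- cycle$start_to

  fa <- .window_extremum(trace, s + (fa_center - half_width) * L,
                         s + (fa_center + half_width) * L)
  # the TV window is clipped on the right (0.6 * half_width) so its chord
  # endpoint stays clear of the steep descent into the V-IC trough
  tv <- .window_extremum(trace, s + (tv_center - half_width) * L,
                         s + (tv_center + 0.6 * half_width) * L)

  pick_opposite <- function(ev, kind) {
    if (is.null(ev) || nrow(ev) == 0) return(NA_integer_)
    hit <- ev$sample_index[ev$event == kind &
                             ev$sample_index >= s &
                             ev$sample_index < cycle$end_to]
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  oto <- pick_opposite(opposite_events, "TO")
  oic <- pick_opposite(opposite_events, "IC")
  ohr <- pick_opposite(opposite_events, "HR")
  hr <- pick_opposite(hr_events, "HR")

  idx <- c(FA = fa, TV = tv, OTO = oto, OIC = oic, HR = hr, OHR = ohr)
  out <- new_events(foot = rep(cycle$foot, length(idx)),
                    cycle_index = rep(cycle$cycle_index, length(idx)),
                    event = names(idx),
                    sample_index = unname(idx),
                    flag = ifelse(is.na(idx), "missing", "ok"))
  out$frac <- (out$sample_index - s) / L
  out
}

# most prominent feature in [lo, hi]: the interior sample deviating most
# from the window chord. Equals the most prominent local extremum for a
# clear peak/dip, and still resolves a shoulder riding a monotone slope
# (e.g. the tibia-vertical dip on the descent into the V-IC trough).
# A flat window carries no feature and yields NA.
.window_extremum <- function(trace, lo, hi) {
  x <- trace$ax
  lo <- max(1L, .loc(trace, round(lo)))
  hi <- min(length(x), .loc(trace, round(hi)))
  if (hi - lo < 2L) return(NA_integer_)
  j <- lo:hi
  chord <- x[lo] + (x[hi] - x[lo]) * (j - lo) / (hi - lo)
  dev <- x[j] - chord
  if (all(abs(dev) < 1e-9)) return(NA_integer_)
  .abs(trace, j[which.max(abs(dev))])
}

#' Seven-period breakdown of one gait cycle
#'
#' Maps the cycle's event positions to the seven gait periods, each as a
#' percentage of the cycle: initial swing (TO to FA), midswing (FA to TV),
#' terminal swing (TV to IC), loading response (IC to OTO), midstance (OTO
#' to HR), terminal stance (HR to OIC) and preswing (OIC to the next TO).
#' When heel rise is unavailable (it requires annotation), midstance and
#' terminal stance are merged into `mid_terminal_stance` and flagged.
#'
#' @param cycle_events Events data frame for the cycle (from
#'   [locate_characteristics()]).
#' @param cycle The matching row of `gait_segmentation$cycles`.
#' @param merge_missing_hr Merge midstance/terminal stance when HR is
#'   missing (default `TRUE`) instead of returning all-`NA` stance columns.
#' @return One-row data frame: foot, cycle_index, the seven period
#'   percentages, `mid_terminal_stance`, and `flag`.
#' @export
compute_periods <- function(cycle_events, cycle, merge_missing_hr = TRUE) {
  L <- cycle$cycle_len
  get <- function(kind) {
    i <- cycle_events$sample_index[cycle_events$event == kind]
    if (length(i) == 0 || is.na(i[1])) NA_integer_ else i[1]
  }
  b <- c(TO = cycle$start_to, FA = get("FA"), TV = get("TV"), IC = cycle$ic,
         OTO = get("OTO"), HR = get("HR"), OIC = get("OIC"),
         TO2 = cycle$end_to)
  out <- data.frame(foot = cycle$foot, cycle_index = cycle$cycle_index,
                    initial_swing = NA_real_, midswing = NA_real_,
                    terminal_swing = NA_real_, loading_response = NA_real_,
                    midstance = NA_real_, terminal_stance = NA_real_,
                    preswing = NA_real_, mid_terminal_stance = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  pct <- function(a, z) (b[[z]] - b[[a]]) / L * 100

  known <- b[!is.na(b)]
  if (any(diff(known) < 0)) {
    out$flag <- "order-violation"
    return(out)
  }
  if (anyNA(b[c("FA", "TV", "OTO", "OIC")])) {
    out$flag <- "missing-events"
    return(out)
  }
  out$initial_swing <- pct("TO", "FA")
  out$midswing <- pct("FA", "TV")
  out$terminal_swing <- pct("TV", "IC")
  out$loading_response <- pct("IC", "OTO")
  out$preswing <- pct("OIC", "TO2")
  if (is.na(b[["HR"]])) {
    if (merge_missing_hr) {
      out$mid_terminal_stance <- pct("OTO", "OIC")
      out$flag <- "hr-missing"
    } else out$flag <- "missing-events"
  } else {
    out$midstance <- pct("OTO", "HR")
    out$terminal_stance <- pct("HR", "OIC")
    out$mid_terminal_stance <- pct("OTO", "OIC")
  }
  out
}

#' Aggregate per-cycle phases into a walk-type phase table
#'
#' Mean stance/swing percentage per foot per walk type: cycles are averaged
#' within each participant first, then participants averaged with equal
#' weight. Difference rows are left minus right.
#'
#' @param phases Data frame with columns participant, walk_type, foot,
#'   stance_pct, swing_pct (one row per cycle).
#' @return A `gait_table` data frame: `metric` column (left_swing,
#'   right_swing, swing_diff, left_stance, right_stance, stance_diff) and
#'   one column per walk type present.
#' @export
aggregate_phase_table <- function(phases) {
  stopifnot(all(c("participant", "walk_type", "foot",
                  "stance_pct", "swing_pct") %in% names(phases)))
  types <- intersect(walk_types(), unique(phases$walk_type))
  if (length(types) == 0) stop("no walk types present", call. = FALSE)
  cell <- function(type, foot, what) {
    d <- phases[phases$walk_type == type & phases$foot == foot, ]
    if (nrow(d) == 0) return(NA_real_)
    per_part <- tapply(d[[what]], d$participant, mean)
    mean(per_part)
  }
  tab <- data.frame(metric = c("left_swing", "right_swing", "swing_diff",
                               "left_stance", "right_stance", "stance_diff"),
                    stringsAsFactors = FALSE)
  for (ty in types) {
    ls <- cell(ty, "left", "swing_pct"); rs <- cell(ty, "right", "swing_pct")
    lt <- cell(ty, "left", "stance_pct"); rt <- cell(ty, "right", "stance_pct")
    if (all(is.na(c(ls, rs, lt, rt)))) {
      warning("walk type ", ty, " has no segmented cycles; omitted")
      next
    }
    tab[[ty]] <- c(ls, rs, ls - rs, lt, rt, lt - rt)
  }
  structure(tab, class = c("gait_table", "data.frame"))
}

#' Aggregate per-cycle period breakdowns into a walk-type period table
#'
#' Mean of each of the seven gait-period percentages per foot per walk
#' type (cycles averaged within participant, then across participants).
#' Cycles flagged by [compute_periods()] are excluded. When every retained
#' cycle lacks heel rise, the merged `mid_terminal_stance` row is reported
#' in place of midstance/terminal stance.
#'
#' @param periods Data frame of [compute_periods()] rows plus participant
#'   and walk_type columns.
#' @return A `gait_table` data frame with a `metric` column
#'   (`left_preswing` ... `right_terminal_stance`) and one column per type.
#' @export
aggregate_period_table <- function(periods) {
  ok <- periods[periods$flag %in% c("ok", "hr-missing"), ]
  if (nrow(ok) == 0) stop("no valid period breakdowns", call. = FALSE)
  types <- intersect(walk_types(), unique(ok$walk_type))
  have_hr <- any(ok$flag == "ok")
  pnames <- if (have_hr) PERIOD_REPORT_ORDER
            else setdiff(PERIOD_REPORT_ORDER,
                         c("midstance", "terminal_stance"))
  if (!have_hr) pnames <- c(pnames, "mid_terminal_stance")
  metrics <- c(paste0("left_", pnames), paste0("right_", pnames))
  tab <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (ty in types) {
    col <- numeric(0)
    for (foot in c("left", "right")) {
      d <- ok[ok$walk_type == ty & ok$foot == foot, ]
      for (pn in pnames) {
        col <- c(col, if (nrow(d) == 0) NA_real_ else {
          per_part <- tapply(d[[pn]], d$participant, mean, na.rm = TRUE)
          mean(per_part, na.rm = TRUE)
        })
      }
    }
    if (all(is.na(col))) {
      warning("walk type ", ty, " has no valid periods; omitted")
      next
    }
    tab[[ty]] <- col
  }
  structure(tab, class = c("gait_table", "data.frame"))
}

#' @export
print.gait_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write a phase/period table to CSV (2 decimal places)
#' @param tab A `gait_table`.
#' @param path Output file path.
#' @param digits Decimal places (default 2, conventional for gait tables).
#' @return `path`, invisibly.
#' @export
write_gait_table <- function(tab, path, digits = 2) {
  y <- as.data.frame(tab)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) format(round(v, digits), nsmall = digits))
  write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
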