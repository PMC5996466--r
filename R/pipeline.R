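#' Configuration for the end-to-end gait pipeline
#'
#' @param mode `"simulate"` (generate a cohort) or `"ingest"` (read trace
#'   and annotation CSVs from `input_dir`).
#' @param n_participants,types,n_cycles Cohort size in simulate mode.
#' @param sim A [sim_params()] used as the simulation base.
#' @param input_dir Directory of `<participant>_<walktype>_<foot>.csv`
#'   traces (and optional `<participant>_<walktype>_truth.csv` annotation
#'   files) in ingest mode.
#' @param out_dir Output directory for the report bundle.
#' @param cutoff_hz,filter_order Low-pass settings, see [lowpass()].
#' @param threshold_factor,expected_frac,tol_frac Segmentation settings.
#' @param corr_mode `"amplitude"` or `"timing"`, see [correlation_table()].
#' @param seed Seed controlling every source of randomness.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            n_participants = 2, types = walk_types(),
                            n_cycles = 21, sim = sim_params(),
                            input_dir = NULL, out_dir = tempfile("gait_run_"),
                            cutoff_hz = 20, filter_order = 4,
                            threshold_factor = 0.5, expected_frac = 0.60,
                            tol_frac = 0.05, corr_mode = "amplitude",
                            seed = 1, log_level = "info") {
  mode <- match.arg(mode)
  if (mode == "ingest") {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("ingest mode requires an existing input_dir", call. = FALSE)
  }
  structure(
    list(mode = mode, n_participants = n_participants, types = types,
         n_cycles = n_cycles, sim = sim, input_dir = input_dir,
         out_dir = out_dir, cutoff_hz = cutoff_hz,
         filter_order = filter_order, threshold_factor = threshold_factor,
         expected_frac = expected_frac, tol_frac = tol_frac,
         corr_mode = corr_mode, seed = seed, log_level = log_level),
    class = "pipeline_config"
  )
}

#' Build a pipeline configuration from a YAML file
#'
#' Flat keys mirroring the [pipeline_config()] arguments; keys under `sim:`
#' mirror [sim_params()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim_args <- cfg$sim %||% list()
  cfg$sim <- do.call(sim_params, sim_args)
  do.call(pipeline_config, cfg)
}

#' Analyse a cohort of walk records
#'
#' Runs preprocessing, segmentation, extraction and analysis on an
#' in-memory cohort: low-pass filtering, leading-clearance origin
#' detection and trimming, per-foot cycle segmentation, characteristic
#' location (heel rise from the record's annotation events), period
#' computation, and the aggregate tables and statistics.
#'
#' @param cohort A `gait_cohort` (from [make_cohort()] or ingestion); each
#'   record needs `left`/`right` traces, `participant`, `walk_type`,
#'   `cadence_bpm` and optionally `truth` (annotation events).
#' @param cutoff_hz,filter_order,threshold_factor,expected_frac,tol_frac
#'   Stage settings, see [lowpass()], [detect_vic()], [find_to()].
#' @param corr_mode Correlation value mode, see [correlation_table()].
#' @param sync Detect and trim the still lead before segmentation
#'   (default `TRUE`; disabled automatically when a trace has no lead).
#' @return List of class `gait_analysis`: per-cycle data frames `phases`,
#'   `periods`, `characteristics`, the aggregates `phase_table`,
#'   `period_table`, `correlation`, `sway`, a `qc` summary and
#'   `segmentations`.
#' @export
analyze_cohort <- function(cohort, cutoff_hz = 20, filter_order = 4,
                           threshold_factor = 0.5, expected_frac = 0.60,
                           tol_frac = 0.05, corr_mode = "amplitude",
                           sync = TRUE) {
  phases <- list(); periods <- list(); chars <- list()
  segs <- list(); sways <- list()
  qc <- list(n_records = length(cohort), n_vic = 0L, n_cycles = 0L,
             n_ic_undetected = 0L, n_to_undetected = 0L,
             n_order_violation = 0L, n_period_dropped = 0L)

  for (rec in cohort) {
    ann <- if (!is.null(rec$truth)) rec$truth$events else new_events()
    feet <- list(left = rec$left, right = rec$right)
    filtered <- list(); seg <- list()
    for (f in names(feet)) {
      tr <- lowpass(feet[[f]], cutoff_hz, filter_order)
      if (sync) {
        origin <- tryCatch(
          find_lead_origin(tr, min_still_s = min(8, rec$params$lead_still_s
                                                 %||% 8)),
          error = function(e) NA_integer_)
        if (!is.na(origin)) tr <- trim_trace(tr, origin)
      }
      filtered[[f]] <- tr
      s <- segment_cycles(tr, cadence_bpm = rec$cadence_bpm,
                          threshold_factor = threshold_factor,
                          expected_frac = expected_frac,
                          tol_frac = tol_frac)
      seg[[f]] <- s
      for (k in c("n_vic", "n_cycles", "n_ic_undetected",
                  "n_to_undetected", "n_order_violation"))
        qc[[k]] <- qc[[k]] + s$qc[[k]]
      sways[[length(sways) + 1L]] <- data.frame(
        walk_type = rec$walk_type, participant = rec$participant,
        ay_g = tr$ay, stringsAsFactors = FALSE)
    }
    for (f in names(feet)) {
      s <- seg[[f]]
      if (s$qc$n_cycles == 0) next
      opp <- c("left" = "right", "right" = "left")[[f]]
      opp_events <- rbind(seg[[opp]]$events,
                          ann[ann$foot == opp & ann$event == "HR", ])
      hr_events <- ann[ann$foot == f & ann$event == "HR", ]
      ph <- compute_phases(s)
      ph$participant <- rec$participant
      ph$walk_type <- rec$walk_type
      ph$cadence_bpm <- rec$cadence_bpm %||% NA_real_
      phases[[length(phases) + 1L]] <- ph
      for (k in seq_len(nrow(s$cycles))) {
        cy <- s$cycles[k, ]
        ev <- locate_characteristics(cy, filtered[[f]], opp_events, hr_events)
        pd <- compute_periods(ev, cy)
        pd$participant <- rec$participant
        pd$walk_type <- rec$walk_type
        if (!pd$flag %in% c("ok", "hr-missing"))
          qc$n_period_dropped <- qc$n_period_dropped + 1L
        periods[[length(periods) + 1L]] <- pd
        seg_ev <- s$events[s$events$cycle_index == cy$cycle_index, ]
        seg_ev$frac <- (seg_ev$sample_index - cy$start_to) / cy$cycle_len
        allev <- rbind(seg_ev, ev)
        allev$amplitude_g <- vapply(allev$sample_index, function(si) {
          if (is.na(si)) return(NA_real_)
          i1 <- .loc(filtered[[f]], si)
          if (i1 < 1 || i1 > n_samples(filtered[[f]])) NA_real_
          else filtered[[f]]$ax[i1]
        }, numeric(1))
        allev$participant <- rec$participant
        allev$walk_type <- rec$walk_type
        allev$cadence_bpm <- rec$cadence_bpm %||% NA_real_
        chars[[length(chars) + 1L]] <- allev
      }
    }
    segs[[length(segs) + 1L]] <- list(participant = rec$participant,
                                      walk_type = rec$walk_type, seg = seg)
  }

  phases <- do.call(rbind, phases)
  periods <- do.call(rbind, periods)
  chars <- do.call(rbind, chars)
  if (is.null(phases) || nrow(phases) == 0)
    stop("no gait cycles recovered from the cohort", call. = FALSE)

  structure(
    list(phases = phases, periods = periods, characteristics = chars,
         phase_table = aggregate_phase_table(phases),
         period_table = aggregate_period_table(periods),
         correlation = correlation_table(chars, mode = corr_mode),
         sway = sway_summary(do.call(rbind, sways)),
         qc = qc, segmentations = segs),
    class = "gait_analysis"
  )
}

#' Run the full five-stage gait pipeline
#'
#' Acquisition (simulate or ingest), preprocessing, segmentation,
#' extraction and analysis, writing a report bundle to
#' `config$out_dir`: `events.csv`, `phase_table.csv`, `period_table.csv`,
#' `correlation.csv`, `sway_summary.csv`, `validation.csv`, `qc.json` and
#' `manifest.json` (config, seed, versions). A failing stage leaves a
#' `FAILED` marker naming the stage and re-raises the error.
#'
#' @param config A [pipeline_config()].
#' @return The `gait_analysis` result, invisibly, with `out_dir` attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (config$log_level != "quiet")
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  stage <- "acquisition"
  res <- tryCatch({
    log("stage 1/5 acquisition (%s mode)", config$mode)
    cohort <- if (config$mode == "simulate") {
      base <- config$sim
      base$seed <- config$seed
      make_cohort(config$n_participants, config$types, base,
                  n_cycles = config$n_cycles, seed = config$seed)
    } else {
      ingest_cohort(config$input_dir)
    }
    stage <- "analysis"
    log("stages 2-5: preprocess, segment, extract, analyse (%d records)",
        length(cohort))
    an <- analyze_cohort(cohort, config$cutoff_hz, config$filter_order,
                         config$threshold_factor, config$expected_frac,
                         config$tol_frac, config$corr_mode)
    stage <- "reporting"
    write_events(an$characteristics[c("foot", "cycle_index", "event",
                                      "sample_index", "flag")],
                 file.path(config$out_dir, "events.csv"))
    write_gait_table(an$phase_table,
                     file.path(config$out_dir, "phase_table.csv"))
    write_gait_table(an$period_table,
                     file.path(config$out_dir, "period_table.csv"))
    write_correlation(an$correlation,
                      file.path(config$out_dir, "correlation.csv"))
    write.csv(as.data.frame(an$sway),
              file.path(config$out_dir, "sway_summary.csv"),
              row.names = FALSE, quote = FALSE)
    val <- validate_tables(an$period_table, an$phase_table)
    write.csv(as.data.frame(val),
              file.path(config$out_dir, "validation.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(an$qc, file.path(config$out_dir, "qc.json"),
                         auto_unbox = TRUE)
    manifest <- list(
      seed = config$seed, mode = config$mode,
      config = unclass(config)[setdiff(names(config), "sim")],
      sim = unclass(config$sim),
      package_version = as.character(utils::packageVersion("cadgait")),
      r_version = R.version.string)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
    log("bundle written to %s (%d cycles)", config$out_dir, an$qc$n_cycles)
    an
  }, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  attr(res, "out_dir") <- config$out_dir
  invisible(res)
}

#' Ingest a cohort from trace CSV files
#'
#' Reads every `<participant>_<walktype>_<foot>.csv` pair in a directory
#' (as written by [write_cohort()]) plus optional
#' `<participant>_<walktype>_truth.csv` annotation files.
#'
#' @param input_dir Directory of trace CSVs.
#' @return A `gait_cohort`.
#' @export
ingest_cohort <- function(input_dir) {
  files <- list.files(input_dir, pattern = "_(left|right)\\.csv$")
  if (length(files) == 0) stop("no trace files found in ", input_dir,
                               call. = FALSE)
  keys <- unique(sub("_(left|right)\\.csv$", "", files))
  records <- lapply(keys, function(k) {
    m <- regmatches(k, regexec("^(.+?)_(.+)$", k))[[1]]
    if (length(m) != 3) stop("unrecognised file name pattern: ", k,
                             call. = FALSE)
    participant <- m[2]; type <- m[3]
    if (!type %in% walk_types())
      stop("unknown walk type in file name: ", type, call. = FALSE)
    left <- read_trace(file.path(input_dir, paste0(k, "_left.csv")))
    right <- read_trace(file.path(input_dir, paste0(k, "_right.csv")))
    tf <- file.path(input_dir, paste0(k, "_truth.csv"))
    truth <- if (file.exists(tf))
      structure(list(events = read_truth(tf),
                     cycle_boundaries = NULL), class = "gait_truth")
    else NULL
    tempo <- .type_tempo(type)
    structure(list(left = left, right = right, truth = truth,
                   participant = participant, walk_type = type,
                   tempo_bpm = tempo,
                   cadence_bpm = if (is.na(tempo)) NULL else tempo,
                   params = list(lead_still_s = 10,
                                 sample_rate_hz = left$sample_rate_hz)),
              class = "gait_walk")
  })
  structure(records, class = "gait_cohort")
}

#' Write a cohort's traces and annotations to a directory
#'
#' One `<participant>_<walktype>_<foot>.csv` per foot and one
#' `<participant>_<walktype>_truth.csv` annotation file per record.
#'
#' @param cohort A `gait_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort) {
    k <- sprintf("%s_%s", rec$participant, rec$walk_type)
    write_trace(rec$left, file.path(dir, paste0(k, "_left.csv")))
    write_trace(rec$right, file.path(dir, paste0(k, "_right.csv")))
    if (!is.null(rec$truth))
      write_truth(rec$truth, file.path(dir, paste0(k, "_truth.csv")))
  }
  invisible(dir)
}

#' Consistency checks between a period table and a phase table
#'
#' Report-only arithmetic validation: swing + stance must equal 100 for
#' each foot and walk type; the three swing periods must sum to the swing
#' phase and the four stance periods to the stance phase; difference rows
#' must equal left minus right. Violations are listed with their magnitude
#' in percentage points.
#'
#' @param period_table,phase_table `gait_table`s (e.g. from
#'   [aggregate_period_table()] / [aggregate_phase_table()] or
#'   [reference_gait_tables()]).
#' @param tol Tolerance in percentage points (default 0.005, i.e. printed
#'   2-decimal precision).
#' @return Data frame of class `gait_validation` with columns check,
#'   walk_type, metric, expected, actual, magnitude (0 rows when
#'   consistent).
#' @export
validate_tables <- function(period_table, phase_table, tol = 0.005) {
  types <- intersect(names(phase_table), names(period_table))
  types <- setdiff(types, "metric")
  g <- function(tab, metric, ty) {
    v <- tab[[ty]][tab$metric == metric]
    if (length(v) == 0) NA_real_ else v
  }
  out <- list()
  add <- function(check, ty, metric, expected, actual) {
    if (is.na(expected) || is.na(actual)) return()
    if (abs(expected - actual) > tol)
      out[[length(out) + 1L]] <<- data.frame(
        check = check, walk_type = ty, metric = metric,
        expected = expected, actual = actual,
        magnitude = abs(expected - actual), stringsAsFactors = FALSE)
  }
  swing_parts <- c("initial_swing", "midswing", "terminal_swing")
  stance_parts <- c("preswing", "loading_response", "midstance",
                    "terminal_stance")
  for (ty in types) {
    for (foot in c("left", "right")) {
      sw <- g(phase_table, paste0(foot, "_swing"), ty)
      st <- g(phase_table, paste0(foot, "_stance"), ty)
      add("phase-complement", ty, paste0(foot, "_swing+stance"), 100, sw + st)
      psum <- sum(vapply(paste0(foot, "_", swing_parts),
                         function(mm) g(period_table, mm, ty), numeric(1)))
      add("swing-period-sum", ty, paste0(foot, "_swing"), sw, psum)
      ssum <- sum(vapply(paste0(foot, "_", stance_parts),
                         function(mm) g(period_table, mm, ty), numeric(1)))
      add("stance-period-sum", ty, paste0(foot, "_stance"), st, ssum)
    }
    add("difference-row", ty, "swing_diff",
        g(phase_table, "left_swing", ty) - g(phase_table, "right_swing", ty),
        g(phase_table, "swing_diff", ty))
    add("difference-row", ty, "stance_diff",
        g(phase_table, "left_stance", ty) - g(phase_table, "right_stance", ty),
        g(phase_table, "stance_diff", ty))
  }
  res <- if (length(out) == 0) {
    data.frame(check = character(), walk_type = character(),
               metric = character(), expected = numeric(),
               actual = numeric(), magnitude = numeric(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  structure(res, class = c("gait_validation", "data.frame"))
}

#' Reference phase and period tables for the seven walk types
#'
#' Published-style reference tables (mean stance/swing phase percentages
#' and seven-period percentages per foot for the seven walk types of the
#' cadence-controlled protocol), shipped as plain CSV. Useful as worked
#' input for [validate_tables()] and as generative targets for simulation.
#'
#' @return List with `phase` and `period` `gait_table`s.
#' @export
reference_gait_tables <- function() {
  read_tab <- function(f) {
    df <- read.csv(system.file("extdata", f, package = "cadgait",
                               mustWork = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
    structure(df, class = c("gait_table", "data.frame"))
  }
  list(phase = read_tab("gait_phase_reference.csv"),
       period = read_tab("gait_period_reference.csv"))
}
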