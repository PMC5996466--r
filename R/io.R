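#' Write a trace to CSV
#'
#' Comma-separated, '.' decimal, mandatory header `time_s,ax_g,ay_g,az_g`.
#' Time stamps encode the absolute origin: `time_s = sample_index / fs`
#' including any trimmed offset, so a round trip preserves `t0_offset`.
#'
#' @param trace A [signal_trace].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  n <- n_samples(trace)
  idx <- (seq_len(n) - 1L) + trace$t0_offset
  df <- data.frame(time_s = idx / trace$sample_rate_hz,
                   ax_g = trace$ax, ay_g = trace$ay, az_g = trace$az)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace from CSV
#'
#' Reads the dialect written by [write_trace()]. Malformed rows (missing or
#' non-numeric cells) are reported with their file line numbers; samples
#' outside the +/-16 g sensor range are rejected.
#'
#' @param path CSV file with header `time_s,ax_g,ay_g,az_g`.
#' @param foot `"left"` or `"right"`; if `NULL`, inferred from a
#'   `_left`/`_right` component of the file name.
#' @param sample_rate_hz Override for the sampling rate; by default it is
#'   inferred from the median spacing of `time_s`.
#' @return A validated [signal_trace].
#' @export
read_trace <- function(path, foot = NULL, sample_rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.csv(path, colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("no samples in ", path, call. = FALSE)
  )
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("no samples in ", path, call. = FALSE)

  num <- lapply(df[need], function(col) suppressWarnings(as.numeric(col)))
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad))
    stop("non-numeric cell(s) at line(s) ",
         paste(utils::head(which(bad) + 1L, 5L), collapse = ", "),
         " of ", path, call. = FALSE)
  over <- abs(num$ax_g) > 16 | abs(num$ay_g) > 16 | abs(num$az_g) > 16
  if (any(over))
    stop("|acceleration| > 16 g at line(s) ",
         paste(utils::head(which(over) + 1L, 5L), collapse = ", "),
         " of ", path, call. = FALSE)

  if (is.null(foot)) {
    base <- tolower(basename(path))
    foot <- if (grepl("(^|[_-])left([_.-]|$)", base)) "left"
            else if (grepl("(^|[_-])right([_.-]|$)", base)) "right"
            else stop("cannot infer foot from file name; pass foot=",
                      call. = FALSE)
  }
  fs <- sample_rate_hz
  if (is.null(fs)) {
    if (nrow(df) >= 2) {
      dt <- median(diff(num$time_s))
      if (!is.finite(dt) || dt <= 0)
        stop("cannot infer sample rate from time_s", call. = FALSE)
      fs <- round(1 / dt, 6)
    } else fs <- 120
  }
  t0 <- as.integer(round(num$time_s[1] * fs))
  signal_trace(num$ax_g, num$ay_g, num$az_g, fs, foot, t0_offset = t0)
}

#' FFT magnitude spectrum of one axis
#'
#' One-sided discrete Fourier magnitude spectrum with bin spacing
#' `sample_rate_hz / N`, frequencies from 0 to the Nyquist rate.
#'
#' @param trace A [signal_trace] with at least 2 samples.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Object of class `gait_spectrum` with fields `freqs_hz`,
#'   `magnitude` (unnormalised `|DFT|`), `n_samples`, `sample_rate_hz`.
#' @export
trace_spectrum <- function(trace, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  v <- axis_series(trace, axis)
  n <- length(v)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  X <- fft(v)
  k <- floor(n / 2) + 1L
  structure(
    list(freqs_hz = (0:(k - 1L)) * trace$sample_rate_hz / n,
         magnitude = Mod(X)[1:k],
         n_samples = n, sample_rate_hz = trace$sample_rate_hz, axis = axis),
    class = "gait_spectrum"
  )
}

#' Time-domain energy implied by a spectrum (Parseval)
#'
#' @param spec A `gait_spectrum`.
#' @return `sum(x^2)` of the underlying series, reconstructed from the
#'   one-sided magnitudes.
#' @export
spectrum_energy <- function(spec) {
  n <- spec$n_samples
  m2 <- spec$magnitude^2
  k <- length(m2)
  double_bins <- if (n %% 2 == 0) seq_len(k)[-c(1, k)] else seq_len(k)[-1]
  (m2[1] + 2 * sum(m2[double_bins]) +
      if (n %% 2 == 0) m2[k] else 0) / n
}

#' Write a spectrum to CSV (`freq_hz,magnitude`)
#' @param spec A `gait_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  write.csv(data.frame(freq_hz = spec$freqs_hz, magnitude = spec$magnitude),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero phase, so event timing is not delayed) to all three axes. The
#' trace is extended by odd reflection at both ends before filtering so
#' start-of-trace transients do not corrupt the still lead.
#'
#' @param trace A [signal_trace].
#' @param cutoff_hz Cut-off frequency in Hz, in (0, Nyquist); default 20,
#'   which keeps the gait band and removes sensor noise.
#' @param order Filter order (default 4).
#' @return A filtered [signal_trace] of identical length.
#' @export
lowpass <- function(trace, cutoff_hz = 20, order = 4) {
  fs <- trace$sample_rate_hz
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, sample_rate_hz/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  f <- function(x) .filtfilt_padded(bf, x)
  signal_trace(f(trace$ax), f(trace$ay), f(trace$az), fs, trace$foot,
               t0_offset = trace$t0_offset)
}

# forward-backward filtering with odd (point-reflected) edge padding
.filtfilt_padded <- function(bf, x) {
  n <- length(x)
  p <- min(n - 1L, 60L)
  if (p < 1L) return(x)
  head_pad <- 2 * x[1] - x[(p + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(p + 1):(p + n)]
}

#' Locate the synchronised time origin from the standing-still lead
#'
#' Recordings begin with the wearer standing still for a known minimum
#' duration; the first sample at which movement energy appears is the
#' synchronised origin shared by the sensor signal and any annotation
#' stream. Movement energy is measured as a trailing moving RMS of the x
#' and y axes (mean per-axis power over a short window). Because a trailing
#' window reacts up to one window early, the still run is required to last
#' `min_still_s` minus one window.
#'
#' @param trace A [signal_trace] (filter first for noisy recordings).
#' @param min_still_s Minimum still-lead duration in seconds (default 10).
#' @param still_threshold_g RMS threshold in g below which the wearer is
#'   considered still (default 0.1).
#' @param window_s Moving-RMS window in seconds (default 0.25).
#' @return Absolute 0-based sample index of the origin.
#' @export
find_lead_origin <- function(trace, min_still_s = 10,
                             still_threshold_g = 0.1, window_s = 0.25) {
  fs <- trace$sample_rate_hz
  n <- n_samples(trace)
  if (n <= min_still_s * fs)
    stop("trace shorter than min_still_s", call. = FALSE)
  w <- max(1L, as.integer(round(window_s * fs)))
  p <- (trace$ax^2 + trace$ay^2) / 2
  cp <- cumsum(p)
  lo <- pmax(0, seq_len(n) - w)
  rms <- sqrt((cp - c(0, cp)[lo + 1L]) / (seq_len(n) - lo))
  crossing <- which(rms >= still_threshold_g)
  if (length(crossing) == 0)
    stop("no walking segment after clearance", call. = FALSE)
  i0 <- crossing[1]
  required <- max(1L, as.integer(round(min_still_s * fs)) - w)
  if (i0 - 1L < required)
    stop("no leading clearance found", call. = FALSE)
  .abs(trace, i0)
}
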