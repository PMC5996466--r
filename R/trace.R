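#' Triaxial accelerometer trace for one foot
#'
#' Container for a uniformly sampled triaxial acceleration series in g.
#' Axes follow the foot-mounted sensor convention: x = longitudinal (the
#' axis carrying the gait landmarks), y = lateral (body sway), z = vertical.
#' The sensor full scale is +/-16 g; values outside it are rejected.
#'
#' @param ax,ay,az Numeric acceleration series in g, equal length >= 1.
#'   `az` may be omitted (filled with zeros).
#' @param sample_rate_hz Sampling rate in Hz (default 120).
#' @param foot `"left"` or `"right"`.
#' @param t0_offset Number of samples trimmed from the original recording
#'   origin (0 for a full recording). Event indices reported by the package
#'   are always expressed relative to the original origin.
#' @return An object of class `signal_trace`.
#' @seealso [read_trace()], [lowpass()], [trim_trace()]
#' @export
signal_trace <- function(ax, ay, az = NULL, sample_rate_hz = 120,
                         foot = c("left", "right"), t0_offset = 0L) {
  foot <- match.arg(foot)
  ax <- as.numeric(ax)
  ay <- as.numeric(ay)
  if (is.null(az)) az <- numeric(length(ax))
  az <- as.numeric(az)
  n <- length(ax)
  if (n < 1L) stop("no samples", call. = FALSE)
  if (length(ay) != n || length(az) != n)
    stop("axis series must have identical length", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive", call. = FALSE)
  bad <- !is.finite(ax) | !is.finite(ay) | !is.finite(az)
  if (any(bad))
    stop("non-finite acceleration at sample(s) ",
         paste(utils::head(which(bad) - 1L, 5L), collapse = ", "),
         call. = FALSE)
  over <- abs(ax) > 16 | abs(ay) > 16 | abs(az) > 16
  if (any(over))
    stop("|acceleration| exceeds the 16 g sensor full scale at sample(s) ",
         paste(utils::head(which(over) - 1L, 5L), collapse = ", "),
         call. = FALSE)
  structure(
    list(ax = ax, ay = ay, az = az,
         sample_rate_hz = as.numeric(sample_rate_hz),
         foot = foot, t0_offset = as.integer(t0_offset)),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s foot, %d samples @ %g Hz (%.2f s), offset %d\n",
              x$foot, length(x$ax), x$sample_rate_hz,
              length(x$ax) / x$sample_rate_hz, x$t0_offset))
  invisible(x)
}

#' Number of samples in a trace
#' @param trace A [signal_trace].
#' @return Integer sample count.
#' @export
n_samples <- function(trace) length(trace$ax)

#' Extract one axis of a trace
#' @param trace A [signal_trace].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Numeric vector.
#' @export
axis_series <- function(trace, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  switch(axis, x = trace$ax, y = trace$ay, z = trace$az)
}

#' Trim the start of a trace at a synchronised origin
#'
#' Drops all samples before `origin` (an absolute 0-based index) and records
#' the trim in `t0_offset` so downstream event indices remain absolute.
#'
#' @param trace A [signal_trace].
#' @param origin Absolute 0-based sample index of the new first sample.
#' @return A [signal_trace] starting at `origin`.
#' @export
trim_trace <- function(trace, origin) {
  origin <- as.integer(origin)
  if (origin < trace$t0_offset)
    stop("origin precedes the trace start", call. = FALSE)
  i1 <- origin - trace$t0_offset + 1L
  if (i1 > n_samples(trace)) stop("origin beyond trace end", call. = FALSE)
  keep <- i1:n_samples(trace)
  signal_trace(trace$ax[keep], trace$ay[keep], trace$az[keep],
               trace$sample_rate_hz, trace$foot, t0_offset = origin)
}

# absolute 0-based index -> 1-based position inside the trace vectors
.loc <- function(trace, abs_idx) as.integer(abs_idx) - trace$t0_offset + 1L

# 1-based position inside the trace vectors -> absolute 0-based index
.abs <- function(trace, i1) as.integer(i1) - 1L + trace$t0_offset

# canonical events data frame used across the package
new_events <- function(foot = character(), cycle_index = integer(),
                       event = character(), sample_index = integer(),
                       flag = character()) {
  data.frame(foot = foot, cycle_index = as.integer(cycle_index),
             event = event, sample_index = as.integer(sample_index),
             flag = flag, stringsAsFactors = FALSE)
}
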