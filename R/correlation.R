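#' Pearson correlation coefficient from raw sums
#'
#' Computes `r = (n*Sxy - Sx*Sy) / sqrt((n*Sxx - Sx^2) * (n*Syy - Sy^2))`
#' directly from the raw sums of the two series. Pairs with a missing value
#' are dropped. A constant series leaves the coefficient undefined and
#' yields `NA` (never 0).
#'
#' @param x,y Numeric series of equal length (>= 2 complete pairs).
#' @return The coefficient in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  dx <- n * sum(x^2) - sum(x)^2
  dy <- n * sum(y^2) - sum(y)^2
  if (dx <= 0 || dy <= 0) return(NA_real_)
  r <- (n * sum(x * y) - sum(x) * sum(y)) / sqrt(dx * dy)
  min(1, max(-1, r))
}

#' Correlation-degree band of a coefficient
#'
#' Bands the magnitude of a Pearson coefficient: `|r| < 0.4` low,
#' `0.4 <= |r| < 0.7` moderate, `0.7 <= |r| <= 1` high. A boundary value
#' falls in the upper band. `|r| = 1` is reported as
#' `"totally correlated"`.
#'
#' @param r Numeric vector of coefficients with `|r| <= 1` (`NA` allowed).
#' @return Character vector of `"low"`, `"moderate"`, `"high"`,
#'   `"totally correlated"` or `NA`.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE))
    stop("|r| must not exceed 1", call. = FALSE)
  a <- abs(r)
  out <- rep(NA_character_, length(r))
  out[!is.na(a) & a < 0.4] <- "low"
  out[!is.na(a) & a >= 0.4 & a < 0.7] <- "moderate"
  out[!is.na(a) & a >= 0.7] <- "high"
  out[!is.na(a) & a == 1] <- "totally correlated"
  out
}

#' Cadence/characteristic correlation matrix
#'
#' Builds the pairwise Pearson correlation matrix between cadence and the
#' per-cycle gait characteristics, pooling cycles across participants and
#' walks. In `"amplitude"` mode a characteristic's value is the magnitude
#' of the filtered x-axis acceleration at the event sample (motion
#' strength); in `"timing"` mode it is the event's fraction-of-cycle
#' position. A variable missing in more than half of the cycles is kept but
#' flagged.
#'
#' @param chars Data frame of per-cycle characteristic values with columns
#'   participant, walk_type, cadence_bpm, foot, cycle_index, event, and
#'   `amplitude_g` / `frac`.
#' @param variables Characteristic names to include (default the six
#'   signal-bearing events: TO, FA, OHR, TV, V-IC, IC-P).
#' @param mode `"amplitude"` (default) or `"timing"`.
#' @return Object of class `correlation_matrix`: `labels`, `r` (symmetric,
#'   unit diagonal), `n` (complete pairs per entry), `band`
#'   (classification of each entry), `flagged` (variables sparse in > 50%
#'   of cycles), `mode`.
#' @export
correlation_table <- function(chars,
                              variables = c("TO", "FA", "OHR", "TV",
                                            "V-IC", "IC-P"),
                              mode = c("amplitude", "timing")) {
  mode <- match.arg(mode)
  valcol <- if (mode == "amplitude") "amplitude_g" else "frac"
  stopifnot(all(c("participant", "walk_type", "cadence_bpm", "foot",
                  "cycle_index", "event", valcol) %in% names(chars)))
  key <- interaction(chars$participant, chars$walk_type, chars$foot,
                     chars$cycle_index, drop = TRUE)
  cells <- split(chars, key)
  wide <- do.call(rbind, lapply(cells, function(d) {
    row <- setNames(rep(NA_real_, length(variables) + 1L),
                    c("cadence", variables))
    row["cadence"] <- d$cadence_bpm[1]
    fl <- if ("flag" %in% names(d)) d$flag else rep("ok", nrow(d))
    for (v in variables) {
      hit <- d[[valcol]][d$event == v & fl == "ok"]
      hit <- hit[!is.na(hit)]
      if (length(hit) > 0)
        row[v] <- if (mode == "amplitude") abs(hit[1]) else hit[1]
    }
    row
  }))
  labels <- colnames(wide)
  k <- length(labels)
  r <- diag(1, k); nmat <- matrix(0L, k, k)
  dimnames(r) <- dimnames(nmat) <- list(labels, labels)
  for (i in seq_len(k)) {
    nmat[i, i] <- sum(!is.na(wide[, i]))
    for (j in seq_len(k)) {
      if (j <= i) next
      keep <- !is.na(wide[, i]) & !is.na(wide[, j])
      nmat[i, j] <- nmat[j, i] <- sum(keep)
      r[i, j] <- r[j, i] <-
        if (sum(keep) >= 2) pearson(wide[keep, i], wide[keep, j])
        else NA_real_
    }
  }
  flagged <- labels[colSums(!is.na(wide)) < nrow(wide) / 2]
  structure(
    list(labels = labels, r = r, n = nmat,
         band = matrix(classify_correlation(r), k, k,
                       dimnames = dimnames(r)),
         flagged = flagged, mode = mode),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<correlation_matrix> mode = %s, %d cycles pooled\n",
              x$mode, max(x$n)))
  print(round(x$r, digits))
  if (length(x$flagged) > 0)
    cat("flagged (sparse in > 50% of cycles):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Write a correlation matrix to CSV
#' @param cm A `correlation_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(cm, path) {
  df <- data.frame(variable = cm$labels, round(cm$r, 4),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Lateral-sway summary per walk type
#'
#' Summarises the lateral (y-axis) acceleration of the walking segment of
#' each walk type with its extremes and quartiles (linear-interpolation
#' quartiles, type 7). The spread of the lateral acceleration is a simple
#' balance indicator: larger sway means less stable gait.
#'
#' @param sway Data frame with columns `walk_type` and `ay_g` (walking
#'   samples only, still lead excluded), e.g. from [collect_sway()].
#' @return Data frame of class `sway_summary`: walk_type, min_g, q1_g,
#'   median_g, q3_g, max_g, n.
#' @export
sway_summary <- function(sway) {
  stopifnot(all(c("walk_type", "ay_g") %in% names(sway)))
  types <- intersect(walk_types(), unique(sway$walk_type))
  rows <- lapply(types, function(ty) {
    v <- sway$ay_g[sway$walk_type == ty]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning("walk type ", ty, " has no sway samples; omitted")
      return(NULL)
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(walk_type = ty, min_g = min(v), q1_g = q[1], median_g = q[2],
               q3_g = q[3], max_g = max(v), n = length(v),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("sway_summary", "data.frame"))
}

#' Collect walking-segment lateral acceleration from a cohort
#'
#' @param cohort A `gait_cohort` from [make_cohort()].
#' @return Data frame walk_type, participant, ay_g (lead excluded).
#' @export
collect_sway <- function(cohort) {
  do.call(rbind, lapply(cohort, function(rec) {
    lead_n <- round(rec$params$lead_still_s * rec$params$sample_rate_hz)
    drop_lead <- function(v) if (lead_n > 0) v[-seq_len(lead_n)] else v
    ay <- c(drop_lead(rec$left$ay), drop_lead(rec$right$ay))
    data.frame(walk_type = rec$walk_type, participant = rec$participant,
               ay_g = ay, stringsAsFactors = FALSE)
  }))
}
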