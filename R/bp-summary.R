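#' Classic blood-pressure variability parameters
#'
#' Computes the standard per-patient BP summary over a set of readings: mean,
#' maximum, minimum, range (max - min), sample SD (divisor n - 1) and
#' successive variation (SV), the root-mean-square of successive differences
#' of consecutive readings in time order:
#' \deqn{SV = \sqrt{\sum_{i=1}^{m-1} (x_{i+1}-x_i)^2 / (m-1)}.}
#' With `sv_cv = TRUE` the SV is additionally normalised by the mean
#' (coefficient-style successive variation).
#'
#' @param values numeric readings (mmHg), in time order.
#' @param which which parameters to compute (default all six). `mean`, `max`,
#'   `min` and `range` are defined from one reading; `sd` and `sv` require at
#'   least two and raise an error otherwise.
#' @param sv_cv logical; normalise SV by the mean.
#' @return named numeric vector of the requested parameters.
#' @examples
#' bp_parameters(c(120, 130, 140))  # sd = 10, sv = 10
#' @export
bp_parameters <- function(values,
                          which = c("mean", "max", "min", "range", "sd", "sv"),
                          sv_cv = FALSE) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(values) < 1L || anyNA(values)) stop("need at least one non-missing value")
  if (any(c("sd", "sv") %in% which) && length(values) < 2L)
    stop("sd and sv are undefined for fewer than 2 values")
  all6 <- c(mean = mean(values), max = max(values), min = min(values),
            range = max(values) - min(values),
            sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
            sv = if (length(values) >= 2L) {
              s <- sqrt(sum(diff(values)^2) / (length(values) - 1L))
              if (sv_cv) s / mean(values) else s
            } else NA_real_)
  all6[which]
}

#' Day / night observation masks
#'
#' Splits the observation indices of a 24-h series into daytime and nighttime
#' according to clock time: an observation `t` hours after infusion start
#' falls in daytime iff `(onset + t) mod 24` lies in the half-open day window.
#' The two masks always partition the indices.
#'
#' @param times hours since infusion start.
#' @param onset clock time of infusion start, hours in `[0, 24)` or an
#'   `"HH:MM"` string.
#' @param day_window length-2 numeric, the `[start, end)` daytime clock
#'   interval in hours; default `c(6, 22)` (06:00-22:00).
#' @return list with logical vectors `day` and `night`.
#' @export
day_night_masks <- function(times, onset, day_window = c(6, 22)) {
  onset <- parse_clock(onset)
  stopifnot(length(day_window) == 2L, day_window[1L] < day_window[2L],
            day_window[2L] - day_window[1L] <= 24)
  clock <- (onset + times) %% 24
  day <- clock >= day_window[1L] & clock < day_window[2L]
  list(day = day, night = !day)
}

parse_clock <- function(x) {
  if (is.character(x)) {
    p <- strsplit(x, ":", fixed = TRUE)[[1L]]
    if (length(p) != 2L) stop("clock time must be \"HH:MM\"")
    x <- as.numeric(p[1L]) + as.numeric(p[2L]) / 60
  }
  if (is.na(x) || x < 0 || x >= 24) stop("clock time must lie in [0, 24)")
  x
}

#' Single-time-point BP values
#'
#' Extracts the admission value (earliest reading) and the value at the end
#' of the 1-h alteplase infusion ("immediately after thrombolysis"), taken at
#' the reading nearest `post_time` with ties broken toward the earlier time.
#'
#' @param values readings (mmHg); `times` hours, same length, increasing.
#' @param times observation times in hours.
#' @param post_time target time of the post-thrombolysis reading (default 1 h).
#' @return named numeric `c(admission, post_thrombolysis)`.
#' @export
bp_point_values <- function(values, times, post_time = 1) {
  if (length(values) == 0L) stop("empty series")
  stopifnot(length(values) == length(times))
  o <- order(times)
  values <- values[o]; times <- times[o]
  i <- which.min(abs(times - post_time))  # ties -> earlier (first minimum)
  c(admission = values[1L], post_thrombolysis = values[i])
}

#' Per-patient BP parameter table
#'
#' Computes, for every patient and channel in a long-format BP table, the
#' classic variability parameters over the full 24 h and over day and night
#' windows, plus the admission and immediate post-thrombolysis values.
#'
#' @param bp long-format data frame with columns `patient_id`, `channel`,
#'   `time_h`, `value_mmhg`.
#' @param onset clock time(s) of infusion start: a single value or a named
#'   vector/list keyed by patient id (hours or `"HH:MM"`).
#' @param day_window daytime clock interval, see [day_night_masks()].
#' @param sv_cv normalise SV by the mean.
#' @return data frame with one row per patient x channel x window
#'   (`h24`, `daytime`, `nighttime`) and columns `mean`, `max`, `min`,
#'   `range`, `sd`, `sv`, `admission`, `post_thrombolysis`. Windows with
#'   fewer than two readings carry `NA` summaries.
#' @export
bp_parameter_table <- function(bp, onset = 8, day_window = c(6, 22),
                               sv_cv = FALSE) {
  check_bp_long(bp)
  onset_for <- function(pid) {
    if (length(onset) == 1L && is.null(names(onset))) return(parse_clock(onset[[1L]]))
    if (!pid %in% names(onset)) stop("no onset time for patient ", pid)
    parse_clock(onset[[pid]])
  }
  out <- list()
  for (key in split(seq_len(nrow(bp)), list(bp$patient_id, bp$channel), drop = TRUE)) {
    rows <- bp[key, ]
    rows <- rows[order(rows$time_h), ]
    pid <- as.character(rows$patient_id[1L])
    masks <- day_night_masks(rows$time_h, onset_for(pid), day_window)
    pts <- bp_point_values(rows$value_mmhg, rows$time_h)
    for (w in c("h24", "daytime", "nighttime")) {
      sel <- switch(w, h24 = rep(TRUE, nrow(rows)), daytime = masks$day,
                    nighttime = masks$night)
      pars <- if (sum(sel) >= 2L) bp_parameters(rows$value_mmhg[sel], sv_cv = sv_cv)
              else c(mean = NA_real_, max = NA_real_, min = NA_real_,
                     range = NA_real_, sd = NA_real_, sv = NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, channel = as.character(rows$channel[1L]), window = w,
        t(pars), admission = pts[["admission"]],
        post_thrombolysis = pts[["post_thrombolysis"]])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
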