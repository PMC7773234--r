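#' Per-area brushing durations of an aggregated session
#'
#' Sums interval lengths by area label (uncoded intervals excluded), splits
#' closed-jaw combined codes evenly onto their member sextants with
#' [split_combined_durations()], and returns the full 18-vector in
#' [enumerate_areas()] order. These are the d_i of the isochronicity formula.
#'
#' @param intervals a `coded_intervals` tibble from [bin_stream()].
#' @return named numeric vector of seconds over the 18 areas, with attribute
#'   `total_s` (the summed coded duration).
#' @export
area_durations <- function(intervals) {
  coded <- intervals[!is_uncoded(intervals$label), ]
  full <- setNames(numeric(18), enumerate_areas())
  if (nrow(coded) > 0) {
    d <- tapply(coded$end_s - coded$start_s, coded$label, sum)
    d <- split_combined_durations(setNames(as.numeric(d), names(d)))
    full[names(d)] <- d
  }
  attr(full, "total_s") <- sum(full)
  full
}

#' Count area changes (events) in a label sequence
#'
#' Restricts the time-ordered sequence to labels in `area_set` (other labels,
#' including the uncoded sentinel, are removed so that an excursion outside
#' the set and back does not count), collapses runs of equal labels, and
#' counts the transitions between consecutive distinct labels.
#'
#' @param labels character vector of labels in time order.
#' @param area_set labels to retain (default: all 21 area codes).
#' @return integer change count (0 for an empty restricted sequence).
#' @examples
#' count_events(c("0102", "0102", "0202", "0202", "0102"))  # 2
#' @export
count_events <- function(labels, area_set = enumerate_areas(include_combined = TRUE)) {
  x <- labels[labels %in% area_set]
  if (length(x) <= 1) return(0L)
  sum(x[-1] != x[-length(x)])
}

#' Consistency of a brushing session
#'
#' `C = max(0, (1 - b/x) * i/n)`: rewards reaching all areas (`i` of `n`)
#' while changing area rarely (`b` changes over `x` seconds of brushing).
#' Clamped at zero when changes outnumber seconds.
#'
#' @param b number of changes between areas.
#' @param x total brushing duration in seconds (must be positive).
#' @param i_reached number of areas reached.
#' @param n number of reachable areas (12 smooth areas for the TSI).
#' @return consistency in `[0, 1]`.
#' @examples
#' consistency(b = 11, x = 120, i_reached = 12)  # 0.9083...
#' @export
consistency <- function(b, x, i_reached, n = 12) {
  if (!is.numeric(x) || x <= 0) tt_validation_error("x must be a positive duration")
  if (b < 0) tt_validation_error("b must be non-negative")
  if (i_reached < 0 || i_reached > n) tt_validation_error("i_reached must lie in [0, n]")
  max(0, (1 - b / x) * i_reached / n)
}

#' Isochronicity of a brushing session
#'
#' `I = 1 - n/(2(n-1)) * sum(|d_i/x - 1/n|)`: 1 when brushing time is spread
#' perfectly evenly over the `n` areas, 0 when it is concentrated in a single
#' area.
#'
#' @param durations numeric vector of per-area brushing durations `d_i`,
#'   seconds.
#' @param x total brushing duration in seconds; defaults to `sum(durations)`
#'   and must agree with it to within `tol`.
#' @param tol tolerance for the duration-sum check (one 100 Hz sample period
#'   by default).
#' @return isochronicity in `[0, 1]`.
#' @examples
#' isochronicity(rep(10, 12))              # 1
#' isochronicity(c(120, rep(0, 11)))       # 0
#' @export
isochronicity <- function(durations, x = sum(durations), tol = 0.011) {
  if (!is.numeric(x) || x <= 0) tt_validation_error("x must be a positive duration")
  if (any(durations < 0)) tt_validation_error("durations must be non-negative")
  if (abs(sum(durations) - x) > tol) {
    tt_validation_error("durations must sum to x (within one sample period)")
  }
  n <- length(durations)
  if (n < 2) tt_validation_error("isochronicity needs at least two areas")
  # algebraically identical to 1 - n/(2(n-1)) * sum(|d_i/x - 1/n|) but exact
  # at the closed-form extremes (all-even and fully concentrated vectors)
  1 - sum(abs(durations * n - x)) / (2 * (n - 1) * x)
}

#' Toothbrushing Systematics Index of an aggregated session
#'
#' The TSI and its sub-measures are computed on the 12 smooth (vestibular and
#' oral) areas only, ignoring occlusal/incisal brushing:
#'
#' * `x` — seconds brushed on smooth surfaces (combined codes contribute
#'   after their even split);
#' * `b` — changes between smooth areas on the aggregated interval grid,
#'   counted after removing occlusal and uncoded intervals and collapsing
#'   runs (an occlusal interruption that returns to the same smooth area is
#'   not a change);
#' * `i_reached` — number of the 12 areas with strictly positive duration;
#' * `C = max(0, (1 - b/x) * i/n)`, `I = 1 - n/(2(n-1)) * sum|d_i/x - 1/n|`,
#'   `TSI = C + I` in `[0, 2]`.
#'
#' @param intervals a `coded_intervals` tibble from [bin_stream()].
#' @return a list of class `tsi_result` with `C`, `I`, `TSI`, `b`, `x`,
#'   `i_reached`, `n`, `durations` (the 12-vector) and the session metadata.
#' @export
tsi <- function(intervals) {
  smooth <- smooth_areas()
  d_all <- area_durations(intervals)
  d12 <- d_all[smooth]
  x <- sum(d12)
  if (x <= 0) {
    tt_validation_error(
      "TSI undefined: no smooth-surface (vestibular/oral) brushing time in this session")
  }
  b <- count_events(intervals$label, area_set = c(smooth, combined_codes()))
  i_reached <- sum(d12 > 0)
  C <- consistency(b, x, i_reached, n = 12)
  I <- isochronicity(d12, x, tol = max(0.011, 1e-9 * x))
  structure(list(
    C = C, I = I, TSI = C + I, b = b, x = x, i_reached = i_reached, n = 12L,
    durations = d12,
    source = attr(intervals, "source", exact = TRUE),
    subject_id = attr(intervals, "subject_id", exact = TRUE),
    session = attr(intervals, "session", exact = TRUE)
  ), class = "tsi_result")
}

#' @export
print.tsi_result <- function(x, ...) {
  cat(sprintf(
    "<tsi_result> TSI = %.4f (C = %.4f, I = %.4f); b = %d changes, x = %.1f s, %d/%d areas reached\n",
    x$TSI, x$C, x$I, x$b, x$x, x$i_reached, x$n))
  invisible(x)
}

#' One-row metrics summary of an aggregated session
#'
#' Emits the per-session outcome measures: total coded duration, event count
#' over all areas on the aggregated grid, the TSI inputs and scores, and the
#' 18 per-area durations as wide columns `d_<area>`. Sessions with no
#' smooth-surface time get `NA` systematics scores with a warning.
#'
#' @param intervals a `coded_intervals` tibble from [bin_stream()].
#' @return a one-row tibble.
#' @export
session_metrics <- function(intervals) {
  d_all <- area_durations(intervals)
  events <- count_events(intervals$label)
  ts <- tryCatch(tsi(intervals), tt_validation_error = function(e) {
    warning(conditionMessage(e))
    NULL
  })
  row <- tibble(
    subject_id = attr(intervals, "subject_id", exact = TRUE) %||% NA_character_,
    session = attr(intervals, "session", exact = TRUE) %||% NA_character_,
    source = attr(intervals, "source", exact = TRUE) %||% NA_character_,
    brush = attr(intervals, "brush", exact = TRUE) %||% NA_character_,
    total_coded_s = attr(d_all, "total_s"),
    events = as.integer(events),
    b = if (is.null(ts)) NA_integer_ else as.integer(ts$b),
    x = if (is.null(ts)) NA_real_ else ts$x,
    i_reached = if (is.null(ts)) NA_integer_ else as.integer(ts$i_reached),
    C = if (is.null(ts)) NA_real_ else ts$C,
    I = if (is.null(ts)) NA_real_ else ts$I,
    TSI = if (is.null(ts)) NA_real_ else ts$TSI
  )
  dur <- as.data.frame(as.list(setNames(as.numeric(d_all),
                                        paste0("d_", names(d_all)))))
  dplyr::bind_cols(row, as_tibble(dur))
}
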