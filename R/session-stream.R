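#' Construct a coded session stream
#'
#' A session stream is one source's time-ordered coded record of one brushing
#' session: either event-based (video observation, columns `start_s`, `end_s`,
#' `area`) or sample-based (motion tracking, columns `t_s`, `area`, optionally
#' `angle_deg` and `region`). All times are seconds from session start and all
#' intervals are half-open `[start, end)`.
#'
#' @param records a data frame of records (see Details).
#' @param subject_id subject identifier.
#' @param session `"baseline"` or `"post_instruction"`.
#' @param source `"VO"` (video observation) or `"MT"` (motion tracking).
#' @param brush `"manual"` or `"powered"`.
#' @param rate_hz nominal sampling rate: 100 for MT samples, 50 for VO-derived
#'   frames.
#' @param bin_s aggregation bin length in seconds (0.5 by default).
#' @param session_start_s,session_end_s session span in seconds; the end
#'   defaults to the last record.
#'
#' @details Event records must be non-overlapping and lie within the session
#' span; sample times must be strictly increasing. Area codes are validated
#' with [parse_area_code()]; the sentinel [uncoded_label()] is also allowed.
#'
#' @return an object of class `session_stream` (a list with the validated
#'   `records` tibble plus metadata).
#' @export
session_stream <- function(records, subject_id, session, source, brush,
                           rate_hz = if (identical(source, "MT")) 100 else 50,
                           bin_s = 0.5,
                           session_start_s = 0, session_end_s = NULL) {
  records <- as_tibble(records)
  if (!session %in% c("baseline", "post_instruction")) {
    tt_validation_error("session must be 'baseline' or 'post_instruction'")
  }
  if (!source %in% c("VO", "MT")) tt_validation_error("source must be 'VO' or 'MT'")
  if (!brush %in% c("manual", "powered")) {
    tt_validation_error("brush must be 'manual' or 'powered'")
  }
  if (rate_hz <= 0 || bin_s <= 0) {
    tt_validation_error("rate_hz and bin_s must be positive")
  }
  kind <- if (all(c("start_s", "end_s") %in% names(records))) "events"
          else if ("t_s" %in% names(records)) "samples"
          else tt_format_error("records need either start_s/end_s or t_s columns")
  if (!"area" %in% names(records)) tt_format_error("records need an 'area' column")
  coded <- !is_uncoded(records$area)
  if (any(coded)) parse_area_code(records$area[coded])

  if (kind == "events" && nrow(records) > 0) {
    records <- records[order(records$start_s), ]
    if (any(records$end_s <= records$start_s)) {
      tt_validation_error("events must have end_s > start_s")
    }
    if (nrow(records) > 1) {
      ov <- records$start_s[-1] < records$end_s[-nrow(records)] - 1e-9
      if (any(ov)) {
        tt_validation_error(sprintf("overlapping events at record %d",
                                    which(ov)[1] + 1L))
      }
    }
  }
  if (kind == "samples" && nrow(records) > 1) {
    if (any(diff(records$t_s) <= 0)) {
      tt_validation_error(sprintf("sample times not strictly increasing at record %d",
                                  which(diff(records$t_s) <= 0)[1] + 1L))
    }
  }
  if (is.null(session_end_s)) {
    session_end_s <- if (nrow(records) == 0) session_start_s
    else if (kind == "events") max(records$end_s) else max(records$t_s) + 1 / rate_hz
  }
  t_lo <- if (kind == "events") records$start_s else records$t_s
  t_hi <- if (kind == "events") records$end_s else records$t_s
  if (nrow(records) > 0 &&
      (min(t_lo) < session_start_s - 1e-9 || max(t_hi) > session_end_s + 1e-9)) {
    tt_validation_error("records fall outside [session_start_s, session_end_s]")
  }
  structure(
    list(records = records, subject_id = as.character(subject_id),
         session = session, source = source, brush = brush, kind = kind,
         rate_hz = rate_hz, bin_s = bin_s,
         session_start_s = session_start_s, session_end_s = session_end_s),
    class = "session_stream"
  )
}

#' @export
print.session_stream <- function(x, ...) {
  cat(sprintf("<session_stream> %s / %s / %s / %s: %d %s over [%.2f, %.2f) s\n",
              x$subject_id, x$session, x$source, x$brush, nrow(x$records),
              x$kind, x$session_start_s, x$session_end_s))
  invisible(x)
}

#' Expand a video-observation event stream to a frame grid
#'
#' Emits one sample per frame tick so that event-based (VO) and sample-based
#' (MT) records share a single representation. A frame is labelled by the
#' event covering its midpoint; frames covered by no event get the explicit
#' [uncoded_label()] sentinel, never silently dropped.
#'
#' @param stream an event-based [session_stream()].
#' @param rate_hz frame rate; defaults to the stream's nominal rate (50 fps).
#' @return a tibble with columns `t_s` (frame start time) and `label`.
#' @export
rasterize_events <- function(stream, rate_hz = stream$rate_hz) {
  stopifnot(inherits(stream, "session_stream"))
  if (stream$kind != "events") tt_validation_error("rasterize_events needs an event-based stream")
  if (!is.numeric(rate_hz) || rate_hz <= 0) tt_validation_error("rate_hz must be positive")
  span <- stream$session_end_s - stream$session_start_s
  n <- ceiling(span * rate_hz - 1e-9)
  if (n <= 0) return(tibble(t_s = numeric(0), label = character(0)))
  k <- seq_len(n) - 1L
  t0 <- stream$session_start_s + k / rate_hz
  mid <- stream$session_start_s + (k + 0.5) / rate_hz
  lab <- rep(.uncoded, n)
  ev <- stream$records
  if (nrow(ev) > 0) {
    # epsilon keeps midpoints that coincide with a boundary (up to float
    # rounding) in the covering event
    idx <- findInterval(mid + 1e-9, ev$start_s)
    hit <- idx >= 1L & mid + 1e-9 < ev$end_s[pmax(idx, 1L)] &
      mid < stream$session_end_s
    lab[hit] <- ev$area[idx[hit]]
  }
  tibble(t_s = t0, label = lab)
}

#' Sample tibble of a stream (identity for MT, rasterized for VO)
#'
#' @param stream a [session_stream()].
#' @param rate_hz frame rate used when rasterizing an event stream.
#' @return tibble with `t_s`, `label` and, when present, `angle_deg`, `region`.
#' @export
stream_samples <- function(stream, rate_hz = stream$rate_hz) {
  stopifnot(inherits(stream, "session_stream"))
  if (stream$kind == "events") return(rasterize_events(stream, rate_hz))
  out <- tibble(t_s = stream$records$t_s, label = stream$records$area)
  if ("angle_deg" %in% names(stream$records)) out$angle_deg <- stream$records$angle_deg
  if ("region" %in% names(stream$records)) out$region <- stream$records$region
  out
}
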