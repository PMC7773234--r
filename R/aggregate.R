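#' Majority label of the samples in one interval
#'
#' Returns the most frequent label among the interval's samples, ignoring
#' uncoded samples. Ties are broken in favour of the label occurring first in
#' time among those with the highest count. An interval with no coded sample
#' gets the [uncoded_label()] sentinel (not an error).
#'
#' @param labels character vector of sample labels in time order.
#' @return a single label.
#' @examples
#' majority_label(c("0202", "0102", "0102", "0202"))  # tie -> first in time
#' @export
majority_label <- function(labels) {
  coded <- !is_uncoded(labels)
  if (!any(coded)) return(.uncoded)
  labels <- labels[coded]
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  firsts <- vapply(top, function(l) which(labels == l)[1], integer(1))
  top[which.min(firsts)]
}

# vectorised majority vote over many intervals at once
.majority_by_interval <- function(interval, label) {
  df <- tibble(interval = interval, label = label, pos = seq_along(label))
  df <- df[!is_uncoded(df$label), ]
  if (nrow(df) == 0) {
    return(tibble(interval = integer(0), label = character(0), support = integer(0)))
  }
  df |>
    group_by(interval, label) |>
    summarise(n_lab = n(), first_pos = min(pos), .groups = "drop_last") |>
    arrange(desc(n_lab), first_pos, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(support = n_lab) |>
    (\(d) d[, c("interval", "label", "support")])()
}

#' Aggregate a stream onto the common interval grid
#'
#' Samples are binned into half-open intervals `[k*bin_s, (k+1)*bin_s)` from
#' session start; each interval is labelled by [majority_label()]. A trailing
#' partial interval (shorter than `bin_s`) is kept and labelled from its
#' available samples, so duration is conserved. Intervals containing no coded
#' sample carry the [uncoded_label()] sentinel with support 0.
#'
#' @param stream a [session_stream()] (event streams are rasterized first) or
#'   a plain sample tibble with `t_s` and `label` columns, in which case
#'   `session_start_s`/`session_end_s` default to the sample span.
#' @param bin_s interval length in seconds (default 0.5).
#' @return a tibble of class `coded_intervals` with columns `index` (0-based),
#'   `start_s`, `end_s`, `label`, `support`, carrying the session metadata as
#'   attributes.
#' @export
bin_stream <- function(stream, bin_s = 0.5) {
  if (!is.numeric(bin_s) || bin_s <= 0) tt_validation_error("bin_s must be positive")
  if (inherits(stream, "session_stream")) {
    samples <- stream_samples(stream)
    start <- stream$session_start_s
    end <- stream$session_end_s
    meta <- stream[c("subject_id", "session", "source", "brush")]
  } else {
    samples <- as_tibble(stream)
    if (!all(c("t_s", "label") %in% names(samples))) {
      tt_format_error("sample input needs t_s and label columns")
    }
    # each sample stands for one sample period; infer the period from the
    # tick spacing so the coded span ends one period after the last sample
    dt <- if (nrow(samples) > 1) median(diff(samples$t_s)) else bin_s
    start <- if (nrow(samples)) min(samples$t_s) else 0
    end <- if (nrow(samples)) max(samples$t_s) + dt else 0
    meta <- list(subject_id = NA_character_, session = NA_character_,
                 source = NA_character_, brush = NA_character_)
  }
  n_int <- max(1L, ceiling((end - start) / bin_s - 1e-9))
  idx <- pmin(floor((samples$t_s - start) / bin_s + 1e-9), n_int - 1L)
  voted <- .majority_by_interval(as.integer(idx), samples$label)
  out <- tibble(
    index = 0:(n_int - 1L),
    start_s = start + (0:(n_int - 1L)) * bin_s,
    end_s = pmin(start + (1:n_int) * bin_s, end),
    label = .uncoded,
    support = 0L
  )
  if (nrow(voted) > 0) {
    pos <- voted$interval + 1L
    out$label[pos] <- voted$label
    out$support[pos] <- as.integer(voted$support)
  }
  structure(out, class = c("coded_intervals", class(out)),
            subject_id = meta$subject_id, session = meta$session,
            source = meta$source, brush = meta$brush, bin_s = bin_s)
}

#' Classify a surface from the brush angle
#'
#' Motion tracking discriminates occlusal/incisal from smooth-surface
#' brushing by the inclination of the brush-head axis relative to the
#' occlusal plane: at or below the regional threshold (20 degrees on molars,
#' 13 degrees on anterior teeth by default) the brush is on the
#' occlusal/incisal surface; above it, on the smooth surface of the side
#' given by `side`.
#'
#' @param angle_deg numeric vector of angles in `[0, 90]` degrees.
#' @param region `"molar"` or `"anterior"`, recycled as needed.
#' @param thresholds an [angle_thresholds()].
#' @param side `"vestibular_side"` or `"oral_side"`: which smooth surface the
#'   brush is on when the angle exceeds the threshold.
#' @return character vector of surface codes (`"01"`, `"02"` or `"03"`).
#' @examples
#' classify_surface_from_angle(25, "molar", side = "vestibular_side")  # "02"
#' classify_surface_from_angle(15, "molar")                            # "01"
#' @export
classify_surface_from_angle <- function(angle_deg, region,
                                        thresholds = angle_thresholds(),
                                        side = c("vestibular_side", "oral_side")) {
  side <- match.arg(side)
  if (any(!is.finite(angle_deg)) || any(angle_deg < 0 | angle_deg > 90)) {
    tt_validation_error("angle_deg must lie in [0, 90] degrees")
  }
  if (!all(region %in% c("molar", "anterior"))) {
    tt_validation_error("region must be 'molar' or 'anterior'")
  }
  thr <- ifelse(region == "anterior", thresholds$anterior_deg, thresholds$molar_deg)
  smooth <- if (side == "vestibular_side") "02" else "03"
  ifelse(angle_deg <= thr, "01", smooth)
}

#' Re-derive MT surfaces from the angle channel
#'
#' Applies [classify_surface_from_angle()] per sample (classification before
#' majority voting). The side of a smooth classification is taken from the
#' sample's recorded surface; samples recorded as occlusal that classify as
#' smooth get the vestibular side. Combined-code samples are left untouched
#' (closed-jaw brushing is vestibular by definition).
#'
#' @param stream a sample-based [session_stream()] with an `angle_deg`
#'   column; streams without one are returned unchanged.
#' @param thresholds an [angle_thresholds()].
#' @return the stream with reclassified `area` codes.
#' @export
classify_stream_surfaces <- function(stream, thresholds = angle_thresholds()) {
  stopifnot(inherits(stream, "session_stream"))
  rec <- stream$records
  if (stream$kind != "samples" || !"angle_deg" %in% names(rec) || nrow(rec) == 0) {
    return(stream)
  }
  sx <- area_sextant(rec$area)
  sf <- area_surface(rec$area)
  use <- !is.na(rec$angle_deg) & !(sx %in% names(.combined_pairs)) &
    !is_uncoded(rec$area)
  if (!any(use)) return(stream)
  region <- if ("region" %in% names(rec)) rec$region[use] else
    ifelse(sx[use] %in% c("02", "05"), "anterior", "molar")
  side <- ifelse(sf[use] == "03", "oral_side", "vestibular_side")
  new_sf <- sf[use]
  for (s in c("vestibular_side", "oral_side")) {
    pick <- side == s
    if (any(pick)) {
      new_sf[pick] <- classify_surface_from_angle(
        rec$angle_deg[use][pick], region[pick], thresholds, side = s)
    }
  }
  rec$area[use] <- paste0(sx[use], new_sf)
  stream$records <- rec
  stream
}

#' Pair two interval sequences of one session
#'
#' Pairs the VO and MT interval labels by index over the intersection of the
#' two coded spans; if one stream is longer, its surplus intervals are
#' dropped with a warning. Intervals where either side is uncoded are kept
#' but flagged `coded = FALSE` and excluded from all agreement denominators.
#'
#' @param vo_intervals,mt_intervals `coded_intervals` from [bin_stream()] for
#'   the same subject and session.
#' @return a tibble of class `paired_intervals` with columns `index`,
#'   `start_s`, `vo_label`, `mt_label`, `coded`.
#' @export
pair_streams <- function(vo_intervals, mt_intervals) {
  meta <- function(x, f) attr(x, f, exact = TRUE)
  for (f in c("subject_id", "session")) {
    a <- meta(vo_intervals, f); b <- meta(mt_intervals, f)
    if (!is.na(a) && !is.na(b) && a != b) {
      tt_validation_error(sprintf("cannot pair streams: %s differs (%s vs %s)", f, a, b))
    }
  }
  if (!isTRUE(all.equal(meta(vo_intervals, "bin_s"), meta(mt_intervals, "bin_s")))) {
    tt_validation_error("cannot pair streams: different bin_s grids")
  }
  n <- min(nrow(vo_intervals), nrow(mt_intervals))
  if (nrow(vo_intervals) != nrow(mt_intervals)) {
    warning(sprintf("stream lengths differ (%d vs %d intervals); %d dropped from the longer",
                    nrow(vo_intervals), nrow(mt_intervals),
                    abs(nrow(vo_intervals) - nrow(mt_intervals))))
  }
  out <- tibble(
    index = vo_intervals$index[seq_len(n)],
    start_s = vo_intervals$start_s[seq_len(n)],
    vo_label = vo_intervals$label[seq_len(n)],
    mt_label = mt_intervals$label[seq_len(n)]
  )
  out$coded <- !is_uncoded(out$vo_label) & !is_uncoded(out$mt_label)
  structure(out, class = c("paired_intervals", class(out)),
            subject_id = meta(vo_intervals, "subject_id"),
            session = meta(vo_intervals, "session"),
            brush = meta(vo_intervals, "brush"),
            bin_s = meta(vo_intervals, "bin_s"))
}

#' Split closed-jaw combined durations onto their member sextants
#'
#' The duration of each combined vestibular code (`1602`, `2502`, `3402`) is
#' distributed evenly (50/50) onto the vestibular areas of its two member
#' sextants; total duration is conserved exactly.
#'
#' @param durations named numeric vector of seconds per area code; may mix
#'   single-sextant and combined codes.
#' @return named numeric vector over single-sextant areas only.
#' @examples
#' split_combined_durations(c("1602" = 4))            # 0102: 2, 0602: 2
#' split_combined_durations(c("2502" = 1, "0202" = 1))
#' @export
split_combined_durations <- function(durations) {
  if (length(durations) == 0) return(setNames(numeric(0), character(0)))
  if (is.null(names(durations))) tt_format_error("durations must be named by area code")
  parse_area_code(names(durations))
  sx <- area_sextant(names(durations))
  comb <- sx %in% names(.combined_pairs)
  out <- durations[!comb]
  for (i in which(comb)) {
    members <- .combined_pairs[[sx[i]]]
    for (m in members) {
      tgt <- paste0(m, "02")
      out[tgt] <- (if (tgt %in% names(out)) out[[tgt]] else 0) + durations[[i]] / 2
    }
  }
  out
}

#' Sensitivity of the angle classifier to threshold perturbation
#'
#' Re-runs the per-sample surface classification with both thresholds shifted
#' by `delta_deg` and reports the fraction of samples whose label changes —
#' a robustness harness for the occlusal/smooth decision.
#'
#' @param stream a sample-based [session_stream()] with an angle channel.
#' @param thresholds baseline [angle_thresholds()].
#' @param delta_deg vector of perturbations in degrees (default `c(-3, 3)`).
#' @return a tibble with columns `delta_deg` and `changed_fraction`.
#' @export
threshold_sensitivity <- function(stream, thresholds = angle_thresholds(),
                                  delta_deg = c(-3, 3)) {
  base <- classify_stream_surfaces(stream, thresholds)$records$area
  res <- lapply(delta_deg, function(d) {
    th <- angle_thresholds(thresholds$molar_deg + d, thresholds$anterior_deg + d)
    pert <- classify_stream_surfaces(stream, th)$records$area
    tibble(delta_deg = d, changed_fraction = mean(pert != base))
  })
  bind_rows(res)
}
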