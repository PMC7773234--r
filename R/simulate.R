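#' Behaviour profile for the session generator
#'
#' Describes one subject's brushing behaviour as a semi-Markov walk over the
#' 18 areas: dwell times are drawn from a truncated normal, the next area from
#' visit weights (excluding the current area). A profile may instead carry a
#' fixed `follow_sequence` of areas (systematic, post-instruction brushing),
#' in which case the walk visits them in order.
#'
#' @param area_dwell_mean_s,area_dwell_sd_s mean and sd of the dwell time per
#'   visited area, seconds; dwells are truncated below at 0.5 s.
#' @param area_visit_weights non-negative visit weights, one per area of
#'   [enumerate_areas()]; need not be normalised.
#' @param switch_rate expected area changes per minute (informational record;
#'   the dwell mean is the operative parameter, `60/switch_rate` for a
#'   homogeneous walk).
#' @param oral_neglect fraction in `[0, 1]` by which oral-surface weights are
#'   downweighted (habitual brushers mostly neglect oral surfaces).
#' @param combined_code_prob probability that a vestibular stretch is brushed
#'   with closed jaws, i.e. coded with the combined code of its sextant pair.
#' @param total_duration_s total session duration, seconds.
#' @param follow_sequence optional ordered character vector of area codes to
#'   visit deterministically instead of the random walk.
#' @param area_skip_prob probability that an area of `follow_sequence` is
#'   skipped (imperfect adherence to the instruction); ignored for the
#'   random walk.
#' @return a list of class `behaviour_profile`.
#' @export
behaviour_profile <- function(area_dwell_mean_s = 5,
                              area_dwell_sd_s = 3,
                              area_visit_weights = setNames(rep(1, 18), enumerate_areas()),
                              switch_rate = 60 / area_dwell_mean_s,
                              oral_neglect = 0,
                              combined_code_prob = 0,
                              total_duration_s = 150,
                              follow_sequence = NULL,
                              area_skip_prob = 0) {
  w <- area_visit_weights
  if (length(w) != 18 || any(w < 0) || all(w == 0) || any(!is.finite(w))) {
    tt_validation_error("area_visit_weights must be 18 non-negative weights, not all zero")
  }
  if (is.null(names(w))) names(w) <- enumerate_areas()
  probs <- c(oral_neglect = oral_neglect, combined_code_prob = combined_code_prob,
             area_skip_prob = area_skip_prob)
  if (any(probs < 0 | probs > 1)) tt_validation_error("probabilities must lie in [0, 1]")
  if (total_duration_s <= 0 || area_dwell_mean_s <= 0 || area_dwell_sd_s < 0) {
    tt_validation_error("durations must be positive")
  }
  if (!is.null(follow_sequence)) parse_area_code(follow_sequence)
  structure(list(
    area_dwell_mean_s = area_dwell_mean_s, area_dwell_sd_s = area_dwell_sd_s,
    area_visit_weights = w, switch_rate = switch_rate,
    oral_neglect = oral_neglect, combined_code_prob = combined_code_prob,
    total_duration_s = total_duration_s, follow_sequence = follow_sequence,
    area_skip_prob = area_skip_prob
  ), class = "behaviour_profile")
}

#' Error model of the two observation sources
#'
#' @param neighbour_confusion_prob probability that the stretch following an
#'   area change starts with a block assigned to a neighbouring sextant
#'   (tracker imprecision near area boundaries).
#' @param occlusal_smooth_jitter_sd_deg sd, in degrees, of the per-stretch
#'   brush-angle offset around its surface-typical value; large offsets push
#'   a stretch across the occlusal/smooth threshold.
#' @param micro_transition_rate expected number of spurious short MT
#'   excursions to an adjacent area, per minute (inflates MT event counts).
#' @param vo_min_event_s minimum duration a stretch must have to be coded as
#'   a separate event by the video observer; shorter stretches are merged
#'   into their neighbours (0.5 s by default).
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(neighbour_confusion_prob = 0.45,
                        occlusal_smooth_jitter_sd_deg = 6,
                        micro_transition_rate = 14,
                        vo_min_event_s = 0.5) {
  if (neighbour_confusion_prob < 0 || neighbour_confusion_prob > 1) {
    tt_validation_error("neighbour_confusion_prob must lie in [0, 1]")
  }
  if (occlusal_smooth_jitter_sd_deg < 0 || micro_transition_rate < 0 ||
      vo_min_event_s < 0) {
    tt_validation_error("rates and standard deviations must be non-negative")
  }
  structure(list(
    neighbour_confusion_prob = neighbour_confusion_prob,
    occlusal_smooth_jitter_sd_deg = occlusal_smooth_jitter_sd_deg,
    micro_transition_rate = micro_transition_rate,
    vo_min_event_s = vo_min_event_s
  ), class = "noise_model")
}

#' Ready-made habitual and instructed behaviour profiles
#'
#' `"habitual"` emulates untrained brushing: frequent switching, vestibular-
#' heavy visit weights, strong oral neglect, occasional closed-jaw combined
#' codes. `"instructed"` follows the systematic sequence of
#' [systematic_sequence()] deterministically with near-equal dwell per area.
#'
#' @param kind `"habitual"` or `"instructed"`.
#' @param brush `"manual"` or `"powered"` (kept as metadata; the behavioural
#'   defaults are shared).
#' @param overrides named list of [behaviour_profile()] fields to override.
#' @return a `behaviour_profile`.
#' @export
make_profile <- function(kind = c("habitual", "instructed"),
                         brush = c("manual", "powered"),
                         overrides = list()) {
  kind <- match.arg(kind)
  brush <- match.arg(brush)
  if (kind == "habitual") {
    areas <- enumerate_areas()
    w <- setNames(ifelse(area_surface(areas) == "02", 1.0,
                         ifelse(area_surface(areas) == "01", 0.5, 1.0)), areas)
    args <- list(
      area_dwell_mean_s = 5, area_dwell_sd_s = 3,
      area_visit_weights = w, switch_rate = 12,
      oral_neglect = 0.7, combined_code_prob = 0.15,
      total_duration_s = 150
    )
  } else {
    args <- list(
      area_dwell_mean_s = 160 / 18, area_dwell_sd_s = 1.5,
      switch_rate = 17 / (160 / 60),
      oral_neglect = 0, combined_code_prob = 0,
      total_duration_s = 160,
      follow_sequence = systematic_sequence(),
      area_skip_prob = 0.12
    )
  }
  args <- utils::modifyList(args, overrides)
  do.call(behaviour_profile, args)
}

# frame grid (50 fps): transitions finer than a video frame are unobservable
# by either source, so ground truth lives on this grid
.frame_s <- 0.02
.snap <- function(t) round(t / .frame_s) * .frame_s

# truncated-normal dwell times, lower bound 0.5 s (shorter stretches are not
# separable behaviour units on the coding scheme's own terms)
.rdwell <- function(n, mean, sd, lower = 0.5) {
  out <- rnorm(n, mean, sd)
  for (i in 1:20) {
    bad <- out < lower
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower)
}

# ground-truth event path from a profile: tibble(start_s, end_s, label)
.simulate_truth <- function(profile) {
  total <- .snap(profile$total_duration_s)
  if (!is.null(profile$follow_sequence)) {
    labels <- profile$follow_sequence
    if (profile$area_skip_prob > 0) {
      keep <- runif(length(labels)) >= profile$area_skip_prob
      if (sum(keep) >= 2) labels <- labels[keep]
    }
    dwell <- .rdwell(length(labels), total / length(labels), profile$area_dwell_sd_s)
  } else {
    w <- profile$area_visit_weights
    areas <- names(w)
    oral <- area_surface(areas) == "03"
    w[oral] <- w[oral] * (1 - profile$oral_neglect)
    if (all(w == 0)) tt_validation_error("all visit weights zero after oral_neglect")
    n_guess <- max(8L, ceiling(total / profile$area_dwell_mean_s * 2) + 4L)
    labels <- character(n_guess)
    labels[1] <- sample(areas, 1, prob = w)
    for (i in 2:n_guess) {
      wi <- w
      wi[labels[i - 1]] <- 0
      # a walk with a single positive-weight area never leaves it
      labels[i] <- if (sum(wi) == 0) labels[i - 1] else sample(areas, 1, prob = wi)
    }
    dwell <- .rdwell(n_guess, profile$area_dwell_mean_s, profile$area_dwell_sd_s)
  }
  # closed-jaw combined coding of vestibular stretches
  vest <- area_surface(labels) == "02"
  use_comb <- vest & runif(length(labels)) < profile$combined_code_prob
  if (any(use_comb)) {
    sx <- area_sextant(labels[use_comb])
    pair_of <- c("01" = "16", "06" = "16", "02" = "25", "05" = "25",
                 "03" = "34", "04" = "34")
    labels[use_comb] <- paste0(pair_of[sx], "02")
  }
  ends <- .snap(cumsum(dwell))
  keep <- ends <= total + 1e-9
  labels <- labels[keep]; ends <- pmin(ends[keep], total)
  if (length(ends) == 0 || max(ends) < total - 1e-9) {
    labels <- c(labels, if (length(labels)) labels[length(labels)] else
      names(which.max(profile$area_visit_weights)))
    ends <- c(ends, total)
  }
  starts <- c(0, head(ends, -1))
  ok <- ends > starts + 1e-9
  ev <- tibble(start_s = starts[ok], end_s = ends[ok], label = labels[ok])
  # collapse consecutive repeats (can arise from combined-code substitution)
  if (nrow(ev) > 1) {
    new_run <- c(TRUE, ev$label[-1] != ev$label[-nrow(ev)])
    run <- cumsum(new_run)
    ev <- tibble(
      start_s = tapply(ev$start_s, run, min)[as.character(unique(run))],
      end_s = tapply(ev$end_s, run, max)[as.character(unique(run))],
      label = ev$label[new_run]
    )
  }
  ev
}

# label lookup with a small epsilon so that sample ticks falling exactly on a
# (floating-point-snapped) boundary are assigned to the new event
.truth_label_at <- function(truth, t) {
  idx <- findInterval(t + 1e-9, truth$start_s)
  lab <- rep(.uncoded, length(t))
  hit <- idx >= 1 & t + 1e-9 < truth$end_s[pmax(idx, 1)]
  lab[hit] <- truth$label[idx[hit]]
  lab
}

# a neighbouring-sextant area with the same surface (used for confusions)
.neighbour_area <- function(label) {
  sx <- area_sextant(label)
  sf <- area_surface(label)
  if (sx %in% names(.combined_pairs)) return(label)  # combined codes kept
  nb <- sample(.sextant_neighbours[[sx]], 1)
  paste0(nb, sf)
}

.make_mt_stream <- function(truth, noise, thresholds, meta, rate_hz = 100) {
  total <- max(truth$end_s)
  n <- round(total * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  stretch <- findInterval(t + 1e-9, truth$start_s)
  lab <- truth$label[stretch]
  true_surface <- area_surface(lab)
  true_surface[area_sextant(lab) %in% names(.combined_pairs)] <- "02"

  # neighbour-sextant confusion: a short block after each boundary is
  # assigned to a neighbouring sextant
  if (noise$neighbour_confusion_prob > 0 && nrow(truth) > 1) {
    for (j in 2:nrow(truth)) {
      if (runif(1) < noise$neighbour_confusion_prob) {
        w <- runif(1, 0.1, 0.4)
        sel <- t + 1e-9 >= truth$start_s[j] & t < truth$start_s[j] + w
        if (any(sel)) lab[sel] <- .neighbour_area(truth$label[j])
      }
    }
  }
  # spurious micro-transitions: brief excursions to an adjacent area. The
  # tracker flickers when the brush acts in the border region of an area, so
  # candidate excursions (Poisson at the nominal per-minute rate) only
  # materialise close to a ground-truth area change; sessions with little
  # switching therefore show little flicker.
  if (noise$micro_transition_rate > 0 && nrow(truth) > 1) {
    k <- rpois(1, noise$micro_transition_rate * total / 60)
    if (k > 0) {
      at <- runif(k, 0, total)
      bounds <- truth$start_s[-1]
      near <- vapply(at, function(u) min(abs(u - bounds)) <= 1.25, logical(1))
      at <- at[near]
      dur <- runif(length(at), 0.1, 0.6)
      base <- .truth_label_at(truth, at)
      for (j in seq_along(at)) {
        if (is_uncoded(base[j])) next
        sel <- t >= at[j] & t < at[j] + dur[j]
        if (any(sel)) lab[sel] <- .neighbour_area(base[j])
      }
    }
  }
  # brush-angle channel: occlusal stretches sit 8 degrees below the regional
  # threshold, smooth stretches 8 degrees above; a per-stretch offset models
  # subject- and position-level tilt variation and occasionally crosses the
  # threshold (the occlusal/smooth confusion mode)
  sx <- area_sextant(lab)
  region <- ifelse(sx %in% c("02", "05", "25"), "anterior", "molar")
  thr <- ifelse(region == "anterior", thresholds$anterior_deg, thresholds$molar_deg)
  base_angle <- ifelse(true_surface == "01", thr - 8, thr + 8)
  offset <- rnorm(nrow(truth), 0, noise$occlusal_smooth_jitter_sd_deg)
  angle <- base_angle + offset[stretch] +
    if (noise$occlusal_smooth_jitter_sd_deg > 0) rnorm(n, 0, 1) else 0
  angle <- pmin(pmax(angle, 0), 90)

  session_stream(
    tibble(t_s = t, area = lab, angle_deg = angle, region = region),
    subject_id = meta$subject_id, session = meta$session, source = "MT",
    brush = meta$brush, rate_hz = rate_hz,
    session_start_s = 0, session_end_s = total
  )
}

.make_vo_stream <- function(truth, noise, meta) {
  ev <- truth
  # the video observer does not code stretches shorter than vo_min_event_s as
  # separate events: merge them into the preceding (or following) event
  if (noise$vo_min_event_s > 0) {
    repeat {
      len <- ev$end_s - ev$start_s
      short <- which(len < noise$vo_min_event_s - 1e-9)
      if (length(short) == 0 || nrow(ev) == 1) break
      i <- short[which.min(len[short])]
      if (i > 1) {
        ev$end_s[i - 1] <- ev$end_s[i]
      } else {
        ev$start_s[i + 1] <- ev$start_s[i]
      }
      ev <- ev[-i, ]
      # re-collapse equal neighbours created by the merge
      if (nrow(ev) > 1) {
        same <- which(ev$label[-1] == ev$label[-nrow(ev)])
        while (length(same) > 0) {
          j <- same[1]
          ev$end_s[j] <- ev$end_s[j + 1]
          ev <- ev[-(j + 1), ]
          same <- if (nrow(ev) > 1) which(ev$label[-1] == ev$label[-nrow(ev)]) else integer(0)
        }
      }
    }
  }
  session_stream(
    tibble(start_s = ev$start_s, end_s = ev$end_s, area = ev$label),
    subject_id = meta$subject_id, session = meta$session, source = "VO",
    brush = meta$brush, rate_hz = 50,
    session_start_s = 0, session_end_s = max(ev$end_s)
  )
}

#' Simulate one paired VO/MT brushing session
#'
#' Draws a ground-truth area path from the behaviour profile (a semi-Markov
#' walk, or the fixed systematic sequence), then derives the motion-tracking
#' stream (100 Hz samples with neighbour-sextant confusion, micro-transitions
#' and a brush-angle channel) and the video-observation stream (timed events
#' with short stretches merged away). Ground-truth transition times are
#' snapped to the 0.02 s video frame grid, the finest resolution at which
#' either source can observe a change. Identical seeds give identical output.
#'
#' @param profile a [behaviour_profile()].
#' @param noise a [noise_model()].
#' @param seed integer seed for this session.
#' @param subject_id,session,brush session metadata.
#' @param thresholds [angle_thresholds()] used to centre the generated angle
#'   channel.
#' @return a list with elements `vo` and `mt` ([session_stream()]s) and
#'   `truth` (list: `events` tibble, `durations` named 18-vector of true
#'   per-area seconds after combined-code splitting, `n_events` true change
#'   count).
#' @examples
#' s <- simulate_session(make_profile("habitual"), noise_model(), seed = 7)
#' s$vo
#' @export
simulate_session <- function(profile, noise = noise_model(), seed = 1L,
                             subject_id = "S001", session = "baseline",
                             brush = "manual",
                             thresholds = angle_thresholds()) {
  stopifnot(inherits(profile, "behaviour_profile"), inherits(noise, "noise_model"))
  meta <- list(subject_id = subject_id, session = session, brush = brush)
  with_seed(as.integer(seed), {
    truth <- .simulate_truth(profile)
    mt <- .make_mt_stream(truth, noise, thresholds, meta)
    vo <- .make_vo_stream(truth, noise, meta)
    dur <- tapply(truth$end_s - truth$start_s, truth$label, sum)
    dur <- split_combined_durations(setNames(as.numeric(dur), names(dur)))
    full <- setNames(numeric(18), enumerate_areas())
    full[names(dur)] <- dur
    list(vo = vo, mt = mt,
         truth = list(events = truth, durations = full,
                      n_events = nrow(truth) - 1L))
  })
}

# deterministic per-subject/session seed derivation from the master seed
.derive_seed <- function(master, subject_index, session_index) {
  as.integer((as.numeric(master) + 104729 * subject_index +
                9973 * session_index) %% 2147483647)
}

#' Simulate a whole paired-observation study
#'
#' Generates baseline (habitual) sessions for every subject and
#' post-instruction (systematic) sessions for the instructed subset, each as
#' a paired VO/MT stream with ground truth. Subject-level heterogeneity
#' (switch rate, oral neglect, session duration, instruction adherence) is
#' drawn from population distributions; per-subject seeds are derived
#' deterministically from the master seed so any subset reproduces
#' independently.
#'
#' @param n_manual,n_powered subjects per toothbrush arm (study defaults 51
#'   and 52).
#' @param n_instructed subjects, taken proportionally from both arms, who
#'   also brush a post-instruction session (default 46).
#' @param seed master seed.
#' @param noise a [noise_model()] shared by all sessions.
#' @param session_duration_mean_s population mean of the habitual session
#'   duration, seconds.
#' @param profile_overrides named list forwarded to [make_profile()] for
#'   every subject (applied after the subject-level draws).
#' @param thresholds [angle_thresholds()] for the generated angle channel.
#' @return a list of class `brushing_study` with a `sessions` tibble
#'   (`subject_id`, `brush`, `session` plus list-columns `vo`, `mt`, `truth`)
#'   and the generating `config`.
#' @export
simulate_study <- function(n_manual = 51, n_powered = 52, n_instructed = 46,
                           seed = 1L, noise = noise_model(),
                           session_duration_mean_s = 150,
                           profile_overrides = list(),
                           thresholds = angle_thresholds()) {
  if (n_manual < 0 || n_powered < 0 || n_instructed < 0 ||
      n_instructed > n_manual + n_powered) {
    tt_validation_error("arm sizes must be non-negative and n_instructed <= total")
  }
  n_total <- n_manual + n_powered
  brush <- c(rep("manual", n_manual), rep("powered", n_powered))
  n_instr_manual <- if (n_total > 0) floor(n_instructed * n_manual / n_total) else 0
  n_instr_powered <- n_instructed - n_instr_manual
  instructed <- c(seq_len(n_manual) <= n_instr_manual,
                  seq_len(n_powered) <= n_instr_powered)
  if (n_manual == 0) instructed <- seq_len(n_powered) <= n_instr_powered
  if (n_powered == 0) instructed <- seq_len(n_manual) <= n_instr_manual

  rows <- vector("list", n_total + n_instructed)
  r <- 0L
  for (i in seq_len(n_total)) {
    sid <- sprintf("S%03d", i)
    # subject-level heterogeneity, reproducible from the derived seed
    subj_seed <- .derive_seed(seed, i, 0L)
    pars <- with_seed(subj_seed, list(
      switch_rate = rlnorm(1, log(15), 0.4),
      oral_neglect = rbeta(1, 5, 2),
      total_s = max(90, rnorm(1, session_duration_mean_s, 25)),
      dwell_sd_frac = runif(1, 0.4, 0.8),
      adherence_sd = runif(1, 0.8, 2.5)
    ))
    hab <- make_profile("habitual", brush[i], utils::modifyList(list(
      area_dwell_mean_s = 60 / pars$switch_rate,
      area_dwell_sd_s = 60 / pars$switch_rate * pars$dwell_sd_frac,
      switch_rate = pars$switch_rate,
      oral_neglect = pars$oral_neglect,
      total_duration_s = pars$total_s
    ), profile_overrides))
    r <- r + 1L
    rows[[r]] <- c(list(subject_id = sid, brush = brush[i], session = "baseline"),
                   simulate_session(hab, noise, .derive_seed(seed, i, 1L),
                                    subject_id = sid, session = "baseline",
                                    brush = brush[i], thresholds = thresholds))
    if (instructed[i]) {
      ins <- make_profile("instructed", brush[i], utils::modifyList(list(
        area_dwell_sd_s = pars$adherence_sd,
        total_duration_s = max(120, pars$total_s)
      ), profile_overrides))
      r <- r + 1L
      rows[[r]] <- c(list(subject_id = sid, brush = brush[i],
                          session = "post_instruction"),
                     simulate_session(ins, noise, .derive_seed(seed, i, 2L),
                                      subject_id = sid,
                                      session = "post_instruction",
                                      brush = brush[i], thresholds = thresholds))
    }
  }
  sessions <- tibble(
    subject_id = vapply(rows, `[[`, "", "subject_id"),
    brush = vapply(rows, `[[`, "", "brush"),
    session = vapply(rows, `[[`, "", "session"),
    vo = lapply(rows, `[[`, "vo"),
    mt = lapply(rows, `[[`, "mt"),
    truth = lapply(rows, `[[`, "truth")
  )
  structure(list(
    sessions = sessions,
    config = list(n_manual = n_manual, n_powered = n_powered,
                  n_instructed = n_instructed, seed = seed, noise = noise,
                  session_duration_mean_s = session_duration_mean_s,
                  thresholds = thresholds)
  ), class = "brushing_study")
}

#' @export
print.brushing_study <- function(x, ...) {
  cat(sprintf("<brushing_study> %d sessions (%d subjects; %d post-instruction), master seed %s\n",
              nrow(x$sessions), length(unique(x$sessions$subject_id)),
              sum(x$sessions$session == "post_instruction"),
              format(x$config$seed)))
  invisible(x)
}
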