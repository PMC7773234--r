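#' Default pipeline configuration
#'
#' Every parameter defaults to the study's stated value where one exists:
#' 0.5 s aggregation bins, 20 and 13 degree angle thresholds, significance
#' level 0.05, 8 s equivalence margin, and arm sizes 51 manual / 52 powered /
#' 46 instructed.
#'
#' @param seed master seed for the synthetic study.
#' @param n_manual,n_powered,n_instructed arm sizes.
#' @param bin_s aggregation bin length, seconds.
#' @param molar_deg,anterior_deg angle thresholds, degrees.
#' @param alpha significance level.
#' @param margin_s equivalence margin, seconds.
#' @param noise a [noise_model()].
#' @param session_duration_mean_s mean habitual session duration, seconds.
#' @param profile_overrides forwarded to [simulate_study()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_manual = 51, n_powered = 52,
                            n_instructed = 46, bin_s = 0.5,
                            molar_deg = 20, anterior_deg = 13,
                            alpha = 0.05, margin_s = 8.0,
                            noise = noise_model(),
                            session_duration_mean_s = 150,
                            profile_overrides = list()) {
  structure(list(
    seed = as.integer(seed), n_manual = n_manual, n_powered = n_powered,
    n_instructed = n_instructed, bin_s = bin_s,
    thresholds = angle_thresholds(molar_deg, anterior_deg),
    alpha = alpha, margin_s = margin_s, noise = noise,
    session_duration_mean_s = session_duration_mean_s,
    profile_overrides = profile_overrides
  ), class = "pipeline_config")
}

#' Aggregate and analyse one paired session
#'
#' Rasterizes the VO events, re-derives MT surfaces from the angle channel,
#' bins both streams onto the common grid, pairs them, and computes the
#' per-session agreement and metrics.
#'
#' @param vo,mt the VO (events) and MT (samples) [session_stream()]s.
#' @param bin_s aggregation bin, seconds.
#' @param thresholds [angle_thresholds()] for the MT surface classifier; use
#'   `NULL` to keep the recorded MT surfaces.
#' @return list with `vo_intervals`, `mt_intervals`, `paired`,
#'   `matching_pct`, and `metrics` (two rows, one per source).
#' @export
analyse_session <- function(vo, mt, bin_s = 0.5, thresholds = angle_thresholds()) {
  if (!is.null(thresholds)) mt <- classify_stream_surfaces(mt, thresholds)
  vo_int <- bin_stream(vo, bin_s)
  mt_int <- bin_stream(mt, bin_s)
  paired <- suppressWarnings(pair_streams(vo_int, mt_int))
  list(
    vo_intervals = vo_int, mt_intervals = mt_int, paired = paired,
    matching_pct = matching_proportion(paired),
    metrics = bind_rows(session_metrics(vo_int), session_metrics(mt_int))
  )
}

#' Aggregate and analyse a whole simulated study
#'
#' Maps [analyse_session()] over every session of a [simulate_study()]
#' result and pools the outputs.
#'
#' @param study a `brushing_study`.
#' @param bin_s aggregation bin, seconds.
#' @param thresholds [angle_thresholds()] for the MT surface classifier.
#' @return list with `metrics` (per session x source), `agreement` (per
#'   session), `paired` (list of paired tables), and `n_intervals` (total
#'   paired coded intervals, baseline sessions).
#' @export
analyse_study <- function(study, bin_s = 0.5, thresholds = angle_thresholds()) {
  stopifnot(inherits(study, "brushing_study"))
  ss <- study$sessions
  res <- lapply(seq_len(nrow(ss)), function(i) {
    analyse_session(ss$vo[[i]], ss$mt[[i]], bin_s, thresholds)
  })
  agreement <- tibble(
    subject_id = ss$subject_id, session = ss$session, brush = ss$brush,
    matching_pct = vapply(res, `[[`, numeric(1), "matching_pct")
  )
  metrics <- bind_rows(lapply(res, `[[`, "metrics"))
  paired <- lapply(res, `[[`, "paired")
  names(paired) <- paste(ss$subject_id, ss$session, sep = "_")
  base <- ss$session == "baseline"
  n_intervals <- sum(vapply(paired[base], function(p) sum(p$coded), numeric(1)))
  list(metrics = metrics, agreement = agreement, paired = paired,
       n_intervals = n_intervals)
}

#' Run the complete synthetic study end to end
#'
#' One deterministic command chaining simulation, aggregation, agreement,
#' metrics and statistics, writing every intermediate and final table as
#' delimited text into `out_dir`:
#'
#' * `manifest.json` — configuration echo, package version, per-stage record
#'   counts, and flagged-interval counts;
#' * `streams/` — one `vo_events` and one `mt_samples` file per session;
#' * `intervals.csv`, `paired_intervals.csv` — the aggregated grids;
#' * `agreement_sessions.csv`, `agreement_summary.csv`,
#'   `matching_histogram.csv` — per-session and study-level agreement;
#' * `confusion_matrix.csv`, `heatmap_table.csv` — pooled baseline confusion
#'   structure;
#' * `metrics.csv` — per-session outcome measures;
#' * `report_*.csv` — the inferential tables.
#'
#' Identical configurations (including the master seed) produce identical
#' outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param write_streams also write every per-session stream file (default
#'   TRUE; disable to save space in large runs).
#' @return invisibly, a list with the in-memory results (`study` config,
#'   `agreement`, `summary`, `confusion`, `metrics`, `report`, `paths`).
#' @export
run_full_study <- function(out_dir, config = pipeline_config(),
                           write_streams = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(
    n_manual = config$n_manual, n_powered = config$n_powered,
    n_instructed = config$n_instructed, seed = config$seed,
    noise = config$noise,
    session_duration_mean_s = config$session_duration_mean_s,
    profile_overrides = config$profile_overrides,
    thresholds = config$thresholds
  )
  if (write_streams) {
    sdir <- file.path(out_dir, "streams")
    dir.create(sdir, showWarnings = FALSE)
    for (i in seq_len(nrow(study$sessions))) {
      tag <- paste(study$sessions$subject_id[i], study$sessions$session[i], sep = "_")
      write_session_stream(study$sessions$vo[[i]], file.path(sdir, paste0(tag, "_vo.csv")))
      write_session_stream(study$sessions$mt[[i]], file.path(sdir, paste0(tag, "_mt.csv")))
    }
  }
  ana <- analyse_study(study, config$bin_s, config$thresholds)

  intervals_long <- bind_rows(lapply(ana$paired, function(p) {
    tibble(subject_id = attr(p, "subject_id"), session = attr(p, "session"),
           index = p$index, start_s = p$start_s,
           vo_label = p$vo_label, mt_label = p$mt_label, coded = p$coded)
  }))
  base_a <- ana$agreement[ana$agreement$session == "baseline", ]
  summary <- matching_distribution(base_a$matching_pct)
  base_paired <- ana$paired[vapply(ana$paired, function(p)
    attr(p, "session") == "baseline", logical(1))]
  confusion <- confusion_matrix(base_paired)
  heat <- heatmap_table(confusion)
  report <- run_study_analysis(ana$metrics, ana$agreement, config$alpha)

  p <- function(...) file.path(out_dir, ...)
  tt_write_table(intervals_long, p("paired_intervals.csv"))
  tt_write_table(ana$agreement, p("agreement_sessions.csv"))
  tt_write_table(summary$summary, p("agreement_summary.csv"))
  tt_write_table(summary$histogram, p("matching_histogram.csv"))
  cm_df <- as.data.frame(unclass(confusion))
  cm_df <- cbind(vo = rownames(cm_df), cm_df)
  tt_write_table(cm_df, p("confusion_matrix.csv"))
  tt_write_table(heat, p("heatmap_table.csv"))
  tt_write_table(ana$metrics, p("metrics.csv"))
  for (nm in c("brush_matching", "area_durations", "vo_vs_mt",
               "events_correlation", "instruction_effects")) {
    if (!is.null(report[[nm]])) {
      tt_write_table(report[[nm]], p(paste0("report_", nm, ".csv")))
    }
  }
  manifest <- list(
    package_version = as.character(packageVersion("toothtrack")),
    config = list(
      seed = config$seed, n_manual = config$n_manual,
      n_powered = config$n_powered, n_instructed = config$n_instructed,
      bin_s = config$bin_s,
      molar_deg = config$thresholds$molar_deg,
      anterior_deg = config$thresholds$anterior_deg,
      alpha = config$alpha, margin_s = config$margin_s,
      session_duration_mean_s = config$session_duration_mean_s,
      noise = unclass(config$noise)
    ),
    counts = list(
      sessions = nrow(study$sessions),
      baseline_sessions = sum(study$sessions$session == "baseline"),
      post_instruction_sessions = sum(study$sessions$session == "post_instruction"),
      paired_intervals_total = nrow(intervals_long),
      paired_intervals_coded = sum(intervals_long$coded),
      paired_intervals_uncoded_flagged = sum(!intervals_long$coded),
      pooled_baseline_coded_intervals = ana$n_intervals
    ),
    skipped_comparisons = report$skipped
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(config = config, agreement = ana$agreement, summary = summary,
                 confusion = confusion, metrics = ana$metrics, report = report,
                 n_intervals = ana$n_intervals, paths = out_dir))
}
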