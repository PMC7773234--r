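.mmm <- function(x) sprintf("%.2f (%.2f; %.2f)", median(x), min(x), max(x))

#' Mann-Whitney U comparison of two independent groups
#'
#' Two-sided rank-sum test: exact when the smaller group has at most 8
#' untied observations, otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @param label optional comparison label carried into the result.
#' @return one-row tibble: `comparison`, group sizes, `statistic` (U for
#'   group A), `p_value`, `method`, and median (min; max) summaries.
#' @export
mann_whitney <- function(group_a, group_b, label = "A_vs_B") {
  if (length(group_a) == 0 || length(group_b) == 0) {
    tt_validation_error("both groups must be non-empty")
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- min(length(group_a), length(group_b)) <= 8 && !ties
  ht <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                     correct = TRUE))
  tibble(
    comparison = label,
    n_a = length(group_a), n_b = length(group_b),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (exact) "exact" else "normal_approx",
    summary_a = .mmm(group_a), summary_b = .mmm(group_b),
    median_a = median(group_a), median_b = median(group_b)
  )
}

#' Wilcoxon signed-rank test of paired differences
#'
#' Two-sided; zero differences are dropped before ranking (classical
#' convention), reported in `n_zero`. Exact null distribution for at most 25
#' untied non-zero differences, normal approximation otherwise.
#'
#' @param differences numeric vector of paired differences.
#' @param label optional comparison label.
#' @return one-row tibble with `statistic` (V, the positive-rank sum),
#'   `p_value`, `n`, `n_zero`, `method` and a median (min; max) summary.
#' @export
wilcoxon_signed_rank <- function(differences, label = "paired") {
  d <- differences[differences != 0]
  n_zero <- length(differences) - length(d)
  if (length(d) == 0) {
    tt_validation_error("all paired differences are zero: signed-rank test degenerate")
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  tibble(
    comparison = label,
    n = length(d), n_zero = n_zero,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (exact) "exact" else "normal_approx",
    summary_d = .mmm(differences), median_d = median(differences)
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; constant input is an error
#' (the correlation is undefined).
#'
#' @param x,y equal-length numeric vectors, length at least 3.
#' @param label optional label.
#' @return one-row tibble with `rho`, `p_value` and `n`.
#' @export
spearman_rho <- function(x, y, label = "correlation") {
  if (length(x) != length(y) || length(x) < 3) {
    tt_validation_error("spearman_rho needs equal-length vectors of length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    tt_validation_error("correlation undefined for constant input")
  }
  ties <- any(duplicated(x)) || any(duplicated(y))
  ht <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = !ties))
  tibble(comparison = label, n = length(x),
         rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Holm (step-down Bonferroni) adjustment of p-values
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values in the input order; each at least the raw value,
#'   at most the plain Bonferroni value, capped at 1.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))  # 0.03, 0.04, 0.04
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    tt_validation_error("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

#' Equivalence check via the two-sided 90% confidence interval
#'
#' Computes the t-based two-sided confidence interval (90% by default, dual
#' to two one-sided tests at 5%) of the mean paired difference and declares
#' equivalence when the whole interval lies within the margin band.
#'
#' @param differences numeric vector of paired differences, seconds (n >= 2).
#' @param margin_s equivalence margin in seconds (default 8.0, i.e. the band
#'   `[-8, 8]`).
#' @param level confidence level of the two-sided interval (default 0.90).
#' @return one-row tibble: `mean_difference_s`, `ci_low_s`, `ci_high_s`,
#'   `margin_s`, `equivalent`.
#' @export
equivalence_ci <- function(differences, margin_s = 8.0, level = 0.90) {
  if (length(differences) < 2) tt_validation_error("equivalence CI needs n >= 2")
  if (sd(differences) == 0) {
    ci <- rep(mean(differences), 2)
  } else {
    ci <- t.test(differences, conf.level = level)$conf.int
  }
  tibble(
    n = length(differences),
    mean_difference_s = mean(differences),
    ci_low_s = ci[1], ci_high_s = ci[2],
    margin_s = margin_s,
    equivalent = ci[1] >= -margin_s && ci[2] <= margin_s
  )
}

#' Full inferential report of a paired-observation study
#'
#' Runs the study's comparison battery on per-session metrics and agreement
#' tables:
#'
#' 1. manual-versus-powered comparison of the per-session matching
#'    proportions (Mann-Whitney U, baseline sessions);
#' 2. per-area VO-versus-MT duration comparisons across the 18 areas
#'    (Wilcoxon signed-rank, Holm-adjusted over the 18 tests);
#' 3. VO-versus-MT comparisons of event counts and TSI per brush type
#'    (Wilcoxon signed-rank) with the Spearman correlation of the two
#'    sources' event counts;
#' 4. baseline-versus-post-instruction comparisons of TSI, isochronicity,
#'    consistency and events per brush type and source (Wilcoxon
#'    signed-rank on within-subject differences).
#'
#' Comparisons whose required sessions are missing are skipped and listed in
#' the `skipped` element.
#'
#' @param metrics per-session metrics tibble as stacked [session_metrics()]
#'   rows (both sources).
#' @param agreement per-session agreement tibble with columns `subject_id`,
#'   `session`, `brush`, `matching_pct`.
#' @param alpha significance level (default 0.05).
#' @return a list of class `study_report` with tibbles `brush_matching`,
#'   `area_durations`, `vo_vs_mt`, `events_correlation`,
#'   `instruction_effects`, plus `alpha` and `skipped`.
#' @export
run_study_analysis <- function(metrics, agreement, alpha = 0.05) {
  skipped <- character(0)
  base_m <- metrics[metrics$session == "baseline", ]
  base_a <- agreement[agreement$session == "baseline", ]

  # (1) matching proportion by brush type
  brush_matching <- NULL
  am <- base_a$matching_pct[base_a$brush == "manual"]
  ap <- base_a$matching_pct[base_a$brush == "powered"]
  if (length(am) > 0 && length(ap) > 0) {
    brush_matching <- mann_whitney(am, ap, "matching_pct_manual_vs_powered")
  } else {
    skipped <- c(skipped, "brush_matching: need both brush arms")
  }

  # (2) per-area VO vs MT durations, Holm over the 18 areas
  area_durations <- NULL
  wide <- .vo_mt_pairs(base_m)
  if (!is.null(wide) && nrow(wide) > 1) {
    rows <- lapply(enumerate_areas(), function(a) {
      dv <- wide[[paste0("d_", a, "_VO")]]
      dm <- wide[[paste0("d_", a, "_MT")]]
      dif <- dv - dm
      if (all(dif == 0)) {
        tibble(area = a, n = length(dif), statistic = NA_real_,
               p_value = NA_real_, summary_vo = .mmm(dv), summary_mt = .mmm(dm))
      } else {
        w <- wilcoxon_signed_rank(dif, label = a)
        tibble(area = a, n = w$n + w$n_zero, statistic = w$statistic,
               p_value = w$p_value, summary_vo = .mmm(dv), summary_mt = .mmm(dm))
      }
    })
    area_durations <- bind_rows(rows)
    ok <- !is.na(area_durations$p_value)
    area_durations$p_adjusted <- NA_real_
    area_durations$p_adjusted[ok] <- holm_adjust(area_durations$p_value[ok])
    area_durations$significant <- !is.na(area_durations$p_adjusted) &
      area_durations$p_adjusted < alpha
  } else {
    skipped <- c(skipped, "area_durations: need paired VO/MT baseline sessions")
  }

  # (3) VO vs MT events and TSI per brush, plus event-count correlation
  vo_vs_mt <- NULL
  events_correlation <- NULL
  if (!is.null(wide) && nrow(wide) > 1) {
    vm_rows <- list(); ec_rows <- list()
    for (br in intersect(c("manual", "powered"), unique(wide$brush))) {
      wb <- wide[wide$brush == br, ]
      if (nrow(wb) < 2) {
        skipped <- c(skipped, sprintf("vo_vs_mt[%s]: fewer than 2 paired sessions", br))
        next
      }
      for (measure in c("events", "TSI")) {
        mv <- wb[[paste0(measure, "_VO")]]
        mm <- wb[[paste0(measure, "_MT")]]
        keep <- complete.cases(mv, mm)
        if (sum(keep) < 2 || all(mv[keep] == mm[keep])) next
        w <- wilcoxon_signed_rank(mv[keep] - mm[keep],
                                  label = sprintf("%s_VO_vs_MT_%s", measure, br))
        vm_rows[[length(vm_rows) + 1]] <- tibble(
          brush = br, measure = measure, n = w$n + w$n_zero,
          summary_vo = .mmm(mv[keep]), summary_mt = .mmm(mm[keep]),
          statistic = w$statistic, p_value = w$p_value
        )
      }
      ev_ok <- complete.cases(wb$events_VO, wb$events_MT)
      if (sum(ev_ok) >= 3 && sd(wb$events_VO[ev_ok]) > 0 && sd(wb$events_MT[ev_ok]) > 0) {
        sp <- spearman_rho(wb$events_VO[ev_ok], wb$events_MT[ev_ok],
                           label = sprintf("events_%s", br))
        ec_rows[[length(ec_rows) + 1]] <- tibble(
          brush = br, n = sp$n, rho = sp$rho, p_value = sp$p_value)
      }
    }
    if (length(vm_rows)) vo_vs_mt <- bind_rows(vm_rows)
    if (length(ec_rows)) events_correlation <- bind_rows(ec_rows)
  }

  # (4) instruction effect: baseline vs post-instruction within subject
  instruction_effects <- NULL
  post <- metrics[metrics$session == "post_instruction", ]
  if (nrow(post) > 0) {
    ie_rows <- list()
    for (br in intersect(c("manual", "powered"), unique(post$brush))) {
      for (src in c("VO", "MT")) {
        b0 <- base_m[base_m$brush == br & base_m$source == src, ]
        p1 <- post[post$brush == br & post$source == src, ]
        j <- inner_join(b0, p1, by = "subject_id", suffix = c("_b", "_pi"))
        if (nrow(j) < 2) {
          skipped <- c(skipped,
                       sprintf("instruction_effects[%s/%s]: fewer than 2 paired subjects", br, src))
          next
        }
        for (measure in c("TSI", "I", "C", "events")) {
          vb <- j[[paste0(measure, "_b")]]
          vp <- j[[paste0(measure, "_pi")]]
          keep <- complete.cases(vb, vp)
          if (sum(keep) < 2 || all(vp[keep] == vb[keep])) next
          dif <- vp[keep] - vb[keep]
          w <- wilcoxon_signed_rank(dif, label = sprintf("%s_%s_%s", measure, br, src))
          ie_rows[[length(ie_rows) + 1]] <- tibble(
            brush = br, source = src, measure = measure, n = sum(keep),
            summary_baseline = .mmm(vb[keep]),
            summary_post_instruction = .mmm(vp[keep]),
            summary_difference = .mmm(dif),
            median_difference = median(dif),
            statistic = w$statistic, p_value = w$p_value,
            significant = w$p_value < alpha
          )
        }
      }
    }
    if (length(ie_rows)) instruction_effects <- bind_rows(ie_rows)
  } else {
    skipped <- c(skipped, "instruction_effects: no post-instruction sessions")
  }

  structure(list(
    brush_matching = brush_matching,
    area_durations = area_durations,
    vo_vs_mt = vo_vs_mt,
    events_correlation = events_correlation,
    instruction_effects = instruction_effects,
    alpha = alpha, skipped = skipped
  ), class = "study_report")
}

# reshape baseline metrics to one row per subject with _VO/_MT suffixes
.vo_mt_pairs <- function(base_m) {
  vo <- base_m[base_m$source == "VO", ]
  mt <- base_m[base_m$source == "MT", ]
  if (nrow(vo) == 0 || nrow(mt) == 0) return(NULL)
  keep <- c("subject_id", "brush", "events", "TSI", "I", "C",
            paste0("d_", enumerate_areas()))
  j <- inner_join(vo[, keep], mt[, setdiff(keep, "brush")],
                  by = "subject_id", suffix = c("_VO", "_MT"))
  if (nrow(j) == 0) NULL else j
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in c("brush_matching", "area_durations", "vo_vs_mt",
               "events_correlation", "instruction_effects")) {
    tb <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.null(tb)) "skipped" else sprintf("%d rows", nrow(tb))))
  }
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
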