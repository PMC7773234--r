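#' Proportion of identically classified intervals
#'
#' The headline agreement statistic: the percentage of coded 0.5 s intervals
#' in which both sources assign the identical area (sextant and surface both
#' correct). Intervals flagged uncoded on either side are excluded from the
#' denominator.
#'
#' @param paired a `paired_intervals` table from [pair_streams()].
#' @return percentage in `[0, 100]`.
#' @export
matching_proportion <- function(paired) {
  coded <- paired[paired$coded, ]
  if (nrow(coded) == 0) {
    tt_validation_error("matching proportion undefined: no coded interval pairs")
  }
  100 * mean(coded$vo_label == coded$mt_label)
}

#' Cross-tabulate interval labels into a confusion matrix
#'
#' Rows are the video-observation labels, columns the motion-tracking labels,
#' both over the full area set including the combined codes, in the order of
#' `enumerate_areas(include_combined = TRUE)`. Counts pool over all supplied
#' sessions; only coded pairs contribute.
#'
#' @param paired a `paired_intervals` table or a list of them.
#' @return an integer matrix of class `confusion_matrix` with a
#'   `total_intervals` attribute.
#' @export
confusion_matrix <- function(paired) {
  if (inherits(paired, "paired_intervals")) paired <- list(paired)
  lv <- enumerate_areas(include_combined = TRUE)
  m <- matrix(0L, length(lv), length(lv), dimnames = list(vo = lv, mt = lv))
  for (p in paired) {
    coded <- p[p$coded, ]
    if (nrow(coded) == 0) next
    t_ <- table(factor(coded$vo_label, levels = lv),
                factor(coded$mt_label, levels = lv))
    m <- m + unclass(t_)
  }
  structure(m, class = c("confusion_matrix", "matrix", "array"),
            total_intervals = sum(m))
}

#' Adjacency class of a pair of area codes
#'
#' Classifies a (VO, MT) label pair for mismatch severity:
#'
#' * `match` — identical codes;
#' * `adjacent` — plausible boundary confusions: same surface on neighbouring
#'   sextants (consecutive within an arch, or the vertically opposing
#'   closed-jaw pairs), occlusal/incisal versus a smooth surface of the same
#'   sextant, or a combined code versus the vestibular area of one of its
#'   member sextants;
#' * `non_adjacent` — everything else (notably vestibular versus oral, and
#'   opposite sides of the mouth), the problematic confusions.
#'
#' The classification is symmetric in its arguments.
#'
#' @param a,b character vectors of area codes (recycled to common length).
#' @return character vector with values `match`, `adjacent`, `non_adjacent`.
#' @examples
#' adjacency_class("0102", "0202")  # neighbouring sextants -> adjacent
#' adjacency_class("0102", "0103")  # vestibular vs oral    -> non_adjacent
#' adjacency_class("0101", "0102")  # occlusal vs smooth    -> adjacent
#' @export
adjacency_class <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  parse_area_code(a); parse_area_code(b)
  one <- function(x, y) {
    if (x == y) return("match")
    sxx <- area_sextant(x); sxy <- area_sextant(y)
    sfx <- area_surface(x); sfy <- area_surface(y)
    comb_x <- sxx %in% names(.combined_pairs)
    comb_y <- sxy %in% names(.combined_pairs)
    if (comb_x || comb_y) {
      # a combined code is adjacent to each member sextant's vestibular area
      if (comb_x && !comb_y && sfy == "02" && sxy %in% .combined_pairs[[sxx]]) {
        return("adjacent")
      }
      if (comb_y && !comb_x && sfx == "02" && sxx %in% .combined_pairs[[sxy]]) {
        return("adjacent")
      }
      return("non_adjacent")
    }
    if (sfx == sfy && sxy %in% .sextant_neighbours[[sxx]]) return("adjacent")
    if (sxx == sxy && (sfx == "01" || sfy == "01")) return("adjacent")
    "non_adjacent"
  }
  vapply(seq_len(n), function(i) one(a[i], b[i]), character(1))
}

#' Annotated off-diagonal table of a confusion matrix (heat-map export)
#'
#' The diagonal (matches) is excluded; cells with zero mismatches are
#' omitted. Each remaining cell carries its count, a grey intensity
#' proportional to the count (1 for the largest cell), and its
#' [adjacency_class()] so that non-adjacent (problematic) confusions can be
#' shaded differently.
#'
#' @param confusion a [confusion_matrix()].
#' @return tibble with columns `vo`, `mt`, `count`, `intensity`, `class`.
#' @export
heatmap_table <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_matrix"))
  m <- unclass(confusion)
  off <- which(m > 0 & row(m) != col(m), arr.ind = TRUE)
  if (nrow(off) == 0) {
    return(tibble(vo = character(0), mt = character(0), count = integer(0),
                  intensity = numeric(0), class = character(0)))
  }
  counts <- m[off]
  tibble(
    vo = rownames(m)[off[, 1]],
    mt = colnames(m)[off[, 2]],
    count = as.integer(counts),
    intensity = counts / max(counts),
    class = adjacency_class(rownames(m)[off[, 1]], colnames(m)[off[, 2]])
  ) |> arrange(desc(count))
}

#' Plot the mismatch heat map
#'
#' Grey tiles shade mismatch counts (diagonal omitted); non-adjacent
#' confusions are drawn in red. Requires ggplot2.
#'
#' @param confusion a [confusion_matrix()].
#' @return a ggplot object.
#' @export
plot_confusion_heatmap <- function(confusion) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_confusion_heatmap() requires the ggplot2 package")
  }
  ht <- heatmap_table(confusion)
  lv <- enumerate_areas(include_combined = TRUE)
  ht$vo <- factor(ht$vo, levels = rev(lv))
  ht$mt <- factor(ht$mt, levels = lv)
  ht$fill <- ifelse(ht$class == "non_adjacent", "non_adjacent", "adjacent")
  ggplot2::ggplot(ht, ggplot2::aes(x = mt, y = vo)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = intensity, fill = fill)) +
    ggplot2::geom_text(ggplot2::aes(label = count), size = 2.5) +
    ggplot2::scale_fill_manual(values = c(adjacent = "grey20", non_adjacent = "red3")) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(x = "motion tracking", y = "video observation",
                  alpha = "relative count", fill = "confusion class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Unweighted Cohen's kappa between two coded sequences
#'
#' Chance-corrected agreement on the requested projection of the area code:
#' the full `area`, the `sextant` digits only, or the `surface` digits only.
#' Pairs where either label is uncoded are excluded. If both sequences are
#' constant and identical, expected agreement is 1 and kappa is returned as 1
#' with a warning.
#'
#' @param codes_a,codes_b equal-length character vectors of labels.
#' @param dimension `"area"`, `"sextant"` or `"surface"`.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(codes_a, codes_b,
                        dimension = c("area", "sextant", "surface")) {
  dimension <- match.arg(dimension)
  if (length(codes_a) != length(codes_b) || length(codes_a) == 0) {
    tt_validation_error("cohen_kappa needs two equal-length, non-empty sequences")
  }
  keep <- !is_uncoded(codes_a) & !is_uncoded(codes_b)
  a <- codes_a[keep]; b <- codes_b[keep]
  if (length(a) == 0) tt_validation_error("no coded pairs for kappa")
  proj <- switch(dimension, area = identity, sextant = area_sextant,
                 surface = area_surface)
  a <- proj(a); b <- proj(b)
  lv <- union(a, b)
  po <- mean(a == b)
  pe <- sum((table(factor(a, lv)) / length(a)) * (table(factor(b, lv)) / length(b)))
  if (isTRUE(all.equal(pe, 1))) {
    warning("expected agreement is 1 (constant identical sequences); kappa defined as 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Distribution summary of per-session matching proportions
#'
#' @param per_session_pcts numeric vector of per-session matching percentages.
#' @return a list of class `agreement_summary`: `summary`, a one-row tibble
#'   with the median (min; max) and the percentage of sessions reaching at
#'   least 80% and at least 90% matches (inclusive thresholds), and
#'   `histogram`, counts over 2.5-percentage-point bins for plotting.
#' @export
matching_distribution <- function(per_session_pcts) {
  x <- per_session_pcts
  if (length(x) == 0 || any(!is.finite(x)) || any(x < 0 | x > 100)) {
    tt_validation_error("per-session percentages must be finite values in [0, 100]")
  }
  breaks <- seq(0, 100, by = 2.5)
  # half-open bins [low, high); 100 falls into the last bin
  bin <- pmin(findInterval(x, breaks), length(breaks) - 1L)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  structure(list(
    summary = tibble(
      n_sessions = length(x),
      median_pct = median(x), min_pct = min(x), max_pct = max(x),
      fraction_ge_80 = 100 * mean(x >= 80),
      fraction_ge_90 = 100 * mean(x >= 90)
    ),
    histogram = tibble(bin_low = head(breaks, -1), bin_high = breaks[-1],
                       count = counts,
                       proportion = counts / length(x))
  ), class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<agreement_summary> %d sessions: median %.1f%% (min %.1f; max %.1f); >=80%%: %.1f%%, >=90%%: %.1f%%\n",
    s$n_sessions, s$median_pct, s$min_pct, s$max_pct,
    s$fraction_ge_80, s$fraction_ge_90))
  invisible(x)
}
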