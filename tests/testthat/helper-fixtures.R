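# fixture builders and independent oracles shared across test files

# hand-build a coded_intervals tibble (one label per bin)
fake_intervals <- function(labels, bin_s = 0.5, source = "VO",
                           subject_id = "S001", session = "baseline",
                           brush = "manual") {
  n <- length(labels)
  out <- tibble::tibble(
    index = 0:(n - 1L),
    start_s = (0:(n - 1L)) * bin_s,
    end_s = (1:n) * bin_s,
    label = labels,
    support = ifelse(is_uncoded(labels), 0L, 1L)
  )
  structure(out, class = c("coded_intervals", class(out)),
            subject_id = subject_id, session = session, source = source,
            brush = brush, bin_s = bin_s)
}

fake_paired <- function(vo, mt, bin_s = 0.5, subject_id = "S001",
                        session = "baseline", brush = "manual") {
  n <- length(vo)
  out <- tibble::tibble(index = 0:(n - 1L), start_s = (0:(n - 1L)) * bin_s,
                        vo_label = vo, mt_label = mt,
                        coded = !is_uncoded(vo) & !is_uncoded(mt))
  structure(out, class = c("paired_intervals", class(out)),
            subject_id = subject_id, session = session, brush = brush,
            bin_s = bin_s)
}

vo_stream <- function(starts, ends, areas, ...) {
  session_stream(tibble::tibble(start_s = starts, end_s = ends, area = areas),
                 subject_id = "S001", session = "baseline", source = "VO",
                 brush = "manual", ...)
}

mt_stream <- function(t, areas, angle = NULL, region = NULL, ...) {
  rec <- tibble::tibble(t_s = t, area = areas)
  if (!is.null(angle)) rec$angle_deg <- angle
  if (!is.null(region)) rec$region <- region
  session_stream(rec, subject_id = "S001", session = "baseline", source = "MT",
                 brush = "manual", ...)
}

# a short profile for fast property runs (not the study defaults)
quick_profile <- function(total_s = 40, ...) {
  make_profile("habitual", overrides = utils::modifyList(
    list(total_duration_s = total_s), list(...)))
}

# --- independent oracles -----------------------------------------------------

# brute-force per-interval majority with first-in-time tie-break
oracle_majority <- function(labels) {
  labels <- labels[!is_uncoded(labels)]
  if (length(labels) == 0) return(uncoded_label())
  best <- NULL; best_n <- -1L; best_first <- Inf
  for (l in unique(labels)) {
    n_l <- sum(labels == l); f_l <- which(labels == l)[1]
    if (n_l > best_n || (n_l == best_n && f_l < best_first)) {
      best <- l; best_n <- n_l; best_first <- f_l
    }
  }
  best
}

# literal transcriptions of the systematics formulas
oracle_consistency <- function(b, x, i, n) max(0, (1 - b / x) * (i / n))
oracle_isochronicity <- function(d, x) {
  n <- length(d)
  1 - (n / (2 * (n - 1))) * sum(abs(d / x - 1 / n))
}

# exact two-sided Mann-Whitney p by full enumeration of rank splits
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  pl <- mean(us <= u_obs); pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# exact two-sided signed-rank p by enumeration of all sign patterns
oracle_sr_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  pl <- mean(vs <= v_obs); pu <- mean(vs >= v_obs)
  min(1, 2 * min(pl, pu))
}

# direct kappa from observed and chance agreement
oracle_kappa <- function(a, b) {
  lv <- union(a, b)
  po <- mean(a == b)
  pe <- sum((table(factor(a, lv)) / length(a)) * (table(factor(b, lv)) / length(b)))
  (po - pe) / (1 - pe)
}

# transitions of a label sequence restricted to a set, runs collapsed
oracle_events <- function(labels, set) {
  x <- labels[labels %in% set]
  if (length(x) <= 1) return(0L)
  r <- rle(x)
  length(r$values) - 1L
}
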