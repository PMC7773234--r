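#' Read a session stream from a delimited text file
#'
#' Two dialects are supported, both comma-separated with a header row and
#' optional leading comment lines of the form `# key=value`:
#'
#' * `vo_events`: columns `subject_id, session, brush, source, start_s,
#'   end_s, area` — one row per coded event.
#' * `mt_samples`: columns `subject_id, session, brush, source, t_s, area`
#'   plus optional `angle_deg` and `region` (`molar`/`anterior`) — one row
#'   per sensor sample.
#'
#' A `# sync_offset_s=<float>` comment gives the session start on the
#' recorder's clock; it is subtracted from all times at read time so that
#' streams are always expressed in seconds from session start. Optional
#' `# session_start_s=` / `# session_end_s=` comments carry the session span
#' (already in session clock); otherwise the span is inferred from the
#' records.
#'
#' @param path file path.
#' @param dialect `"vo_events"` or `"mt_samples"`.
#' @return a [session_stream()].
#' @export
read_session_stream <- function(path, dialect = c("vo_events", "mt_samples")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) tt_format_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  n_head <- if (any(!is_comment)) which(!is_comment)[1] - 1L else length(lines)
  meta <- list(sync_offset_s = 0, session_start_s = NA_real_, session_end_s = NA_real_)
  for (cl in lines[seq_len(n_head)]) {
    m <- regmatches(cl, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*(-?[0-9.]+)", cl))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta)) meta[[m[2]]] <- as.numeric(m[3])
  }
  body <- lines[!is_comment]
  if (length(body) == 0) tt_format_error(sprintf("no header row in %s", path))
  # read everything as character (preserves leading zeros of area codes),
  # then coerce the numeric columns
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", stringsAsFactors = FALSE)
  for (nc in intersect(c("start_s", "end_s", "t_s", "angle_deg"), names(df))) {
    df[[nc]] <- as.numeric(df[[nc]])
  }
  need <- c("subject_id", "session", "brush", "source",
            if (dialect == "vo_events") c("start_s", "end_s") else "t_s", "area")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    tt_format_error(sprintf("%s: missing mandatory column(s): %s",
                            path, paste(missing_cols, collapse = ", ")))
  }
  line_of <- function(i) n_head + 1L + i  # comments + header + record index
  if (nrow(df) > 0) {
    if (dialect == "mt_samples" && nrow(df) > 1 && any(diff(df$t_s) <= 0)) {
      bad <- which(diff(df$t_s) <= 0)[1] + 1L
      tt_format_error(sprintf("%s: non-monotonic sample time at line %d",
                              path, line_of(bad)))
    }
    if (dialect == "vo_events") {
      o <- order(df$start_s)
      if (any(df$end_s[o][-nrow(df)] - 1e-9 > df$start_s[o][-1])) {
        bad <- o[which(df$end_s[o][-nrow(df)] - 1e-9 > df$start_s[o][-1])[1] + 1L]
        tt_format_error(sprintf("%s: overlapping events at line %d",
                                path, line_of(bad)))
      }
    }
  } else {
    warning(sprintf("%s: valid header but zero records", path))
  }
  off <- meta$sync_offset_s
  tcols <- intersect(c("start_s", "end_s", "t_s"), names(df))
  for (tc in tcols) df[[tc]] <- df[[tc]] - off
  first <- function(col, default) if (nrow(df) > 0) df[[col]][1] else default
  rec_cols <- intersect(c("start_s", "end_s", "t_s", "area", "angle_deg", "region"),
                        names(df))
  session_stream(
    records = df[, rec_cols, drop = FALSE],
    subject_id = first("subject_id", "unknown"),
    session = first("session", "baseline"),
    source = first("source", if (dialect == "vo_events") "VO" else "MT"),
    brush = first("brush", "manual"),
    session_start_s = if (is.na(meta$session_start_s)) 0 else meta$session_start_s,
    session_end_s = if (is.na(meta$session_end_s)) NULL else meta$session_end_s
  )
}

#' Write a session stream to its delimited text dialect
#'
#' The dialect is chosen from the stream's kind (events write `vo_events`,
#' samples write `mt_samples`). Times are written with millisecond precision,
#' angles to 0.01 degrees; optional columns that are absent from the stream
#' are omitted from the file. `read_session_stream()` on the result
#' reproduces the stream (round-trip contract).
#'
#' @param stream a [session_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_stream <- function(stream, path) {
  stopifnot(inherits(stream, "session_stream"))
  rec <- stream$records
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# sync_offset_s=0.000",
    sprintf("# session_start_s=%.3f", stream$session_start_s),
    sprintf("# session_end_s=%.3f", stream$session_end_s)
  ), con)
  meta <- list(subject_id = stream$subject_id, session = stream$session,
               brush = stream$brush, source = stream$source)
  if (stream$kind == "events") {
    cols <- c("start_s", "end_s", "area")
  } else {
    cols <- c("t_s", "area",
              intersect(c("angle_deg", "region"), names(rec)))
  }
  header <- c(names(meta), cols)
  writeLines(paste(header, collapse = ","), con)
  if (nrow(rec) > 0) {
    fmt_col <- function(col) {
      v <- rec[[col]]
      if (col %in% c("start_s", "end_s", "t_s")) sprintf("%.3f", v)
      else if (col == "angle_deg") sprintf("%.2f", v)
      else as.character(v)
    }
    body <- do.call(paste, c(
      lapply(names(meta), function(nm) rep(meta[[nm]], nrow(rec))),
      lapply(cols, fmt_col),
      list(sep = ",")
    ))
    writeLines(body, con)
  }
  invisible(path)
}

# shared writer for result tables: comma-separated, 4 decimal places
tt_write_table <- function(df, path, digits = 4) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- round(df[[nm]], digits)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
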