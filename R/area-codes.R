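#' @name area-codes
#' @title The dental area coding scheme
#'
#' @description
#' The dentition is divided into six sextants and each sextant into three
#' surfaces, giving 18 brushable areas. An area code is the 4-digit string
#' `<sextant><surface>`:
#'
#' * sextant `01` upper right posterior, `02` upper anterior, `03` upper left
#'   posterior, `04` lower left posterior, `05` lower anterior, `06` lower
#'   right posterior;
#' * surface `01` occlusal/incisal, `02` vestibular (cheek/lip side), `03`
#'   oral (tongue/palate side).
#'
#' Three *combined* sextant codes — `16`, `25`, `34` — describe closed-jaw
#' brushing across the vertically opposing sextant pairs (01,06), (02,05) and
#' (03,04). Brushing with closed jaws can only touch the vestibular surface,
#' so combined sextants are valid with surface `02` only.
#'
#' Time that is not covered by any coding is carried as the explicit sentinel
#' label `"uncoded"` (see [uncoded_label()]); it is excluded from agreement
#' denominators and duration sums, never silently dropped.
NULL

.sextants <- sprintf("%02d", 1:6)
.surfaces <- c("01", "02", "03")
.combined_pairs <- list(
  "16" = c("01", "06"),
  "25" = c("02", "05"),
  "34" = c("03", "04")
)
.uncoded <- "uncoded"

# sextant adjacency: consecutive within an arch (01-02-03 upper, 04-05-06
# lower) plus the vertically opposing closed-jaw pairs
.sextant_neighbours <- list(
  "01" = c("02", "06"),
  "02" = c("01", "03", "05"),
  "03" = c("02", "04"),
  "04" = c("03", "05"),
  "05" = c("02", "04", "06"),
  "06" = c("01", "05")
)

#' Sentinel label for uncoded time
#'
#' @return The string used throughout the package to mark time covered by no
#'   coding. Uncoded intervals are excluded from agreement denominators and
#'   from all duration sums.
#' @export
uncoded_label <- function() .uncoded

#' Test for the uncoded sentinel
#'
#' @param x character vector of labels.
#' @return logical vector, `TRUE` where `x` is the uncoded sentinel.
#' @export
is_uncoded <- function(x) x == .uncoded

#' Parse and validate a 4-digit area code
#'
#' @param code character vector of 4-digit codes, e.g. `"0102"` (upper right
#'   posterior sextant, vestibular surface) or the closed-jaw combined code
#'   `"1602"`.
#' @return the validated codes, invisibly identical to the input.
#'   Malformed strings raise a format error; digit pairs outside the coding
#'   scheme (or a combined sextant with a non-vestibular surface) raise a
#'   validation error naming the offending pair.
#' @examples
#' parse_area_code("0102")
#' parse_area_code(c("0603", "2502"))
#' @export
parse_area_code <- function(code) {
  if (!is.character(code)) {
    tt_format_error("area codes must be character strings")
  }
  bad_form <- is.na(code) | nchar(code) != 4L | !grepl("^[0-9]{4}$", code)
  if (any(bad_form)) {
    tt_format_error(sprintf(
      "malformed area code(s): %s (expected 4 decimal digits)",
      paste(unique(code[bad_form]), collapse = ", ")
    ))
  }
  sx <- substr(code, 1L, 2L)
  sf <- substr(code, 3L, 4L)
  bad_sf <- !(sf %in% .surfaces)
  if (any(bad_sf)) {
    tt_validation_error(sprintf(
      "unknown surface code(s): %s (valid: 01, 02, 03)",
      paste(unique(sf[bad_sf]), collapse = ", ")
    ))
  }
  combined <- sx %in% names(.combined_pairs)
  bad_sx <- !(sx %in% .sextants) & !combined
  if (any(bad_sx)) {
    tt_validation_error(sprintf(
      "unknown sextant code(s): %s (valid: 01-06 or combined 16, 25, 34)",
      paste(unique(sx[bad_sx]), collapse = ", ")
    ))
  }
  bad_comb <- combined & sf != "02"
  if (any(bad_comb)) {
    tt_validation_error(sprintf(
      "combined sextant(s) %s only valid with vestibular surface 02 (got surface %s)",
      paste(unique(sx[bad_comb]), collapse = ", "),
      paste(unique(sf[bad_comb]), collapse = ", ")
    ))
  }
  invisible(code)
}

#' Enumerate the area code space
#'
#' @param include_combined also append the three closed-jaw combined codes
#'   `1602`, `2502`, `3402` after the 18 single-sextant areas.
#' @return character vector of area codes in sextant-major order
#'   (`0101, 0102, 0103, 0201, ...`); length 18, or 21 with combined codes.
#' @examples
#' enumerate_areas()            # the 18 single-sextant areas
#' enumerate_areas(TRUE)        # plus 1602, 2502, 3402
#' @export
enumerate_areas <- function(include_combined = FALSE) {
  base <- as.vector(t(outer(.sextants, .surfaces, paste0)))
  if (isTRUE(include_combined)) c(base, combined_codes()) else base
}

#' The closed-jaw combined vestibular codes
#'
#' @return `c("1602", "2502", "3402")`.
#' @export
combined_codes <- function() paste0(names(.combined_pairs), "02")

#' The 12 smooth-surface areas used for systematics scoring
#'
#' Vestibular and oral surfaces of all six sextants; occlusal/incisal areas
#' are excluded from consistency, isochronicity and TSI.
#'
#' @return character vector of 12 area codes in sextant-major order.
#' @export
smooth_areas <- function() {
  a <- enumerate_areas()
  a[substr(a, 3, 4) %in% c("02", "03")]
}

#' Sextant and surface projections of an area code
#'
#' @param code character vector of area codes (combined codes allowed).
#' @return 2-character sextant or surface codes.
#' @export
area_sextant <- function(code) substr(code, 1L, 2L)

#' @rdname area_sextant
#' @export
area_surface <- function(code) substr(code, 3L, 4L)

# member single sextants of a (possibly combined) sextant code
.sextant_members <- function(sx) {
  if (sx %in% names(.combined_pairs)) .combined_pairs[[sx]] else sx
}

#' The canonical systematic brushing sequence
#'
#' The instruction order used for systematic toothbrushing: all six oral
#' surfaces first (lower right posterior, lower anterior, lower left
#' posterior, then the upper jaw posterior-to-anterior-to-contralateral),
#' followed by the six vestibular surfaces (upper right posterior around the
#' arches to lower right posterior), and finally the occlusal surfaces. All
#' 12 smooth areas appear exactly once before any occlusal area.
#'
#' @return character vector of 18 area codes in instruction order.
#' @examples
#' systematic_sequence()[1]  # starts on a lower-jaw oral surface
#' @export
systematic_sequence <- function() {
  c(
    "0603", "0503", "0403", "0103", "0203", "0303",  # oral, lower then upper
    "0102", "0202", "0302", "0402", "0502", "0602",  # vestibular around arches
    "0101", "0201", "0301", "0401", "0501", "0601"   # occlusal last
  )
}

#' Angle thresholds for occlusal-versus-smooth classification
#'
#' Motion tracking cannot observe which bristles touch the tooth; instead the
#' inclination of the brush-head axis relative to the occlusal plane is
#' thresholded. The defaults (20 degrees on molars, 13 degrees on anterior
#' teeth) discriminate occlusal/incisal from smooth-surface brushing.
#'
#' @param molar_deg threshold in degrees for posterior (molar) sextants.
#' @param anterior_deg threshold in degrees for the anterior sextants.
#' @return a list of class `angle_thresholds`.
#' @export
angle_thresholds <- function(molar_deg = 20, anterior_deg = 13) {
  if (!is.numeric(molar_deg) || !is.numeric(anterior_deg) ||
      molar_deg <= 0 || molar_deg >= 90 || anterior_deg <= 0 || anterior_deg >= 90) {
    tt_validation_error("angle thresholds must be strictly between 0 and 90 degrees")
  }
  structure(list(molar_deg = molar_deg, anterior_deg = anterior_deg),
            class = "angle_thresholds")
}
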