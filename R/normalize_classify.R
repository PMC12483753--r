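#' Stress level labels
#'
#' The four bands on the normalized 0-500 scale, in increasing order of
#' arousal. Band edges are lower-exclusive / upper-inclusive:
#' No stress (<= 200), Minor stress (200, 300\], High stress (300, 400\],
#' Very high stress (> 400).
#'
#' @return Character vector of the four display labels, ordered.
#' @export
stress_levels <- function() {
  c("No stress", "Minor stress", "High stress", "Very high stress")
}

#' Per-subject calibration profile
#'
#' Holds the additive calibration offset applied to filtered readings and
#' the subject-specific baseline minimum and maximum that anchor the
#' dynamic-range normalization: a calibrated reading at `b_min` maps to 0
#' and at `b_max` to 500. Degenerate profiles (`b_max <= b_min`) are
#' rejected at construction so the normalization denominator is always
#' positive.
#'
#' @param c_offset Calibration offset, signal units (may be negative).
#' @param b_min,b_max Subject baseline minimum and maximum, signal units,
#'   with `b_max > b_min` strictly.
#' @return An object of class `calibration_profile`.
#' @examples
#' calibration_profile(c_offset = 0, b_min = 100, b_max = 300)
#' @export
calibration_profile <- function(c_offset = 0, b_min, b_max) {
  for (nm in c("c_offset", "b_min", "b_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (b_max <= b_min) {
    stop("invalid calibration profile: b_max must be strictly greater than b_min",
         call. = FALSE)
  }
  structure(list(c_offset = as.numeric(c_offset), b_min = as.numeric(b_min),
                 b_max = as.numeric(b_max)),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile> c_offset =", x$c_offset,
      "| b_min =", x$b_min, "| b_max =", x$b_max, "\n")
  invisible(x)
}

#' Apply the calibration offset
#'
#' Adds the per-subject offset to filtered estimates before normalization.
#'
#' @param x_est Numeric vector of filtered values.
#' @param profile A [calibration_profile()].
#' @return `x_est + c_offset`.
#' @export
apply_offset <- function(x_est, profile) {
  if (!inherits(profile, "calibration_profile")) {
    stop("`profile` must be a calibration_profile", call. = FALSE)
  }
  if (!is.numeric(x_est) || anyNA(x_est) || any(!is.finite(x_est))) {
    stop("`x_est` must be finite", call. = FALSE)
  }
  x_est + profile$c_offset
}

#' Dynamic range normalization onto the 0-500 scale
#'
#' Linearly rescales calibrated readings so that the subject's baseline
#' minimum maps to 0 and baseline maximum to 500:
#' \deqn{\mathrm{GSR}_{norm} = \frac{A_{cal} - B_{min}}{B_{max} - B_{min}} \times 500.}
#' Values falling outside \[0, 500\] (readings beyond the calibrated range)
#' are clamped, and the `clamped` column records where that happened so the
#' raw excursion is not silently lost.
#'
#' @param a_calibrated Numeric vector of calibrated (offset-adjusted) values.
#' @param profile A [calibration_profile()].
#' @return A data.frame with columns `gsr_norm` (in \[0, 500\]) and
#'   `clamped` (logical).
#' @examples
#' p <- calibration_profile(b_min = 100, b_max = 300)
#' normalize_gsr(c(100, 200, 300), p)
#' @export
normalize_gsr <- function(a_calibrated, profile) {
  if (!inherits(profile, "calibration_profile")) {
    stop("`profile` must be a calibration_profile", call. = FALSE)
  }
  if (!is.numeric(a_calibrated) || length(a_calibrated) == 0L ||
      anyNA(a_calibrated) || any(!is.finite(a_calibrated))) {
    stop("`a_calibrated` must be a non-empty finite numeric vector", call. = FALSE)
  }
  raw <- (a_calibrated - profile$b_min) / (profile$b_max - profile$b_min) * 500
  clamped <- raw < 0 | raw > 500
  data.frame(gsr_norm = pmin(pmax(raw, 0), 500), clamped = clamped)
}

#' Classify a normalized GSR value into a stress band
#'
#' Bands follow the printed inequalities exactly (lower-exclusive,
#' upper-inclusive): No stress for values <= 200, Minor stress on
#' (200, 300\], High stress on (300, 400\], Very high stress above 400.
#' Values above 500 are accepted and classify as Very high stress — field
#' devices report raw normalized values slightly beyond the calibrated
#' range — but negative values are a domain error.
#'
#' @param gsr_norm Numeric vector of non-negative normalized values.
#' @return Ordered factor over [stress_levels()].
#' @examples
#' classify_stress(c(189, 254, 378, 432))
#' @export
classify_stress <- function(gsr_norm) {
  if (!is.numeric(gsr_norm) || anyNA(gsr_norm) || any(!is.finite(gsr_norm))) {
    stop("`gsr_norm` must be finite and numeric", call. = FALSE)
  }
  if (any(gsr_norm < 0)) {
    stop("`gsr_norm` must be non-negative (normalized scale starts at 0)",
         call. = FALSE)
  }
  lv <- stress_levels()
  # left.open gives (lo, hi] bins, matching the printed upper-inclusive bands
  idx <- findInterval(gsr_norm, c(200, 300, 400), left.open = TRUE) + 1L
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Estimate a subject baseline from a resting calibration window
#'
#' The per-subject baseline anchors `b_min` and `b_max` are taken as the
#' minimum and maximum of filtered readings recorded during a calibration
#' window, optionally widened upward by a guard fraction `eps` of the span.
#' No outlier rejection is performed: a single spurious sample widens the
#' range, so calibration windows should be inspected upstream.
#'
#' @param filtered_rest_samples Numeric vector of at least `min_samples`
#'   filtered readings from the calibration window.
#' @param eps Guard fraction added to the top of the range; default 0.
#' @param min_samples Minimum acceptable window length; default 10.
#' @return A [calibration_profile()] with `c_offset = 0`.
#' @export
estimate_baseline <- function(filtered_rest_samples, eps = 0, min_samples = 10L) {
  x <- filtered_rest_samples
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("calibration samples must be finite and numeric", call. = FALSE)
  }
  if (length(x) < min_samples) {
    stop(sprintf("insufficient calibration window: %d samples, need at least %d",
                 length(x), min_samples), call. = FALSE)
  }
  b_min <- min(x)
  b_max <- max(x)
  if (b_max == b_min) {
    stop("degenerate baseline: calibration window is constant", call. = FALSE)
  }
  calibration_profile(c_offset = 0, b_min = b_min,
                      b_max = b_max + eps * (b_max - b_min))
}

#' Band counts for a table of normalized values
#'
#' Takes a table with one column of normalized values per subject and
#' returns, per subject, how many values fall in each of the four stress
#' bands. Missing cells (ragged columns stored in a rectangular table) are
#' skipped, so each column's counts sum to its number of non-missing
#' values. Non-numeric cells are an error naming the offending row and
#' column.
#'
#' @param table A data.frame, one subject per column, normalized values in
#'   cells.
#' @return A data.frame with one row per stress level (rownames are the
#'   level labels) and one column per subject.
#' @examples
#' classify_table(load_table2_fixture())
#' @export
classify_table <- function(table) {
  if (!is.data.frame(table)) stop("`table` must be a data.frame", call. = FALSE)
  lv <- stress_levels()
  out <- vapply(names(table), function(cn) {
    col <- table[[cn]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric cell at row %d, column \"%s\"", bad[1L], cn),
             call. = FALSE)
      }
      col <- num
    }
    col <- col[!is.na(col)]
    if (length(col) == 0L) return(stats::setNames(rep(0L, 4L), lv))
    tab <- table(classify_stress(col))
    stats::setNames(as.integer(tab[lv]), lv)
  }, integer(4L))
  as.data.frame(out, check.names = FALSE)
}
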