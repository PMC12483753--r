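#' Acquisition configuration
#'
#' Bundles the constants needed to interpret raw sensor output: the serial
#' calibration baseline used by the resistance curve (the no-contact analog
#' reading obtained while trimming the Grove GSR sensor's potentiometer) and
#' a display-rounding flag for the bit-depth mapping.
#'
#' @param serial_calibration Integer baseline count on the 10-bit serial
#'   scale, in (0, 1023]. Obtained during sensor calibration with no skin
#'   contact.
#' @param round_mapped Logical; if `TRUE`, [map_12bit_to_10bit()] rounds its
#'   output (half to even) for display. The analysis pipeline always consumes
#'   full precision, so this defaults to `FALSE`.
#' @return An object of class `acquisition_config`.
#' @examples
#' acquisition_config(serial_calibration = 512)
#' @export
acquisition_config <- function(serial_calibration = 512L, round_mapped = FALSE) {
  if (!is.numeric(serial_calibration) || length(serial_calibration) != 1L ||
      !is.finite(serial_calibration) ||
      serial_calibration != as.integer(serial_calibration)) {
    stop("`serial_calibration` must be a single integer count", call. = FALSE)
  }
  if (serial_calibration <= 0 || serial_calibration > 1023) {
    stop("`serial_calibration` must lie in (0, 1023]", call. = FALSE)
  }
  if (!is.logical(round_mapped) || length(round_mapped) != 1L || is.na(round_mapped)) {
    stop("`round_mapped` must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(serial_calibration = as.integer(serial_calibration),
         round_mapped = round_mapped),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("<acquisition_config> serial_calibration =", x$serial_calibration,
      "| round_mapped =", x$round_mapped, "\n")
  invisible(x)
}

#' Map 12-bit ADC counts onto the 10-bit scale
#'
#' The sensor is read at 12-bit resolution (counts 0-4095); downstream
#' filtering and normalization operate on a 10-bit scale (0-1023). The map
#' is the exact linear rescaling `adc12 * 1023 / 4095`, returned at full
#' precision: rounding is a display concern only.
#'
#' @param adc12 Integer vector of raw ADC counts in \[0, 4095\].
#' @param config Optional [acquisition_config()]; only its `round_mapped`
#'   flag is consulted.
#' @return Numeric vector of mapped values in \[0, 1023\].
#' @examples
#' map_12bit_to_10bit(c(0L, 2048L, 4095L))
#' @export
map_12bit_to_10bit <- function(adc12, config = NULL) {
  if (!is.numeric(adc12) || length(adc12) == 0L) {
    stop("`adc12` must be a non-empty numeric vector of integer counts in [0, 4095]",
         call. = FALSE)
  }
  if (anyNA(adc12) || any(!is.finite(adc12))) {
    stop("`adc12` contains missing or non-finite values; counts must be integers in [0, 4095]",
         call. = FALSE)
  }
  if (any(adc12 != floor(adc12))) {
    stop("`adc12` must be integer counts (12-bit ADC output in [0, 4095])",
         call. = FALSE)
  }
  if (any(adc12 < 0) || any(adc12 > 4095)) {
    stop("`adc12` out of range: valid 12-bit counts lie in [0, 4095]",
         call. = FALSE)
  }
  out <- adc12 * (1023 / 4095)
  if (!is.null(config) && isTRUE(config$round_mapped)) out <- round(out)
  out
}

#' Skin resistance and conductance from the serial reading
#'
#' The Grove GSR sensor sits in a voltage-divider configuration; given the
#' current analog reading and the no-contact calibration baseline, skin
#' resistance (ohms) is approximated by
#' \deqn{R = \frac{(1024 + 2\,\mathrm{SPR}) \times 10000}{\mathrm{cal} - \mathrm{SPR}}}
#' where SPR is the serial port reading and cal the serial calibration value.
#' Skin conductance (siemens) is its reciprocal. A reading at or above the
#' calibration baseline makes the denominator non-positive and is rejected:
#' the resistance is undefined there.
#'
#' @param serial_port_reading Numeric vector of analog readings, counts in
#'   \[0, 1023\], each strictly below the calibration baseline.
#' @param config An [acquisition_config()] (or a bare number, taken as the
#'   serial calibration value).
#' @return A data.frame with columns `reading`, `resistance` (ohms) and
#'   `conductance` (siemens).
#' @examples
#' skin_resistance(0, acquisition_config(512))    # 20000 ohms
#' skin_resistance(200, acquisition_config(712))  # 27812.5 ohms
#' @export
skin_resistance <- function(serial_port_reading, config = acquisition_config()) {
  if (is.numeric(config) && length(config) == 1L) {
    config <- acquisition_config(serial_calibration = config)
  }
  if (!inherits(config, "acquisition_config")) {
    stop("`config` must be an acquisition_config", call. = FALSE)
  }
  spr <- serial_port_reading
  if (!is.numeric(spr) || length(spr) == 0L || anyNA(spr) || any(!is.finite(spr))) {
    stop("`serial_port_reading` must be finite counts in [0, 1023]", call. = FALSE)
  }
  if (any(spr < 0) || any(spr > 1023)) {
    stop("`serial_port_reading` out of range: counts lie in [0, 1023]", call. = FALSE)
  }
  cal <- config$serial_calibration
  if (any(spr >= cal)) {
    stop("reading at or above calibration baseline; resistance undefined",
         call. = FALSE)
  }
  resistance <- ((1024 + 2 * spr) * 10000) / (cal - spr)
  data.frame(reading = spr,
             resistance = resistance,
             conductance = 1 / resistance)
}

#' Read a raw GSR stream from CSV
#'
#' Streams are CSV files with a header row and columns `t_ms` (timestamps in
#' milliseconds, strictly increasing) and `adc12` (integer 12-bit counts).
#' Validation failures name the offending line so malformed captures can be
#' fixed at the source.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with integer-valued columns `t_ms` and `adc12`.
#' @seealso [write_gsr_stream()]
#' @export
read_gsr_stream <- function(path) {
  if (!file.exists(path)) stop("stream file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("t_ms", "adc12") %in% names(df))) {
    stop("stream CSV must have header columns `t_ms` and `adc12`", call. = FALSE)
  }
  t_ms <- suppressWarnings(as.numeric(df$t_ms))
  adc12 <- suppressWarnings(as.numeric(df$adc12))
  # +1 for the header row: report the physical line in the file
  bad <- which(is.na(t_ms) | is.na(adc12) | adc12 != floor(adc12) |
                 adc12 < 0 | adc12 > 4095)
  if (length(bad) > 0L) {
    stop(sprintf("malformed stream row at line %d of %s (t_ms=%s, adc12=%s)",
                 bad[1L] + 1L, path, df$t_ms[bad[1L]], df$adc12[bad[1L]]),
         call. = FALSE)
  }
  if (length(t_ms) > 1L && any(diff(t_ms) <= 0)) {
    i <- which(diff(t_ms) <= 0)[1L]
    stop(sprintf("timestamps must be strictly increasing; violation at line %d of %s",
                 i + 2L, path), call. = FALSE)
  }
  data.frame(t_ms = t_ms, adc12 = as.integer(adc12))
}

#' Write a raw GSR stream to CSV
#'
#' @param stream A data.frame with columns `t_ms` and `adc12`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_gsr_stream <- function(stream, path) {
  if (!is.data.frame(stream) || !all(c("t_ms", "adc12") %in% names(stream))) {
    stop("`stream` must be a data.frame with columns `t_ms` and `adc12`",
         call. = FALSE)
  }
  utils::write.csv(stream[, c("t_ms", "adc12")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
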