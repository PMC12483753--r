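#' Pipeline configuration
#'
#' Bundles the per-stage configurations for a replay run: acquisition
#' constants, Kalman filter parameters, the subject's calibration profile,
#' and the sampling cadence.
#'
#' @param acquisition An [acquisition_config()].
#' @param kalman A [kalman_params()].
#' @param calibration A [calibration_profile()].
#' @param sample_period_ms Sampling cadence in milliseconds; default 100.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(acquisition = acquisition_config(),
                            kalman = kalman_params(),
                            calibration,
                            sample_period_ms = 100) {
  if (!inherits(acquisition, "acquisition_config")) {
    stop("`acquisition` must be an acquisition_config", call. = FALSE)
  }
  if (!inherits(kalman, "kalman_params")) {
    stop("`kalman` must be a kalman_params", call. = FALSE)
  }
  if (!inherits(calibration, "calibration_profile")) {
    stop("`calibration` must be a calibration_profile", call. = FALSE)
  }
  if (!is.numeric(sample_period_ms) || length(sample_period_ms) != 1L ||
      sample_period_ms <= 0) {
    stop("`sample_period_ms` must be a single positive number", call. = FALSE)
  }
  structure(list(acquisition = acquisition, kalman = kalman,
                 calibration = calibration,
                 sample_period_ms = sample_period_ms),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> cadence", x$sample_period_ms, "ms\n")
  print(x$acquisition); print(x$kalman); print(x$calibration)
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file has four sections mirroring the pipeline stages:
#' `acquisition` (`serial_calibration`, `round_mapped`), `kalman`
#' (`e_m`, `e_p0`, `x0`, `q`), `calibration` (`c_offset`, `b_min`,
#' `b_max`) and `pipeline` (`sample_period_ms`). Missing keys fall back to
#' the package defaults; `calibration.b_min` and `calibration.b_max` are
#' required.
#'
#' @param path Path to a YAML config file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  acq <- cfg$acquisition
  kal <- cfg$kalman
  cal <- cfg$calibration
  pip <- cfg$pipeline
  if (is.null(cal$b_min) || is.null(cal$b_max)) {
    stop("config error: calibration.b_min and calibration.b_max are required",
         call. = FALSE)
  }
  pipeline_config(
    acquisition = acquisition_config(
      serial_calibration = if (is.null(acq$serial_calibration)) 512L else acq$serial_calibration,
      round_mapped = isTRUE(acq$round_mapped)
    ),
    kalman = kalman_params(
      e_m = if (is.null(kal$e_m)) 4.0 else kal$e_m,
      e_p0 = if (is.null(kal$e_p0)) 1.0 else kal$e_p0,
      x0 = kal$x0,
      q = if (is.null(kal$q)) 0.0 else kal$q
    ),
    calibration = calibration_profile(
      c_offset = if (is.null(cal$c_offset)) 0 else cal$c_offset,
      b_min = cal$b_min, b_max = cal$b_max
    ),
    sample_period_ms = if (is.null(pip$sample_period_ms)) 100 else pip$sample_period_ms
  )
}

#' Write a pipeline configuration to a YAML file
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  yaml::write_yaml(list(
    acquisition = unclass(config$acquisition),
    kalman = Filter(Negate(is.null), unclass(config$kalman)),
    calibration = unclass(config$calibration),
    pipeline = list(sample_period_ms = config$sample_period_ms)
  ), path)
  invisible(path)
}

#' Replay a raw stream through the full pipeline
#'
#' Applies the stages in device order — 12-to-10-bit mapping, Kalman
#' filtering, calibration offset, dynamic range normalization, stress
#' classification — to every sample of a recorded (or simulated) stream.
#' Per-stage elapsed times are measured and attached as the
#' `"stage_timings"` attribute (milliseconds over the whole series); they
#' are instrumentation only and depend on the host.
#'
#' @param stream A data.frame with columns `t_ms` and `adc12`, or a path to
#'   a stream CSV readable by [read_gsr_stream()].
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per input sample and columns `t_ms`,
#'   `adc12`, `adc10`, `x_est`, `gsr_norm`, `clamped`, `level`. Empty input
#'   yields an empty data.frame with the same columns (with a warning).
#' @examples
#' prof <- calibration_profile(b_min = 250, b_max = 350)
#' cfg <- pipeline_config(calibration = prof)
#' stream <- data.frame(t_ms = c(0, 100, 200), adc12 = c(1200, 1210, 1190))
#' run_replay(stream, cfg)
#' @export
run_replay <- function(stream, config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config error: `config` must be a pipeline_config", call. = FALSE)
  }
  timings <- c(read = 0, filter = 0, normalize = 0, emit = 0)
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (is.character(stream)) stream <- read_gsr_stream(stream)
  if (!is.data.frame(stream) || !all(c("t_ms", "adc12") %in% names(stream))) {
    stop("input error: stream must have columns `t_ms` and `adc12`",
         call. = FALSE)
  }
  if (nrow(stream) == 0L) {
    warning("empty stream: no records produced")
    out <- data.frame(t_ms = numeric(), adc12 = integer(), adc10 = numeric(),
                      x_est = numeric(), gsr_norm = numeric(),
                      clamped = logical(),
                      level = factor(character(), levels = stress_levels(),
                                     ordered = TRUE))
    attr(out, "stage_timings") <- timings
    return(out)
  }
  adc10 <- map_12bit_to_10bit(stream$adc12, config$acquisition)
  timings[["read"]] <- (tic() - t0) * 1000

  t0 <- tic()
  x_est <- kalman_filter(adc10, config$kalman)
  timings[["filter"]] <- (tic() - t0) * 1000

  t0 <- tic()
  a_cal <- apply_offset(as.numeric(x_est), config$calibration)
  norm <- normalize_gsr(a_cal, config$calibration)
  level <- classify_stress(norm$gsr_norm)
  timings[["normalize"]] <- (tic() - t0) * 1000

  t0 <- tic()
  out <- data.frame(t_ms = stream$t_ms, adc12 = stream$adc12, adc10 = adc10,
                    x_est = as.numeric(x_est), gsr_norm = norm$gsr_norm,
                    clamped = norm$clamped, level = level)
  timings[["emit"]] <- (tic() - t0) * 1000
  attr(out, "stage_timings") <- timings
  out
}

#' Write pipeline records to JSONL or CSV
#'
#' @param records Output of [run_replay()].
#' @param path Output path.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"`.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) stop("`records` must be a data.frame", call. = FALSE)
  if (format == "csv") {
    rec <- records
    rec$level <- as.character(rec$level)
    utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (nrow(records) > 0L) {
      for (i in seq_len(nrow(records))) {
        row <- as.list(records[i, , drop = FALSE])
        row$level <- as.character(row$level)
        writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
      }
    }
  }
  invisible(path)
}

#' Read pipeline records from a JSONL file
#'
#' @param path Path to a JSONL file written by [write_records()].
#' @return A data.frame of pipeline records.
#' @export
read_records_jsonl <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(t_ms = numeric(), adc12 = integer(), adc10 = numeric(),
                      x_est = numeric(), gsr_norm = numeric(),
                      clamped = logical(),
                      level = factor(character(), levels = stress_levels(),
                                     ordered = TRUE)))
  }
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
  out <- do.call(rbind, rows)
  out$level <- factor(out$level, levels = stress_levels(), ordered = TRUE)
  rownames(out) <- NULL
  out
}

#' Count and fraction of records per stress level
#'
#' @param records Output of [run_replay()], or any data.frame with a
#'   `level` column over [stress_levels()].
#' @return A data.frame with columns `level`, `count`, `fraction`. Counts
#'   sum to the record count; fractions sum to 1 (all zero for empty
#'   input).
#' @export
summarize_levels <- function(records) {
  lv <- stress_levels()
  if (!is.data.frame(records) || !"level" %in% names(records)) {
    stop("`records` must be a data.frame with a `level` column", call. = FALSE)
  }
  level <- factor(as.character(records$level), levels = lv, ordered = TRUE)
  counts <- as.integer(table(level))
  n <- sum(counts)
  data.frame(level = factor(lv, levels = lv, ordered = TRUE),
             count = counts,
             fraction = if (n > 0) counts / n else rep(0, 4L))
}

#' Percent agreement between two label sequences
#'
#' The fraction of positions at which a predicted stress-level sequence
#' matches a reference sequence, as a percentage.
#'
#' @param predicted,truth Equal-length, non-empty vectors of stress levels
#'   (factors or characters).
#' @return A single number in \[0, 100\].
#' @examples
#' percent_agreement(c("No stress", "High stress"), c("No stress", "High stress"))
#' @export
percent_agreement <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("input error: `predicted` and `truth` must have equal length",
         call. = FALSE)
  }
  if (length(predicted) == 0L) {
    stop("input error: sequences must be non-empty", call. = FALSE)
  }
  100 * mean(as.character(predicted) == as.character(truth))
}
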