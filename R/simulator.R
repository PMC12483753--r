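# Internal: run expr with a locally seeded RNG, restoring global state after.
# One seeded generator per stream; the caller's RNG is never disturbed.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Internal: canonical level codes <-> display labels
.level_codes <- c(no_stress = "No stress", minor = "Minor stress",
                  high = "High stress", very_high = "Very high stress")

# Tonic elevation of each stress state, as a fraction of the subject's
# dynamic range. Chosen so that a stream normalized against a calibration
# window spanning the full range lands mid-band: 0.2 -> 100 (No stress),
# 0.5 -> 250 (Minor), 0.7 -> 350 (High), 0.9 -> 450 (Very high).
.level_fraction <- c(no_stress = 0.2, minor = 0.5, high = 0.7, very_high = 0.9)

# SCR (skin conductance response) arrival-rate multiplier per state:
# sympathetic arousal raises the nonspecific SCR rate.
.level_rate_mult <- c(no_stress = 1, minor = 2, high = 3, very_high = 4)

#' Synthetic GSR stream configuration
#'
#' Parameters of the per-subject signal model: a resting baseline with slow
#' linear drift, transient skin conductance responses (SCRs: linear rise,
#' exponential decay, exponentially distributed amplitude, Poisson arrivals
#' whose rate scales with the scheduled stress state), a state-dependent
#' tonic elevation, and additive Gaussian sensor noise. The stream opens
#' with a calibration window that sweeps the subject's full dynamic range
#' (rest, ramp to maximal response, hold, return to rest), emulating the
#' relax/stimulus procedure used to set per-subject baseline anchors.
#'
#' @param seed Integer RNG seed; identical seeds give bit-identical streams.
#' @param duration_s Total stream length in seconds, including the
#'   calibration window.
#' @param sample_period_ms Sampling cadence in milliseconds; default 100
#'   (10 Hz).
#' @param baseline_adc12 Resting signal level, 12-bit counts.
#' @param dynamic_range_adc12 Subject's response range above baseline,
#'   12-bit counts; tonic stress elevations are fractions of this range.
#' @param drift_per_min Linear baseline drift, counts per minute.
#' @param scr_rate_per_min Resting SCR arrival rate, events per minute;
#'   scaled up under stress states.
#' @param scr_amplitude Mean SCR amplitude, counts (exponential).
#' @param scr_rise_s,scr_decay_s SCR rise time and decay time constant,
#'   seconds.
#' @param noise_sd Additive Gaussian sensor noise standard deviation, counts.
#' @param calibration_window_s Length of the opening calibration sweep,
#'   seconds.
#' @param stress_state_schedule `NULL` (rest throughout) or a data.frame
#'   with columns `start_s`, `end_s`, `level` (codes `"no_stress"`,
#'   `"minor"`, `"high"`, `"very_high"`); intervals must be non-overlapping
#'   and lie within \[calibration_window_s, duration_s\]. Gaps are rest.
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(seed = 1L,
                             duration_s = 120,
                             sample_period_ms = 100,
                             baseline_adc12 = 1200,
                             dynamic_range_adc12 = 400,
                             drift_per_min = 2,
                             scr_rate_per_min = 3,
                             scr_amplitude = 15,
                             scr_rise_s = 1,
                             scr_decay_s = 4,
                             noise_sd = 8,
                             calibration_window_s = 30,
                             stress_state_schedule = NULL) {
  num1 <- function(x, nm, lo = -Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo) {
      stop("`", nm, "` must be a single finite number", if (lo > -Inf)
        paste0(" >= ", lo) else "", call. = FALSE)
    }
  }
  num1(seed, "seed"); num1(duration_s, "duration_s", 0)
  num1(sample_period_ms, "sample_period_ms")
  if (sample_period_ms <= 0) stop("`sample_period_ms` must be > 0", call. = FALSE)
  num1(baseline_adc12, "baseline_adc12", 0)
  num1(dynamic_range_adc12, "dynamic_range_adc12", 0)
  num1(drift_per_min, "drift_per_min")
  num1(scr_rate_per_min, "scr_rate_per_min", 0)
  num1(scr_amplitude, "scr_amplitude", 0)
  num1(scr_rise_s, "scr_rise_s", 0); num1(scr_decay_s, "scr_decay_s", 0)
  num1(noise_sd, "noise_sd", 0)
  num1(calibration_window_s, "calibration_window_s", 0)
  if (calibration_window_s > duration_s) {
    stop("calibration window longer than the stream", call. = FALSE)
  }
  sched <- stress_state_schedule
  if (!is.null(sched)) {
    if (!is.data.frame(sched) ||
        !all(c("start_s", "end_s", "level") %in% names(sched))) {
      stop("schedule must be a data.frame with columns start_s, end_s, level",
           call. = FALSE)
    }
    if (!all(sched$level %in% names(.level_codes))) {
      stop("schedule levels must be one of: ",
           paste(names(.level_codes), collapse = ", "), call. = FALSE)
    }
    if (any(sched$start_s < calibration_window_s) || any(sched$end_s > duration_s) ||
        any(sched$end_s <= sched$start_s)) {
      stop("schedule intervals must lie within [calibration_window_s, duration_s]",
           call. = FALSE)
    }
    sched <- sched[order(sched$start_s), , drop = FALSE]
    if (nrow(sched) > 1L &&
        any(sched$start_s[-1L] < sched$end_s[-nrow(sched)])) {
      stop("schedule intervals must be non-overlapping", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 sample_period_ms = sample_period_ms,
                 baseline_adc12 = baseline_adc12,
                 dynamic_range_adc12 = dynamic_range_adc12,
                 drift_per_min = drift_per_min,
                 scr_rate_per_min = scr_rate_per_min,
                 scr_amplitude = scr_amplitude,
                 scr_rise_s = scr_rise_s, scr_decay_s = scr_decay_s,
                 noise_sd = noise_sd,
                 calibration_window_s = calibration_window_s,
                 stress_state_schedule = sched),
            class = "simulator_config")
}

#' @export
print.simulator_config <- function(x, ...) {
  cat("<simulator_config>", x$duration_s, "s @", x$sample_period_ms,
      "ms | baseline", x$baseline_adc12, "+ range", x$dynamic_range_adc12,
      "counts | noise sd", x$noise_sd, "| seed", x$seed, "\n")
  invisible(x)
}

# Internal: piecewise-constant state code per time (seconds)
.state_at <- function(t_s, config) {
  lev <- rep("no_stress", length(t_s))
  sched <- config$stress_state_schedule
  if (!is.null(sched)) {
    for (i in seq_len(nrow(sched))) {
      lev[t_s >= sched$start_s[i] & t_s < sched$end_s[i]] <- sched$level[i]
    }
  }
  lev
}

# Internal: tonic fraction of dynamic range at each time, including the
# calibration sweep (rest 30% - ramp up 30% - hold max 10% - ramp down 30%).
.tonic_fraction <- function(t_s, config) {
  f <- .level_fraction[.state_at(t_s, config)]
  cal <- config$calibration_window_s
  if (cal > 0) {
    u <- t_s / cal
    in_cal <- t_s < cal
    fc <- numeric(sum(in_cal))
    uu <- u[in_cal]
    fc[uu < 0.3] <- 0
    ramp_up <- uu >= 0.3 & uu < 0.6
    fc[ramp_up] <- (uu[ramp_up] - 0.3) / 0.3
    fc[uu >= 0.6 & uu < 0.7] <- 1
    ramp_dn <- uu >= 0.7
    fc[ramp_dn] <- 1 - (uu[ramp_dn] - 0.7) / 0.3 * (1 - .level_fraction["no_stress"])
    f[in_cal] <- fc
  }
  unname(f)
}

#' Simulate one subject's GSR stream
#'
#' Generates a noise-free clean trace (baseline + drift + tonic stress
#' elevation + SCR pulses), adds Gaussian sensor noise, and quantizes to
#' 12-bit ADC counts. The returned object carries the clean trace and a
#' per-sample ground-truth stress label (derived from the tonic elevation,
#' so labels are also defined during the calibration sweep) for
#' parameter-recovery and accuracy experiments.
#'
#' @param config A [simulator_config()].
#' @return An object of class `gsr_sim`: a list with elements `samples`
#'   (data.frame `t_ms`, `adc12`), `clean` (numeric, counts, unquantized),
#'   `labels` (ordered factor over [stress_levels()]), `calibration_idx`
#'   (indices of the calibration window) and `config`.
#' @examples
#' sim <- simulate_subject_stream(simulator_config(seed = 7, duration_s = 60))
#' head(sim$samples)
#' @export
simulate_subject_stream <- function(config = simulator_config()) {
  if (!inherits(config, "simulator_config")) {
    stop("`config` must be a simulator_config", call. = FALSE)
  }
  period_s <- config$sample_period_ms / 1000
  n <- floor(config$duration_s / period_s)
  if (n < 1L) stop("stream too short for one sample", call. = FALSE)
  t_s <- (seq_len(n) - 1L) * period_s
  f <- .tonic_fraction(t_s, config)
  clean <- config$baseline_adc12 + f * config$dynamic_range_adc12 +
    config$drift_per_min * (t_s / 60)

  with_local_seed(config$seed, {
    # SCR arrivals: homogeneous Poisson within each constant-rate segment
    state <- .state_at(t_s, config)
    cal <- config$calibration_window_s
    seg_bounds <- sort(unique(c(0, cal, config$duration_s,
                                config$stress_state_schedule$start_s,
                                config$stress_state_schedule$end_s)))
    for (i in seq_len(length(seg_bounds) - 1L)) {
      a <- seg_bounds[i]; b <- seg_bounds[i + 1L]
      if (b <= a) next
      mult <- if (a < cal) 1 else
        .level_rate_mult[.state_at(a + 1e-9, config)]
      rate <- config$scr_rate_per_min * mult
      n_ev <- stats::rpois(1L, rate * (b - a) / 60)
      if (n_ev > 0L) {
        t0 <- sort(stats::runif(n_ev, a, b))
        amp <- stats::rexp(n_ev, rate = 1 / max(config$scr_amplitude, 1e-12))
        if (config$scr_amplitude == 0) amp <- rep(0, n_ev)
        for (j in seq_len(n_ev)) {
          u <- t_s - t0[j]
          act <- u >= 0 & u <= config$scr_rise_s + 8 * config$scr_decay_s
          if (!any(act)) next
          uu <- u[act]
          shape <- ifelse(uu < config$scr_rise_s,
                          if (config$scr_rise_s > 0) uu / config$scr_rise_s else 1,
                          exp(-(uu - config$scr_rise_s) /
                                max(config$scr_decay_s, 1e-12)))
          clean[act] <- clean[act] + amp[j] * shape
        }
      }
    }
    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
    adc12 <- as.integer(pmin(pmax(round(clean + noise), 0), 4095))
    labels <- classify_stress(pmin(pmax(f, 0), 1) * 500)
    structure(list(samples = data.frame(t_ms = t_s * 1000, adc12 = adc12),
                   clean = clean,
                   labels = labels,
                   calibration_idx = which(t_s < cal),
                   config = config),
              class = "gsr_sim")
  })
}

#' @export
print.gsr_sim <- function(x, ...) {
  cat("<gsr_sim>", nrow(x$samples), "samples @", x$config$sample_period_ms,
      "ms | labels:", paste(names(table(droplevels(x$labels))),
                            table(droplevels(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a cohort of normalized readings
#'
#' Draws `samples_per_subject` normalized GSR values for each of
#' `n_subjects`, each subject assigned to one stress band and drawing
#' uniformly within it. The default band assignment cycles Very high /
#' High / Minor / No stress across subjects, mirroring the structure of the
#' bundled printed cohort table.
#'
#' @param n_subjects Number of subjects; default 32.
#' @param samples_per_subject Readings per subject; default 20.
#' @param seed Integer RNG seed.
#' @param bands Optional character vector of level codes (`"no_stress"`,
#'   `"minor"`, `"high"`, `"very_high"`), one per subject; recycled pattern
#'   by default.
#' @return A data.frame with one row per reading: columns `subject`
#'   (factor), `sample` (index within subject), `gsr_norm`, `level`
#'   (assigned band, ordered factor).
#' @examples
#' cohort <- simulate_cohort(seed = 3)
#' nrow(cohort)  # 32 x 20 = 640
#' @export
simulate_cohort <- function(n_subjects = 32L, samples_per_subject = 20L,
                            seed = 1L, bands = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 1 ||
      n_subjects != floor(n_subjects)) {
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(samples_per_subject) || samples_per_subject < 1 ||
      samples_per_subject != floor(samples_per_subject)) {
    stop("`samples_per_subject` must be a positive integer", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  samples_per_subject <- as.integer(samples_per_subject)
  if (is.null(bands)) {
    bands <- rep(c("very_high", "high", "minor", "no_stress"),
                 length.out = n_subjects)
  }
  if (length(bands) != n_subjects || !all(bands %in% names(.level_codes))) {
    stop("`bands` must give one valid level code per subject", call. = FALSE)
  }
  band_lo <- c(no_stress = 0, minor = 200, high = 300, very_high = 400)
  band_hi <- c(no_stress = 200, minor = 300, high = 400, very_high = 500)
  with_local_seed(seed, {
    vals <- unlist(lapply(seq_len(n_subjects), function(i) {
      stats::runif(samples_per_subject, band_lo[bands[i]], band_hi[bands[i]])
    }))
    subj <- factor(rep(sprintf("Subject %d", seq_len(n_subjects)),
                       each = samples_per_subject),
                   levels = sprintf("Subject %d", seq_len(n_subjects)))
    data.frame(subject = subj,
               sample = rep(seq_len(samples_per_subject), n_subjects),
               gsr_norm = vals,
               level = factor(.level_codes[rep(bands, each = samples_per_subject)],
                              levels = stress_levels(), ordered = TRUE))
  })
}

#' Reshape a simulated cohort to a per-subject table
#'
#' @param cohort Output of [simulate_cohort()].
#' @return A data.frame with one column of normalized values per subject,
#'   suitable for [classify_table()].
#' @export
cohort_to_table <- function(cohort) {
  if (!is.data.frame(cohort) ||
      !all(c("subject", "sample", "gsr_norm") %in% names(cohort))) {
    stop("`cohort` must be the output of simulate_cohort()", call. = FALSE)
  }
  wide <- stats::reshape(cohort[, c("subject", "sample", "gsr_norm")],
                         idvar = "sample", timevar = "subject",
                         direction = "wide")
  wide <- wide[order(wide$sample), , drop = FALSE]
  out <- wide[, -1L, drop = FALSE]
  names(out) <- sub("^gsr_norm\\.", "", names(out))
  rownames(out) <- NULL
  out
}

#' The bundled printed cohort table
#'
#' A 16-subject cohort of normalized GSR readings recorded on the 0-500
#' scale, with each subject's column labelled by the stress band their
#' readings fall in. Subjects 1-4 carry 14 readings; subjects 5-16 carry
#' 13, so the rectangular table pads their final row with `NA`.
#'
#' @return A data.frame with columns `"Person 1"` ... `"Person 16"` and an
#'   attribute `"band"`: an ordered factor giving each column's stress band.
#' @examples
#' tab <- load_table2_fixture()
#' tab[["Person 1"]][1]  # 432
#' attr(tab, "band")[["Person 1"]]
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_cohort.csv", package = "gsrstress",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  band <- factor(rep(c("Very high stress", "High stress", "Minor stress",
                       "No stress"), 4L),
                 levels = stress_levels(), ordered = TRUE)
  names(band) <- names(tab)
  attr(tab, "band") <- band
  tab
}
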