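#' Scalar Kalman filter parameters
#'
#' The noise-reduction stage is a one-dimensional Kalman filter with
#' measurement error `e_m`, initial estimated error `e_p0`, and an initial
#' state policy: either seed the estimate with the first measurement
#' (`x0 = NULL`, the default) or with an explicit value. `q` is an optional
#' additive process-noise term applied to the error estimate after each
#' update; with the default `q = 0` the error estimate decays monotonically
#' to zero and the filter converges to a static average of everything it has
#' seen, which is the exact printed recursion. Streaming applications that
#' must keep tracking a moving signal set `q > 0`.
#'
#' @param e_m Measurement error, same units as the signal; > 0.
#' @param e_p0 Initial estimated error; > 0.
#' @param x0 Explicit initial state estimate, or `NULL` to use the first
#'   measurement.
#' @param q Process noise added to the error estimate each step; >= 0.
#' @return An object of class `kalman_params`.
#' @examples
#' kalman_params(e_m = 4, e_p0 = 1)
#' @export
kalman_params <- function(e_m = 4.0, e_p0 = 1.0, x0 = NULL, q = 0.0) {
  stopifnot_scalar <- function(x, nm, positive = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    if (positive && x <= 0) stop("`", nm, "` must be > 0", call. = FALSE)
    if (!positive && x < 0) stop("`", nm, "` must be >= 0", call. = FALSE)
  }
  stopifnot_scalar(e_m, "e_m")
  stopifnot_scalar(e_p0, "e_p0")
  stopifnot_scalar(q, "q", positive = FALSE)
  if (!is.null(x0)) {
    if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0)) {
      stop("`x0` must be NULL or a single finite number", call. = FALSE)
    }
    x0 <- as.numeric(x0)
  }
  structure(list(e_m = as.numeric(e_m), e_p0 = as.numeric(e_p0),
                 x0 = x0, q = as.numeric(q)),
            class = "kalman_params")
}

#' @export
print.kalman_params <- function(x, ...) {
  cat("<kalman_params> e_m =", x$e_m, "| e_p0 =", x$e_p0,
      "| x0 =", if (is.null(x$x0)) "first measurement" else x$x0,
      "| q =", x$q, "\n")
  invisible(x)
}

#' Kalman gain
#'
#' The weight in \[0, 1\] given to a new measurement against the running
#' estimate: `K = e_p / (e_p + e_m)`. A zero measurement error yields full
#' trust in the measurement (K = 1); a zero estimated error yields full
#' trust in the state (K = 0). Both zero is degenerate and rejected.
#'
#' @param e_p Estimated error, >= 0.
#' @param e_m Measurement error, >= 0.
#' @return The gain, a number in \[0, 1\].
#' @examples
#' kalman_gain(1, 1)    # 0.5
#' kalman_gain(0.5, 1)  # 1/3
#' @export
kalman_gain <- function(e_p, e_m) {
  if (!is.numeric(e_p) || !is.numeric(e_m) || length(e_p) != 1L ||
      length(e_m) != 1L || !is.finite(e_p) || !is.finite(e_m) ||
      e_p < 0 || e_m < 0) {
    stop("`e_p` and `e_m` must be single non-negative finite numbers",
         call. = FALSE)
  }
  if (e_p == 0 && e_m == 0) {
    stop("degenerate filter: e_p and e_m cannot both be zero", call. = FALSE)
  }
  e_p / (e_p + e_m)
}

#' Initialize the Kalman filter state
#'
#' @param params A [kalman_params()] object.
#' @param first_measurement The first observed value; required when the
#'   initial-state policy is first-measurement (`x0 = NULL`).
#' @return An object of class `kalman_state` with fields `x_est`, `e_p`,
#'   `k_last` and `n_steps`.
#' @export
kalman_init <- function(params, first_measurement = NULL) {
  if (!inherits(params, "kalman_params")) {
    stop("`params` must be a kalman_params object", call. = FALSE)
  }
  x0 <- params$x0
  if (is.null(x0)) {
    if (is.null(first_measurement)) {
      stop("first-measurement policy requires `first_measurement`", call. = FALSE)
    }
    if (!is.numeric(first_measurement) || !is.finite(first_measurement)) {
      stop("`first_measurement` must be finite", call. = FALSE)
    }
    x0 <- as.numeric(first_measurement)
  }
  structure(list(x_est = x0, e_p = params$e_p0, k_last = NA_real_,
                 n_steps = 0L),
            class = "kalman_state")
}

#' @export
print.kalman_state <- function(x, ...) {
  cat(sprintf("<kalman_state> x_est = %.6g | e_p = %.6g | k_last = %s | steps = %d\n",
              x$x_est, x$e_p,
              if (is.na(x$k_last)) "NA" else sprintf("%.6g", x$k_last),
              x$n_steps))
  invisible(x)
}

#' One Kalman update
#'
#' Consumes a measurement `z` and returns the updated state: the gain
#' `K = e_p/(e_p + e_m)`, the innovation update `x' = x + K (z - x)`, and
#' the error update `e_p' = (1 - K) e_p` (plus the optional process noise
#' `q`). The updated estimate always lies between the previous estimate and
#' the measurement.
#'
#' @param state A `kalman_state` from [kalman_init()] or a previous step.
#' @param z A finite measurement.
#' @param params A [kalman_params()] object.
#' @return The updated `kalman_state`.
#' @examples
#' p <- kalman_params(e_m = 1, e_p0 = 1, x0 = 0)
#' kalman_step(kalman_init(p), 10, p)  # x_est = 5, e_p = 0.5
#' @export
kalman_step <- function(state, z, params) {
  if (!inherits(state, "kalman_state")) {
    stop("`state` must be a kalman_state object", call. = FALSE)
  }
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z)) {
    stop("measurement `z` must be a single finite number", call. = FALSE)
  }
  k <- kalman_gain(state$e_p, params$e_m)
  x <- state$x_est + k * (z - state$x_est)
  e_p <- (1 - k) * state$e_p + params$q
  structure(list(x_est = x, e_p = e_p, k_last = k,
                 n_steps = state$n_steps + 1L),
            class = "kalman_state")
}

#' Filter a whole series
#'
#' Runs the scalar Kalman recursion over a vector of measurements and
#' returns the trace of state estimates, one per input sample. Under the
#' default first-measurement policy the first output equals the first
#' sample (the filter is seeded with it, then updated by it, which leaves
#' it unchanged).
#'
#' @param z Non-empty numeric vector of finite measurements.
#' @param params A [kalman_params()] object.
#' @return Numeric vector of filtered estimates, same length as `z`, with
#'   the final `kalman_state` attached as attribute `"state"`.
#' @examples
#' kalman_filter(c(10, 10, 10), kalman_params(e_m = 1, e_p0 = 1, x0 = 0))
#' @export
kalman_filter <- function(z, params = kalman_params()) {
  if (!is.numeric(z) || length(z) == 0L) {
    stop("`z` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(z) || any(!is.finite(z))) {
    stop("`z` must contain only finite values", call. = FALSE)
  }
  n <- length(z)
  out <- numeric(n)
  # scalar recursion, loop-free state bookkeeping kept in plain doubles
  x <- if (is.null(params$x0)) z[1L] else params$x0
  e_p <- params$e_p0
  e_m <- params$e_m
  q <- params$q
  k <- NA_real_
  for (i in seq_len(n)) {
    k <- e_p / (e_p + e_m)
    x <- x + k * (z[i] - x)
    e_p <- (1 - k) * e_p + q
    out[i] <- x
  }
  attr(out, "state") <- structure(
    list(x_est = x, e_p = e_p, k_last = k, n_steps = n),
    class = "kalman_state"
  )
  out
}
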