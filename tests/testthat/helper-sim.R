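# Shared fixtures for simulator-backed tests.

# A four-state schedule visiting every stress band after the calibration
# window of a 150 s stream.
four_state_schedule <- function() {
  data.frame(start_s = c(30, 60, 90, 120),
             end_s = c(60, 90, 120, 150),
             level = c("minor", "high", "very_high", "no_stress"))
}

four_state_config <- function(seed, noise_sd = 20) {
  simulator_config(seed = seed, duration_s = 150, noise_sd = noise_sd,
                   stress_state_schedule = four_state_schedule())
}

# Run the full pipeline on a simulated stream: map -> filter (tracking
# filter, q > 0) -> profile from the stream's calibration window ->
# normalize -> classify. bypass = TRUE skips the Kalman stage.
run_sim_pipeline <- function(sim, params = kalman_params(e_m = 4, e_p0 = 1, q = 1),
                             bypass = FALSE) {
  adc10 <- map_12bit_to_10bit(sim$samples$adc12)
  x_est <- if (bypass) adc10 else as.numeric(kalman_filter(adc10, params))
  prof <- estimate_baseline(x_est[sim$calibration_idx])
  norm <- normalize_gsr(apply_offset(x_est, prof), prof)
  pred <- classify_stress(norm$gsr_norm)
  post <- setdiff(seq_along(pred), sim$calibration_idx)
  list(pred = pred, post = post,
       agreement = percent_agreement(pred[post], sim$labels[post]))
}
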