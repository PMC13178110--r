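# Shared fixtures: all synthetic, built in code.

# Minimal frame table with given intensities for on/off frames, strictly
# alternating starting LED-off, at 41 fps.
make_frames <- function(on, off, fps = 41) {
  n <- 2 * max(length(on), length(off))
  on <- rep_len(on, n / 2)
  off <- rep_len(off, n / 2)
  tibble::tibble(
    frame_index = seq_len(n) - 1L,
    timestamp = (seq_len(n) - 1) / fps,
    led_state = rep_len(c(0L, 1L), n),
    roi_intensity = as.numeric(rbind(off, on))
  )
}

# Two identically-distributed vehicle arms: the null cohort for calibration.
null_cohort_spec <- function(seed, n_animals = 8) {
  cohort_spec(
    n_animals = n_animals,
    treatments = list(drug_profile("vehicle", label = "vehicle_A"),
                      drug_profile("vehicle", label = "vehicle_B")),
    seed = seed
  )
}

# Vehicle + calibrated inhibitor cohort (steady-state delta-FRET target_pct).
effect_cohort_spec <- function(seed, target_pct = 30, params = sensor_params(),
                               n_animals = 8) {
  f <- inhibition_for_steady_state(params, target_pct)
  cohort_spec(
    n_animals = n_animals,
    treatments = list(drug_profile("vehicle"),
                      drug_profile("inhibitor", magnitude = f)),
    seed = seed
  )
}

# p-value of the treatment main effect from the full pipeline
pipeline_treatment_p <- function(spec, params = sensor_params(),
                                 schedule = session_schedule()) {
  co <- simulate_cohort(spec, params, schedule)
  ex <- process_experiment(co)
  res <- rm_two_way_anova(ex$delta_fret)
  tidy(res)$p_value[tidy(res)$term == "treatment"]
}
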