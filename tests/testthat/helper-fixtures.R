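# Shared fixtures: compact generator configs and hand-built trial tables.

small_config <- function(seed = 101, pupil_duration_s = 30, ...) {
  generator_config(seed = seed, n_patients = 4, n_controls = 5,
                   pupil_duration_s = pupil_duration_s, ...)
}

# A noise-free configuration: every saccade lands exactly on the main
# sequence and no distractors or blinks occur.
noiseless_config <- function(seed = 101, ...) {
  generator_config(seed = seed, v_group_sd = 0, gain_sd = 0, gain_mean = 1,
                   amplitude_noise_cv = 0, velocity_noise_cv = 0,
                   patient_v_offset = 0, distractor_rate = 0,
                   blink_rate = 0, pupil_noise_sd = 0, pupil_drift_amp = 0,
                   ...)
}

control_subject <- function(config, id = "HC01") {
  gen_subject_params(config, "control", id)
}

# One hand-built trial: a metadata row plus its ordered saccade events.
make_trial <- function(events, task = "prosaccade", ecc = 5,
                       subject_id = "S1", condition = "placebo",
                       trial_index = 1) {
  trial <- data.frame(subject_id = subject_id, group = "patient",
                      condition = condition, task = task,
                      trial_index = trial_index,
                      target_side = if (ecc > 0) "right" else "left",
                      target_eccentricity_deg = ecc, target_onset_ms = 1000,
                      stringsAsFactors = FALSE)
  ev <- do.call(rbind, lapply(events, function(e) data.frame(
    subject_id = subject_id, group = "patient", condition = condition,
    task = task, trial_index = trial_index,
    target_onset_ms = 1000,
    target_side = if (ecc > 0) "right" else "left",
    target_eccentricity_deg = ecc,
    sacc_onset_ms = e$lat,
    sacc_duration_ms = e$dur %||% 40,
    amplitude_deg = e$amp,
    peak_velocity_deg_s = e$pv %||% (130 * sqrt(e$amp)),
    start_x_deg = e$start %||% 0,
    end_x_deg = e$end %||% (sign(ecc) * e$amp),
    stringsAsFactors = FALSE)))
  list(trial = trial, events = ev)
}

bind_trials <- function(...) {
  parts <- list(...)
  list(trials = do.call(rbind, lapply(parts, `[[`, "trial")),
       events = do.call(rbind, lapply(parts, `[[`, "events")))
}

# Independent dense-trapezoid oracle for the JZS Bayes factor: integrates
# the non-central t likelihood against the Cauchy effect-size prior on a
# fine grid (a different representation than the package's scale-mixture
# quadrature).
jzs_oracle <- function(t, n_eff, df, r = sqrt(2) / 2, lim = 20, len = 60001) {
  d <- seq(-lim, lim, length.out = len)
  num <- sum(suppressWarnings(dt(t, df, ncp = d * sqrt(n_eff))) *
               dcauchy(d, 0, r)) * (d[2] - d[1])
  num / dt(t, df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
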