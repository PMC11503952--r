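# Synthetic cohort generation: subjects, sessions, trials, saccade events and
# resting pupil traces with known ground-truth parameters.  The generator
# mirrors the task design of a prosaccade/antisaccade battery recorded at
# 500 Hz: a central fixation of 800-1200 ms, a 200 ms gap, then a lateral
# target at +/-3, +/-5 or +/-7 degrees; 24 trials per task with equal counts
# per eccentricity.

#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable parameter of the simulated study: cohort sizes,
#' task constants, population distributions of the kinematic ground truth,
#' the latency model, the latency-error coupling, pupil-trace parameters,
#' and per-condition drug offsets.  Defaults encode the crossover design the
#' pipeline targets: 19 patients tested on drug and placebo, 25 controls
#' tested once.
#'
#' The latency model is a shifted lognormal: `latency_shift` (ms) plus a
#' lognormal with log-mean `latency_meanlog` and log-sd `latency_sdlog`.
#' Peak velocity follows the square-root main sequence
#' `v = V * sqrt(amplitude)` with multiplicative noise of coefficient of
#' variation `velocity_noise_cv`.  Antisaccade errors are drawn from a
#' logistic model coupling error probability to the (standardized) latency
#' of the trial, so that fast responses are more error prone
#' (`urgency_coupling`).
#'
#' @param n_patients,n_controls cohort sizes.
#' @param trials_per_task trials per task block; must be divisible by the
#'   number of eccentricities.
#' @param eccentricities signed target locations in degrees, symmetric
#'   about 0.
#' @param fixation_duration_range central fixation duration range (ms).
#' @param gap_duration gap between fixation offset and target onset (ms).
#' @param sampling_rate tracker sampling rate (Hz).
#' @param v_group_mean,v_group_sd population mean and SD of the
#'   main-sequence coefficient V (deg s^-1 per sqrt(deg)) for controls.
#' @param patient_v_offset additive shift of the patient group's V relative
#'   to controls (their untreated main sequence sits above the normative
#'   curve); the drug's `v_shift` acts against it.
#' @param latency_meanlog,latency_sdlog,latency_shift shifted-lognormal
#'   latency parameters (log-ms, log-ms, ms).
#' @param latency_subject_sd between-subject SD of the log-mean latency.
#' @param gain_mean,gain_sd population distribution of saccadic gain
#'   (amplitude / eccentricity; < 1 is hypometria).
#' @param amplitude_noise_cv,velocity_noise_cv trial-level multiplicative
#'   noise (coefficient of variation) on amplitude and peak velocity.
#' @param error_propensity_mean,error_propensity_sd population distribution
#'   of the antisaccade error propensity (logit units).
#' @param urgency_coupling coupling (>= 0) between standardized latency and
#'   the error logit; positive values make fast trials more error prone.
#' @param distractor_rate probability that a trial carries a small early
#'   distractor saccade (amplitude < 1 deg, latency < 90 ms) ahead of the
#'   primary saccade, to exercise the downstream validity gates.
#' @param blink_rate blinks per minute in the resting pupil trace.
#' @param pupil_baseline_mean,pupil_baseline_sd population distribution of
#'   resting pupil diameter (arbitrary tracker units).
#' @param pupil_noise_sd white-noise SD of the pupil trace (a.u.).
#' @param pupil_drift_amp,pupil_drift_freq slow sinusoidal drift amplitude
#'   (a.u.) and frequency (Hz).
#' @param pupil_duration_s resting recording duration (s).
#' @param drug_effect named list of additive condition offsets applied on
#'   the active-drug session: `latency_shift` (ms), `v_shift`
#'   (deg s^-1 sqrt(deg)^-1), `error_logit_shift` (logits), `pupil_shift`
#'   (a.u.).
#' @param seed single global integer seed; all per-subject substreams are
#'   derived from it by stable hashing of the subject id.
#'
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_patients = 19,
                             n_controls = 25,
                             trials_per_task = 24,
                             eccentricities = c(-7, -5, -3, 3, 5, 7),
                             fixation_duration_range = c(800, 1200),
                             gap_duration = 200,
                             sampling_rate = 500,
                             v_group_mean = 130,
                             v_group_sd = 10,
                             patient_v_offset = 10,
                             latency_meanlog = log(110),
                             latency_sdlog = 0.35,
                             latency_shift = 90,
                             latency_subject_sd = 0.10,
                             gain_mean = 0.9,
                             gain_sd = 0.05,
                             amplitude_noise_cv = 0.05,
                             velocity_noise_cv = 0.10,
                             error_propensity_mean = -1.4,
                             error_propensity_sd = 0.5,
                             urgency_coupling = 0.8,
                             distractor_rate = 0.05,
                             blink_rate = 15,
                             pupil_baseline_mean = 3000,
                             pupil_baseline_sd = 300,
                             pupil_noise_sd = 20,
                             pupil_drift_amp = 50,
                             pupil_drift_freq = 0.05,
                             pupil_duration_s = 180,
                             drug_effect = list(latency_shift = -15,
                                                v_shift = -10,
                                                error_logit_shift = 0.6,
                                                pupil_shift = 150),
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  for (f in c("n_patients", "n_controls", "trials_per_task"))
    if (!is_count(cfg[[f]])) stopf("generator_config: '%s' must be a positive integer", f)
  ecc <- cfg$eccentricities
  if (length(ecc) == 0 || any(ecc == 0) ||
      !setequal(round(sort(ecc), 9), round(sort(-ecc), 9)))
    stopf("generator_config: eccentricities must be non-zero and symmetric about 0")
  fr <- cfg$fixation_duration_range
  if (length(fr) != 2 || fr[1] >= fr[2])
    stopf("generator_config: fixation_duration_range must be (low, high) with low < high")
  if (!is.numeric(cfg$sampling_rate) || cfg$sampling_rate <= 0)
    stopf("generator_config: sampling_rate must be > 0")
  if (cfg$urgency_coupling < 0)
    stopf("generator_config: urgency_coupling must be >= 0")
  need <- c("latency_shift", "v_shift", "error_logit_shift", "pupil_shift")
  if (!all(need %in% names(cfg$drug_effect)))
    stopf("generator_config: drug_effect must name %s", paste(need, collapse = ", "))
  invisible(cfg)
}

#' Draw latent parameters for one simulated subject
#'
#' Samples the subject's true main-sequence coefficient, latency
#' distribution, saccadic gain, antisaccade error propensity and resting
#' pupil baseline from the population distributions in `config`.  Patients'
#' V is centred at `v_group_mean + patient_v_offset`; controls at
#' `v_group_mean`.
#'
#' @param config a [generator_config()].
#' @param group `"patient"` or `"control"`.
#' @param subject_id subject label (also seeds the subject's substream).
#' @param seed integer seed; defaults to a substream derived from
#'   `config$seed` and `subject_id`.
#' @return an object of class `subject_params`.
#' @export
gen_subject_params <- function(config, group, subject_id = NULL, seed = NULL) {
  validate_generator_config(config)
  if (!group %in% c("patient", "control"))
    stopf("gen_subject_params: unknown group '%s'", group)
  if (is.null(subject_id))
    subject_id <- if (group == "patient") "PD00" else "HC00"
  if (is.null(seed)) seed <- child_seed(config$seed, paste0("params:", subject_id))
  with_seed(seed, {
    v_centre <- config$v_group_mean +
      if (group == "patient") config$patient_v_offset else 0
    v_true <- rnorm(1, v_centre, config$v_group_sd)
    while (v_true <= 0) v_true <- rnorm(1, v_centre, config$v_group_sd)
    gain <- rnorm(1, config$gain_mean, config$gain_sd)
    while (gain <= 0) gain <- rnorm(1, config$gain_mean, config$gain_sd)
    out <- list(
      subject_id = subject_id,
      group = group,
      v_true = v_true,
      latency_meanlog = rnorm(1, config$latency_meanlog, config$latency_subject_sd),
      latency_sdlog = config$latency_sdlog,
      latency_shift = config$latency_shift,
      gain = gain,
      error_propensity = rnorm(1, config$error_propensity_mean,
                               config$error_propensity_sd),
      pupil_baseline = rnorm(1, config$pupil_baseline_mean,
                             config$pupil_baseline_sd))
  })
  class(out) <- "subject_params"
  out
}

# Condition-specific latency shift (ms) and V offset for a session.
condition_offsets <- function(config, condition) {
  atx <- identical(condition, "atomoxetine")
  list(latency = if (atx) config$drug_effect$latency_shift else 0,
       v = if (atx) config$drug_effect$v_shift else 0,
       error_logit = if (atx) config$drug_effect$error_logit_shift else 0,
       pupil = if (atx) config$drug_effect$pupil_shift else 0)
}

# Analytic mean and SD of the population shifted-lognormal latency under a
# given condition.  The error model standardizes trial latencies against
# these population moments (not the subject's own), so that habitually fast
# responders carry a higher error probability across subjects while fast
# trials remain more error prone within subject.
latency_moments <- function(config, shift_eff) {
  s2 <- config$latency_sdlog^2 + config$latency_subject_sd^2
  m <- exp(config$latency_meanlog + s2 / 2)
  list(mean = shift_eff + m, sd = m * sqrt(expm1(s2)))
}

# Raised-cosine velocity trace for one saccade.  Peak velocity vp at
# mid-flight, zero velocity at both ends; duration is chosen so that the
# trace integrates exactly to the saccade amplitude (D = 2A / vp).  Samples
# span [0, D] uniformly (at least 12 points, otherwise ~sampling_rate).
velocity_trace <- function(amplitude, peak_velocity, sampling_rate) {
  dur_ms <- 2 * amplitude / peak_velocity * 1000
  n <- max(13L, as.integer(round(dur_ms / 1000 * sampling_rate)) + 1L)
  if (n %% 2L == 0L) n <- n + 1L   # odd count puts a sample on the peak
  t_norm <- seq(0, 1, length.out = n)
  list(t_norm = t_norm,
       velocity = peak_velocity * 0.5 * (1 - cos(2 * pi * t_norm)),
       duration_ms = dur_ms)
}

# Shared machinery for the two tasks.  Draws the trial schedule (balanced
# eccentricities in randomized order), fixation durations, latencies,
# amplitudes and peak velocities; the caller supplies the executed saccade
# direction per trial.
gen_trial_core <- function(subject, config, condition, task, seed) {
  validate_generator_config(config)
  n_ecc <- length(config$eccentricities)
  if (config$trials_per_task %% n_ecc != 0)
    stopf("trials_per_task (%d) must be divisible by the number of eccentricities (%d)",
          config$trials_per_task, n_ecc)
  off <- condition_offsets(config, condition)
  with_seed(seed, {
    n <- config$trials_per_task
    ecc <- sample(rep(config$eccentricities, n / n_ecc))
    fix <- runif(n, config$fixation_duration_range[1], config$fixation_duration_range[2])
    lat <- (config$latency_shift + off$latency) +
      rlnorm(n, subject$latency_meanlog, subject$latency_sdlog)
    amp <- pmax(subject$gain * abs(ecc) *
                  (1 + rnorm(n, 0, config$amplitude_noise_cv)), 0.1)
    v_eff <- max(subject$v_true + off$v, 1)
    pv <- pmax(v_eff * sqrt(amp) * (1 + rnorm(n, 0, config$velocity_noise_cv)), 1)
    distract <- runif(n) < config$distractor_rate
    d_amp <- runif(n, 0.2, 1.0)
    d_lat <- runif(n, 20, 80)
    err_u <- runif(n)      # consumed by the antisaccade error model
    list(trial_index = seq_len(n), target_eccentricity = ecc,
         fixation_duration = fix, latency = lat, amplitude = amp,
         peak_velocity = pv, v_eff = v_eff, offsets = off,
         distract = distract, d_amp = d_amp, d_lat = d_lat, err_u = err_u,
         task = task)
  })
}

# Assemble the tidy trial / event / velocity-sample tables from a drawn core.
assemble_trials <- function(core, subject, config, condition, direction,
                            correct, samples) {
  n <- length(core$trial_index)
  target_onset <- core$fixation_duration + config$gap_duration
  dur_ms <- 2 * core$amplitude / core$peak_velocity * 1000
  trials <- data.frame(
    subject_id = subject$subject_id, group = subject$group,
    condition = condition, task = core$task,
    trial_index = core$trial_index,
    target_side = ifelse(core$target_eccentricity > 0, "right", "left"),
    target_eccentricity_deg = core$target_eccentricity,
    fixation_duration_ms = core$fixation_duration,
    target_onset_ms = target_onset,
    true_latency_ms = core$latency,
    true_correct = correct,
    stringsAsFactors = FALSE)

  primary <- data.frame(
    subject_id = subject$subject_id, group = subject$group,
    condition = condition, task = core$task,
    trial_index = core$trial_index,
    target_onset_ms = target_onset,
    target_side = trials$target_side,
    target_eccentricity_deg = core$target_eccentricity,
    sacc_onset_ms = core$latency,
    sacc_duration_ms = dur_ms,
    amplitude_deg = core$amplitude,
    peak_velocity_deg_s = core$peak_velocity,
    start_x_deg = 0,
    end_x_deg = direction * core$amplitude,
    stringsAsFactors = FALSE)

  events <- primary
  if (any(core$distract)) {
    i <- which(core$distract)
    d_pv <- core$v_eff * sqrt(core$d_amp[i])
    distractors <- data.frame(
      subject_id = subject$subject_id, group = subject$group,
      condition = condition, task = core$task,
      trial_index = core$trial_index[i],
      target_onset_ms = target_onset[i],
      target_side = trials$target_side[i],
      target_eccentricity_deg = core$target_eccentricity[i],
      sacc_onset_ms = core$d_lat[i],
      sacc_duration_ms = 2 * core$d_amp[i] / d_pv * 1000,
      amplitude_deg = core$d_amp[i],
      peak_velocity_deg_s = d_pv,
      start_x_deg = 0,
      end_x_deg = sign(core$target_eccentricity[i]) * core$d_amp[i],
      stringsAsFactors = FALSE)
    events <- rbind(events, distractors)
    events <- events[order(events$trial_index, events$sacc_onset_ms), ]
    rownames(events) <- NULL
  }

  vel <- NULL
  if (samples) {
    tr <- lapply(seq_len(n), function(i)
      velocity_trace(core$amplitude[i], core$peak_velocity[i], config$sampling_rate))
    n_s <- vapply(tr, function(x) length(x$t_norm), integer(1))
    vel <- data.frame(
      subject_id = subject$subject_id, condition = condition, task = core$task,
      trial_index = rep(core$trial_index, n_s),
      t_norm = unlist(lapply(tr, `[[`, "t_norm")),
      velocity = unlist(lapply(tr, `[[`, "velocity")),
      duration_ms = rep(dur_ms, n_s),
      stringsAsFactors = FALSE)
  }
  list(trials = trials, events = events, velocity_samples = vel)
}

#' Simulate one prosaccade block
#'
#' Generates `trials_per_task` prosaccade trials with balanced, randomized
#' eccentricities.  Each trial's primary saccade lies on the subject's
#' main sequence `v = V sqrt(amplitude)` up to multiplicative noise, with
#' amplitude `gain * |eccentricity| * (1 + noise)` and a shifted-lognormal
#' latency (plus the drug's latency offset on active-drug sessions).  A
#' raised-cosine velocity trace whose peak equals the drawn peak velocity is
#' attached per saccade.  A small fraction of trials additionally carry an
#' early sub-degree distractor saccade that downstream validity gates must
#' reject.
#'
#' @param subject a [gen_subject_params()] result.
#' @param config a [generator_config()].
#' @param condition `"placebo"`, `"atomoxetine"` or `"control"`.
#' @param seed integer seed (defaults to a substream of `config$seed`).
#' @param samples attach per-saccade velocity sample traces?
#' @return list with `trials`, `events` and (if `samples`)
#'   `velocity_samples` data frames.
#' @export
gen_prosaccade_trials <- function(subject, config, condition,
                                  seed = NULL, samples = TRUE) {
  if (is.null(seed))
    seed <- child_seed(config$seed, paste0("pro:", subject$subject_id, ":", condition))
  core <- gen_trial_core(subject, config, condition, "prosaccade", seed)
  direction <- sign(core$target_eccentricity)   # prosaccades go to the target
  assemble_trials(core, subject, config, condition, direction,
                  correct = rep(TRUE, length(direction)), samples = samples)
}

#' Simulate one antisaccade block
#'
#' As [gen_prosaccade_trials()], but each trial carries an error indicator
#' drawn from `plogis(error_propensity + urgency_coupling * (-z_latency) +
#' drug logit shift)`, where `z_latency` standardizes the trial latency
#' against the subject's analytic latency distribution.  Error trials are
#' executed toward the target (and are therefore faster on average when
#' `urgency_coupling > 0`); correct antisaccades go the opposite way.
#'
#' @inheritParams gen_prosaccade_trials
#' @return list with `trials`, `events` and (if `samples`)
#'   `velocity_samples` data frames; `trials$true_correct` records the
#'   ground-truth error indicator.
#' @export
gen_antisaccade_trials <- function(subject, config, condition,
                                   seed = NULL, samples = TRUE) {
  if (is.null(seed))
    seed <- child_seed(config$seed, paste0("anti:", subject$subject_id, ":", condition))
  core <- gen_trial_core(subject, config, condition, "antisaccade", seed)
  off <- core$offsets
  lm_ <- latency_moments(config, config$latency_shift + off$latency)
  z <- (core$latency - lm_$mean) / lm_$sd
  p_err <- stats::plogis(subject$error_propensity + off$error_logit +
                           config$urgency_coupling * (-z))
  err <- core$err_u < p_err
  direction <- ifelse(err, sign(core$target_eccentricity),
                      -sign(core$target_eccentricity))
  assemble_trials(core, subject, config, condition, direction,
                  correct = !err, samples = samples)
}

#' Simulate a resting pupil-diameter trace
#'
#' Diameter samples at `sampling_rate` around the subject's baseline
#' (plus the drug's pupil shift on active-drug sessions), with a slow
#' sinusoidal drift and white noise.  Blinks occur at `blink_rate` per
#' minute; each blink zeroes the diameter and clears the validity mask for
#' a 50-200 ms run.
#'
#' @inheritParams gen_prosaccade_trials
#' @param duration_s recording duration in seconds.
#' @return a [pupil_trace()].
#' @export
gen_pupil_trace <- function(subject, config, condition,
                            duration_s = config$pupil_duration_s, seed = NULL) {
  validate_generator_config(config)
  if (duration_s <= 0) stopf("gen_pupil_trace: duration_s must be > 0")
  if (is.null(seed))
    seed <- child_seed(config$seed, paste0("pupil:", subject$subject_id, ":", condition))
  off <- condition_offsets(config, condition)
  fs <- config$sampling_rate
  n <- as.integer(round(duration_s * fs))
  with_seed(seed, {
    t_ms <- (seq_len(n) - 1) * 1000 / fs
    phase <- runif(1, 0, 2 * pi)
    x <- subject$pupil_baseline + off$pupil +
      config$pupil_drift_amp * sin(2 * pi * config$pupil_drift_freq * t_ms / 1000 + phase) +
      rnorm(n, 0, config$pupil_noise_sd)
    valid <- rep(TRUE, n)
    n_blinks <- rpois(1, config$blink_rate * duration_s / 60)
    if (n_blinks > 0) {
      onset <- sort(runif(n_blinks, 0, duration_s * 1000))
      blen <- runif(n_blinks, 50, 200)
      for (k in seq_len(n_blinks)) {
        i0 <- max(1L, as.integer(floor(onset[k] / 1000 * fs)) + 1L)
        i1 <- min(n, as.integer(ceiling((onset[k] + blen[k]) / 1000 * fs)))
        if (i0 <= i1) { valid[i0:i1] <- FALSE; x[i0:i1] <- 0 }
      }
    }
    pupil_trace(time = t_ms, diameter = x, valid = valid, sampling_rate = fs)
  })
}

#' Simulate a full crossover cohort
#'
#' Generates `n_patients` patients tested in two sessions (drug and placebo,
#' visit order block-randomized) and `n_controls` controls tested once, and
#' returns all tidy tables plus the latent ground-truth parameters for
#' recovery testing.
#'
#' @param config a [generator_config()].
#' @param pupil simulate resting pupil traces? (The pupil table is by far
#'   the largest output; disable when only saccade tables are needed.)
#' @param samples attach velocity sample traces?
#' @return an object of class `cohort`: a list with data frames `sessions`,
#'   `trials`, `events`, `velocity_samples`, `pupil` and `truth`.
#' @export
gen_cohort <- function(config, pupil = TRUE, samples = TRUE) {
  validate_generator_config(config)
  pat_ids <- sprintf("PD%02d", seq_len(config$n_patients))
  ctl_ids <- sprintf("HC%02d", seq_len(config$n_controls))
  first <- with_seed(child_seed(config$seed, "visit_order"),
                     sample(rep(c("atomoxetine", "placebo"),
                                length.out = config$n_patients)))

  sessions <- rbind(
    data.frame(subject_id = rep(pat_ids, each = 2), group = "patient",
               condition = as.vector(vapply(first, function(f)
                 c(f, setdiff(c("atomoxetine", "placebo"), f)), character(2))),
               visit_order = rep(1:2, config$n_patients),
               stringsAsFactors = FALSE),
    data.frame(subject_id = ctl_ids, group = "control", condition = "control",
               visit_order = NA_integer_, stringsAsFactors = FALSE))

  subjects <- c(
    lapply(pat_ids, function(id) gen_subject_params(config, "patient", id)),
    lapply(ctl_ids, function(id) gen_subject_params(config, "control", id)))
  names(subjects) <- c(pat_ids, ctl_ids)

  acc <- list(trials = list(), events = list(), vel = list(), pupil = list())
  for (i in seq_len(nrow(sessions))) {
    id <- sessions$subject_id[i]; cond <- sessions$condition[i]
    sub <- subjects[[id]]
    pro <- gen_prosaccade_trials(sub, config, cond, samples = samples)
    anti <- gen_antisaccade_trials(sub, config, cond, samples = samples)
    vo <- sessions$visit_order[i]
    add_vo <- function(df) { if (!is.null(df)) df$visit_order <- vo; df }
    acc$trials[[i]] <- add_vo(rbind(pro$trials, anti$trials))
    acc$events[[i]] <- add_vo(rbind(pro$events, anti$events))
    if (samples) acc$vel[[i]] <- rbind(pro$velocity_samples, anti$velocity_samples)
    if (pupil) {
      tr <- gen_pupil_trace(sub, config, cond)
      acc$pupil[[i]] <- data.frame(subject_id = id, condition = cond,
                                   time_ms = tr$time, pupil_au = tr$diameter,
                                   valid = tr$valid, stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, lapply(subjects, function(s) data.frame(
    subject_id = s$subject_id, group = s$group, v_true = s$v_true,
    latency_meanlog = s$latency_meanlog, latency_sdlog = s$latency_sdlog,
    latency_shift = s$latency_shift, gain = s$gain,
    error_propensity = s$error_propensity, pupil_baseline = s$pupil_baseline,
    stringsAsFactors = FALSE)))
  rownames(truth) <- NULL

  out <- list(
    config = config,
    sessions = sessions,
    trials = do.call(rbind, acc$trials),
    events = do.call(rbind, acc$events),
    velocity_samples = if (samples) do.call(rbind, acc$vel) else NULL,
    pupil = if (pupil) do.call(rbind, acc$pupil) else NULL,
    truth = truth)
  rownames(out$trials) <- rownames(out$events) <- NULL
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic oculomotor cohort\n")
  cat(sprintf("  %d sessions (%d patients x 2, %d controls x 1)\n",
              nrow(x$sessions), x$config$n_patients, x$config$n_controls))
  cat(sprintf("  %d trials, %d saccade events\n", nrow(x$trials), nrow(x$events)))
  if (!is.null(x$pupil))
    cat(sprintf("  pupil: %d samples across sessions\n", nrow(x$pupil)))
  invisible(x)
}

#' Write a simulated cohort to plain-text tables
#'
#' Writes `events.tsv`, `trials.tsv`, `truth.tsv`,
#' `velocity_samples.tsv` (if present) and `pupil.csv` (if present) under
#' `dir`, all UTF-8 with header rows.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$events, file.path(dir, "events.tsv"))
  write_tsv(cohort$trials, file.path(dir, "trials.tsv"))
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  if (!is.null(cohort$velocity_samples))
    write_tsv(cohort$velocity_samples, file.path(dir, "velocity_samples.tsv"))
  if (!is.null(cohort$pupil))
    utils::write.csv(cohort$pupil, file.path(dir, "pupil.csv"), row.names = FALSE)
  invisible(dir)
}
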