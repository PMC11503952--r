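# Synthetic cohort generator: parameter draws, task structure, kinematic
# ground truth, latency-error coupling and pupil traces.

test_that("config validation rejects malformed inputs", {
  expect_error(generator_config(n_patients = 0), "positive integer")
  expect_error(generator_config(eccentricities = c(-3, 5)), "symmetric")
  expect_error(generator_config(fixation_duration_range = c(1200, 800)),
               "low < high")
  expect_error(gen_subject_params(generator_config(), "giraffe"),
               "unknown group")
})

test_that("subject parameters collapse to population means at zero variance", {
  cfg <- generator_config(v_group_sd = 0, gain_sd = 0, seed = 5)
  s <- gen_subject_params(cfg, "control", "HC01")
  expect_identical(s$v_true, cfg$v_group_mean)
  expect_identical(s$gain, cfg$gain_mean)
  # patients sit at the offset population mean
  p <- gen_subject_params(cfg, "patient", "PD01")
  expect_identical(p$v_true, cfg$v_group_mean + cfg$patient_v_offset)
})

test_that("identical seeds give identical draws; substreams differ by subject", {
  cfg <- generator_config(seed = 42)
  a <- gen_subject_params(cfg, "control", "HC01")
  b <- gen_subject_params(cfg, "control", "HC01")
  expect_identical(a, b)
  c_ <- gen_subject_params(cfg, "control", "HC02")
  expect_false(identical(a$v_true, c_$v_true))
})

test_that("population draws of V obey the law of large numbers", {
  cfg <- generator_config(v_group_mean = 130, v_group_sd = 10, seed = 9)
  v <- vapply(seq_len(10000), function(i)
    gen_subject_params(cfg, "control", sprintf("HC%05d", i))$v_true,
    numeric(1))
  expect_lt(abs(mean(v) - 130), 3 * 10 / sqrt(10000))
})

test_that("noise-free prosaccades sit exactly on the main sequence", {
  cfg <- noiseless_config()
  s <- control_subject(cfg)
  tr <- gen_prosaccade_trials(s, cfg, "control")
  ev <- tr$events
  expect_equal(ev$amplitude_deg, abs(ev$target_eccentricity_deg))
  expect_lt(max(abs(ev$peak_velocity_deg_s - s$v_true * sqrt(ev$amplitude_deg))),
            1e-9)
  # noise-free point check: gain 1, +5 deg, V = 130
  five <- ev[ev$target_eccentricity_deg == 5, ][1, ]
  expect_equal(five$amplitude_deg, 5)
  expect_equal(five$peak_velocity_deg_s, 130 * sqrt(5))
})

test_that("trial schedules balance eccentricities and respect the latency floor", {
  cfg <- generator_config(seed = 3)
  s <- control_subject(cfg)
  tr <- gen_prosaccade_trials(s, cfg, "control", samples = FALSE)
  counts <- table(tr$trials$target_eccentricity_deg)
  expect_setequal(as.integer(names(counts)), c(-7, -5, -3, 3, 5, 7))
  expect_true(all(counts == 4))
  expect_true(all(tr$trials$true_latency_ms > cfg$latency_shift))
  bad <- generator_config(trials_per_task = 25)
  expect_error(gen_prosaccade_trials(s, bad, "control"), "divisible")
})

test_that("attached velocity profiles peak at the drawn value and integrate to amplitude", {
  cfg <- generator_config(seed = 13)
  s <- control_subject(cfg)
  tr <- gen_prosaccade_trials(s, cfg, "control")
  vs <- split(tr$velocity_samples, tr$velocity_samples$trial_index)
  ev <- tr$events[tr$events$amplitude_deg > 1.5, ]   # primaries only
  for (i in as.character(ev$trial_index)) {
    v <- vs[[i]]
    t_s <- v$t_norm * v$duration_ms[1] / 1000
    integral <- sum(diff(t_s) * (head(v$velocity, -1) + tail(v$velocity, -1)) / 2)
    amp <- ev$amplitude_deg[ev$trial_index == as.integer(i)]
    expect_lt(abs(integral - amp) / amp, 0.01)
    expect_equal(max(v$velocity),
                 ev$peak_velocity_deg_s[ev$trial_index == as.integer(i)],
                 tolerance = 1e-3)
  }
})

test_that("antisaccade errors vanish at extreme negative propensity and track latency", {
  cfg <- generator_config(error_propensity_mean = -20, error_propensity_sd = 0,
                          urgency_coupling = 0, seed = 21)
  s <- gen_subject_params(cfg, "control", "HC01")
  tr <- gen_antisaccade_trials(s, cfg, "control", samples = FALSE)
  expect_true(all(tr$trials$true_correct))

  # Monte-Carlo check of the built-in latency-error coupling
  cfg2 <- generator_config(trials_per_task = 5004, urgency_coupling = 1,
                           distractor_rate = 0, seed = 22)
  s2 <- gen_subject_params(cfg2, "control", "HC01")
  tr2 <- gen_antisaccade_trials(s2, cfg2, "control", samples = FALSE)
  lat <- tr2$trials$true_latency_ms
  err <- !tr2$trials$true_correct
  expect_gt(sum(err), 50)
  expect_lt(mean(lat[err]), mean(lat[!err]))

  # determinism of the error pattern
  tr3 <- gen_antisaccade_trials(s2, cfg2, "control", samples = FALSE)
  expect_identical(tr2$trials$true_correct, tr3$trials$true_correct)
})

test_that("pupil traces have the right length, shift and blink statistics", {
  cfg <- noiseless_config()
  s <- control_subject(cfg)
  tr <- gen_pupil_trace(s, cfg, "control", duration_s = 180)
  expect_length(tr$diameter, 90000)           # 3 min at 500 Hz
  expect_true(all(tr$valid))
  expect_equal(diff(range(tr$diameter)), 0)   # constant at zero noise/drift

  cfg2 <- noiseless_config(drug_effect = list(latency_shift = 0, v_shift = 0,
                                              error_logit_shift = 0,
                                              pupil_shift = 0.5))
  p <- gen_subject_params(cfg2, "patient", "PD01")
  atx <- gen_pupil_trace(p, cfg2, "atomoxetine", duration_s = 10)
  plc <- gen_pupil_trace(p, cfg2, "placebo", duration_s = 10)
  expect_equal(mean(atx$diameter) - mean(plc$diameter), 0.5)

  cfg3 <- generator_config(blink_rate = 20, seed = 31)
  s3 <- control_subject(cfg3)
  tr3 <- gen_pupil_trace(s3, cfg3, "control", duration_s = 60)
  expect_gt(sum(!tr3$valid), 0)
  runs <- rle(!tr3$valid)
  expect_true(all(runs$lengths[runs$values] <= 0.3 * 500))  # blinks < 300 ms
})

test_that("cohorts have the crossover structure and deterministic serialization", {
  cfg <- small_config()
  co <- gen_cohort(cfg, pupil = FALSE, samples = FALSE)
  expect_equal(nrow(co$sessions), 4 * 2 + 5)
  pat <- co$sessions[co$sessions$group == "patient", ]
  for (id in unique(pat$subject_id))
    expect_setequal(pat$condition[pat$subject_id == id],
                    c("atomoxetine", "placebo"))
  first <- pat$condition[pat$visit_order == 1]
  expect_true(all(c("atomoxetine", "placebo") %in% first))
  expect_equal(nrow(co$trials), (4 * 2 + 5) * 48)

  co2 <- gen_cohort(cfg, pupil = FALSE, samples = FALSE)
  expect_identical(co$events, co2$events)
  expect_identical(co$truth, co2$truth)

  # default study dimensions: 19 x 2 + 25 sessions
  dflt <- generator_config(seed = 1)
  ids <- c(sprintf("PD%02d", 1:19), sprintf("HC%02d", 1:25))
  expect_equal(19 * 2 + 25, 63)
  expect_equal(length(ids), 44)
})

test_that("written cohorts round-trip through the strict readers", {
  cfg <- small_config(pupil_duration_s = 16)
  co <- gen_cohort(cfg, pupil = TRUE, samples = FALSE)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  ev <- read_events(file.path(dir, "events.tsv"))
  expect_equal(nrow(ev), nrow(co$events))
  expect_equal(ev$peak_velocity_deg_s, co$events$peak_velocity_deg_s,
               tolerance = 1e-12)
  pu <- read_pupil(file.path(dir, "pupil.csv"))
  expect_equal(nrow(pu), nrow(co$pupil))
})
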