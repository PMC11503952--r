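# Trial parsing: gates, direction classification, participant-level
# outlier filtering and task summaries.

test_that("primary selection applies strict amplitude and latency gates", {
  tt <- make_trial(list(list(amp = 0.8, lat = 120), list(amp = 4.2, lat = 210)))
  p <- select_primary(tt$events, tt$trial)
  expect_true(p$valid)
  expect_equal(p$amplitude_deg, 4.2)          # first event fails the gate

  anticipatory <- make_trial(list(list(amp = 5, lat = 80)))
  p2 <- select_primary(anticipatory$events, anticipatory$trial)
  expect_false(p2$valid)
  expect_equal(p2$removal_reason, "no_valid_primary")

  boundary <- make_trial(list(list(amp = 1.5, lat = 200)))
  p3 <- select_primary(boundary$events, boundary$trial)
  expect_false(p3$valid)                      # the bound is exclusive (> 1.5)

  # other boundaries are exclusive too
  for (e in list(list(amp = 10, lat = 200), list(amp = 5, lat = 90),
                 list(amp = 5, lat = 2500))) {
    b <- make_trial(list(e))
    expect_false(select_primary(b$events, b$trial)$valid)
  }

  # a trial with no events at all is invalid
  lone <- make_trial(list(list(amp = 4, lat = 200)), trial_index = 1)
  no_ev <- make_trial(list(list(amp = 4, lat = 200)), trial_index = 2)
  trials <- rbind(lone$trial, no_ev$trial)
  p4 <- select_primary(lone$events, trials)
  expect_equal(sum(p4$valid), 1)
})

test_that("direction classification matches the task rules", {
  a <- make_trial(list(list(amp = 4.1, lat = 200, end = 4.1)),
                  task = "antisaccade", ecc = 5)
  ca <- classify_direction(select_primary(a$events, a$trial))
  expect_false(ca$correct)                    # toward target on antisaccade

  b <- make_trial(list(list(amp = 2.8, lat = 200, end = -2.8)),
                  task = "prosaccade", ecc = -3)
  cb <- classify_direction(select_primary(b$events, b$trial))
  expect_true(cb$correct)

  c_ <- make_trial(list(list(amp = 5, lat = 200, end = -5)),
                   task = "antisaccade", ecc = 7)
  cc <- classify_direction(select_primary(c_$events, c_$trial))
  expect_true(cc$correct)

  # wrong-way prosaccade is discarded under the default rule
  d <- make_trial(list(list(amp = 4, lat = 200, end = -4)),
                  task = "prosaccade", ecc = 5)
  cd <- classify_direction(select_primary(d$events, d$trial))
  expect_false(cd$valid)
  expect_equal(cd$removal_reason, "prosaccade_wrong_direction")

  # zero horizontal displacement is ambiguous
  e <- make_trial(list(list(amp = 4, lat = 200, start = 2, end = 2)))
  ce <- classify_direction(select_primary(e$events, e$trial))
  expect_false(ce$valid)
  expect_equal(ce$removal_reason, "ambiguous_direction")
})

test_that("first_toward rule recovers a later toward-target prosaccade", {
  tt <- make_trial(list(list(amp = 4, lat = 150, end = -4),
                        list(amp = 4.5, lat = 300, end = 4.5)), ecc = 5)
  # default: the wrong-way first saccade is primary, trial discarded
  dflt <- classify_direction(select_primary(tt$events, tt$trial))
  expect_false(dflt$valid)
  # alternative: search on for the first toward-target valid saccade
  alt <- classify_direction(
    select_primary(tt$events, tt$trial, prosaccade_rule = "first_toward"),
    prosaccade_rule = "first_toward")
  expect_true(alt$valid)
  expect_equal(alt$latency_ms, 300)
})

test_that("the 2.5 SD filter removes the hand-computed outlier in one pass", {
  lats <- c(rep(200, 9), 2000)
  trials <- do.call(bind_trials, lapply(seq_along(lats), function(i)
    make_trial(list(list(amp = 4, lat = lats[i])), task = "antisaccade",
               ecc = 5, trial_index = i)))
  p <- classify_direction(select_primary(trials$events, trials$trials))
  f <- participant_outlier_filter(p, k = 2.5)
  # mean 380, sd 569.2 -> only the 2000 ms trial exceeds 2.5 SD
  expect_equal(sum(!f$valid), 1)
  expect_equal(f$removal_reason[f$latency_ms == 2000], "outlier_latency")
  expect_equal(sum(f$valid), 9)

  # all-identical latencies: SD 0, deviation 0 is not > 0, nothing removed
  same <- do.call(bind_trials, lapply(1:5, function(i)
    make_trial(list(list(amp = 4, lat = 300)), task = "antisaccade",
               ecc = 5, trial_index = i)))
  ps <- classify_direction(select_primary(same$events, same$trials))
  fs <- participant_outlier_filter(ps)
  expect_true(all(fs$valid))

  # fewer than 3 valid trials: flagged, unfiltered
  two <- do.call(bind_trials, lapply(1:2, function(i)
    make_trial(list(list(amp = 4, lat = 100 * i + 100)), task = "antisaccade",
               ecc = 5, trial_index = i)))
  ft <- participant_outlier_filter(
    classify_direction(select_primary(two$events, two$trials)))
  expect_true(all(ft$cell_too_small))
  expect_true(all(ft$valid))
})

test_that("prosaccade filtering screens velocity residuals within participant", {
  set.seed(8)
  n <- 20
  amp <- runif(n, 2, 8)
  pv <- 60 + 65 * amp + rnorm(n, 0, 5)
  pv[7] <- 60 + 65 * amp[7] + 400          # huge residual, typical velocity range
  trials <- do.call(bind_trials, lapply(seq_len(n), function(i)
    make_trial(list(list(amp = amp[i], lat = 200, pv = pv[i])),
               task = "prosaccade", ecc = 5, trial_index = i)))
  p <- classify_direction(select_primary(trials$events, trials$trials))
  f <- participant_outlier_filter(p)
  expect_false(f$valid[f$trial_index == 7])
  expect_equal(f$removal_reason[f$trial_index == 7], "outlier_velocity_residual")
})

test_that("task summaries count completions and error rates as defined", {
  correct <- c(rep(TRUE, 17), rep(FALSE, 5))
  lats <- c(rep(250, 22), 5000, 5000)        # last two removed by the gate
  trials <- do.call(bind_trials, lapply(1:24, function(i)
    make_trial(list(list(amp = 4, lat = lats[i],
                         end = if (i <= 22 && !correct[i]) 4 else -4)),
               task = "antisaccade", ecc = 5, trial_index = i)))
  parsed <- parse_trials(trials$events, trials$trials)
  s <- parsed$summary
  expect_equal(s$n_trials_total, 24)
  expect_equal(s$n_removed, 2)
  expect_equal(s$n_errors, 5)
  expect_equal(s$error_rate, 5 / 22)
  expect_equal(nrow(parsed$removal_log), 2)

  # degenerate rates
  all_err <- do.call(bind_trials, lapply(1:4, function(i)
    make_trial(list(list(amp = 4, lat = 250, end = 4)),
               task = "antisaccade", ecc = 5, trial_index = i)))
  sa <- parse_trials(all_err$events, all_err$trials)$summary
  expect_equal(sa$error_rate, 1)
})

test_that("parsing a simulated cohort is idempotent and conserves trials", {
  cfg <- small_config(seed = 55)
  co <- gen_cohort(cfg, pupil = FALSE, samples = FALSE)
  p1 <- parse_trials(co$events, co$trials)
  p2 <- parse_trials(co$events, co$trials)
  expect_identical(p1$primary, p2$primary)
  # conservation: every removed trial appears exactly once in the log
  expect_equal(nrow(p1$removal_log),
               sum(p1$summary$n_trials_total) - sum(p1$summary$n_completed))
  expect_equal(sum(p1$summary$n_trials_total), nrow(co$trials))
})

test_that("observed error rates track the generator's ground truth", {
  cfg <- generator_config(seed = 66, urgency_coupling = 0,
                          error_propensity_sd = 0, error_propensity_mean = -1,
                          trials_per_task = 240, distractor_rate = 0)
  s <- gen_subject_params(cfg, "control", "HC01")
  tr <- gen_antisaccade_trials(s, cfg, "control", samples = FALSE)
  p_true <- plogis(-1)
  obs <- mean(!tr$trials$true_correct)
  halfwidth <- 2.58 * sqrt(p_true * (1 - p_true) / 240)
  expect_lt(abs(obs - p_true), halfwidth)

  # incorrect antisaccades are faster than correct ones with coupling on
  cfg2 <- small_config(seed = 67)
  co <- gen_cohort(cfg2, pupil = FALSE, samples = FALSE)
  parsed <- parse_trials(co$events, co$trials)
  anti <- parsed$primary[parsed$primary$valid &
                           parsed$primary$task == "antisaccade", ]
  expect_lt(mean(anti$latency_ms[!anti$correct]),
            mean(anti$latency_ms[anti$correct]))
})
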