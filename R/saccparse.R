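# Trial parsing: primary-saccade selection under amplitude/latency gates,
# direction classification, participant-level +/-2.5 SD outlier filtering,
# and task summaries (antisaccade error rates).

trial_key_cols <- c("subject_id", "condition", "task", "trial_index")

#' Select the primary saccade per trial
#'
#' The primary saccade is the first event (by onset) whose amplitude lies
#' strictly inside `amp_bounds` and whose latency lies strictly inside
#' `lat_bounds` (both bounds exclusive, as the gates are meant to rule out
#' microsaccades, off-screen saccades, anticipations and inattention).
#' For prosaccade trials with `prosaccade_rule = "first_toward"` only
#' toward-target events are eligible; with the default `"discard"` the first
#' valid event is taken regardless of direction and wrong-way prosaccades
#' are invalidated later by [classify_direction()].
#'
#' @param events data frame in the `events.tsv` schema (one row per
#'   detected saccade), ordered or orderable by `sacc_onset_ms` within trial.
#' @param trials data frame of trial metadata (`trials.tsv` schema); one row
#'   per trial.  Trials without any event are marked invalid.
#' @param amp_bounds exclusive amplitude gate (deg).
#' @param lat_bounds exclusive latency gate (ms).
#' @param prosaccade_rule `"discard"` or `"first_toward"`.
#' @return the trials data frame augmented with the primary saccade's
#'   kinematics (`latency_ms`, `amplitude_deg`, `peak_velocity_deg_s`,
#'   `sacc_duration_ms`, `start_x_deg`, `end_x_deg`), plus `valid` and
#'   `removal_reason`.
#' @export
select_primary <- function(events, trials, amp_bounds = c(1.5, 10),
                           lat_bounds = c(90, 2500),
                           prosaccade_rule = c("discard", "first_toward")) {
  prosaccade_rule <- match.arg(prosaccade_rule)
  ev <- events[order(events$subject_id, events$condition, events$task,
                     events$trial_index, events$sacc_onset_ms), ]
  pass <- ev$amplitude_deg > amp_bounds[1] & ev$amplitude_deg < amp_bounds[2] &
    ev$sacc_onset_ms > lat_bounds[1] & ev$sacc_onset_ms < lat_bounds[2]
  if (prosaccade_rule == "first_toward") {
    toward <- sign(ev$end_x_deg - ev$start_x_deg) ==
      sign(ev$target_eccentricity_deg)
    pass <- pass & (ev$task != "prosaccade" | toward)
  }
  ev <- ev[pass, ]
  first <- ev[!duplicated(ev[trial_key_cols]), ]

  out <- trials
  out$key <- do.call(paste, c(out[trial_key_cols], sep = "\r"))
  first$key <- do.call(paste, c(first[trial_key_cols], sep = "\r"))
  m <- match(out$key, first$key)
  out$latency_ms <- first$sacc_onset_ms[m]
  out$amplitude_deg <- first$amplitude_deg[m]
  out$peak_velocity_deg_s <- first$peak_velocity_deg_s[m]
  out$sacc_duration_ms <- first$sacc_duration_ms[m]
  out$start_x_deg <- first$start_x_deg[m]
  out$end_x_deg <- first$end_x_deg[m]
  out$key <- NULL
  out$valid <- !is.na(m)
  out$removal_reason <- ifelse(out$valid, NA_character_, "no_valid_primary")
  out
}

#' Classify primary-saccade direction
#'
#' Direction is the sign of the horizontal displacement
#' `end_x_deg - start_x_deg` (the task is horizontal).  A prosaccade is
#' correct if directed toward the target; an antisaccade is correct if
#' directed away.  Zero displacement is flagged ambiguous and the trial
#' invalidated.  Under the default prosaccade rule, prosaccade trials whose
#' primary saccade goes the wrong way are removed from analysis
#' (`removal_reason = "prosaccade_wrong_direction"`); antisaccade trials are
#' kept either way, the incorrect ones counting as errors.
#'
#' @param primary output of [select_primary()].
#' @param prosaccade_rule as in [select_primary()]; under `"first_toward"`
#'   wrong-way prosaccade primaries cannot occur by construction.
#' @return `primary` with a logical `correct` column and updated
#'   validity/removal columns.
#' @export
classify_direction <- function(primary,
                               prosaccade_rule = c("discard", "first_toward")) {
  prosaccade_rule <- match.arg(prosaccade_rule)
  dirn <- sign(primary$end_x_deg - primary$start_x_deg)
  tgt <- sign(primary$target_eccentricity_deg)
  ambiguous <- primary$valid & dirn == 0
  primary$valid[ambiguous] <- FALSE
  primary$removal_reason[ambiguous] <- "ambiguous_direction"
  toward <- dirn == tgt
  primary$correct <- ifelse(primary$task == "prosaccade", toward, !toward)
  primary$correct[!primary$valid] <- NA
  if (prosaccade_rule == "discard") {
    bad <- primary$valid & primary$task == "prosaccade" & !toward
    primary$valid[bad] <- FALSE
    primary$removal_reason[bad] <- "prosaccade_wrong_direction"
    primary$correct[bad] <- NA
  }
  primary
}

#' Participant-level outlier filter
#'
#' Within each (subject, condition, task) cell, removes trials whose
#' measures deviate more than `k` sample SDs from the participant's cell
#' mean.  Prosaccade trials are screened jointly on latency, peak velocity,
#' amplitude, and the within-participant peak-velocity residual (velocity
#' regressed on amplitude inside the cell); antisaccade trials on latency
#' only.  The filter is single-pass: means and SDs are computed once on the
#' incoming valid trials and not recomputed after removals.  Cells with
#' fewer than 3 valid trials are flagged and left unfiltered.
#'
#' @param primary output of [classify_direction()].
#' @param k SD multiplier.
#' @return `primary` with outlier trials invalidated
#'   (`removal_reason = "outlier_<measure>"`) and a logical
#'   `cell_too_small` column.
#' @export
participant_outlier_filter <- function(primary, k = 2.5) {
  primary$cell_too_small <- FALSE
  cell <- interaction(primary$subject_id, primary$condition, primary$task,
                      drop = TRUE)
  for (cl in levels(cell)) {
    idx <- which(cell == cl & primary$valid)
    if (length(idx) == 0) next
    if (length(idx) < 3) {
      primary$cell_too_small[cell == cl] <- TRUE
      next
    }
    sub <- primary[idx, ]
    screen <- list(latency = sub$latency_ms)
    if (sub$task[1] == "prosaccade") {
      screen$peak_velocity <- sub$peak_velocity_deg_s
      screen$amplitude <- sub$amplitude_deg
      if (sd0(sub$amplitude_deg) > 0) {
        fit <- stats::lm.fit(cbind(1, sub$amplitude_deg), sub$peak_velocity_deg_s)
        screen$velocity_residual <- fit$residuals
      }
    }
    reason <- rep(NA_character_, length(idx))
    for (ms in names(screen)) {
      x <- screen[[ms]]
      bad <- abs(x - mean(x)) > k * sd0(x)
      reason[bad & is.na(reason)] <- paste0("outlier_", ms)
    }
    rm_ <- !is.na(reason)
    primary$valid[idx[rm_]] <- FALSE
    primary$removal_reason[idx[rm_]] <- reason[rm_]
    primary$correct[idx[rm_]] <- NA
  }
  primary
}

#' Summarize a parsed trial set
#'
#' Per (subject, condition, task): total trials, removals, completed trials,
#' antisaccade error counts and the error rate
#' `n_errors / (n_trials_total - n_removed)`.
#'
#' @param primary filtered output of [participant_outlier_filter()].
#' @return data frame with one row per cell, with columns `n_trials_total`,
#'   `n_removed`, `n_completed`, `n_errors`, `error_rate` (NA for
#'   prosaccade rows and for cells with zero completed trials, the latter
#'   flagged by `undefined_rate`).
#' @export
summarize_task <- function(primary) {
  if (!"group" %in% names(primary)) primary$group <- NA_character_
  cells <- unique(primary[c("subject_id", "group", "condition", "task")])
  rownames(cells) <- NULL
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- primary$subject_id == cells$subject_id[i] &
      primary$condition == cells$condition[i] & primary$task == cells$task[i]
    sub <- primary[sel, ]
    n_total <- nrow(sub)
    n_removed <- sum(!sub$valid)
    n_completed <- n_total - n_removed
    is_anti <- cells$task[i] == "antisaccade"
    n_errors <- if (is_anti) sum(!sub$correct[sub$valid]) else NA_integer_
    rate <- if (is_anti && n_completed > 0) n_errors / n_completed else NA_real_
    data.frame(cells[i, ], n_trials_total = n_total, n_removed = n_removed,
               n_completed = n_completed, n_errors = n_errors,
               error_rate = rate,
               undefined_rate = is_anti && n_completed == 0,
               mean_latency_ms = mean(sub$latency_ms[sub$valid]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Parse a cohort's event tables end to end
#'
#' Chains [select_primary()], [classify_direction()],
#' [participant_outlier_filter()] and [summarize_task()], and extracts the
#' removal log.
#'
#' @inheritParams select_primary
#' @param k outlier-filter SD multiplier.
#' @return list with `primary` (tidy per-trial rows), `removal_log` and
#'   `summary` data frames.
#' @export
parse_trials <- function(events, trials, amp_bounds = c(1.5, 10),
                         lat_bounds = c(90, 2500), k = 2.5,
                         prosaccade_rule = c("discard", "first_toward")) {
  prosaccade_rule <- match.arg(prosaccade_rule)
  p <- select_primary(events, trials, amp_bounds, lat_bounds, prosaccade_rule)
  p <- classify_direction(p, prosaccade_rule)
  p <- participant_outlier_filter(p, k)
  log_cols <- c(trial_key_cols, "removal_reason")
  removal_log <- p[!p$valid, log_cols]
  rownames(removal_log) <- NULL
  list(primary = p, removal_log = removal_log, summary = summarize_task(p))
}
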