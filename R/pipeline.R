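# Orchestration and file formats: strict TSV/CSV readers and writers, the
# run configuration, and the end-to-end driver that chains simulation,
# pupil preprocessing, trial parsing, kinematics, main-sequence modelling
# and the inferential summaries, with a reproducibility manifest.

events_schema <- c("subject_id", "group", "condition", "task", "trial_index",
                   "target_onset_ms", "target_side", "target_eccentricity_deg",
                   "sacc_onset_ms", "sacc_duration_ms", "amplitude_deg",
                   "peak_velocity_deg_s", "start_x_deg", "end_x_deg")
events_numeric <- c("trial_index", "target_onset_ms", "target_eccentricity_deg",
                    "sacc_onset_ms", "sacc_duration_ms", "amplitude_deg",
                    "peak_velocity_deg_s", "start_x_deg", "end_x_deg")
pupil_schema <- c("subject_id", "condition", "time_ms", "pupil_au", "valid")

check_schema <- function(df, required, numeric_cols, path) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  for (cl in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[cl]])) {
      v <- suppressWarnings(as.numeric(df[[cl]]))
      if (any(is.na(v) & !is.na(df[[cl]])))
        stopf("%s: column '%s' is not parseable as numeric (decimal commas or stray text?)",
              path, cl)
      df[[cl]] <- v
    }
  }
  df
}

#' Read a saccade event table
#'
#' Reads a tab-separated `events.tsv` with a mandatory header, validates the
#' required columns and rejects non-numeric content (e.g. localized decimal
#' commas) in numeric fields with a column-level error.  Unknown columns are
#' preserved.
#'
#' @param path path to the TSV file.
#' @return data frame of saccade events.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("read_events: no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_schema(df, events_schema, events_numeric, path)
}

#' Read a long-format pupil table
#'
#' @param path path to `pupil.csv`.
#' @return data frame with `subject_id`, `condition`, `time_ms`, `pupil_au`,
#'   `valid`.
#' @export
read_pupil <- function(path) {
  if (!file.exists(path)) stopf("read_pupil: no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- check_schema(df, pupil_schema, c("time_ms", "pupil_au"), path)
  df$valid <- as.logical(df$valid)
  df
}

#' Write a data frame as a headered TSV
#'
#' Plain UTF-8, tab separation, no quoting, no row names; the format every
#' tabular artifact of the pipeline uses.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects the seed, the generator configuration (or paths to existing
#' input tables), every module parameter, and the output directory.
#'
#' @param out_dir output directory.
#' @param seed global integer seed (propagated to the generator unless a
#'   generator config is supplied explicitly).
#' @param generator a [generator_config()]; defaults to
#'   `generator_config(seed = seed)`.  Set to `NULL` to run from existing
#'   files instead of simulating.
#' @param events_path,pupil_path,trials_path input paths, used when
#'   `generator` is `NULL`.
#' @param window_s,max_missing,pad_ms,hann_ms,clip_sd pupil parameters.
#' @param pupil_normalize z-scoring baseline scope, `"subject"` or
#'   `"session"`.
#' @param amp_bounds,lat_bounds,sd_k,prosaccade_rule parsing parameters.
#' @param n_boot bootstrap resamples for the main-sequence fits.
#' @param prior_scale JZS Cauchy prior scale.
#' @param run_pupil,run_profiles enable/disable optional stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       generator = generator_config(seed = seed),
                       events_path = NULL, pupil_path = NULL,
                       trials_path = NULL,
                       window_s = 15, max_missing = 0.15, pad_ms = 100,
                       hann_ms = 200, clip_sd = 3,
                       pupil_normalize = "subject",
                       amp_bounds = c(1.5, 10), lat_bounds = c(90, 2500),
                       sd_k = 2.5, prosaccade_rule = "discard",
                       n_boot = 1000, prior_scale = sqrt(2) / 2,
                       run_pupil = TRUE, run_profiles = TRUE) {
  cfg <- as.list(environment())
  if (!is.null(cfg$generator)) validate_generator_config(cfg$generator)
  if (is.null(cfg$generator) && is.null(cfg$events_path))
    stopf("run_config: either a generator config or events_path is required")
  stopifnot(amp_bounds[1] < amp_bounds[2], lat_bounds[1] < lat_bounds[2],
            sd_k > 0, n_boot >= 1, prior_scale > 0)
  class(cfg) <- "run_config"
  cfg
}

config_digest <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (or reading of existing tables), pupil
#' preprocessing, trial parsing and filtering, velocity residuals and
#' time-normalized profiles, main-sequence fits (control reference first,
#' then per patient condition) with normative deviation tests, and the
#' inferential summary.  All tabular outputs are written under
#' `config$out_dir` together with a human-readable `report.txt` and a
#' `manifest.json` recording the config hash, input checksums, per-stage
#' row counts, package version and seed.
#'
#' @param config a [run_config()].
#' @return list of class `run_result` with the in-memory outputs and the
#'   manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  checksums <- list()

  # --- simulate or load -----------------------------------------------------
  if (!is.null(config$generator)) {
    cohort <- stage("simulate", gen_cohort(config$generator,
                                           pupil = config$run_pupil,
                                           samples = config$run_profiles))
    stage("simulate", write_cohort(cohort, config$out_dir))
    events <- cohort$events; trials <- cohort$trials
    pupil <- cohort$pupil; vel <- cohort$velocity_samples
  } else {
    events <- stage("read", read_events(config$events_path))
    checksums[[config$events_path]] <- unname(tools::md5sum(config$events_path))
    trials <- if (!is.null(config$trials_path)) {
      checksums[[config$trials_path]] <- unname(tools::md5sum(config$trials_path))
      stage("read", utils::read.delim(config$trials_path, stringsAsFactors = FALSE))
    } else unique(events[c("subject_id", "group", "condition", "task",
                           "trial_index", "target_side",
                           "target_eccentricity_deg", "target_onset_ms")])
    pupil <- NULL
    if (config$run_pupil) {
      if (is.null(config$pupil_path) || !file.exists(config$pupil_path %||% ""))
        stopf("pipeline stage 'pupil' failed: pupil input file not found (%s)",
              config$pupil_path %||% "<unset>")
      checksums[[config$pupil_path]] <- unname(tools::md5sum(config$pupil_path))
      pupil <- stage("pupil", read_pupil(config$pupil_path))
    }
    vel <- NULL
  }
  counts$events <- nrow(events); counts$trials <- nrow(trials)

  # --- pupil ----------------------------------------------------------------
  pupil_summary <- NULL
  if (config$run_pupil && !is.null(pupil)) {
    fs <- if (!is.null(config$generator)) config$generator$sampling_rate else 500
    pupil_summary <- stage("pupil", process_pupil_cohort(
      pupil, sampling_rate = fs, normalize = config$pupil_normalize,
      window_s = config$window_s, max_missing = config$max_missing,
      pad_ms = config$pad_ms, hann_ms = config$hann_ms,
      clip_sd = config$clip_sd))
    write_tsv(pupil_summary, file.path(config$out_dir, "pupil_summary.tsv"))
    counts$pupil_sessions <- nrow(pupil_summary)
  }

  # --- parse ----------------------------------------------------------------
  parsed <- stage("parse", parse_trials(
    events, trials, amp_bounds = config$amp_bounds,
    lat_bounds = config$lat_bounds, k = config$sd_k,
    prosaccade_rule = config$prosaccade_rule))
  write_tsv(parsed$primary, file.path(config$out_dir, "primary_saccades.tsv"))
  write_tsv(parsed$removal_log, file.path(config$out_dir, "removal_log.tsv"))
  write_tsv(parsed$summary, file.path(config$out_dir, "task_summary.tsv"))
  counts$primary_valid <- sum(parsed$primary$valid)
  counts$removed <- nrow(parsed$removal_log)

  pro <- parsed$primary[parsed$primary$valid &
                          parsed$primary$task == "prosaccade", ]

  # --- kinematics -----------------------------------------------------------
  resid <- stage("kinemetrics", fit_velocity_residuals(pro, scope = "global"))
  write_tsv(resid$data, file.path(config$out_dir, "residuals.tsv"))
  if (config$run_profiles && !is.null(vel)) {
    keep <- do.call(paste, c(pro[trial_key_cols], sep = "\r"))
    vkey <- do.call(paste, c(vel[trial_key_cols], sep = "\r"))
    prof <- stage("kinemetrics",
                  time_normalized_profile(vel[vkey %in% keep, ]))
    write_tsv(prof, file.path(config$out_dir, "profiles.tsv"))
    write_tsv(aggregate_profiles(prof),
              file.path(config$out_dir, "profiles_group.tsv"))
    counts$profile_saccades <- nrow(prof) / 10
  }

  # --- main sequence --------------------------------------------------------
  seed0 <- if (!is.null(config$generator)) config$generator$seed else config$seed
  fits <- list(); deltas <- list()
  grp <- function(cond) pro[pro$condition == cond, ]
  for (cond in intersect(c("control", "placebo", "atomoxetine"),
                         unique(pro$condition))) {
    g <- grp(cond)
    fits[[cond]] <- stage("mainseq", bootstrap_v(
      g$amplitude_deg, g$peak_velocity_deg_s, n_boot = config$n_boot,
      seed = child_seed(seed0, paste0("boot:", cond))))
  }
  if (!is.null(fits$control)) {
    for (cond in intersect(c("placebo", "atomoxetine"), names(fits))) {
      g <- grp(cond)
      deltas[[cond]] <- stage("mainseq", delta_peak_velocity(
        g$amplitude_deg, g$peak_velocity_deg_s, v_ref = fits$control$V,
        prior_scale = config$prior_scale))
    }
  }
  fit_json <- lapply(fits, function(f)
    list(V = f$V, v_point = f$v_point, ci95 = f$ci95,
         n_saccades = f$n_saccades, n_boot = f$n_boot, seed = f$seed))
  jsonlite::write_json(fit_json, file.path(config$out_dir, "mainseq_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(deltas)) {
    dtab <- do.call(rbind, lapply(names(deltas), function(cd) data.frame(
      condition = cd, n = deltas[[cd]]$n, v_ref = deltas[[cd]]$v_ref,
      mean_delta = deltas[[cd]]$mean, se = deltas[[cd]]$se,
      t = deltas[[cd]]$t, df = deltas[[cd]]$df, p = deltas[[cd]]$p,
      bf10 = deltas[[cd]]$bf10, stringsAsFactors = FALSE)))
    write_tsv(dtab, file.path(config$out_dir, "deltas.tsv"))
  }

  # --- stats ----------------------------------------------------------------
  stats_rows <- list()
  if (!is.null(pupil_summary)) {
    atx <- pupil_summary[pupil_summary$condition == "atomoxetine", ]
    plc <- pupil_summary[pupil_summary$condition == "placebo", ]
    common <- intersect(atx$subject_id, plc$subject_id)
    if (length(common) >= 2) {
      d <- atx$mean_z[match(common, atx$subject_id)] -
        plc$mean_z[match(common, plc$subject_id)]
      tt <- stats::t.test(d, mu = 0)
      bf <- jzs_bf_t(unname(tt$statistic), n1 = length(d),
                     prior_scale = config$prior_scale)
      stats_rows$pupil <- data.frame(
        measure = "pupil_mean_z_atomoxetine_minus_placebo",
        n = length(d), estimate = mean(d), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value, bf10 = bf$bf10,
        stringsAsFactors = FALSE)
    }
  }
  for (cd in names(deltas))
    stats_rows[[paste0("delta_", cd)]] <- data.frame(
      measure = paste0("delta_peak_velocity_", cd, "_vs_control"),
      n = deltas[[cd]]$n, estimate = deltas[[cd]]$mean, t = deltas[[cd]]$t,
      df = deltas[[cd]]$df, p = deltas[[cd]]$p, bf10 = deltas[[cd]]$bf10,
      stringsAsFactors = FALSE)
  stats_tab <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  if (!is.null(stats_tab)) {
    rownames(stats_tab) <- NULL
    write_tsv(stats_tab, file.path(config$out_dir, "stats_summary.tsv"))
  }

  # --- report + manifest ----------------------------------------------------
  rpt <- file.path(config$out_dir, "report.txt")
  lines <- c("saccadeflow pipeline report",
             sprintf("seed: %d", seed0),
             sprintf("events: %d rows; trials: %d; valid primaries: %d; removed: %d",
                     counts$events, counts$trials, counts$primary_valid,
                     counts$removed),
             "",
             "Main-sequence fits (V, deg/s per sqrt(deg)):",
             vapply(names(fits), function(cd) sprintf(
               "  %-12s V = %7.2f  [%.2f, %.2f]  n = %d", cd, fits[[cd]]$V,
               fits[[cd]]$ci95[1], fits[[cd]]$ci95[2], fits[[cd]]$n_saccades),
               character(1)))
  if (length(deltas))
    lines <- c(lines, "", "Delta peak velocity vs control curve:",
               vapply(names(deltas), function(cd) sprintf(
                 "  %-12s mean = %6.2f deg/s, t(%d) = %.2f, p = %.4g, BF10 = %.3g",
                 cd, deltas[[cd]]$mean, deltas[[cd]]$df, deltas[[cd]]$t,
                 deltas[[cd]]$p, deltas[[cd]]$bf10), character(1)))
  if (!is.null(stats_tab) && "pupil" %in% names(stats_rows))
    lines <- c(lines, "", sprintf(
      "Pupil (paired, drug - placebo): mean dz = %.3f, t(%d) = %.2f, p = %.4g, BF10 = %.3g",
      stats_rows$pupil$estimate, stats_rows$pupil$df, stats_rows$pupil$t,
      stats_rows$pupil$p, stats_rows$pupil$bf10))
  writeLines(lines, rpt)

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  manifest <- list(
    package = "saccadeflow",
    version = as.character(utils::packageVersion("saccadeflow")),
    seed = seed0,
    config_md5 = config_digest(unclass(config)),
    input_checksums = checksums,
    output_checksums = as.list(tools::md5sum(sort(outputs))),
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(manifest = manifest, parsed = parsed,
                 pupil_summary = pupil_summary, residuals = resid,
                 fits = fits, deltas = deltas, stats = stats_tab),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("saccadeflow run:", x$manifest$row_counts$events, "events,",
      x$manifest$row_counts$primary_valid, "valid primary saccades\n")
  for (cd in names(x$fits))
    cat(sprintf("  V[%s] = %.2f\n", cd, x$fits[[cd]]$V))
  invisible(x)
}
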