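# Saccade kinematics beyond the raw event table: peak-velocity residuals
# (velocity with the main-sequence amplitude dependence regressed out) and
# time-normalized velocity / amplitude profiles in 10 bins.

#' Fit peak-velocity residuals
#'
#' Ordinary least squares of peak velocity on amplitude
#' (`velocity = a + b * amplitude + e`); the residuals serve as the
#' amplitude-corrected velocity measure.  The regression scope is either
#' `"global"` (one fit pooled over all rows, so residuals are comparable
#' across conditions) or `"participant"` (one fit per subject/condition/task
#' cell, as used by the outlier filter).
#'
#' @param data data frame with `amplitude_deg` and `peak_velocity_deg_s`
#'   (and the cell columns when `scope = "participant"`).
#' @param scope `"global"` or `"participant"`.
#' @return list of class `residual_model`: `coefficients` (data frame with
#'   `intercept`, `slope` and the fit scope) and `data` (the input with a
#'   `velocity_residual` column).  Residuals within every fitted scope sum
#'   to zero and are orthogonal to amplitude.
#' @export
fit_velocity_residuals <- function(data, scope = c("global", "participant")) {
  scope <- match.arg(scope)
  if (nrow(data) < 3) stopf("fit_velocity_residuals: need >= 3 saccades")
  fit_one <- function(df, label) {
    if (sd0(df$amplitude_deg) == 0)
      stopf("fit_velocity_residuals: constant amplitude in scope '%s' (rank deficient)",
            label)
    f <- stats::lm(peak_velocity_deg_s ~ amplitude_deg, data = df)
    list(coef = data.frame(scope = label,
                           intercept = unname(stats::coef(f)[1]),
                           slope = unname(stats::coef(f)[2]),
                           n = nrow(df), stringsAsFactors = FALSE),
         resid = unname(stats::resid(f)))
  }
  data$velocity_residual <- NA_real_
  if (scope == "global") {
    f <- fit_one(data, "global")
    data$velocity_residual <- f$resid
    coefs <- f$coef
  } else {
    cell <- interaction(data$subject_id, data$condition, data$task, drop = TRUE)
    coefs <- list()
    for (cl in levels(cell)) {
      idx <- which(cell == cl)
      f <- fit_one(data[idx, ], cl)
      data$velocity_residual[idx] <- f$resid
      coefs[[cl]] <- f$coef
    }
    coefs <- do.call(rbind, coefs)
    rownames(coefs) <- NULL
  }
  structure(list(coefficients = coefs, data = data, scope = scope),
            class = "residual_model")
}

#' @export
print.residual_model <- function(x, ...) {
  cat(sprintf("residual_model (%s scope): %d fit(s)\n", x$scope,
              nrow(x$coefficients)))
  print(utils::head(x$coefficients, 5))
  invisible(x)
}

#' Time-normalized saccade profiles
#'
#' Maps each saccade's samples onto normalized time `[0, 1]`, partitions
#' them into `n_bins` equal-width bins (half-open, last bin closed), and
#' returns per-bin mean velocity and mean cumulative amplitude travelled
#' (trapezoidal integral of velocity over real time).  Saccades with fewer
#' than `n_bins` samples are linearly resampled to `10 * n_bins` points
#' first.
#'
#' @param samples data frame with `t_norm`, `velocity`, `duration_ms` and
#'   id columns `subject_id`, `condition`, `task`, `trial_index`
#'   (the `velocity_samples.tsv` schema).
#' @param n_bins number of bins.
#' @return data frame with one row per saccade and bin: id columns,
#'   `bin_index`, `mean_velocity`, `mean_amplitude_travelled`.
#' @export
time_normalized_profile <- function(samples, n_bins = 10) {
  if (nrow(samples) == 0) stopf("time_normalized_profile: empty samples")
  key <- do.call(paste, c(samples[c("subject_id", "condition", "task",
                                    "trial_index")], sep = "\r"))
  out <- lapply(split(samples, key), function(s) {
    s <- s[order(s$t_norm), ]
    t_norm <- s$t_norm; v <- s$velocity
    if (length(t_norm) < n_bins) {
      grid <- seq(0, 1, length.out = 10 * n_bins)
      v <- stats::approx(t_norm, v, xout = grid, rule = 2)$y
      t_norm <- grid
    }
    t_s <- t_norm * s$duration_ms[1] / 1000
    # cumulative trapezoid of velocity over real time = amplitude travelled
    cumamp <- c(0, cumsum(diff(t_s) * (utils::head(v, -1) + utils::tail(v, -1)) / 2))
    bin <- pmin(floor(t_norm * n_bins) + 1L, n_bins)
    data.frame(subject_id = s$subject_id[1], condition = s$condition[1],
               task = s$task[1], trial_index = s$trial_index[1],
               bin_index = seq_len(n_bins),
               mean_velocity = vapply(seq_len(n_bins), function(b)
                 mean(v[bin == b]), numeric(1)),
               mean_amplitude_travelled = vapply(seq_len(n_bins), function(b)
                 mean(cumamp[bin == b]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average time-normalized profiles over saccades
#'
#' @param profiles output of [time_normalized_profile()].
#' @param by grouping columns (default: condition).
#' @return data frame of per-bin group means.
#' @export
aggregate_profiles <- function(profiles, by = "condition") {
  agg <- stats::aggregate(
    profiles[c("mean_velocity", "mean_amplitude_travelled")],
    by = profiles[c(by, "bin_index")], FUN = mean)
  agg[order(agg[[by[1]]], agg$bin_index), ]
}
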