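# Square-root main-sequence model: closed-form least squares, case-resampling
# bootstrap of the coefficient, and the normative deviation statistic
# (delta peak velocity against a frozen reference curve).

#' Closed-form least-squares fit of the square-root main sequence
#'
#' Fits `y = V * sqrt(x)` by minimizing the sum of squared errors; the
#' minimizer is `V = sum(y * sqrt(x)) / sum(x)`.
#'
#' @param x absolute amplitudes (deg), all > 0.
#' @param y peak velocities (deg/s).
#' @return the scalar estimate `V` (deg s^-1 per sqrt(deg)).
#' @export
fit_sqrt <- function(x, y) {
  if (length(x) < 1 || length(x) != length(y))
    stopf("fit_sqrt: x and y must be non-empty and of equal length")
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("fit_sqrt: amplitudes must be finite and > 0")
  sum(y * sqrt(x)) / sum(x)
}

#' Bootstrap the main-sequence coefficient
#'
#' Draws `n_boot` case resamples of the saccade set (with replacement,
#' optionally stratified within subjects), refits [fit_sqrt()] on each, and
#' summarizes the bootstrap distribution by its median and the 2.5/97.5
#' percentile interval.
#'
#' @param x,y as in [fit_sqrt()].
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for reproducible resampling.
#' @param strata optional factor (e.g. subject id) for stratified
#'   resampling; default resamples across all saccades.
#' @return object of class `mainseq_fit`: `V` (bootstrap median), `v_point`
#'   (full-sample estimate), `bootstrap_V`, `ci95`, `n_saccades`, `seed`.
#' @export
bootstrap_v <- function(x, y, n_boot = 1000, seed = NULL, strata = NULL) {
  n <- length(x)
  if (n < 2) stopf("bootstrap_v: need >= 2 saccades")
  v_point <- fit_sqrt(x, y)
  num <- y * sqrt(x)
  idx <- with_seed(seed, {
    if (is.null(strata)) {
      matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    } else {
      strata <- as.factor(strata)
      groups <- split(seq_len(n), strata)
      do.call(cbind, lapply(groups, function(g)
        matrix(g[sample.int(length(g), length(g) * n_boot, replace = TRUE)],
               nrow = n_boot)))
    }
  })
  bv <- matrix(num[idx], nrow = n_boot)
  bx <- matrix(x[idx], nrow = n_boot)
  boot <- rowSums(bv) / rowSums(bx)
  structure(list(V = stats::median(boot), v_point = v_point,
                 bootstrap_V = boot,
                 ci95 = unname(stats::quantile(boot, c(0.025, 0.975))),
                 n_saccades = n, n_boot = n_boot, seed = seed),
            class = "mainseq_fit")
}

#' @export
print.mainseq_fit <- function(x, ...) {
  cat(sprintf("mainseq_fit: V = %.2f deg/s per sqrt(deg) [95%% CI %.2f, %.2f]\n",
              x$V, x$ci95[1], x$ci95[2]))
  cat(sprintf("  point estimate %.2f; %d saccades, %d bootstrap resamples\n",
              x$v_point, x$n_saccades, x$n_boot))
  invisible(x)
}

#' Deviation from a normative main-sequence curve
#'
#' For each saccade, evaluates the reference curve at the observed amplitude
#' and subtracts: `delta_i = y_i - V_ref * sqrt(x_i)`.  The deltas are
#' summarized by mean and SE and tested against zero with a trial-level
#' one-sample t-test and a default JZS Bayes factor.
#'
#' @param x,y the group's amplitudes and peak velocities.
#' @param v_ref the frozen normative coefficient (e.g. a control group's
#'   [bootstrap_v()] median); never the group's own fit.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return object of class `delta_velocity`: `delta` (per saccade), `mean`,
#'   `se`, `t`, `df`, `p`, `bf10`, `n`, `v_ref`.
#' @export
delta_peak_velocity <- function(x, y, v_ref, prior_scale = sqrt(2) / 2) {
  if (missing(v_ref) || is.null(v_ref) || !is.finite(v_ref))
    stopf("delta_peak_velocity: a finite reference coefficient is required")
  if (any(x <= 0)) stopf("delta_peak_velocity: amplitudes must be > 0")
  delta <- y - v_ref * sqrt(x)
  n <- length(delta)
  if (n >= 2 && sd0(delta) > 0) {
    tt <- stats::t.test(delta, mu = 0)
    bf <- jzs_bf_t(unname(tt$statistic), n1 = n, prior_scale = prior_scale)
    t_ <- unname(tt$statistic); df_ <- unname(tt$parameter)
    p_ <- tt$p.value; bf10 <- bf$bf10
  } else if (n >= 2 && mean(delta) == 0) {
    # exactly on the reference curve: no deviation, no evidence against zero
    t_ <- 0; df_ <- n - 1; p_ <- 1
    bf10 <- jzs_bf_t(0, n1 = n, prior_scale = prior_scale)$bf10
  } else {
    t_ <- df_ <- p_ <- bf10 <- NA_real_   # a single delta carries no test
  }
  structure(list(delta = delta, mean = mean(delta),
                 se = sd0(delta) / sqrt(n),
                 t = t_, df = df_, p = p_, bf10 = bf10, n = n, v_ref = v_ref),
            class = "delta_velocity")
}

#' @export
print.delta_velocity <- function(x, ...) {
  cat(sprintf(
    "delta_velocity vs V_ref = %.2f: mean %.2f deg/s (SE %.2f), t(%d) = %.2f, p = %.3g, BF10 = %.3g\n",
    x$v_ref, x$mean, x$se, x$df, x$t, x$p, x$bf10))
  invisible(x)
}
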