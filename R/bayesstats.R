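# Inferential layer: t-tests from summary statistics (pooled and Welch),
# default JZS (Jeffreys-Zellner-Siow) Bayes factors for one- and two-sample
# t designs, and Pearson correlations with Benjamini-Hochberg FDR
# adjustment within declared families.

#' Group summary (n, mean, SD)
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @return object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (!is_count(n) || n < 2) stopf("group_summary: n must be an integer >= 2")
  if (!is.finite(mean)) stopf("group_summary: mean must be finite")
  if (!is.finite(sd) || sd < 0) stopf("group_summary: sd must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' t-test from summary statistics
#'
#' Two-sample pooled-variance or Welch t-test computed from (n, mean, SD)
#' triples, or a one-sample test of a single summary against `mu`.  The
#' pooled test uses `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)` with
#' `df = n1+n2-2`; the Welch test uses the Welch-Satterthwaite df.
#'
#' @param a a [group_summary()].
#' @param b a second [group_summary()], or `NULL` for a one-sample test.
#' @param variant `"welch"`, `"pooled"` or `"one-sample"`.
#' @param mu null value for the one-sample test.
#' @return object of class `ttest_result`: `t`, `df` (fractional for
#'   Welch), `p_two_sided`, `variant`.
#' @export
t_from_summary <- function(a, b = NULL,
                           variant = c("welch", "pooled", "one-sample"),
                           mu = 0) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "group_summary"))
  if (variant == "one-sample") {
    if (a$sd == 0) stopf("t_from_summary: zero SD, t undefined")
    t <- (a$mean - mu) / (a$sd / sqrt(a$n))
    df <- a$n - 1
  } else {
    stopifnot(inherits(b, "group_summary"))
    if (a$sd == 0 && b$sd == 0)
      stopf("t_from_summary: both SDs are zero, t undefined")
    if (variant == "pooled") {
      sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
      t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
      df <- a$n + b$n - 2
    } else {
      se2 <- a$sd^2 / a$n + b$sd^2 / b$n
      t <- (a$mean - b$mean) / sqrt(se2)
      df <- se2^2 / ((a$sd^2 / a$n)^2 / (a$n - 1) +
                       (b$sd^2 / b$n)^2 / (b$n - 1))
    }
  }
  structure(list(t = t, df = df, p_two_sided = 2 * stats::pt(-abs(t), df),
                 variant = variant),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t-test: t(%.2f) = %.3f, p = %.4g\n",
              x$variant, x$df, x$t, x$p_two_sided))
  invisible(x)
}

# Log marginal likelihood ratio integrand for the JZS Bayes factor under the
# scale-mixture representation of the Cauchy prior: effect-size prior
# Cauchy(0, r) == Normal(0, g r^2) mixed over g ~ InverseGamma(1/2, 1/2).
# Integration over u = log(g) for numerical stability.
jzs_log_integrand <- function(u, t, n_eff, df, r) {
  g <- exp(u)
  a <- 1 + n_eff * g * r^2
  -0.5 * log(a) - (df + 1) / 2 * log1p(t^2 / (a * df)) -
    0.5 * log(2 * pi) - 0.5 * u - 1 / (2 * g)
}

#' Default JZS Bayes factor for a t statistic
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor BF10 for a one- or
#' two-sample t design, placing a Cauchy prior with scale `prior_scale` on
#' the standardized effect size.  One-sample designs use effective sample
#' size `N = n1` and `df = n1 - 1`; two-sample designs use
#' `N = n1 n2 / (n1 + n2)` and `df = n1 + n2 - 2`.  The marginal likelihood
#' under the alternative is evaluated by adaptive quadrature over the
#' Cauchy prior's normal scale-mixture representation (log-substituted
#' mixing variable).
#'
#' @param t observed t statistic.
#' @param n1 first (or only) group size.
#' @param n2 second group size, or `NULL` for a one-sample design.
#' @param prior_scale Cauchy prior scale (default `sqrt(2)/2`).
#' @return object of class `bf_result`: `bf10`, `prior_scale`, `design`,
#'   `error` (relative numerical error estimate).
#' @export
jzs_bf_t <- function(t, n1, n2 = NULL, prior_scale = sqrt(2) / 2) {
  if (!is.finite(t)) stopf("jzs_bf_t: t must be finite")
  if (!is_count(n1) || n1 < 2) stopf("jzs_bf_t: n1 must be an integer >= 2")
  if (is.null(n2)) {
    design <- "one-sample"; n_eff <- n1; df <- n1 - 1
  } else {
    if (!is_count(n2) || n2 < 2) stopf("jzs_bf_t: n2 must be an integer >= 2")
    design <- "two-sample"; n_eff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
  }
  # scale out the peak of the null likelihood so the ratio stays in range
  log_null <- -(df + 1) / 2 * log1p(t^2 / df)
  q <- stats::integrate(function(u)
    exp(jzs_log_integrand(u, t, n_eff, df, prior_scale) - log_null),
    lower = -Inf, upper = Inf, rel.tol = 1e-8, abs.tol = 0)
  structure(list(bf10 = q$value, prior_scale = prior_scale, design = design,
                 n_eff = n_eff, df = df, t = t,
                 error = q$abs.error / q$value),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS BF10 (%s, r = %.3f): %.4g  [t = %.3f, df = %.1f]\n",
              x$design, x$prior_scale, x$bf10, x$t, x$df))
  invisible(x)
}

#' JZS Bayes factor from two group summaries
#'
#' Reconstructs the pooled-variance two-sample t statistic from two
#' (n, mean, SD) triples and evaluates the default JZS BF10 (the pooled t
#' matches the likelihood under which the JZS t Bayes factor is derived;
#' the Welch variant of [t_from_summary()] reproduces printed frequentist
#' p-values instead).
#'
#' @param a,b [group_summary()] objects.
#' @param prior_scale Cauchy prior scale.
#' @return a `bf_result` with the reconstructed `t` attached.
#' @export
bf_from_summaries <- function(a, b, prior_scale = sqrt(2) / 2) {
  tt <- t_from_summary(a, b, variant = "pooled")
  jzs_bf_t(tt$t, n1 = a$n, n2 = b$n, prior_scale = prior_scale)
}

#' Pearson correlations with BH-FDR adjustment within families
#'
#' Computes Pearson's r and the two-sided p-value for each (x, y) pair and
#' applies the Benjamini-Hochberg step-up adjustment within each declared
#' family of comparisons.
#'
#' @param tests a list; each element a list with numeric vectors `x` and
#'   `y` (equal length >= 3), a `label`, and an optional `family`
#'   (default `"default"`).
#' @return data frame with `label`, `family`, `n`, `r`, `p`, `p_adjusted`
#'   and a logical `degenerate` flag for zero-variance inputs (r and p NA,
#'   excluded from the family adjustment).
#' @export
pearson_fdr <- function(tests) {
  rows <- lapply(tests, function(tt) {
    if (length(tt$x) != length(tt$y) || length(tt$x) < 3)
      stopf("pearson_fdr: '%s' needs equal-length vectors of >= 3",
            tt$label %||% "?")
    degen <- sd0(tt$x) == 0 || sd0(tt$y) == 0
    if (degen) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(tt$x, tt$y, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(label = tt$label %||% NA_character_,
               family = tt$family %||% "default",
               n = length(tt$x), r = r, p = p, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- NA_real_
  for (fam in unique(res$family)) {
    i <- which(res$family == fam & !is.na(res$p))
    res$p_adjusted[i] <- stats::p.adjust(res$p[i], method = "BH")
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
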