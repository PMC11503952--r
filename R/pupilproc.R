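# Resting pupil-diameter preprocessing: windowed quality control, blink
# padding, linear interpolation, Hann-window smoothing, and z-scored
# clipped means.

#' Construct a pupil trace
#'
#' @param time sample times in ms, strictly increasing with uniform step
#'   `1000 / sampling_rate`.
#' @param diameter pupil diameter in arbitrary tracker units.
#' @param valid logical validity mask (FALSE during blinks / track loss).
#' @param sampling_rate sampling rate in Hz.
#' @return object of class `pupil_trace`.
#' @export
pupil_trace <- function(time, diameter, valid = rep(TRUE, length(time)),
                        sampling_rate) {
  if (length(time) != length(diameter) || length(time) != length(valid))
    stopf("pupil_trace: time, diameter and valid must have equal length")
  if (length(time) == 0) stopf("pupil_trace: empty trace")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stopf("pupil_trace: sampling_rate must be > 0")
  step <- 1000 / sampling_rate
  if (length(time) > 1 && any(abs(diff(time) - step) > 1e-6))
    stopf("pupil_trace: time must be uniform with step 1000/sampling_rate")
  structure(list(time = as.numeric(time), diameter = as.numeric(diameter),
                 valid = as.logical(valid), sampling_rate = sampling_rate),
            class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("pupil_trace: %d samples @ %g Hz (%.1f s), %.1f%% valid\n",
              length(x$time), x$sampling_rate,
              length(x$time) / x$sampling_rate, 100 * mean(x$valid)))
  invisible(x)
}

#' Windowed signal-quality control
#'
#' Partitions the trace into consecutive windows of `window_s` seconds and
#' drops windows whose fraction of missing (invalid) samples is strictly
#' greater than `max_missing`.  A trailing partial window is dropped.  QC is
#' assessed on the raw validity mask, before any blink padding.
#'
#' @param trace a [pupil_trace()].
#' @param window_s window length in seconds.
#' @param max_missing maximum tolerated missing fraction per window.
#' @return object of class `pupil_qc`: list with `kept` (indices of
#'   surviving windows), `n_windows`, and `samples_per_window`.
#' @export
window_qc <- function(trace, window_s = 15, max_missing = 0.15) {
  stopifnot(inherits(trace, "pupil_trace"))
  spw <- as.integer(round(window_s * trace$sampling_rate))
  n_win <- length(trace$time) %/% spw
  if (n_win == 0) stopf("window_qc: trace shorter than one window")
  miss <- vapply(seq_len(n_win), function(w)
    mean(!trace$valid[((w - 1) * spw + 1):(w * spw)]), numeric(1))
  structure(list(kept = which(miss <= max_missing), n_windows = n_win,
                 samples_per_window = spw), class = "pupil_qc")
}

#' Pad blinks on the validity mask
#'
#' Extends every maximal run of invalid samples by `pad_ms` on both sides.
#' Run detection operates on the original mask, so padding is applied once
#' per physical blink and the operation does not compound on re-application
#' to an already-padded but otherwise unchanged mask's original runs.
#'
#' @param trace a [pupil_trace()].
#' @param pad_ms padding on each side, in ms.
#' @return the trace with an updated validity mask.
#' @export
pad_blinks <- function(trace, pad_ms = 100) {
  stopifnot(inherits(trace, "pupil_trace"))
  pad <- as.integer(round(pad_ms / 1000 * trace$sampling_rate))
  inv <- !trace$valid
  if (!any(inv) || pad == 0) return(trace)
  r <- rle(inv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  newmask <- trace$valid
  for (k in which(r$values)) {
    i0 <- max(1L, starts[k] - pad)
    i1 <- min(length(newmask), ends[k] + pad)
    newmask[i0:i1] <- FALSE
  }
  trace$valid <- newmask
  trace
}

#' Linearly interpolate invalid samples
#'
#' Replaces every invalid sample by linear interpolation between its nearest
#' valid neighbours; leading/trailing gaps are filled by constant extension
#' of the nearest valid value.  All samples are marked valid afterwards; the
#' original mask is retained in attribute `original_valid` so that window QC
#' accounting still refers to true missingness.
#'
#' @param trace a [pupil_trace()].
#' @return the interpolated trace.
#' @export
interpolate_gaps <- function(trace) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (sum(trace$valid) < 2)
    stopf("interpolate_gaps: need at least 2 valid samples")
  orig <- trace$valid
  if (any(!orig)) {
    idx <- which(orig)
    trace$diameter <- stats::approx(x = trace$time[idx], y = trace$diameter[idx],
                                    xout = trace$time, method = "linear",
                                    rule = 2)$y
  }
  trace$valid <- rep(TRUE, length(orig))
  attr(trace, "original_valid") <- orig
  trace
}

#' Hann-window smoothing
#'
#' Convolves the diameter signal with a unit-sum Hann kernel of length
#' `window_ms` (rounded up to an odd number of samples, minimum 3).  Edges
#' are handled by reflection, so the output has the input's length and the
#' smoothed signal never leaves the input's value range.
#'
#' @param trace a [pupil_trace()].
#' @param window_ms kernel length in ms.
#' @return the smoothed trace.
#' @export
hanning_smooth <- function(trace, window_ms = 200) {
  stopifnot(inherits(trace, "pupil_trace"))
  m <- as.integer(ceiling(window_ms / 1000 * trace$sampling_rate))
  if (m %% 2 == 0) m <- m + 1L
  m <- max(m, 3L)
  n <- length(trace$diameter)
  if (m > n) stopf("hanning_smooth: window (%d samples) longer than trace (%d)", m, n)
  k <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / (m - 1)))
  k <- k / sum(k)
  half <- (m - 1L) %/% 2L
  # reflect (without repeating the edge sample) then FFT-free filtering
  x <- c(trace$diameter[(half + 1):2], trace$diameter,
         trace$diameter[(n - 1):(n - half)])
  sm <- stats::filter(x, k, method = "convolution", sides = 2)
  trace$diameter <- as.numeric(sm[(half + 1):(half + n)])
  trace
}

#' Z-score, clip and average over surviving windows
#'
#' Z-scores the samples belonging to kept windows (by default against those
#' samples' own mean and SD; an external `center`/`scale` may be supplied,
#' e.g. a subject-level baseline spanning both sessions), removes samples
#' with `|z| > clip_sd`, and averages the survivors.
#'
#' @param trace a (processed) [pupil_trace()].
#' @param qc a [window_qc()] result.
#' @param clip_sd clipping threshold in SD units.
#' @param center,scale optional external normalization constants.
#' @return object of class `pupil_summary` with fields `mean_z`,
#'   `n_windows_total`, `n_windows_kept`, `fraction_samples_clipped`.
#' @export
zscore_clip_mean <- function(trace, qc, clip_sd = 3, center = NULL, scale = NULL) {
  stopifnot(inherits(trace, "pupil_trace"), inherits(qc, "pupil_qc"))
  out <- structure(list(mean_z = NA_real_, n_windows_total = qc$n_windows,
                        n_windows_kept = length(qc$kept),
                        fraction_samples_clipped = NA_real_),
                   class = "pupil_summary")
  if (length(qc$kept) == 0) {
    attr(out, "qc_failed") <- TRUE
    return(out)
  }
  idx <- unlist(lapply(qc$kept, function(w)
    ((w - 1) * qc$samples_per_window + 1):(w * qc$samples_per_window)))
  x <- trace$diameter[idx]
  if (is.null(center)) center <- mean(x)
  if (is.null(scale)) scale <- stats::sd(x)
  if (!is.finite(scale) || scale <= 0)
    stopf("zscore_clip_mean: zero variance over kept windows")
  z <- (x - center) / scale
  keep <- abs(z) <= clip_sd
  out$mean_z <- mean(z[keep])
  out$fraction_samples_clipped <- mean(!keep)
  out
}

#' @export
print.pupil_summary <- function(x, ...) {
  cat(sprintf("pupil_summary: mean_z = %.4f over %d/%d windows (%.2f%% clipped)\n",
              x$mean_z, x$n_windows_kept, x$n_windows_total,
              100 * x$fraction_samples_clipped))
  invisible(x)
}

#' Full pupil preprocessing chain for one session
#'
#' Runs window QC (on the raw mask), blink padding, linear interpolation,
#' Hann smoothing, and the z-score/clip/mean step restricted to kept
#' windows.
#'
#' @param trace a [pupil_trace()].
#' @param window_s,max_missing see [window_qc()].
#' @param pad_ms see [pad_blinks()].
#' @param hann_ms see [hanning_smooth()].
#' @param clip_sd,center,scale see [zscore_clip_mean()].
#' @return a `pupil_summary`.
#' @export
process_pupil <- function(trace, window_s = 15, max_missing = 0.15,
                          pad_ms = 100, hann_ms = 200, clip_sd = 3,
                          center = NULL, scale = NULL) {
  qc <- window_qc(trace, window_s, max_missing)
  tr <- hanning_smooth(interpolate_gaps(pad_blinks(trace, pad_ms)), hann_ms)
  zscore_clip_mean(tr, qc, clip_sd, center, scale)
}

# Smoothed trace + QC for one session (shared by the cohort driver).
prep_session_trace <- function(trace, window_s, max_missing, pad_ms, hann_ms) {
  qc <- window_qc(trace, window_s, max_missing)
  tr <- hanning_smooth(interpolate_gaps(pad_blinks(trace, pad_ms)), hann_ms)
  kept_idx <- unlist(lapply(qc$kept, function(w)
    ((w - 1) * qc$samples_per_window + 1):(w * qc$samples_per_window)))
  list(trace = tr, qc = qc, kept_values = tr$diameter[kept_idx])
}

#' Pupil preprocessing across a cohort
#'
#' Applies [process_pupil()] to every (subject, condition) trace in a long
#' pupil table.  With `normalize = "subject"` (default) the z-scoring
#' baseline (mean/SD) is computed per subject across all of that subject's
#' sessions, so condition contrasts in diameter survive normalization; with
#' `"session"` each session is normalized against itself.
#'
#' @param pupil data frame with columns `subject_id`, `condition`,
#'   `time_ms`, `pupil_au`, `valid` (the `pupil.csv` schema).
#' @param sampling_rate sampling rate in Hz.
#' @param normalize `"subject"` or `"session"`.
#' @inheritParams process_pupil
#' @return data frame with one row per session: `subject_id`, `condition`,
#'   `mean_z`, `n_windows_kept`, `n_windows_total`,
#'   `fraction_samples_clipped`.
#' @export
process_pupil_cohort <- function(pupil, sampling_rate = 500,
                                 normalize = c("subject", "session"),
                                 window_s = 15, max_missing = 0.15,
                                 pad_ms = 100, hann_ms = 200, clip_sd = 3) {
  normalize <- match.arg(normalize)
  need <- c("subject_id", "condition", "time_ms", "pupil_au", "valid")
  miss <- setdiff(need, names(pupil))
  if (length(miss)) stopf("process_pupil_cohort: missing columns: %s",
                          paste(miss, collapse = ", "))
  out <- list()
  for (id in unique(pupil$subject_id)) {
    sub <- pupil[pupil$subject_id == id, ]
    conds <- unique(sub$condition)
    preps <- lapply(conds, function(cd) {
      s <- sub[sub$condition == cd, ]
      prep_session_trace(
        pupil_trace(s$time_ms, s$pupil_au, as.logical(s$valid), sampling_rate),
        window_s, max_missing, pad_ms, hann_ms)
    })
    if (normalize == "subject") {
      allv <- unlist(lapply(preps, `[[`, "kept_values"))
      ctr <- mean(allv); scl <- stats::sd(allv)
    } else ctr <- scl <- NULL
    for (k in seq_along(conds)) {
      sm <- zscore_clip_mean(preps[[k]]$trace, preps[[k]]$qc, clip_sd,
                             center = ctr, scale = scl)
      out[[length(out) + 1]] <- data.frame(
        subject_id = id, condition = conds[k], mean_z = sm$mean_z,
        n_windows_kept = sm$n_windows_kept,
        n_windows_total = sm$n_windows_total,
        fraction_samples_clipped = sm$fraction_samples_clipped,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
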