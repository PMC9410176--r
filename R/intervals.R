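# Interval measurement on lead V5: tangent-method T end, QT, Bazett QTc,
# Tp-e and the Tp-e/QT, Tp-e/QTc ratios.

#' Locate the T-wave end by the tangent method
#'
#' The isoelectric level is the mean of an `iso_ms`-millisecond window on
#' the PR segment, ending `iso_gap_ms` before QRS onset. (The landmark
#' convention places QRS onset at the maximum upslope of the energy
#' envelope -- on the R upstroke itself -- so the window is backed off far
#' enough to clear the Q deflection and sample truly isoelectric baseline.)
#' After refining the T peak near the hint, the steepest slope
#' back toward baseline is found by sliding a `fit_ms`-millisecond
#' least-squares line along the post-peak limb; the returned index is the
#' intersection of that fitted tangent with the isoelectric level, rounded
#' to the nearest sample. Inverted T waves are handled symmetrically (the
#' steepest rising slope back to baseline is used).
#'
#' @param v5 single-lead amplitude vector, mV
#' @param fs sampling rate, Hz
#' @param t_peak_hint approximate T-peak sample index
#' @param qrs_onset QRS onset sample index (anchors the isoelectric window)
#' @param iso_ms isoelectric estimation window, ms
#' @param iso_gap_ms gap between the isoelectric window and QRS onset, ms
#' @param fit_ms tangent fit window, ms
#' @param search_ms how far past the T peak to search for the steepest
#'   slope, ms
#' @return T-end sample index
#' @export
tangent_t_end <- function(v5, fs, t_peak_hint, qrs_onset,
                          iso_ms = 40, iso_gap_ms = 60, fit_ms = 10,
                          search_ms = 200) {
  n <- length(v5)
  iso_hi <- max(1, qrs_onset - round(iso_gap_ms / 1000 * fs))
  iso_lo <- max(1, iso_hi - round(iso_ms / 1000 * fs) + 1)
  iso <- mean(v5[iso_lo:iso_hi])

  half <- round(0.04 * fs)
  pw <- max(1, t_peak_hint - half):min(n, t_peak_hint + half)
  tp <- pw[which.max(abs(v5[pw] - iso))]
  pol <- sign(v5[tp] - iso)
  if (pol == 0) stop("no T downslope: flat T wave at peak")

  w <- max(2L, round(fit_ms / 1000 * fs))
  last_start <- min(n - w + 1L, tp + round(search_ms / 1000 * fs))
  if (last_start <= tp) stop("no T downslope: no room after T peak")
  starts <- tp:last_start
  xs <- seq_len(w)
  sxx <- sum((xs - mean(xs))^2)
  slopes <- vapply(starts, function(k) {
    y <- v5[k:(k + w - 1L)]
    sum((xs - mean(xs)) * (y - mean(y))) / sxx
  }, numeric(1))
  # steepest slope heading back toward the isoelectric line
  best <- which.min(pol * slopes)
  if (pol * slopes[best] >= 0) stop("no T downslope")
  k <- starts[best]
  y <- v5[k:(k + w - 1L)]
  b <- slopes[best]
  a <- mean(y) - b * mean(xs)           # intercept in window coordinates
  x_cross <- (iso - a) / b              # window coordinate of the crossing
  idx <- as.integer(round(k - 1 + x_cross))
  clamp(idx, tp + 1L, n)
}

#' Tp-e ratios
#'
#' `tpe_qt = tpe/qt`; when `rr` (seconds) is supplied, `tpe_qtc` is the
#' ratio against the Bazett-corrected QT, i.e. `tpe_qt * sqrt(rr)`.
#'
#' @param tpe,qt intervals in ms
#' @param rr RR interval in seconds, optional
#' @return list with `tpe_qt` and (if `rr` given) `tpe_qtc`
#' @export
tpe_ratios <- function(tpe, qt, rr = NULL) {
  stopifnot(qt > 0, tpe > 0)
  out <- list(tpe_qt = tpe / qt)
  if (!is.null(rr)) {
    stopifnot(rr > 0)
    out$tpe_qtc <- tpe / (qt / sqrt(rr))
  }
  out
}

#' Measure QT, QTc, Tp-e and their ratios from lead V5
#'
#' QT runs from QRS onset to the tangent-method T end; Tp-e from the T peak
#' to the same T end; QTc is Bazett-corrected (`qt / sqrt(rr)`, RR in
#' seconds).
#'
#' @param v5 single-lead amplitude vector, mV (same beat window as
#'   `landmarks`)
#' @param landmarks a [detect_landmarks()] result for the beat
#' @param rr RR interval used for Bazett correction, seconds
#' @param fs sampling rate, Hz
#' @param ... passed to [tangent_t_end()]
#' @return object of class `interval_measures`: `qt`, `qtc`, `tpe` (ms),
#'   `tpe_qt`, `tpe_qtc`, `rr` (s) and `t_end` (sample index)
#' @export
measure_intervals <- function(v5, landmarks, rr, fs, ...) {
  if (!is.numeric(rr) || rr <= 0) stop("invalid RR")
  t_end <- tangent_t_end(v5, fs, t_peak_hint = landmarks$t_peak,
                         qrs_onset = landmarks$qrs_onset, ...)
  qt <- (t_end - landmarks$qrs_onset) / fs * 1000
  tpe <- (t_end - landmarks$t_peak) / fs * 1000
  qtc <- qt / sqrt(rr)
  r <- tpe_ratios(tpe, qt, rr)
  structure(list(qt = qt, qtc = qtc, tpe = tpe,
                 tpe_qt = r$tpe_qt, tpe_qtc = r$tpe_qtc,
                 rr = rr, t_end = t_end),
            class = "interval_measures")
}

#' @export
print.interval_measures <- function(x, ...) {
  cat(sprintf(
    "<interval_measures> QT=%.1f ms  QTc=%.1f ms  Tp-e=%.1f ms  Tp-e/QT=%.2f  Tp-e/QTc=%.2f  RR=%.3f s\n",
    x$qt, x$qtc, x$tpe, x$tpe_qt, x$tpe_qtc, x$rr))
  invisible(x)
}
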