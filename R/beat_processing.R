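# Beat-level processing: R-peak detection on the summed cross-lead energy,
# segmentation into fixed windows around each R peak, template (averaged)
# beat construction, random-beat selection, and recording-quality flags.

#' Detect R peaks on the summed cross-lead energy
#'
#' Works on the eight independent leads: each lead is baseline-corrected by
#' its median, the per-sample squared amplitudes are summed across leads,
#' lightly smoothed, and local maxima above an adaptive threshold are kept
#' subject to a refractory period. Peak positions are refined to the local
#' maximum of the unsmoothed energy. Operating on cross-lead energy rather
#' than a single lead makes detection robust to the polarity and placement
#' of any individual electrode.
#'
#' @param record an [ecg_record()]
#' @param refractory minimum distance between peaks, seconds
#' @param threshold_frac detection threshold as a fraction of the maximum
#'   smoothed energy
#' @return integer vector of strictly increasing sample indices, one per beat
#' @export
detect_r_peaks <- function(record, refractory = 0.2, threshold_frac = 0.25) {
  x8 <- derive_independent_leads(record)
  x8 <- x8 - apply(x8, 1, stats::median)
  energy <- colSums(x8^2)
  # ~20 ms moving-average smoothing
  w <- max(1L, round(0.02 * record$fs))
  kern <- rep(1 / w, w)
  sm <- stats::filter(energy, kern, sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  thr <- threshold_frac * max(sm)
  if (max(sm) <= 0) stop("insufficient beats: no energy in record")
  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] >= sm[1:(n - 2)] &
                sm[2:(n - 1)] > sm[3:n], FALSE)
  cand <- which(is_max & sm > thr)
  if (length(cand) == 0) stop("insufficient beats: no peaks above threshold")
  # greedy refractory enforcement, strongest first
  keep <- logical(length(cand))
  ord <- order(sm[cand], decreasing = TRUE)
  ref_n <- round(refractory * record$fs)
  taken <- integer(0)
  for (i in ord) {
    if (length(taken) == 0 || all(abs(cand[i] - taken) >= ref_n)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  peaks <- sort(cand[keep])
  # refine on raw energy within +/- 10 ms
  half <- round(0.01 * record$fs)
  peaks <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(energy[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < 2) stop("insufficient beats: fewer than 2 R peaks")
  peaks
}

#' Segment a recording into beats around detected R peaks
#'
#' Each beat spans a fixed window before and after its R peak (default
#' 300 ms pre to 500 ms post, covering P onset through T end at resting
#' heart rates of 45 bpm and above). Beats whose window would run past
#' either end of the recording are dropped. When the window exceeds the
#' shortest RR interval it is truncated proportionally with a
#' "window/RR conflict" warning. Each beat carries `rr_local`, the median
#' of its adjacent RR intervals.
#'
#' @param record an [ecg_record()]
#' @param r_indices output of [detect_r_peaks()]
#' @param pre,post window extent before/after the R peak, seconds
#' @return list of beats; each beat is a list with `samples` (8 x L matrix
#'   of independent leads, mV), `r_index` (R-peak offset within the
#'   segment), `fs`, `rr_local` (s) and `mode` (unset here)
#' @export
segment_beats <- function(record, r_indices, pre = 0.3, post = 0.5) {
  if (length(r_indices) < 2) stop("insufficient beats: need >= 2 R peaks")
  fs <- record$fs
  rr <- diff(r_indices) / fs
  min_rr <- min(rr)
  if (pre + post > min_rr) {
    scale <- min_rr / (pre + post)
    warning(sprintf(
      "window/RR conflict: %.0f+%.0f ms window exceeds min RR %.0f ms; truncated",
      pre * 1000, post * 1000, min_rr * 1000))
    pre <- pre * scale
    post <- post * scale
  }
  x8 <- derive_independent_leads(record)
  n <- ncol(x8)
  pre_n <- as.integer(round(pre * fs))
  post_n <- as.integer(round(post * fs))
  beats <- list()
  for (k in seq_along(r_indices)) {
    r <- r_indices[k]
    lo <- r - pre_n
    hi <- r + post_n - 1
    if (lo < 1 || hi > n) next
    adj <- c(if (k > 1) rr[k - 1], if (k < length(r_indices)) rr[k])
    beats[[length(beats) + 1]] <- structure(list(
      samples = x8[, lo:hi, drop = FALSE],
      r_index = pre_n + 1L,
      fs = fs,
      rr_local = stats::median(adj),
      mode = NA_character_
    ), class = "ecg_beat")
  }
  if (length(beats) == 0) stop("insufficient beats: all windows truncated")
  beats
}

#' Build the averaged (template) beat
#'
#' Sample-wise mean across beats aligned on their R peak. `rr_local` of the
#' template is the mean of the inputs. Averaging identical beats returns
#' them unchanged; averaging is idempotent.
#'
#' @param beats list of beats from [segment_beats()]
#' @return a single beat with `mode = "averaged"`
#' @export
average_beat <- function(beats) {
  if (length(beats) == 0) stop("no beats")
  lens <- vapply(beats, function(b) ncol(b$samples), integer(1))
  L <- min(lens)
  acc <- 0
  for (b in beats) acc <- acc + b$samples[, seq_len(L), drop = FALSE]
  out <- beats[[1]]
  out$samples <- acc / length(beats)
  out$rr_local <- mean(vapply(beats, function(b) b$rr_local, numeric(1)))
  out$mode <- "averaged"
  out
}

#' Select one beat uniformly at random
#'
#' When three or more beats are available the first and last are excluded
#' (their windows abut the recording edges); with fewer, all are eligible.
#'
#' @param beats list of beats
#' @param seed optional integer for reproducible selection
#' @return a single beat with `mode = "random"`
#' @export
select_random_beat <- function(beats, seed = NULL) {
  if (length(beats) == 0) stop("no beats")
  pool <- if (length(beats) >= 3) 2:(length(beats) - 1) else seq_along(beats)
  idx <- with_seed(seed, pool[sample.int(length(pool), 1)])
  out <- beats[[idx]]
  out$mode <- "random"
  attr(out, "beat_index") <- idx
  out
}

#' Flag displaced leads and high-frequency interference
#'
#' A lead is flagged `displaced` when its RMS (after median baseline
#' removal) falls below `rms_frac` of the median lead RMS, or when its
#' beat-consistency correlation falls below `consistency_min`. The
#' consistency index correlates the lead's odd-numbered-beat average with
#' its even-numbered-beat average (beats located on the cross-lead energy,
#' so the index does not depend on any one lead's morphology or polarity):
#' a connected electrode shows the same beat-locked waveform in both halves,
#' while a displaced or disconnected one yields uncorrelated noise.
#' `high_interference` is flagged when spectral power above `hf_cutoff` Hz
#' exceeds `hf_frac` of the lead's total power. The record is `usable` only
#' if no required lead raises any flag.
#'
#' @param record an [ecg_record()]
#' @param rms_frac,consistency_min,hf_cutoff,hf_frac operational thresholds
#' @return list of class `quality_report`: `per_lead` data.frame (lead, rms,
#'   beat_consistency, hf_ratio, displaced, high_interference) and `usable`
#' @export
quality_check <- function(record, rms_frac = 0.05, consistency_min = 0.2,
                          hf_cutoff = 40, hf_frac = 0.3) {
  x8 <- derive_independent_leads(record)
  x8 <- x8 - apply(x8, 1, stats::median)
  n <- ncol(x8)
  fs <- record$fs
  rms <- sqrt(rowMeans(x8^2))
  med_rms <- stats::median(rms)

  peaks <- tryCatch(suppressWarnings(detect_r_peaks(record)),
                    error = function(e) integer(0))
  pre_n <- round(0.3 * fs); post_n <- round(0.5 * fs)
  peaks <- peaks[peaks - pre_n >= 1 & peaks + post_n - 1 <= n]
  consistency <- rep(0, 8)
  if (length(peaks) >= 2) {
    odd <- peaks[seq_along(peaks) %% 2 == 1]
    even <- peaks[seq_along(peaks) %% 2 == 0]
    avg_of <- function(i, pk) {
      rowMeans(vapply(pk, function(p) x8[i, (p - pre_n):(p + post_n - 1)],
                      numeric(pre_n + post_n)))
    }
    consistency <- vapply(seq_len(8), function(i) {
      a <- avg_of(i, odd); b <- avg_of(i, even)
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    }, numeric(1))
  }
  displaced <- rms < rms_frac * med_rms | consistency < consistency_min

  freqs <- (seq_len(n) - 1) * record$fs / n
  nyq_half <- freqs <= record$fs / 2
  hf_ratio <- vapply(seq_len(8), function(i) {
    p <- Mod(stats::fft(x8[i, ]))^2
    tot <- sum(p[nyq_half][-1])  # drop DC
    if (tot == 0) return(0)
    sum(p[nyq_half & freqs > hf_cutoff]) / tot
  }, numeric(1))
  interference <- hf_ratio > hf_frac

  per_lead <- data.frame(
    lead = rownames(x8), rms = rms, beat_consistency = consistency,
    hf_ratio = hf_ratio, displaced = displaced,
    high_interference = interference, row.names = NULL
  )
  structure(list(per_lead = per_lead,
                 usable = !any(displaced | interference)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> usable=%s\n", x$usable))
  print(x$per_lead, digits = 3)
  invisible(x)
}
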