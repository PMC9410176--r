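# SVD reduction of the eight independent leads to the optimized 3-D
# decomposition space, the per-sample energy envelope, and landmark
# detection on that envelope.

#' Decompose an 8-lead beat into its principal 3-D loop space
#'
#' Singular value decomposition of the baseline-corrected 8 x N lead matrix.
#' The first three principal temporal components, scaled by their singular
#' values, form the loop-space series `s3`; the corresponding left singular
#' vectors are the lead-loading matrix (`weights %*% s3` is the best rank-3
#' reconstruction of the beat). `energy_fraction_3` is the fraction of total
#' signal energy captured by the three components; on clean recordings it is
#' expected to be near 0.99 and values below `qc_warn` raise a warning.
#' Component signs are fixed by convention: each component is flipped so its
#' value at the R peak is non-negative (with a max-abs-sample tie-break),
#' making intermediates reproducible; cosine-based markers are unaffected.
#'
#' @param eight_leads 8 x N numeric matrix, rows I, II, V1..V6 (mV)
#' @param fs sampling rate, Hz
#' @param r_index sample index of the R peak (defaults to the energy argmax)
#' @param baseline_ms per-lead median of the first `baseline_ms` ms is
#'   subtracted before decomposition
#' @param qc_warn warn when `energy_fraction_3` falls below this value
#' @return object of class `decomposed_beat` with fields `s3` (3 x N),
#'   `weights` (8 x 3), `singular_values` (length 8, descending),
#'   `energy_fraction_3`, `fs`, `leads` (the baseline-corrected input) and
#'   `r_index`
#' @export
svd_decompose <- function(eight_leads, fs, r_index = NULL,
                          baseline_ms = 80, qc_warn = 0.95) {
  stopifnot(is.matrix(eight_leads), nrow(eight_leads) == 8,
            ncol(eight_leads) > 8, all(is.finite(eight_leads)), fs > 0)
  nb <- max(1L, min(ncol(eight_leads), round(baseline_ms / 1000 * fs)))
  baseline <- apply(eight_leads[, seq_len(nb), drop = FALSE], 1,
                    stats::median)
  x <- eight_leads - baseline
  if (all(x == 0)) stop("zero-energy beat")
  sv <- svd(x)
  s3 <- diag(sv$d[1:3], nrow = 3) %*% t(sv$v[, 1:3, drop = FALSE])
  weights <- sv$u[, 1:3, drop = FALSE]
  if (is.null(r_index)) r_index <- which.max(colSums(x^2))
  for (k in 1:3) {
    ref <- s3[k, r_index]
    if (ref == 0) ref <- s3[k, which.max(abs(s3[k, ]))]
    if (ref < 0) {
      s3[k, ] <- -s3[k, ]
      weights[, k] <- -weights[, k]
    }
  }
  ef3 <- sum(sv$d[1:3]^2) / sum(sv$d^2)
  if (ef3 < qc_warn) {
    warning(sprintf("3-component energy fraction %.3f below %.2f", ef3, qc_warn))
  }
  rownames(weights) <- rownames(eight_leads)
  structure(list(
    s3 = s3, weights = weights, singular_values = sv$d,
    energy_fraction_3 = ef3, fs = fs, leads = x, r_index = r_index
  ), class = "decomposed_beat")
}

#' Per-sample energy of the 3-D decomposition
#'
#' The squared Euclidean norm of the loop-space vector at each sample,
#' `e3d(t) = s1(t)^2 + s2(t)^2 + s3(t)^2`. This envelope concentrates QRS
#' and T-wave energy regardless of loop orientation and is the signal on
#' which landmarks are located.
#'
#' @param decomposed a [svd_decompose()] result
#' @return object of class `energy_series`: `e3d` (numeric, mV^2) and `fs`
#' @export
energy_vector <- function(decomposed) {
  stopifnot(inherits(decomposed, "decomposed_beat"))
  structure(list(e3d = colSums(decomposed$s3^2), fs = decomposed$fs),
            class = "energy_series")
}

#' Locate QRS and T-wave landmarks on the energy envelope
#'
#' The R peak is the energy argmax within `r_search` seconds of the hint.
#' QRS onset/offset are the points of maximum upslope/downslope of the
#' envelope within `qrs_win` seconds before/after the R peak (the
#' maximum-slope convention for delimiting the R wave on an energy
#' envelope). The T peak is the largest local energy maximum between
#' `t_min`/`t_max` seconds after QRS offset; T start/end are where the
#' envelope crosses `t_frac` of the T-peak energy after remaining beyond
#' the threshold for at least `t_hold` seconds, with an argmin fallback when
#' the envelope never settles below threshold.
#'
#' @param energy an [energy_vector()] result
#' @param r_hint approximate R-peak sample index
#' @param r_search,qrs_win,t_min,t_max,t_frac,t_hold window constants in
#'   seconds (fraction for `t_frac`); operational defaults
#' @return object of class `ecg_landmarks`: sample indices `qrs_onset`,
#'   `r_peak`, `qrs_offset`, `t_start`, `t_peak`, `t_end` satisfying
#'   `qrs_onset < r_peak < qrs_offset < t_start <= t_peak < t_end`
#' @export
detect_landmarks <- function(energy, r_hint, r_search = 0.06,
                             qrs_win = 0.1, t_min = 0.08, t_max = 0.45,
                             t_frac = 0.05, t_hold = 0.02) {
  stopifnot(inherits(energy, "energy_series"))
  e <- energy$e3d
  fs <- energy$fs
  n <- length(e)
  if (r_hint < 1 || r_hint > n) stop("r_hint outside the series")

  win <- max(1, r_hint - round(r_search * fs)):min(n, r_hint + round(r_search * fs))
  r_peak <- win[which.max(e[win])]

  de <- c(diff(e), 0)
  on_win <- max(1, r_peak - round(qrs_win * fs)):(r_peak - 1)
  qrs_onset <- on_win[which.max(de[on_win])]
  off_win <- (r_peak + 1):min(n, r_peak + round(qrs_win * fs))
  qrs_offset <- off_win[which.min(de[off_win - 1])]

  a <- qrs_offset + round(t_min * fs)
  b <- min(n, qrs_offset + round(t_max * fs))
  if (a >= b) stop("flat T wave: no search window after QRS")
  tw <- a:b
  interior <- tw[-c(1, length(tw))]
  loc_max <- interior[e[interior] >= e[interior - 1] &
                        e[interior] > e[interior + 1]]
  if (length(loc_max) == 0 || max(e[loc_max]) < 0.005 * e[r_peak]) {
    stop("flat T wave")
  }
  t_peak <- loc_max[which.max(e[loc_max])]
  thr <- t_frac * e[t_peak]
  hold_n <- max(1L, round(t_hold * fs))

  below <- e < thr
  t_start <- .threshold_crossing(below, from = t_peak, to = qrs_offset + 1,
                                 step = -1L, hold_n = hold_n)
  if (is.na(t_start)) {
    seg <- (qrs_offset + 1):t_peak
    t_start <- seg[which.min(e[seg])]
  }
  t_end <- .threshold_crossing(below, from = t_peak, to = min(n, b + round(t_max * fs)),
                               step = 1L, hold_n = hold_n)
  if (is.na(t_end)) {
    seg <- t_peak:n
    t_end <- seg[which.min(e[seg])]
  }
  if (t_end <= t_peak) t_end <- t_peak + 1L

  lm <- structure(list(qrs_onset = qrs_onset, r_peak = r_peak,
                       qrs_offset = qrs_offset, t_start = t_start,
                       t_peak = t_peak, t_end = t_end),
                  class = "ecg_landmarks")
  if (!(lm$qrs_onset < lm$r_peak && lm$r_peak < lm$qrs_offset &&
        lm$qrs_offset < lm$t_start && lm$t_start <= lm$t_peak &&
        lm$t_peak < lm$t_end)) {
    stop("landmark ordering violated")
  }
  lm
}

# Walk from `from` towards `to` in direction `step`; return the index just
# inside the first below-threshold run of length >= hold_n (NA if none).
# A run cut short by the search boundary still counts.
.threshold_crossing <- function(below, from, to, step, hold_n) {
  i <- from
  while ((step > 0 && i <= to) || (step < 0 && i >= to)) {
    if (below[i]) {
      run <- 0L
      j <- i
      while (((step > 0 && j <= to) || (step < 0 && j >= to)) && below[j]) {
        run <- run + 1L
        j <- j + step
      }
      at_boundary <- (step > 0 && j > to) || (step < 0 && j < to)
      if (run >= hold_n || at_boundary) return(i - step)
      i <- j
    } else {
      i <- i + step
    }
  }
  NA_integer_
}

#' @export
print.ecg_landmarks <- function(x, ...) {
  cat(sprintf(
    "<ecg_landmarks> QRS %d-[%d]-%d  T %d-[%d]-%d (sample indices)\n",
    x$qrs_onset, x$r_peak, x$qrs_offset, x$t_start, x$t_peak, x$t_end))
  invisible(x)
}
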