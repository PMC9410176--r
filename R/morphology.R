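# T-wave morphology markers: total cosine R-to-T (TCRT) and T-wave
# morphology dispersion (TMD, TMDpre, TMDpost).

#' Total cosine R-to-T
#'
#' The mean cosine of the angles between the loop-space QRS vectors and the
#' single T-peak vector. QRS vectors are the `s3` samples between QRS onset
#' and offset whose energy reaches at least `qrs_energy_frac` of the peak
#' QRS energy; the threshold keeps low-energy QRS tail samples (whose
#' directions are noise-dominated) out of the average, and setting it to 0
#' reproduces the literal all-samples definition. Values lie in `[-1, 1]`;
#' negative values indicate a large divergence between the depolarization
#' and repolarization loop orientations.
#'
#' @param decomposed a [svd_decompose()] result
#' @param landmarks a [detect_landmarks()] result for the same beat
#' @param qrs_energy_frac inclusion threshold, fraction of peak QRS energy
#' @return TCRT, unitless in `[-1, 1]`
#' @export
compute_tcrt <- function(decomposed, landmarks, qrs_energy_frac = 0.7) {
  stopifnot(inherits(decomposed, "decomposed_beat"),
            inherits(landmarks, "ecg_landmarks"))
  s3 <- decomposed$s3
  idx <- landmarks$qrs_onset:landmarks$qrs_offset
  e <- colSums(s3[, idx, drop = FALSE]^2)
  keep <- idx[e >= qrs_energy_frac * max(e)]
  tvec <- s3[, landmarks$t_peak]
  t_norm <- sqrt(sum(tvec^2))
  if (t_norm < .Machine$double.eps) stop("degenerate T vector")
  q <- s3[, keep, drop = FALSE]
  q_norm <- sqrt(colSums(q^2))
  ok <- q_norm > .Machine$double.eps
  if (!any(ok)) stop("degenerate QRS loop")
  cosines <- colSums(q[, ok, drop = FALSE] * tvec) / (q_norm[ok] * t_norm)
  clamp(mean(cosines), -1, 1)
}

#' T-wave morphology dispersion
#'
#' Quantifies how heterogeneous the T-wave shape is across leads. The
#' T-window segment of the (baseline-corrected) 8-lead beat is decomposed by
#' SVD; each lead's reconstruction vector is its loading on the first two
#' components, scaled by the singular values. TMD is the mean angle (degrees,
#' in `[0, 180]`) over all 28 unordered lead pairs. Identical T-wave shapes
#' in every lead give parallel reconstruction vectors and TMD of 0. Leads
#' with (numerically) zero-norm vectors are excluded from pairing with a
#' warning; more than 4 such leads make the T loop degenerate.
#'
#' @param decomposed a [svd_decompose()] result
#' @param landmarks a [detect_landmarks()] result for the same beat
#' @param window `"full"` (T start to T end), `"pre"` (start to peak) or
#'   `"post"` (peak to end)
#' @param ndim number of decomposition dimensions for the reconstruction
#'   vectors (2 is the conventional choice; 3 is available)
#' @return mean inter-lead angle, degrees
#' @export
compute_tmd <- function(decomposed, landmarks,
                        window = c("full", "pre", "post"), ndim = 2) {
  stopifnot(inherits(decomposed, "decomposed_beat"),
            inherits(landmarks, "ecg_landmarks"))
  window <- match.arg(window)
  idx <- switch(window,
    full = landmarks$t_start:landmarks$t_end,
    pre = landmarks$t_start:landmarks$t_peak,
    post = landmarks$t_peak:landmarks$t_end
  )
  if (length(idx) < 3) stop("T window too short (< 3 samples)")
  seg <- decomposed$leads[, idx, drop = FALSE]
  sv <- svd(seg)
  k <- min(ndim, length(sv$d))
  vecs <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = nrow(seg))
  norms <- sqrt(rowSums(vecs^2))
  tol <- 1e-9 * max(norms)
  ok <- which(norms > tol)
  if (8 - length(ok) > 4) stop("degenerate T loop")
  if (length(ok) < 8) {
    warning(sprintf("%d zero-norm reconstruction vector(s) excluded from TMD",
                    8 - length(ok)))
  }
  pairs <- utils::combn(ok, 2)
  angles <- apply(pairs, 2, function(p) {
    vector_angle_deg(vecs[p[1], ], vecs[p[2], ])
  })
  mean(angles)
}

#' Compute all morphology markers for one beat
#'
#' Composes the full beat-level chain: [svd_decompose()] on the eight
#' independent leads, [energy_vector()], [detect_landmarks()] seeded at the
#' beat's R index, then [compute_tcrt()] and [compute_tmd()] over the full,
#' pre-peak and post-peak T windows.
#'
#' @param beat a beat from [segment_beats()], [average_beat()] or
#'   [select_random_beat()]
#' @param qrs_energy_frac passed to [compute_tcrt()]
#' @param tmd_ndim passed to [compute_tmd()]
#' @param ... further arguments forwarded to [detect_landmarks()]
#' @return object of class `morphology_markers`: `tcrt`, `tmd`, `tmd_pre`,
#'   `tmd_post`, `mode`, `energy_fraction_3` and the `landmarks` used
#' @export
compute_markers <- function(beat, qrs_energy_frac = 0.7, tmd_ndim = 2, ...) {
  stopifnot(inherits(beat, "ecg_beat"))
  dec <- svd_decompose(beat$samples, beat$fs, r_index = beat$r_index)
  en <- energy_vector(dec)
  lm <- detect_landmarks(en, r_hint = beat$r_index, ...)
  structure(list(
    tcrt = compute_tcrt(dec, lm, qrs_energy_frac = qrs_energy_frac),
    tmd = compute_tmd(dec, lm, "full", ndim = tmd_ndim),
    tmd_pre = compute_tmd(dec, lm, "pre", ndim = tmd_ndim),
    tmd_post = compute_tmd(dec, lm, "post", ndim = tmd_ndim),
    mode = beat$mode,
    energy_fraction_3 = dec$energy_fraction_3,
    landmarks = lm
  ), class = "morphology_markers")
}

#' @export
print.morphology_markers <- function(x, ...) {
  cat(sprintf(
    "<morphology_markers> mode=%s  TCRT=%.3f  TMD=%.1f  TMDpre=%.1f  TMDpost=%.1f  E3frac=%.4f\n",
    x$mode, x$tcrt, x$tmd, x$tmd_pre, x$tmd_post, x$energy_fraction_3))
  invisible(x)
}
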