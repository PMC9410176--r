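# Rank-3 cardiac dipole simulator.
#
# Each beat is a sum of Gaussian-shaped waves (P, Q, R, S, T) attached to
# fixed spatial directions, so the full dipole trajectory lies in a 3-D
# subspace and the spatial angle theta between the QRS axis and the T-wave
# axis is programmable: cos(theta) is the analytic ground truth for TCRT.

#' Fixed dipole-to-lead projection matrix
#'
#' An 8 x 3 matrix mapping the 3-D dipole to the eight independent leads
#' (rows I, II, V1..V6). It is a column-orthogonalized (Loewdin) version of
#' the classical Dower lead field, rescaled to physiological lead gains.
#' Its columns are exactly orthogonal with equal norm, so angles between
#' dipole-space vectors are preserved in lead space -- the property that
#' makes the programmed QRS-T angle recoverable as a cosine after singular
#' value decomposition of the projected leads.
#'
#' @format numeric matrix, 8 rows (leads) x 3 columns (dipole axes)
#' @export
LEAD_PROJECTION <- matrix(c(
   0.570020, -0.439677,  0.087470,
   0.107224,  1.780331,  0.073309,
  -0.559967,  0.166156, -0.844980,
  -0.131005,  0.063667, -1.196440,
   0.609798, -0.095509, -1.014693,
   0.969639,  0.032581, -0.375075,
   0.951809,  0.118241,  0.070420,
   0.737552,  0.101983,  0.308857
), nrow = 8, byrow = TRUE,
  dimnames = list(c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"), NULL))

.DEFAULT_WAVES <- data.frame(
  wave = c("P", "Q", "R", "S", "T"),
  amp_mv = c(0.12, -0.10, 1.00, -0.15, 0.35),
  center_ms = c(-200, -35, 0, 35, 300),
  width_ms = c(22, 10, 12, 10, 50),
  stringsAsFactors = FALSE
)

# Fixed reference frame: T axis and an orthonormal in-plane companion.
# The QRS axis is placed theta degrees away from the T axis inside this
# plane; the plane normal serves as loop-rotation axis. The reference T
# axis projects with uniform (positive) polarity onto all eight leads,
# giving the upright-T pattern of a normal resting ECG.
.T_AXIS_REF <- c(0.812, 0.185, -0.553) / sqrt(sum(c(0.812, 0.185, -0.553)^2))

#' Configuration of a synthetic 12-lead recording
#'
#' @param fs sampling rate, Hz
#' @param duration recording length, seconds (`fs * duration` must be integral)
#' @param heart_rate beats per minute
#' @param theta spatial angle between the QRS axis and the T-wave axis,
#'   degrees in `[0, 180]`; `cos(theta)` is the TCRT ground truth
#' @param qrs_direction,t_direction optional explicit 3-D unit vectors; when
#'   both are given, `theta` (if also given) must agree with their angle to
#'   within 1e-9 on the cosine
#' @param wave_params data.frame with columns `wave`, `amp_mv`,
#'   `center_ms` (offset from the R peak), `width_ms`; defaults give a
#'   plausible adult resting beat
#' @param qrs_loop_spread angular half-width of the QRS loop, degrees: the Q
#'   and S dipole directions sit this far on either side of the R axis
#' @param t_loop_ratio minor-to-major axis ratio of the T loop (0 gives a
#'   strictly rank-1 T wave)
#' @param noise_sd additive white noise per independent lead, mV
#' @param baseline_wander_amplitude,baseline_wander_freq optional sinusoidal
#'   baseline wander, mV and Hz
#' @param seed optional integer; when set, [generate_ecg()] is reproducible
#' @return validated list of class `synth_config`
#' @export
synth_config <- function(fs = 1000, duration = 10, heart_rate = 60,
                         theta = 60, qrs_direction = NULL, t_direction = NULL,
                         wave_params = .DEFAULT_WAVES,
                         qrs_loop_spread = 15, t_loop_ratio = 0.2,
                         noise_sd = 0, baseline_wander_amplitude = 0,
                         baseline_wander_freq = 0.33, seed = NULL) {
  stopifnot(fs > 0, duration > 0, heart_rate > 0,
            qrs_loop_spread >= 0, t_loop_ratio >= 0, noise_sd >= 0)
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9) stop("fs * duration must be an integer")
  if (any(wave_params$width_ms <= 0)) stop("wave widths must be > 0")
  req <- c("P", "Q", "R", "S", "T")
  if (!all(req %in% wave_params$wave)) stop("wave_params must define P,Q,R,S,T")

  if (!is.null(t_direction)) t_direction <- unit_vector(t_direction)
  if (!is.null(qrs_direction)) qrs_direction <- unit_vector(qrs_direction)
  if (!is.null(qrs_direction) && !is.null(t_direction)) {
    ct <- sum(qrs_direction * t_direction)
    if (!missing(theta) && !is.null(theta)) {
      if (abs(cos(theta * pi / 180) - ct) > 1e-9) {
        stop("theta inconsistent with supplied directions")
      }
    }
    theta <- acos(clamp(ct, -1, 1)) * 180 / pi
  } else {
    if (is.null(theta) || theta < 0 || theta > 180) {
      stop("theta must lie in [0, 180] degrees")
    }
    u <- .T_AXIS_REF
    # in-plane companion: Gram-Schmidt of e1 against u
    v <- unit_vector(c(1, 0, 0) - sum(c(1, 0, 0) * u) * u)
    t_direction <- u
    qrs_direction <- cos(theta * pi / 180) * u + sin(theta * pi / 180) * v
  }

  structure(list(
    fs = fs, duration = duration, heart_rate = heart_rate, theta = theta,
    qrs_direction = qrs_direction, t_direction = t_direction,
    wave_params = wave_params, qrs_loop_spread = qrs_loop_spread,
    t_loop_ratio = t_loop_ratio, noise_sd = noise_sd,
    baseline_wander_amplitude = baseline_wander_amplitude,
    baseline_wander_freq = baseline_wander_freq, seed = seed
  ), class = "synth_config")
}

#' Generate the 3-D dipole trajectory for a configuration
#'
#' Beats repeat at `60/heart_rate` second intervals, the first R peak at
#' 0.35 s. Gaussian waves are attached to spatial directions: R exactly on
#' the QRS axis, Q and S rotated `qrs_loop_spread` degrees to either side
#' within the QRS-T plane, T along the T axis with an optional minor-axis
#' component (`t_loop_ratio`) along the plane normal, giving a
#' repolarization loop that spans all three dipole dimensions. The P wave
#' rides on the T axis (the atrial axis is not a QRS-loop property, so it
#' stays fixed as theta varies).
#'
#' @param config a [synth_config()]
#' @return 3 x N numeric matrix (mV) with attributes `fiducials` (R-peak
#'   times/indices and wave timing truth) and `config`
#' @export
generate_dipole <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  rr <- 60 / config$heart_rate
  wp <- config$wave_params
  rownames(wp) <- wp$wave
  if (wp["T", "center_ms"] / 1000 > rr + wp["P", "center_ms"] / 1000) {
    stop("invalid timing: T wave center overlaps the next beat's P wave")
  }
  n <- round(fs * config$duration)
  t <- (seq_len(n) - 1) / fs
  r_centers <- seq(0.35, config$duration - 1 / fs, by = rr)

  # loop-plane rotation axis; degenerate (collinear) geometry falls back to
  # an arbitrary perpendicular
  nrm <- cross3(config$t_direction, config$qrs_direction)
  if (sqrt(sum(nrm^2)) < 1e-9) {
    nrm <- cross3(config$t_direction, c(1, 0, 0))
    if (sqrt(sum(nrm^2)) < 1e-9) nrm <- cross3(config$t_direction, c(0, 1, 0))
  }
  nrm <- unit_vector(nrm)

  # The P wave rides on the T axis: the atrial axis is not a property of the
  # ventricular (QRS) loop, and anchoring it to the fixed repolarization
  # frame keeps pre-QRS baseline geometry independent of theta
  dirs <- list(
    P = config$t_direction,
    Q = rotate_about(config$qrs_direction, nrm, -config$qrs_loop_spread),
    R = config$qrs_direction,
    S = rotate_about(config$qrs_direction, nrm, config$qrs_loop_spread),
    T = config$t_direction
  )
  # T-loop minor axis along the plane normal: the repolarization loop tilts
  # out of the QRS-T plane, so any config with t_loop_ratio > 0 spans all
  # three dipole dimensions
  t_perp <- nrm

  d <- matrix(0, nrow = 3, ncol = n)
  for (rc in r_centers) {
    for (w in wp$wave) {
      c_s <- rc + wp[w, "center_ms"] / 1000
      w_s <- wp[w, "width_ms"] / 1000
      g <- wp[w, "amp_mv"] * exp(-(t - c_s)^2 / (2 * w_s^2))
      d <- d + outer(dirs[[w]], g)
      if (w == "T" && config$t_loop_ratio > 0) {
        # minor axis: scaled Gaussian derivative, peak amplitude
        # amp * t_loop_ratio, zero at the T peak itself
        gm <- wp[w, "amp_mv"] * config$t_loop_ratio * exp(0.5) *
          ((t - c_s) / w_s) * exp(-(t - c_s)^2 / (2 * w_s^2))
        d <- d + outer(t_perp, gm)
      }
    }
  }
  attr(d, "fiducials") <- list(
    r_centers_s = r_centers,
    r_centers_idx = round(r_centers * fs) + 1,
    rr = rr, theta = config$theta, wave_params = wp
  )
  attr(d, "config") <- config
  d
}

#' Project a dipole trajectory onto the 12 standard leads
#'
#' The eight independent leads are `LEAD_PROJECTION %*% dipole` plus
#' additive white noise and optional sinusoidal baseline wander; III, aVR,
#' aVL and aVF are then derived by the Einthoven/Goldberger identities (so
#' their noise is the corresponding combination of limb-lead noise).
#'
#' @param dipole 3 x N matrix from [generate_dipole()]
#' @param config the [synth_config()] used to generate it
#' @param subject_id identifier for the resulting record
#' @return an [ecg_record()] with 12 leads; the generator truth travels
#'   along as attribute `truth`
#' @export
project_to_leads <- function(dipole, config, subject_id = "synthetic") {
  stopifnot(is.matrix(dipole), nrow(dipole) == 3, all(is.finite(dipole)))
  n <- ncol(dipole)
  x8 <- LEAD_PROJECTION %*% dipole
  if (config$noise_sd > 0) {
    x8 <- x8 + matrix(stats::rnorm(8 * n, sd = config$noise_sd), nrow = 8)
  }
  if (config$baseline_wander_amplitude > 0) {
    t <- (seq_len(n) - 1) / config$fs
    wander <- config$baseline_wander_amplitude *
      sin(2 * pi * config$baseline_wander_freq * t)
    x8 <- sweep(x8, 2, wander, "+")
  }
  lead_i <- x8["I", ]; lead_ii <- x8["II", ]
  x12 <- rbind(
    I = lead_i, II = lead_ii, III = lead_ii - lead_i,
    aVR = -(lead_i + lead_ii) / 2, aVL = lead_i - lead_ii / 2,
    aVF = lead_ii - lead_i / 2,
    x8[c("V1", "V2", "V3", "V4", "V5", "V6"), ]
  )
  rec <- ecg_record(t(x12), rownames(x12), fs = config$fs,
                    subject_id = subject_id)
  attr(rec, "truth") <- attr(dipole, "fiducials")
  rec
}

#' Generate a complete synthetic 12-lead recording
#'
#' Convenience wrapper: [generate_dipole()] then [project_to_leads()] under
#' the configuration's seed (if any).
#'
#' @inheritParams project_to_leads
#' @param config a [synth_config()]
#' @return an [ecg_record()]
#' @export
generate_ecg <- function(config, subject_id = "synthetic") {
  with_seed(config$seed,
            project_to_leads(generate_dipole(config), config, subject_id))
}

#' Configuration of a simulated two-group cohort
#'
#' Each subject's QRS-T angle theta is drawn from a group-specific normal
#' distribution and clamped to `[0, 180]` degrees (out-of-range draws are
#' truncated, not resampled). The T-wave axis and loop shape are identical
#' for every subject -- the group difference lives entirely in the
#' orientation of the depolarization (QRS) loop relative to it -- so
#' T-morphology dispersion markers are exchangeable between groups by
#' construction while TCRT separates them.
#'
#' @param n_control,n_case group sizes (either may be 0 for a single-group
#'   cohort)
#' @param theta_control_mean,theta_control_sd,theta_case_mean,theta_case_sd
#'   group theta distributions, degrees; the defaults put the group means of
#'   cos(theta) near 0.44 (control) and 0.08 (case)
#' @param noise_sd additive lead noise, mV
#' @param fs,duration recording parameters passed to [synth_config()]
#' @param heart_rate_range per-subject resting heart rate is drawn uniformly
#'   from this range, bpm
#' @param seed integer seed governing every random draw of the simulation
#' @return validated list of class `cohort_sim_config`
#' @export
cohort_sim_config <- function(n_control = 74, n_case = 50,
                              theta_control_mean = 61, theta_control_sd = 25,
                              theta_case_mean = 85, theta_case_sd = 30,
                              noise_sd = 0.01, fs = 500, duration = 10,
                              heart_rate_range = c(55, 75), seed = NULL) {
  stopifnot(n_control >= 0, n_case >= 0, n_control + n_case >= 1,
            theta_control_sd >= 0, theta_case_sd >= 0, noise_sd >= 0)
  structure(list(
    n_control = n_control, n_case = n_case,
    theta_control_mean = theta_control_mean,
    theta_control_sd = theta_control_sd,
    theta_case_mean = theta_case_mean, theta_case_sd = theta_case_sd,
    noise_sd = noise_sd, fs = fs, duration = duration,
    heart_rate_range = heart_rate_range, seed = seed
  ), class = "cohort_sim_config")
}

# Group-specific covariate generators; rates emulate a middle-aged screening
# population (cases carry a higher statin rate).
.sim_covariates <- function(n, case) {
  if (n == 0) {
    return(data.frame(age = numeric(0), sex = character(0),
                      height = numeric(0), weight = numeric(0),
                      bmi = numeric(0), dyslipidemia = logical(0),
                      hypertension = logical(0), fhx_ihd = logical(0),
                      aspirin = logical(0), acei_arb = logical(0),
                      ccb = logical(0), beta_blocker = logical(0),
                      statin = logical(0), thiazide = logical(0),
                      current_smoker = logical(0), past_smoker = logical(0),
                      sbp = numeric(0), dbp = numeric(0)))
  }
  height <- round(stats::rnorm(n, if (case) 1.71 else 1.69, 0.09), 2)
  bmi <- round(stats::rnorm(n, if (case) 28.1 else 27.5, 4.3), 1)
  data.frame(
    age = round(clamp(stats::rnorm(n, if (case) 58.4 else 57.3, 13), 25, 85)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.53, 0.47)),
    height = height,
    weight = round(bmi * height^2, 1),
    bmi = bmi,
    dyslipidemia = stats::runif(n) < (if (case) 0.76 else 0.662),
    hypertension = stats::runif(n) < (if (case) 0.68 else 0.395),
    fhx_ihd = stats::runif(n) < (if (case) 0.40 else 0.378),
    aspirin = stats::runif(n) < (if (case) 0.50 else 0.351),
    acei_arb = stats::runif(n) < (if (case) 0.52 else 0.365),
    ccb = stats::runif(n) < (if (case) 0.30 else 0.203),
    beta_blocker = stats::runif(n) < (if (case) 0.34 else 0.297),
    statin = stats::runif(n) < (if (case) 0.60 else 0.365),
    thiazide = stats::runif(n) < (if (case) 0.26 else 0.162),
    current_smoker = stats::runif(n) < 0.145,
    past_smoker = stats::runif(n) < 0.25,
    sbp = round(stats::rnorm(n, if (case) 134.4 else 130.5, 20), 1),
    dbp = round(stats::rnorm(n, if (case) 75.5 else 79.0, 11), 1)
  )
}

#' Simulate a two-group cohort of 12-lead recordings
#'
#' @param config a [cohort_sim_config()]
#' @return list with `records` (list of [ecg_record()]) and `cohort` (a
#'   `cohort_table` with group labels, clinical covariates and the hidden
#'   ground-truth column `theta_true` in degrees)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    groups <- c(rep("control", config$n_control),
                rep("dm_ifg", config$n_case))
    n <- length(groups)
    theta <- numeric(n)
    theta[groups == "control"] <- stats::rnorm(
      config$n_control, config$theta_control_mean, config$theta_control_sd)
    theta[groups == "dm_ifg"] <- stats::rnorm(
      config$n_case, config$theta_case_mean, config$theta_case_sd)
    theta <- clamp(theta, 0, 180)
    hr <- stats::runif(n, config$heart_rate_range[1],
                       config$heart_rate_range[2])
    cov <- rbind(.sim_covariates(config$n_control, case = FALSE),
                 .sim_covariates(config$n_case, case = TRUE))
    ids <- sprintf("S%03d", seq_len(n))
    records <- vector("list", n)
    for (i in seq_len(n)) {
      sc <- synth_config(fs = config$fs, duration = config$duration,
                         heart_rate = hr[i], theta = theta[i],
                         noise_sd = config$noise_sd)
      records[[i]] <- generate_ecg(sc, subject_id = ids[i])
    }
    names(records) <- ids
    cohort <- cbind(data.frame(subject_id = ids, group = groups), cov,
                    data.frame(theta_true = theta))
    list(records = records, cohort = as_cohort_table(cohort))
  })
}
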