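# Hand-constructible decomposed beats for direct marker checks.
fake_decomposed <- function(s3, leads = NULL, fs = 500) {
  structure(list(
    s3 = s3,
    weights = diag(8)[, 1:3],
    singular_values = rep(1, 8),
    energy_fraction_3 = 1,
    fs = fs,
    leads = if (is.null(leads)) matrix(0, 8, ncol(s3)) else leads,
    r_index = 1L
  ), class = "decomposed_beat")
}

fake_landmarks <- function(qrs_onset, r_peak, qrs_offset, t_start, t_peak,
                           t_end) {
  structure(list(qrs_onset = qrs_onset, r_peak = r_peak,
                 qrs_offset = qrs_offset, t_start = t_start, t_peak = t_peak,
                 t_end = t_end), class = "ecg_landmarks")
}

test_that("TCRT reproduces hand-computed cosine averages", {
  # two QRS vectors (1,0,0) and (0,1,0) against T vector (1,0,0):
  # cosines 1 and 0, mean 0.5
  s3 <- matrix(0, nrow = 3, ncol = 10)
  s3[, 2] <- c(1, 0, 0)
  s3[, 3] <- c(0, 1, 0)
  s3[, 8] <- c(1, 0, 0)
  lm <- fake_landmarks(2, 2, 3, 6, 8, 10)
  expect_equal(compute_tcrt(fake_decomposed(s3), lm, qrs_energy_frac = 0),
               0.5)
  # collinear same sense -> 1; anti-collinear -> -1
  s3b <- matrix(0, 3, 10)
  s3b[, 2:3] <- c(2, 0, 0)
  s3b[, 8] <- c(5, 0, 0)
  expect_equal(compute_tcrt(fake_decomposed(s3b), lm, qrs_energy_frac = 0), 1)
  s3b[, 8] <- c(-5, 0, 0)
  expect_equal(compute_tcrt(fake_decomposed(s3b), lm, qrs_energy_frac = 0), -1)
  # zero T vector is degenerate
  s3b[, 8] <- 0
  expect_error(compute_tcrt(fake_decomposed(s3b), lm), "degenerate T vector")
})

test_that("the QRS energy threshold excludes low-energy tail vectors", {
  s3 <- matrix(0, 3, 10)
  s3[, 2] <- c(10, 0, 0)   # dominant QRS sample
  s3[, 3] <- c(0, 0.1, 0)  # low-energy tail, orthogonal to T
  s3[, 8] <- c(1, 0, 0)
  lm <- fake_landmarks(2, 2, 3, 6, 8, 10)
  expect_equal(compute_tcrt(fake_decomposed(s3), lm, qrs_energy_frac = 0.7), 1)
  expect_equal(compute_tcrt(fake_decomposed(s3), lm, qrs_energy_frac = 0), 0.5)
})

test_that("TMD reproduces the 4-versus-4 orthogonal-lead hand count", {
  # leads 1-4 share one T waveform, leads 5-8 an orthogonal one:
  # 12 same-direction pairs at 0 deg, 16 cross pairs at 90 deg
  # -> (12*0 + 16*90)/28 = 51.43 deg
  n <- 40
  a <- sin(2 * pi * seq_len(n) / n)
  b <- cos(2 * pi * seq_len(n) / n)
  leads <- rbind(matrix(rep(a, 4), nrow = 4, byrow = TRUE),
                 matrix(rep(b, 4), nrow = 4, byrow = TRUE))
  dec <- fake_decomposed(matrix(1, 3, n), leads = leads)
  # T window must span the full period so the two waveforms stay orthogonal
  lm <- fake_landmarks(1, 2, 3, 1, 20, n)
  expect_equal(compute_tmd(dec, lm, "full"), 16 * 90 / 28, tolerance = 1e-9)
})

test_that("TMD is 0 for identical lead shapes and scale-invariant", {
  n <- 40
  a <- sin(2 * pi * seq_len(n) / n)
  leads <- outer(c(1, 2, 3, 4, 5, 6, 7, 8), a)  # same shape, positive gains
  dec <- fake_decomposed(matrix(1, 3, n), leads = leads)
  lm <- fake_landmarks(1, 2, 3, 5, 20, n)
  expect_equal(compute_tmd(dec, lm, "full"), 0, tolerance = 1e-7)

  rec <- clean_record(duration = 4, fs = 500, noise = 0)
  beats <- segment_beats(rec, detect_r_peaks(rec))
  b <- beats[[2]]
  dec1 <- svd_decompose(b$samples, b$fs, r_index = b$r_index)
  lm1 <- detect_landmarks(energy_vector(dec1), r_hint = b$r_index)
  b$samples <- 2.5 * b$samples
  dec2 <- svd_decompose(b$samples, b$fs, r_index = b$r_index)
  lm2 <- detect_landmarks(energy_vector(dec2), r_hint = b$r_index)
  expect_equal(compute_tmd(dec2, lm2, "full"), compute_tmd(dec1, lm1, "full"),
               tolerance = 1e-9)
})

test_that("degenerate T loops are rejected", {
  n <- 40
  a <- sin(2 * pi * seq_len(n) / n)
  leads <- rbind(matrix(rep(a, 3), nrow = 3, byrow = TRUE),
                 matrix(0, 5, n))  # 5 zero-norm reconstruction vectors
  dec <- fake_decomposed(matrix(1, 3, n), leads = leads)
  lm <- fake_landmarks(1, 2, 3, 5, 20, n)
  expect_error(compute_tmd(dec, lm, "full"), "degenerate T loop")
})

test_that("pipeline TCRT matches cos(theta) on clean beats", {
  m60 <- markers_for(60)
  expect_equal(m60$tcrt, 0.5, tolerance = 0.02)
  m90 <- markers_for(90)
  expect_equal(m90$tcrt, 0, tolerance = 0.02)
  expect_identical(m60$mode, "averaged")
})

test_that("TCRT decreases strictly with theta on clean beats", {
  thetas <- seq(0, 180, by = 20)
  tcrts <- vapply(thetas, function(th) markers_for(th)$tcrt, numeric(1))
  expect_true(all(diff(tcrts) < 0))
  expect_true(all(abs(tcrts - cos(thetas * pi / 180)) <= 0.02))
})

test_that("markers stay in bounds across random configurations", {
  set.seed(202)
  for (i in 1:40) {
    cfg <- synth_config(
      fs = 500, duration = 2, heart_rate = stats::runif(1, 45, 100),
      theta = stats::runif(1, 0, 180),
      qrs_loop_spread = stats::runif(1, 0, 30),
      t_loop_ratio = stats::runif(1, 0.05, 0.4),
      noise_sd = stats::runif(1, 0, 0.02))
    rec <- generate_ecg(cfg)
    beats <- suppressWarnings(segment_beats(rec, detect_r_peaks(rec)))
    m <- compute_markers(beats[[1]])
    expect_gte(m$tcrt, -1); expect_lte(m$tcrt, 1)
    for (v in c(m$tmd, m$tmd_pre, m$tmd_post)) {
      expect_gte(v, 0); expect_lte(v, 180)
    }
  }
})

test_that("TCRT and landmarks are invariant under global dipole rotation", {
  cfg <- synth_config(fs = 500, duration = 2, theta = 55, noise_sd = 0)
  dip <- generate_dipole(cfg)
  ang <- 70 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
  m <- list()
  for (k in 1:2) {
    d <- if (k == 1) dip else R %*% dip
    rec <- project_to_leads(d, cfg)
    beats <- segment_beats(rec, detect_r_peaks(rec))
    m[[k]] <- compute_markers(beats[[1]])
  }
  expect_equal(m[[2]]$tcrt, m[[1]]$tcrt, tolerance = 1e-6)
  expect_identical(unclass(m[[2]]$landmarks), unclass(m[[1]]$landmarks))
  expect_equal(m[[2]]$energy_fraction_3, m[[1]]$energy_fraction_3,
               tolerance = 1e-9)
})

test_that("pipeline TCRT agrees with a brute-force computation on the raw dipole", {
  # oracle: recover the dipole by pseudo-inverting the known lead field,
  # then average cosines between raw QRS dipole vectors and the T-peak
  # dipole vector -- no SVD involved
  for (th in c(30, 100, 160)) {
    cfg <- synth_config(fs = 500, duration = 4, theta = th,
                        qrs_loop_spread = 0, noise_sd = 0)
    rec <- generate_ecg(cfg)
    beats <- segment_beats(rec, detect_r_peaks(rec))
    b <- beats[[2]]
    m <- compute_markers(b)

    pinv <- solve(crossprod(LEAD_PROJECTION), t(LEAD_PROJECTION))
    dip <- pinv %*% b$samples
    lm <- m$landmarks
    e <- colSums(dip^2)
    idx <- lm$qrs_onset:lm$qrs_offset
    keep <- idx[e[idx] >= 0.7 * max(e[idx])]
    tvec <- dip[, lm$t_peak]
    cosines <- colSums(dip[, keep, drop = FALSE] * tvec) /
      (sqrt(colSums(dip[, keep, drop = FALSE]^2)) * sqrt(sum(tvec^2)))
    expect_equal(m$tcrt, mean(cosines), tolerance = 0.02)
  }
})

test_that("random and averaged modes coincide when all beats are identical", {
  rec <- clean_record(duration = 10, fs = 500, noise = 0)
  beats <- segment_beats(rec, detect_r_peaks(rec))
  mr <- compute_markers(select_random_beat(beats, seed = 1))
  ma <- compute_markers(average_beat(beats))
  expect_equal(mr$tcrt, ma$tcrt, tolerance = 1e-9)
  expect_equal(mr$tmd, ma$tmd, tolerance = 1e-9)
  expect_identical(mr$mode, "random")
  expect_identical(ma$mode, "averaged")
})
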