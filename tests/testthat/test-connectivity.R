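test_that("ROI principal components span the signal subspace", {
  fs <- 100; n <- 500; n_tr <- 6
  tt <- (0:(n - 1)) / fs
  base <- rbind(sin(2 * pi * 3 * tt), sin(2 * pi * 7 * tt), sin(2 * pi * 13 * tt))
  mix <- matrix(c(1, 0.2, 0.1, 0.3, 1, 0.2, 0.1, 0.4, 1, 0.5, 0.5, 0.5), 4, 3)
  dat <- array(0, dim = c(n_tr, 4, n))
  for (tr in 1:n_tr) dat[tr, , ] <- mix %*% base
  ep <- roi_epochs(dat, fs = fs, time = tt, roi = paste0("v", 1:4))
  pc <- roi_block_components(ep, 3)
  ## principal angles between recovered weights and the mixing space ~ 0
  qa <- qr.Q(qr(pc$weights))
  qb <- qr.Q(qr(mix))
  sv <- svd(t(qa) %*% qb)$d
  expect_true(all(acos(pmin(sv, 1)) < 1e-6))
  ## variances non-increasing; duplicated channel adds nothing
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  dat5 <- array(0, dim = c(n_tr, 5, n))
  dat5[, 1:4, ] <- dat; dat5[, 5, ] <- dat[, 4, ]
  ep5 <- roi_epochs(dat5, fs = fs, time = tt, roi = paste0("v", 1:5))
  pc5 <- roi_block_components(ep5, 3)
  expect_equal(sum(pc5$var_explained), sum(pc$var_explained), tolerance = 0.2)
  ## rank-deficient input warns
  dat2 <- array(rnorm(n_tr * n), dim = c(n_tr, 1, n))
  dat3 <- array(0, dim = c(n_tr, 3, n))
  for (ch in 1:3) dat3[, ch, ] <- dat2[, 1, ] * ch
  expect_warning(roi_block_components(
    roi_epochs(dat3, fs, tt, paste0("v", 1:3)), 3), "rank")
})

test_that("CSD estimates: coherence bounds and agreement with the analytic VAR spectrum", {
  set.seed(51)
  fs <- 100; n_t <- 200; n_tr <- 150
  ## independent white noise: off-diagonal coherence within sampling bounds
  dat <- array(rnorm(n_tr * 2 * n_t), dim = c(n_tr, 2, n_t))
  ep <- roi_epochs(dat, fs, (0:(n_t - 1)) / fs, c("a", "b"))
  csd <- csd_multitaper(ep, smoothing_hz = 2, time_window = NULL)
  coh <- abs(csd$S[1, 2, ]) / sqrt(Re(csd$S[1, 1, ]) * Re(csd$S[2, 2, ]))
  expect_lt(mean(coh), 3 / sqrt(n_tr * csd$n_tapers))
  ## identical channels: coherence 1 everywhere
  dat2 <- dat; dat2[, 2, ] <- dat[, 1, ]
  ep2 <- roi_epochs(dat2, fs, (0:(n_t - 1)) / fs, c("a", "b"))
  csd2 <- csd_multitaper(ep2, smoothing_hz = 2, time_window = NULL)
  coh2 <- abs(csd2$S[1, 2, ]) / sqrt(Re(csd2$S[1, 1, ]) * Re(csd2$S[2, 2, ]))
  expect_true(all(abs(coh2 - 1) < 1e-9))
  ## VAR(1) cross-spectrum matches the closed form within estimator error
  A1 <- matrix(c(0.5, 0, 0.3, 0.4), 2, 2, byrow = TRUE)
  epv <- sim_var_epochs(A1, matrix(0, 2, 2), 300, n_t, fs, seed = 52)
  csdv <- csd_multitaper(epv, smoothing_hz = 2, time_window = NULL)
  an <- oracle_var_spectrum(list(A1), diag(2), csdv$freq, fs)
  mid <- csdv$freq > 5 & csdv$freq < 45
  rel <- Mod(csdv$S[, , mid] - an$S[, , mid]) / mean(Mod(an$S[, , mid]))
  expect_lt(stats::median(rel), 0.15)
})

test_that("Wilson factorization: identity input, VAR innovations, reconstruction residual", {
  fs <- 100; nh <- 65
  ## identity spectrum factorizes trivially
  Sid <- array(0i, dim = c(3, 3, nh))
  for (k in 1:nh) Sid[, , k] <- diag(3) / fs
  csd_id <- structure(list(S = Sid, freq = seq(0, fs / 2, length.out = nh),
                           fs = fs, n_trials = 1, n_tapers = 1,
                           roi = letters[1:3]), class = "csd")
  fac_id <- wilson_factorize(csd_id, loading = 0)
  expect_lt(max(Mod(fac_id$H[, , 5] - diag(3))), 1e-6)
  expect_lt(max(abs(fac_id$Sigma - diag(3))), 1e-6)
  ## analytic VAR(2) spectrum: innovation covariance recovered within 5%
  fs2 <- 100
  a <- c(2 * 0.8 * cos(2 * pi * 25 / fs2), -0.64)
  A1 <- matrix(c(a[1], 0, 0.2, a[1]), 2, 2, byrow = TRUE)
  A2 <- diag(a[2], 2)
  Sig <- matrix(c(1, 0.2, 0.2, 1.5), 2, 2)
  freq <- seq(0, fs2 / 2, length.out = 161)
  an <- oracle_var_spectrum(list(A1, A2), Sig, freq, fs2)
  csd_v <- structure(list(S = an$S, freq = freq, fs = fs2, n_trials = 1,
                          n_tapers = 1, roi = c("x", "y")), class = "csd")
  fac_v <- wilson_factorize(csd_v)
  expect_lt(max(abs(fac_v$Sigma - Sig) / max(abs(Sig))), 0.05)
  ## random smooth PSD inputs: reconstruction residual below 1e-6
  set.seed(53)
  nh2 <- 33
  B <- array(rnorm(2 * 2 * 5), dim = c(2, 2, 5))
  Sr <- array(0i, dim = c(2, 2, nh2))
  for (k in 1:nh2) {
    w <- 2 * pi * (k - 1) / (2 * (nh2 - 1))
    M <- matrix(0i, 2, 2)
    for (l in 1:5) M <- M + B[, , l] * exp(-1i * w * (l - 1))
    Sr[, , k] <- M %*% Conj(t(M)) + diag(2) * 0.1
  }
  csd_r <- structure(list(S = Sr, freq = seq(0, 50, length.out = nh2), fs = 100,
                          n_trials = 1, n_tapers = 1, roi = c("x", "y")),
                     class = "csd")
  fac_r <- wilson_factorize(csd_r, tol = 1e-8, loading = 0)
  expect_lt(fac_r$relres, 1e-6)
})

test_that("block GC: null for independent blocks, directional for coupled VAR, matches the parametric oracle", {
  set.seed(54)
  fs <- 100; n_t <- 200; n_tr <- 400
  ## independent blocks (3 + 3 channels of white noise)
  dat <- array(rnorm(n_tr * 6 * n_t), dim = c(n_tr, 6, n_t))
  ep0 <- roi_epochs(dat, fs, (0:(n_t - 1)) / fs, paste0("c", 1:6))
  csd0 <- csd_multitaper(ep0, smoothing_hz = 2, time_window = NULL)
  gc0 <- block_gc(csd0, wilson_factorize(csd0), 1:3, 4:6)
  expect_lt(max(gc0$gc, na.rm = TRUE), 0.1)
  ## 2-channel VAR with x -> y only; 4-s windows keep the resonance well
  ## resolved relative to the 1-Hz taper smoothing
  a <- c(2 * 0.8 * cos(2 * pi * 25 / fs), -0.64)
  A1 <- matrix(c(a[1], 0, 0.2, a[1]), 2, 2, byrow = TRUE)
  A2 <- diag(a[2], 2)
  epv <- sim_var_epochs(A1, A2, n_tr, 400, fs, seed = 55)
  csdv <- csd_multitaper(epv, smoothing_hz = 1, time_window = NULL)
  gcv <- block_gc(csdv, wilson_factorize(csdv), 1, 2)
  band <- csdv$freq >= 20 & csdv$freq <= 30
  expect_gt(mean(gcv$gc[band, "a2b"]), 10 * mean(gcv$gc[band, "b2a"]))
  ## parametric oracle from the true coefficients: within 10% at the peak
  gct <- oracle_var_block_gc(list(A1, A2), diag(2), csdv$freq, fs, src = 1, dst = 2)
  pk <- which.max(gct)
  expect_lt(abs(gcv$gc[pk, "a2b"] - gct[pk]) / gct[pk], 0.10)
})

test_that("DAI identities: arithmetic, bounds, antisymmetry, NA handling", {
  expect_equal(dai(0.3, 0.1), 0.5)
  x <- runif(20, 0.01, 2)
  expect_true(all(dai(x, x) == 0))
  expect_true(all(dai(x, rep(0, 20)) == 1))
  expect_true(all(dai(rep(0, 20), x) == -1))
  y <- runif(20, 0.01, 2)
  expect_equal(dai(x, y), -dai(y, x))
  expect_true(all(abs(dai(x, y)) <= 1))
  expect_true(is.na(dai(0, 0)))
  expect_error(dai(-0.1, 0.2), "nonnegative")
})

test_that("phase-resolved GC recovers a phase-locked coupling modulation", {
  set.seed(56)
  n_tr <- 1200                          # 40 trials per non-overlapping bin
  ph <- runif(n_tr, -pi, pi)
  ## broader resonance + moderate coupling keep the bin-resolved GC graded in
  ## the gain (the log saturates for strong coupling, flattening the profile)
  cp <- coupling_spec(strength = 0.3, pole_radius = 0.8, gain_phase = 0)
  ep <- gen_roi_timeseries(ph, coupling = cp, seed = 57)
  pcA <- roi_block_components(resphase:::subset_epochs(ep, 1:3))
  pcB <- roi_block_components(resphase:::subset_epochs(ep, 4:6))
  comb <- resphase:::bind_epochs(pcA$components, pcB$components)
  pgc <- suppressMessages(phase_resolved_gc(comb, ph, fmax = 45))
  reg <- gc_phase_regression(pgc)
  band <- reg$freq >= 7 & reg$freq <= 13
  ## bin profile of forward GC tracks the cosine gain
  f10 <- which.min(abs(pgc$freq - 10))
  prof <- pgc$gc[f10, , "a2b"]
  ok <- is.finite(prof)
  expect_gt(cor(prof[ok], cos(pgc$centres[ok])), 0.7)
  ## modulation phase and direction
  expect_lt(circ_dist(reg$preferred_phase[f10, "a2b"], 0), pi / 4)
  expect_gt(mean(reg$dai_mod[band], na.rm = TRUE), 0.5)
  ## phase-independent coupling: bin-to-bin variation within resampling noise
  ep_flat <- gen_roi_timeseries(ph, coupling = coupling_spec(strength = 0.3,
                                                             pole_radius = 0.8,
                                                             gain_depth = 0),
                                seed = 58)
  pcA2 <- roi_block_components(resphase:::subset_epochs(ep_flat, 1:3))
  pcB2 <- roi_block_components(resphase:::subset_epochs(ep_flat, 4:6))
  comb2 <- resphase:::bind_epochs(pcA2$components, pcB2$components)
  pgc2 <- suppressMessages(phase_resolved_gc(comb2, ph, fmax = 45))
  reg2 <- gc_phase_regression(pgc2)
  ## relative modulation much smaller than in the modulated run
  relmod <- mean(reg2$amplitude[band, "a2b"]) / mean(pgc2$gc[band, , "a2b"], na.rm = TRUE)
  relmod_true <- mean(reg$amplitude[band, "a2b"]) / mean(pgc$gc[band, , "a2b"], na.rm = TRUE)
  expect_lt(relmod, relmod_true / 2)
})

test_that("GC phase regression: flat input gives no modulation; direction swap flips the DAI", {
  set.seed(59)
  nf <- 10; nb <- 30
  centres <- -pi + (seq_len(nb) - 0.5) * 2 * pi / nb
  gc_arr <- array(NA_real_, dim = c(nf, nb, 2),
                  dimnames = list(NULL, NULL, c("a2b", "b2a")))
  gc_arr[, , 1] <- matrix(0.5, nf, nb) + outer(rep(1, nf), 0.2 * cos(centres))
  gc_arr[, , 2] <- 0.5
  pgc <- structure(list(gc = gc_arr, freq = 1:nf, centres = centres,
                        n = rep(20, nb), skipped = integer(0)),
                   class = "phase_gc")
  reg <- gc_phase_regression(pgc)
  expect_equal(unname(reg$amplitude[, "a2b"]), rep(0.2, nf), tolerance = 1e-9)
  expect_lt(max(reg$amplitude[, "b2a"]), 1e-9)
  expect_true(all(reg$dai_mod > 0.99))
  ## swapping the direction labels flips the sign
  pgc_sw <- pgc
  pgc_sw$gc <- pgc$gc[, , c(2, 1)]
  dimnames(pgc_sw$gc)[[3]] <- c("a2b", "b2a")
  reg_sw <- gc_phase_regression(pgc_sw)
  expect_equal(reg_sw$dai_mod, -reg$dai_mod, tolerance = 1e-12)
})
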