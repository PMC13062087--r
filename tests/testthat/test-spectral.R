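test_that("epoch segmentation: window arithmetic, constants, edge drops", {
  fs <- 300
  x <- matrix(rnorm(fs * 30 * 2), ncol = 2)
  on <- c(5, 10, 29.9)      # the last onset has no room for the post window
  expect_message(ep <- segment_epochs(x, fs, on), "dropped")
  expect_equal(dim(ep$data), c(2L, 2L, 780L))
  expect_identical(attr(ep, "dropped"), 3L)
  ## constant input -> constant epochs
  xc <- matrix(3, fs * 10, 1)
  epc <- segment_epochs(xc, fs, 5)
  expect_true(all(epc$data == 3))
  ## a 10 Hz sinusoid survives 600 -> 300 Hz resampling within 1% amplitude
  t6 <- seq(0, 10, by = 1 / 600)
  ep6 <- segment_epochs(matrix(sin(2 * pi * 10 * t6)), 600, 5)
  mid <- ep6$data[1, 1, 100:700]
  expect_lt(abs(diff(range(mid)) / 2 - 1), 0.01)
})

test_that("initial staircase trials are discarded per run, order preserved", {
  sched <- gen_design(design_spec(seed = 31))
  kept <- discard_initial_trials(sched, 10)
  expect_equal(nrow(kept), 660)
  expect_true(all(table(kept$run) == 110))
  expect_true(all(kept$trial > 10))
  expect_identical(discard_initial_trials(sched, 0), sched)
  r1 <- kept[kept$run == 1, "trial"]
  expect_true(all(diff(r1) > 0))
  expect_warning(discard_initial_trials(data.frame(run = 1, trial = 1:5), 10),
                 "no trials")
})

test_that("motion GLM removes linear and quadratic motion coupling, spares orthogonal signal", {
  set.seed(41)
  n <- 3000
  motion <- matrix(rnorm(n * 6), n, 6)
  motion <- apply(motion, 2, cumsum) / 30      # slow drifting motion
  ## parcel fully driven by motion
  y1 <- 0.5 * motion[, 2]
  r1 <- motion_glm_clean(y1, motion)
  expect_lt(sd(r1), 0.05 * sd(y1))
  ## quadratic coupling removed by the order-2 expansion
  y2 <- scale(motion[, 3])^2
  r2 <- motion_glm_clean(as.numeric(y2), motion)
  expect_gt(1 - var(r2) / var(y2), 0.95)
  ## motion-orthogonal signal survives (up to polynomial detrend)
  y3 <- sin(2 * pi * 10 * (1:n) / 300) + rnorm(n, 0, 0.1)
  r3 <- motion_glm_clean(y3, motion)
  expect_gt(cor(r3, y3), 0.99)
})

test_that("derivative whitening: closed-form gain and 1/f flattening", {
  ## constant -> zeros
  ep <- roi_epochs(array(5, dim = c(1, 1, 100)), fs = 100,
                   time = (0:99) / 100, roi = "a")
  expect_true(all(whiten_derivative(ep)$data == 0))
  ## first-difference gain at f equals 2 sin(pi f / fs) (RMS ratio)
  fs <- 300; n <- 3000
  for (f in c(5.3, 20.7, 61.1)) {
    x <- sin(2 * pi * f * (0:(n - 1)) / fs)
    epf <- roi_epochs(array(x, dim = c(1, 1, n)), fs = fs,
                      time = (0:(n - 1)) / fs, roi = "a")
    w <- whiten_derivative(epf)
    gain <- sd(w$data) / sd(x)
    expect_equal(gain, 2 * sin(pi * f / fs), tolerance = 0.01)
  }
  ## whitening flattens an aperiodic 1/f^2 power spectrum over 5-40 Hz
  ## (the squared filter gain rises as f^2 at low frequency)
  set.seed(42)
  bg <- resphase:::onef_noise(600, 24, fs, alpha = 2)
  epb <- roi_epochs(array(t(bg), dim = c(24, 1, 600)), fs = fs,
                    time = (0:599) / fs, roi = "a")
  ps <- multitaper_psd(whiten_derivative(epb), fmin = 5, fmax = 40,
                       smoothing_hz = 1, time_window = NULL)
  logp <- log10(apply(ps$power, 3, mean))
  slope <- coef(lm(logp ~ log10(ps$freq)))[2]
  expect_lt(abs(slope), 0.3)
})

test_that("multitaper PSD: Parseval, peak location, taper count convention", {
  set.seed(43)
  fs <- 300; n <- 480
  ## white noise: flat spectrum integrating to the variance
  x <- array(rnorm(60 * n), dim = c(60, 1, n))
  ep <- roi_epochs(x, fs = fs, time = seq(-1.6, by = 1 / fs, length.out = n),
                   roi = "a")
  ps <- multitaper_psd(ep, fmin = 0, fmax = 150, smoothing_hz = 2)
  expect_equal(ps$n_tapers, floor(2 * (2 * n / fs)) - 1)   # floor(2 NW) - 1
  df <- fs / n
  tot <- mean(apply(ps$power, 1, function(m) sum(m) * df))
  expect_equal(tot, 1, tolerance = 0.05)
  ## pure sinusoid peaks at its frequency
  xs <- array(sin(2 * pi * 10 * (0:(n - 1)) / fs), dim = c(1, 1, n))
  eps <- roi_epochs(xs, fs = fs, time = seq(-1.6, by = 1 / fs, length.out = n),
                    roi = "a")
  pss <- multitaper_psd(eps, fmin = 1, fmax = 40, smoothing_hz = 2)
  expect_equal(pss$freq[which.max(pss$power[1, 1, ])], 10, tolerance = 0.7)
  ## too-small smoothing errors out naming the minimum
  expect_error(multitaper_psd(ep, smoothing_hz = 0.2), "at least")
})

test_that("time-frequency transform localizes an amplitude step", {
  fs <- 300; n <- 780
  tt <- seq(-1.85, by = 1 / fs, length.out = n)
  carrier <- sin(2 * pi * 10 * tt)
  amp <- ifelse(tt > -0.5, 2, 0.5)
  x <- array(rep(amp * carrier, each = 8) + rnorm(8 * n, 0, 0.1),
             dim = c(8, 1, n))
  ep <- roi_epochs(x, fs = fs, time = tt, roi = "a")
  tfr <- tfr_multitaper(ep, fmin = 5, fmax = 20, win_s = 0.4, step_s = 0.1)
  f10 <- which.min(abs(tfr$freq - 10))
  early <- mean(tfr$power[1, f10, tfr$time < -0.8])
  late <- mean(tfr$power[1, f10, tfr$time > -0.2])
  expect_gt(late / early, 4)
  ## zero signal -> zero power
  ep0 <- roi_epochs(array(0, dim = c(2, 1, n)), fs = fs, time = tt, roi = "a")
  tfr0 <- tfr_multitaper(ep0, fmin = 5, fmax = 20, win_s = 0.4, step_s = 0.2)
  expect_equal(max(tfr0$power), 0, tolerance = 1e-20)
})

test_that("phase-binned power: bookkeeping and recovery of a planted modulation", {
  set.seed(44)
  n_tr <- 600
  ph <- runif(n_tr, -pi, pi)
  ep <- gen_roi_timeseries(ph,
                           power_mod = list(A = list(depth = 0.2, phase = pi / 2, p0 = 1),
                                            B = list(depth = 0.2, phase = pi / 2, p0 = 1)),
                           coupling = NULL, channel_noise = 0.3, seed = 45)
  spec <- multitaper_psd(whiten_derivative(ep), fmin = 4, fmax = 20)
  pbs <- phase_binned_power(spec, ph, n_bins = 30, mode = "moving")
  ## moving-mode bookkeeping: each trial lands in width/step = 3 bins
  expect_equal(sum(pbs$n), n_tr * 3)
  reg <- power_phase_regression(pbs)
  f10 <- which.min(abs(reg$freq - 10))
  dep <- mean(reg$depth[1:3, f10])
  expect_lt(abs(dep - 0.2), 0.05)
  phs <- mean(reg$preferred_phase[1:3, f10])
  expect_lt(circ_dist(phs, pi / 2), pi / 9)
})
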