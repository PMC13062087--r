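test_that("normalize_and_clip interpolates excursions and is idempotent", {
  ## a single above-threshold sample between anchors gets bridged
  set.seed(1)
  base <- sin(2 * pi * (0:999) / 100)
  spike <- base
  spike[500] <- 30
  out <- normalize_and_clip(cont_signal(spike, fs = 100))
  expect_lt(max(abs(out$samples)), 2.5 + 1e-9)
  ## below-threshold traces only get standardized
  mild <- cont_signal(base, fs = 100)
  out2 <- normalize_and_clip(mild)
  expect_equal(out2$samples, (base - mean(base)) / sd(base), tolerance = 1e-12)
  ## exact idempotence
  out3 <- normalize_and_clip(out)
  expect_equal(out3$samples, out$samples, tolerance = 1e-12)
  expect_error(normalize_and_clip(rep(5, 10)), "constant|exceeds")
})

test_that("sigh clipping preserves the detected cycle count", {
  resp <- gen_respiration(300, fs = 50, rate_bpm = 15, cycle_jitter = 0.05,
                          amp_jitter = 0.05, sigh_prob = 0.15, seed = 42)
  truth <- attr(resp, "truth")
  expect_gt(length(truth$sigh_cycles), 0)
  clipped <- normalize_and_clip(resp)
  ext <- detect_extrema(clipped)
  ## same count without the sighs
  resp0 <- gen_respiration(300, fs = 50, rate_bpm = 15, cycle_jitter = 0.05,
                           amp_jitter = 0.05, sigh_prob = 0, seed = 42)
  ext0 <- detect_extrema(normalize_and_clip(resp0))
  expect_equal(length(ext$peaks), length(ext0$peaks), tolerance = 0.05)
  expect_equal(length(ext$peaks), length(truth$peak_times_s), tolerance = 0.05)
})

test_that("extrema detection honours the prominence criterion", {
  t <- seq(0, 10, by = 0.01)
  x <- 1.5 * sin(2 * pi * t)          # 10 cycles, amplitude 1.5
  ext <- detect_extrema(x, min_prominence = 1)
  expect_equal(length(ext$peaks), 10)
  expect_equal(length(ext$troughs), 10)
  ## superimposed ripple below prominence is ignored
  xr <- x + 0.15 * sin(2 * pi * 8 * t)
  extr <- detect_extrema(xr, min_prominence = 1)
  expect_equal(length(extr$peaks), 10)
  expect_error(detect_extrema(rep(0, 100)), "no extrema")
})

test_that("phase interpolation follows the trough/peak conventions", {
  rp <- interpolate_phase(301, peaks = 101, troughs = c(1, 201))
  expect_equal(rp$phase[51], -pi / 2, tolerance = 1e-12)   # midway trough->peak
  expect_equal(rp$phase[151], pi / 2, tolerance = 1e-12)   # midway peak->trough
  expect_equal(rp$phase[101], 0)
  expect_equal(rp$phase[1], -pi)
  expect_equal(rp$phase[201], -pi)
  expect_true(all(is.na(rp$phase[202:301])))               # beyond last extremum
  ## monotone within half-cycles
  expect_true(all(diff(rp$phase[1:101]) > 0))
  expect_true(all(diff(rp$phase[102:200]) > 0))
  expect_error(interpolate_phase(300, peaks = c(10, 50), troughs = 100),
               "alternate")
})

test_that("event phases: peaks map to zero; uniform event times give uniform angles", {
  rp <- interpolate_phase(301, peaks = 101, troughs = c(1, 201))
  expect_equal(phase_at_events(rp, c(101, 51)), c(0, -pi / 2))
  expect_message(out <- phase_at_events(rp, c(101, 290)), "undefined")
  expect_true(is.na(out[2]))
  ## jitter-free sinusoidal breathing sampled at uniform times -> uniform phase
  resp <- gen_respiration(600, fs = 50, rate_bpm = 15, cycle_jitter = 0,
                          amp_jitter = 0, sigh_prob = 0, seed = 3)
  ph <- extract_resp_phase(resp)
  set.seed(8)
  ev <- round(runif(500, 50 * 5, 50 * 590))
  ang <- suppressMessages(phase_at_events(ph$phase, ev))
  expect_gt(rayleigh_test(ang[is.finite(ang)])$p, 0.05)
})

test_that("breathing rate arithmetic and round trip", {
  expect_equal(breathing_rate(c(1, 401, 801), fs = 100), 15)
  expect_equal(breathing_rate(c(0, 3, 5) * 100 + 1, fs = 100), 24)
  expect_error(breathing_rate(5, fs = 100), "at least 2")
  resp <- gen_respiration(400, fs = 60, rate_bpm = 12, cycle_jitter = 0,
                          amp_jitter = 0, sigh_prob = 0, seed = 1)
  ph <- extract_resp_phase(resp)
  expect_equal(ph$rate_bpm, 12, tolerance = 1e-3)
})

test_that("pupil preprocessing: diameter conversion, blink recovery, robust scaling", {
  expect_equal(area_to_diameter(pi), 2)
  pup <- gen_pupil(120, fs = 100, blink_rate = 12, seed = 2)
  truth <- attr(pup, "truth")
  out <- preprocess_pupil(pup)
  mask <- attr(out, "blink_mask")
  ## detector recovers at least 90% of inserted blinks
  hit <- vapply(truth$blink_times_s, function(bt) {
    any(mask[round(bt * 100):min(length(mask), round(bt * 100) + 20)])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  ## robust z-scaling by construction
  expect_equal(median(out$samples), 0, tolerance = 1e-9)
  expect_equal(mad(out$samples), 1, tolerance = 1e-6)
  ## blink-free smooth trace passes through up to filtering
  pup0 <- gen_pupil(120, fs = 100, blink_rate = 0, seed = 2)
  out0 <- preprocess_pupil(pup0)
  expect_equal(sum(attr(out0, "blink_mask")), 0)
})

test_that("zero-phase band-pass introduces no group delay", {
  fs <- 100
  t <- seq(0, 60, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)
  sig <- cont_signal(100 + 5 * x, fs = fs, units = "area")
  out <- preprocess_pupil(sig, pupil_config(remove_blink_response = FALSE))
  ## cross-correlation peak at lag zero for a band-limited input
  cc <- ccf(out$samples, x, lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
})

test_that("respiration-coupled pupil component clusters phase at pupil maxima", {
  resp <- gen_respiration(400, fs = 100, rate_bpm = 14, cycle_jitter = 0.05,
                          amp_jitter = 0.05, sigh_prob = 0, seed = 6)
  truth <- attr(resp, "truth")
  pup <- gen_pupil(400, fs = 100, blink_rate = 4, resp_coupling = 4,
                   resp_phase = truth$phase, coupling_phase = 0, seed = 6)
  out <- preprocess_pupil(pup)
  pk <- resphase:::find_prominent_peaks(out$samples, 0.5)
  ang <- truth$phase[pk]
  expect_lt(rayleigh_test(ang)$p, 0.01)
})
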