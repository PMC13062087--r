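## Synthetic session generators with known ground truth. Defaults emulate the
## study conditions: 6 runs x 120 trials (30 per 2x2 cue/timing condition),
## 1600 ms fixation, 50 ms Gabor target, 500 ms response delay, QUEST-driven
## contrast targeting a 0.60 hit rate, quasi-periodic ~15 breaths/min
## respiration with occasional sighs.

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

#' Experimental design specification
#'
#' @param n_runs number of runs.
#' @param per_condition_per_run trials per condition per run (must be even so
#'   left/right target sides can balance).
#' @param fixation_ms,target_ms,delay_ms trial event durations, ms.
#' @param iti_range_ms range of the residual inter-trial interval (response
#'   prompt to next fixation onset), ms.
#' @param seed RNG seed.
#' @return design spec list.
#' @export
design_spec <- function(n_runs = 6L, per_condition_per_run = 30L,
                        fixation_ms = 1600, target_ms = 50, delay_ms = 500,
                        iti_range_ms = c(1200, 2000), seed = 1L) {
  list(n_runs = as.integer(n_runs),
       per_condition_per_run = as.integer(per_condition_per_run),
       fixation_ms = fixation_ms, target_ms = target_ms, delay_ms = delay_ms,
       iti_range_ms = iti_range_ms, seed = as.integer(seed))
}

.conditions <- function() {
  data.frame(condition = c("C+T+", "C+T-", "C-T+", "C-T-"),
             cue_spatial = c(TRUE, TRUE, FALSE, FALSE),
             cue_temporal = c(TRUE, FALSE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

#' Generate a trial schedule
#'
#' Builds the 2x2 cue (spatial) x timing (temporal) design: each condition
#' appears \code{per_condition_per_run} times per run with left/right target
#' sides balanced within condition and run, trial order randomized within run,
#' and event times accumulated from the fixed fixation/target/delay durations
#' plus a uniform inter-trial interval.
#'
#' @param spec a \code{\link{design_spec}}.
#' @return data.frame with one row per trial: \code{run}, \code{trial}
#'   (within run), \code{condition}, \code{cue_spatial}, \code{cue_temporal},
#'   \code{side}, \code{fix_onset_s}, \code{target_onset_s}.
#' @export
gen_design <- function(spec = design_spec()) {
  if (spec$n_runs < 1L || spec$per_condition_per_run < 1L) {
    stop("gen_design: counts must be positive")
  }
  if (spec$per_condition_per_run %% 2L != 0L) {
    stop("gen_design: per_condition_per_run must be even to balance target sides")
  }
  conds <- .conditions()
  out <- vector("list", spec$n_runs)
  set.seed(derive_seed(spec$seed, 11L))
  t_cursor <- 0
  for (r in seq_len(spec$n_runs)) {
    run_rows <- do.call(rbind, lapply(seq_len(nrow(conds)), function(ci) {
      data.frame(condition = conds$condition[ci],
                 cue_spatial = conds$cue_spatial[ci],
                 cue_temporal = conds$cue_temporal[ci],
                 side = rep(c("left", "right"), each = spec$per_condition_per_run / 2L),
                 stringsAsFactors = FALSE)
    }))
    run_rows <- run_rows[sample.int(nrow(run_rows)), , drop = FALSE]
    n_tr <- nrow(run_rows)
    iti <- stats::runif(n_tr, spec$iti_range_ms[1], spec$iti_range_ms[2]) / 1000
    trial_len <- (spec$fixation_ms + spec$target_ms + spec$delay_ms) / 1000 + iti
    fix_onset <- t_cursor + cumsum(c(0, trial_len[-n_tr]))
    run_rows$run <- r
    run_rows$trial <- seq_len(n_tr)
    run_rows$fix_onset_s <- fix_onset
    run_rows$target_onset_s <- fix_onset + spec$fixation_ms / 1000
    t_cursor <- fix_onset[n_tr] + trial_len[n_tr] + 5  # short inter-run gap
    out[[r]] <- run_rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("run", "trial", "condition", "cue_spatial", "cue_temporal", "side",
          "fix_onset_s", "target_onset_s")]
}

#' Generate a quasi-periodic respiration trace
#'
#' Cycle-by-cycle cosine model: each cycle runs trough-to-trough with a
#' log-normally jittered period, log-normally jittered amplitude, and a
#' per-cycle sigh probability that scales the amplitude by
#' \code{sigh_gain_range}. Phase within a cycle is linear in time, so the true
#' phase trace (returned as ground truth) follows the same convention as
#' \code{\link{interpolate_phase}} (trough \eqn{-\pi}, peak 0).
#'
#' @param duration_s trace duration in seconds.
#' @param fs sampling rate in Hz (must exceed twice the breathing frequency).
#' @param rate_bpm mean breathing rate, breaths/min (> 0).
#' @param cycle_jitter SD of the log-period jitter (0 = strictly periodic).
#' @param amp_jitter SD of the log-amplitude jitter.
#' @param sigh_prob per-cycle probability of a sigh.
#' @param sigh_gain_range multiplicative amplitude range of a sigh.
#' @param seed RNG seed.
#' @return respiration \code{cont_signal}; attribute \code{truth} is a list
#'   with \code{phase} (true phase per sample), \code{trough_times_s},
#'   \code{peak_times_s}, \code{sigh_cycles}, \code{rate_bpm}.
#' @export
gen_respiration <- function(duration_s, fs = 300, rate_bpm = 15,
                            cycle_jitter = 0.1, amp_jitter = 0.1,
                            sigh_prob = 0.02, sigh_gain_range = c(2.5, 3),
                            seed = 1L) {
  if (rate_bpm <= 0) stop("gen_respiration: rate must be positive")
  mean_period <- 60 / rate_bpm
  if (fs <= 2 / mean_period) stop("gen_respiration: fs must exceed twice the breathing frequency")
  if (duration_s <= mean_period) stop("gen_respiration: duration must exceed one cycle")
  set.seed(derive_seed(seed, 23L))
  n_cycles <- ceiling(duration_s / mean_period * 1.5) + 5L
  periods <- mean_period * exp(stats::rnorm(n_cycles, 0, cycle_jitter))
  amps <- exp(stats::rnorm(n_cycles, 0, amp_jitter))
  sighs <- stats::runif(n_cycles) < sigh_prob
  amps[sighs] <- amps[sighs] * stats::runif(sum(sighs), sigh_gain_range[1], sigh_gain_range[2])
  starts <- cumsum(c(0, periods))  # trough times
  t <- (seq_len(round(duration_s * fs)) - 1L) / fs
  cyc <- findInterval(t, starts)
  frac <- (t - starts[cyc]) / periods[cyc]
  x <- -amps[cyc] * cos(2 * pi * frac)
  phase <- wrap_angle(-pi + 2 * pi * frac)
  used <- seq_len(max(cyc))
  out <- cont_signal(x, fs, units = "a.u.")
  attr(out, "truth") <- list(
    phase = phase,
    trough_times_s = starts[used],
    peak_times_s = starts[used] + periods[used] / 2,
    sigh_cycles = which(sighs[used]),
    rate_bpm = rate_bpm,
    periods_s = periods[used]
  )
  out
}

#' Observer model for the detection task
#'
#' Cumulative-Gaussian observer whose detection threshold is sinusoidally
#' modulated by respiratory phase:
#' \deqn{m(\theta) = m_0 + A \cos(\theta - \phi_0)}
#' \deqn{\Psi(c;\theta) = \gamma + (1 - \gamma - \lambda)\,\Phi((c - m(\theta))/\sigma)}
#' Threshold is highest at \eqn{\phi_0}, so perceptual sensitivity peaks at
#' \eqn{\phi_0 - \pi}. Contrast is dimensionless in [0, 1].
#'
#' @param guess_rate guess rate \eqn{\gamma} (3AFC default 1/3).
#' @param lapse_rate lapse rate \eqn{\lambda} in [0, 0.5).
#' @param base_threshold baseline threshold \eqn{m_0} (contrast units).
#' @param slope psychometric width \eqn{\sigma} (> 0).
#' @param mod_amplitude modulation amplitude \eqn{A} (contrast units).
#' @param mod_phase modulation phase \eqn{\phi_0} in radians (threshold
#'   maximum; sensitivity is best half a cycle away).
#' @return observer model list.
#' @export
observer_model <- function(guess_rate = 1 / 3, lapse_rate = 0.02,
                           base_threshold = 0.5, slope = 0.15,
                           mod_amplitude = 0, mod_phase = 2 * pi / 3) {
  stopifnot(guess_rate >= 0, guess_rate < 1, lapse_rate >= 0, lapse_rate < 0.5,
            slope > 0)
  if (base_threshold - abs(mod_amplitude) <= 0) {
    stop("observer_model: effective threshold must stay positive for all phases")
  }
  list(guess_rate = guess_rate, lapse_rate = lapse_rate,
       base_threshold = base_threshold, slope = slope,
       mod_amplitude = mod_amplitude, mod_phase = mod_phase)
}

#' Observer hit probability
#'
#' @param observer an \code{\link{observer_model}}.
#' @param contrast stimulus contrast(s).
#' @param phase respiratory phase(s) at target onset.
#' @return probability of a hit.
#' @export
observer_p_hit <- function(observer, contrast, phase = 0) {
  m <- observer$base_threshold +
    observer$mod_amplitude * cos(phase - observer$mod_phase)
  observer$guess_rate + (1 - observer$guess_rate - observer$lapse_rate) *
    stats::pnorm((contrast - m) / observer$slope)
}

#' Simulate a QUEST-controlled detection session
#'
#' Runs the adaptive staircase trial by trial: contrast is proposed from the
#' QUEST posterior, the observer's response is drawn Bernoulli from its
#' psychometric function at the trial's respiratory phase, and the posterior
#' is updated with the outcome.
#'
#' @param schedule trial schedule from \code{\link{gen_design}}.
#' @param phase_at_onset respiratory phase at each trial's target onset
#'   (radians, same length as the schedule).
#' @param observer an \code{\link{observer_model}}.
#' @param quest_cfg a \code{\link{quest_config}}.
#' @param seed RNG seed.
#' @return the schedule with added columns \code{phase_rad}, \code{contrast},
#'   \code{hit}; attribute \code{truth} holds the observer and staircase
#'   parameters, attribute \code{quest_flags} any divergence warnings.
#' @export
simulate_session <- function(schedule, phase_at_onset, observer = observer_model(),
                             quest_cfg = quest_config(), seed = 1L) {
  n <- nrow(schedule)
  if (length(phase_at_onset) != n) stop("simulate_session: one phase per trial required")
  if (any(!is.finite(phase_at_onset))) stop("simulate_session: phase must be defined at every target onset")
  set.seed(derive_seed(seed, 37L))
  state <- quest_create(quest_cfg)
  contrast <- numeric(n)
  hit <- logical(n)
  for (i in seq_len(n)) {
    contrast[i] <- quest_propose(state)
    p <- observer_p_hit(observer, contrast[i], phase_at_onset[i])
    hit[i] <- stats::runif(1) < p
    state <- quest_update(state, contrast[i], hit[i])
  }
  out <- schedule
  out$phase_rad <- phase_at_onset
  out$contrast <- contrast
  out$hit <- hit
  attr(out, "truth") <- list(observer = observer, quest = quest_cfg)
  attr(out, "quest_flags") <- attr(state, "flags")
  out
}

#' ROI coupling specification
#'
#' Ground-truth directed coupling between two ROI blocks: a latent VAR(2)
#' resonator pair in which the lag-1 cross-coefficient from the source to the
#' target latent is scaled per trial by a nonnegative, \eqn{2\pi}-periodic
#' gain of the respiratory phase \code{1 + depth * cos(theta - phase)}.
#'
#' @param from,to ROI labels.
#' @param f0_hz resonance (coupled band centre), Hz.
#' @param strength baseline cross-coefficient.
#' @param gain_depth modulation depth of the coupling gain in [0, 1].
#' @param gain_phase phase of maximal coupling, radians.
#' @param pole_radius AR(2) pole radius (bandwidth of the resonance).
#' @return coupling spec list.
#' @export
coupling_spec <- function(from = "A", to = "B", f0_hz = 10, strength = 0.5,
                          gain_depth = 1, gain_phase = pi / 2,
                          pole_radius = 0.95) {
  stopifnot(gain_depth >= 0, gain_depth <= 1, strength >= 0)
  list(from = from, to = to, f0_hz = f0_hz, strength = strength,
       gain_depth = gain_depth, gain_phase = gain_phase,
       pole_radius = pole_radius, var_order = 2L)
}

coupling_gain <- function(spec, theta) {
  1 + spec$gain_depth * cos(theta - spec$gain_phase)
}

ar2_coefs <- function(f0_hz, fs, r) {
  c(2 * r * cos(2 * pi * f0_hz / fs), -r^2)
}

## 1/f (power ~ 1/f^alpha) noise via spectral shaping, one column per series
onef_noise <- function(n, n_series, fs, alpha = 1) {
  w <- matrix(stats::rnorm(n * n_series), n, n_series)
  W <- stats::mvfft(w)
  f <- c(1, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f + fs / n)  # mirror for the negative-frequency half
  g <- 1 / f^(alpha / 2)
  g[1] <- 0
  X <- W * g
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n
  scale(x, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Generate ROI epoch time series with known phase modulation and coupling
#'
#' Produces epoched multichannel time series for two ROIs (three channels
#' each). Each channel is a weighted copy of a latent band-limited AR(2)
#' oscillation plus 1/f background and white channel noise. Per trial the
#' oscillation of ROI \code{r} is scaled by
#' \eqn{\sqrt{P_0 (1 + d \cos(\theta - \phi_P))}} using the respiratory phase
#' at target onset, and the latent target resonator receives
#' \code{strength * gain(theta)} times the lagged source latent (directed
#' coupling).
#'
#' @param phase_at_onset respiratory phase at target onset, one per trial.
#' @param power_mod list per ROI with \code{depth} (in [0, 1)), \code{phase},
#'   \code{p0}; names "A" and "B".
#' @param coupling a \code{\link{coupling_spec}} or \code{NULL} for
#'   independent ROIs.
#' @param fs sampling rate, Hz.
#' @param window epoch window in seconds around target onset.
#' @param bg_scale standard deviation of the 1/f background relative to the
#'   unit-variance oscillation.
#' @param channel_noise white channel-noise SD.
#' @param osc_f0_hz oscillation centre frequency when uncoupled.
#' @param seed RNG seed.
#' @return object of class \code{roi_epochs} (see \code{\link{roi_epochs}})
#'   with channels A1..A3, B1..B3; attribute \code{truth} carries all
#'   generator parameters.
#' @export
gen_roi_timeseries <- function(phase_at_onset,
                               power_mod = list(
                                 A = list(depth = 0.2, phase = pi / 2, p0 = 1),
                                 B = list(depth = 0.2, phase = pi / 2, p0 = 1)),
                               coupling = coupling_spec(),
                               fs = 300, window = c(-1.85, 0.75),
                               bg_scale = 0.25, channel_noise = 0.3,
                               osc_f0_hz = 10, seed = 1L) {
  for (pm in power_mod) {
    if (pm$depth >= 1) stop("gen_roi_timeseries: modulation depth must be < 1 (power must stay positive)")
  }
  set.seed(derive_seed(seed, 53L))
  n_trials <- length(phase_at_onset)
  n_t <- round((window[2] - window[1]) * fs)
  burn <- 150L
  total <- n_t + burn
  f0 <- if (!is.null(coupling)) coupling$f0_hz else osc_f0_hz
  r <- if (!is.null(coupling)) coupling$pole_radius else 0.95
  a <- ar2_coefs(f0, fs, r)
  cgain <- if (!is.null(coupling)) {
    coupling$strength * coupling_gain(coupling, phase_at_onset)
  } else rep(0, n_trials)

  ## latent VAR(2): x (source), y (target); vectorized across trials
  ex <- matrix(stats::rnorm(total * n_trials), total, n_trials)
  ey <- matrix(stats::rnorm(total * n_trials), total, n_trials)
  x <- matrix(0, total, n_trials)
  y <- matrix(0, total, n_trials)
  for (t in 3:total) {
    x[t, ] <- a[1] * x[t - 1, ] + a[2] * x[t - 2, ] + ex[t, ]
    y[t, ] <- a[1] * y[t - 1, ] + a[2] * y[t - 2, ] + cgain * x[t - 1, ] + ey[t, ]
  }
  x <- x[(burn + 1):total, , drop = FALSE]
  y <- y[(burn + 1):total, , drop = FALSE]
  ## normalize each latent separately (block-diagonal scaling; GC-invariant)
  x <- x / stats::sd(as.vector(x))
  y <- y / stats::sd(as.vector(y))

  mix <- c(1, 0.8, 0.6)
  env <- function(pm) sqrt(pm$p0 * (1 + pm$depth * cos(phase_at_onset - pm$phase)))
  envA <- env(power_mod$A); envB <- env(power_mod$B)
  dat <- array(0, dim = c(n_trials, 6L, n_t))
  lat <- list(x, y); envs <- list(envA, envB)
  for (roi in 1:2) {
    for (ch in 1:3) {
      sig <- t(lat[[roi]]) * envs[[roi]] * mix[ch]   # trials x time
      noise <- matrix(stats::rnorm(n_trials * n_t, sd = channel_noise), n_trials, n_t)
      bgm <- t(onef_noise(n_t, n_trials, fs)) * bg_scale
      dat[, (roi - 1L) * 3L + ch, ] <- sig + noise + bgm
    }
  }
  ep <- roi_epochs(dat, fs = fs,
                   time = window[1] + (seq_len(n_t) - 1L) / fs,
                   roi = c("A1", "A2", "A3", "B1", "B2", "B3"))
  attr(ep, "truth") <- list(power_mod = power_mod, coupling = coupling,
                            osc_f0_hz = f0, ar_coefs = a, fs = fs,
                            phase_at_onset = phase_at_onset)
  ep
}

#' Generate a pupil area trace with blinks
#'
#' Smooth slow fluctuations (low-pass filtered noise) around a baseline area,
#' optional respiration-phase-coupled component, and inserted blink artifacts
#' (transient dropouts to near zero).
#'
#' @param duration_s duration in seconds.
#' @param fs sampling rate, Hz (>= 60).
#' @param blink_rate blinks per minute.
#' @param resp_coupling amplitude of the phase-coupled component (area units);
#'   requires \code{resp_phase}.
#' @param resp_phase true respiratory phase per sample (radians), or NULL.
#' @param coupling_phase phase of maximal pupil area.
#' @param baseline_area baseline area, arbitrary units.
#' @param seed RNG seed.
#' @return area \code{cont_signal}; attribute \code{truth} holds
#'   \code{blink_times_s} and the coupling parameters.
#' @export
gen_pupil <- function(duration_s, fs = 120, blink_rate = 10,
                      resp_coupling = 0, resp_phase = NULL,
                      coupling_phase = 0, baseline_area = 100, seed = 1L) {
  if (fs < 60) stop("gen_pupil: fs must be at least 60 Hz")
  set.seed(derive_seed(seed, 71L))
  n <- round(duration_s * fs)
  slow <- stats::rnorm(n)
  lp <- signal::butter(2, min(0.5 / (fs / 2), 0.99), type = "low")
  slow <- signal::filtfilt(lp, slow)
  slow <- slow / max(stats::sd(slow), 1e-12)
  area <- baseline_area * (1 + 0.05 * slow)
  if (resp_coupling > 0) {
    if (is.null(resp_phase)) stop("gen_pupil: resp_phase required when resp_coupling > 0")
    ph <- resp_phase[seq_len(min(n, length(resp_phase)))]
    if (length(ph) < n) ph <- c(ph, rep(ph[length(ph)], n - length(ph)))
    area <- area + resp_coupling * cos(ph - coupling_phase)
  }
  n_blinks <- stats::rpois(1, blink_rate * duration_s / 60)
  blink_times <- sort(stats::runif(n_blinks, 1, duration_s - 1))
  for (bt in blink_times) {
    dur <- stats::runif(1, 0.1, 0.25)
    i0 <- round(bt * fs); i1 <- min(n, i0 + round(dur * fs))
    area[i0:i1] <- area[i0:i1] * 0.01
  }
  out <- cont_signal(area, fs, units = "area")
  attr(out, "truth") <- list(blink_times_s = blink_times,
                             resp_coupling = resp_coupling,
                             coupling_phase = coupling_phase)
  out
}
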