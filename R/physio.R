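#' Continuous physiological signal
#'
#' Lightweight container for a uniformly sampled trace.
#'
#' @param samples numeric vector.
#' @param fs sampling rate in Hz (> 0).
#' @param units unit label.
#' @param t0 time of the first sample in seconds.
#' @return object of class \code{cont_signal}.
#' @export
cont_signal <- function(samples, fs, units = "a.u.", t0 = 0) {
  stopifnot(is.numeric(samples), length(fs) == 1L, fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, units = units, t0 = t0),
            class = "cont_signal")
}

#' @export
print.cont_signal <- function(x, ...) {
  cat(sprintf("<cont_signal> %d samples @ %g Hz [%s], t0 = %g s (%.1f s)\n",
              length(x$samples), x$fs, x$units, x$t0,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.cont_signal <- function(x) length(x$samples)

signal_times <- function(x) x$t0 + (seq_along(x$samples) - 1L) / x$fs

#' Z-score a respiration trace and clip high-amplitude excursions
#'
#' Standardizes the trace and linearly interpolates contiguous runs whose
#' absolute z-value exceeds \code{clip_z} (default 2.5), anchoring on the
#' nearest retained samples. This removes unusually high-amplitude breaths
#' (sighs) that would otherwise bias prominence-based peak detection. The
#' z-score/clip pair is iterated to a fixed point within the call, which makes
#' the operation exactly idempotent; runs touching the recording edges are held
#' at the nearest retained value.
#'
#' @param x a \code{cont_signal} (or numeric vector).
#' @param clip_z clipping threshold in z units.
#' @param max_pass safety cap on fixed-point iterations.
#' @return clipped, standardized \code{cont_signal}; attribute
#'   \code{n_clipped} holds the number of samples interpolated in the first
#'   pass.
#' @export
normalize_and_clip <- function(x, clip_z = 2.5, max_pass = 25L) {
  v <- if (inherits(x, "cont_signal")) x$samples else as.numeric(x)
  if (length(v) < 3L) stop("normalize_and_clip: need at least 3 samples")
  n_clipped_first <- NA_integer_
  for (pass in seq_len(max_pass)) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("normalize_and_clip: degenerate (constant) trace")
    v <- (v - mean(v)) / s
    bad <- abs(v) > clip_z
    if (pass == 1L) n_clipped_first <- sum(bad)
    if (!any(bad)) break
    if (all(bad)) stop("normalize_and_clip: entire trace exceeds clip threshold")
    keep <- which(!bad)
    v[bad] <- stats::approx(keep, v[keep], xout = which(bad), rule = 2)$y
  }
  out <- if (inherits(x, "cont_signal")) {
    cont_signal(v, x$fs, units = "z", t0 = x$t0)
  } else {
    cont_signal(v, fs = 1, units = "z")
  }
  attr(out, "n_clipped") <- n_clipped_first
  out
}

## local maxima with topographic prominence >= min_prominence
find_prominent_peaks <- function(v, min_prominence) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  core <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
  if (!length(core)) return(integer(0))
  keep <- logical(length(core))
  for (ii in seq_along(core)) {
    i <- core[ii]
    h <- v[i]
    ## walk left until a higher sample; track the minimum en route
    lmin <- h
    j <- i - 1L
    while (j >= 1L && v[j] <= h) { if (v[j] < lmin) lmin <- v[j]; j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && v[j] <= h) { if (v[j] < rmin) rmin <- v[j]; j <- j + 1L }
    prom <- h - max(lmin, rmin)
    keep[ii] <- prom >= min_prominence
  }
  core[keep]
}

#' Detect respiratory peaks and troughs
#'
#' Finds inspiration peaks on the (normalized) trace and expiration troughs on
#' its negation, both with a minimal topographic prominence criterion, then
#' enforces strict alternation by keeping the most extreme sample within runs
#' of same-type extrema.
#'
#' @param x a \code{cont_signal} (normalized respiration) or numeric vector.
#' @param min_prominence minimal peak prominence in z units.
#' @return list with integer sample indices \code{peaks} and \code{troughs}.
#' @export
detect_extrema <- function(x, min_prominence = 1) {
  v <- if (inherits(x, "cont_signal")) x$samples else as.numeric(x)
  peaks <- find_prominent_peaks(v, min_prominence)
  troughs <- find_prominent_peaks(-v, min_prominence)
  if (!length(peaks) && !length(troughs)) {
    stop("detect_extrema: no extrema found at this prominence")
  }
  idx <- c(peaks, troughs)
  type <- rep(c(1L, -1L), c(length(peaks), length(troughs)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  ## collapse consecutive same-type runs
  keep_idx <- integer(0); keep_type <- integer(0)
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j < length(idx) && type[j + 1L] == type[i]) j <- j + 1L
    run <- idx[i:j]
    best <- if (type[i] == 1L) run[which.max(v[run])] else run[which.min(v[run])]
    keep_idx <- c(keep_idx, best)
    keep_type <- c(keep_type, type[i])
    i <- j + 1L
  }
  list(peaks = keep_idx[keep_type == 1L], troughs = keep_idx[keep_type == -1L])
}

#' Interpolate respiratory phase between extrema
#'
#' Builds the conventional respiratory phase vector: linear ramps from trough
#' to peak (\eqn{-\pi \to 0}, inspiration) and peak to trough
#' (\eqn{0 \to \pi}, expiration), so cycles are centred on peak inspiration
#' (phase 0). Trough samples carry \eqn{-\pi} (start of inspiration); samples
#' before the first and after the last extremum are \code{NA}.
#'
#' @param n signal length in samples.
#' @param peaks,troughs integer sample indices from \code{detect_extrema}.
#' @return object of class \code{resp_phase}: list with \code{phase} (length
#'   \code{n}, radians in \code{[-pi, pi)}), \code{peaks}, \code{troughs}.
#' @export
interpolate_phase <- function(n, peaks, troughs) {
  idx <- c(peaks, troughs)
  type <- rep(c(1L, -1L), c(length(peaks), length(troughs)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  if (length(idx) < 2L) stop("interpolate_phase: need at least one trough-peak pair")
  if (any(diff(type) == 0L)) stop("interpolate_phase: extrema do not alternate")
  if (any(idx < 1L | idx > n)) stop("interpolate_phase: extrema outside signal")
  phase <- rep(NA_real_, n)
  for (k in seq_len(length(idx) - 1L)) {
    a <- idx[k]; b <- idx[k + 1L]
    ramp <- seq(0, 1, length.out = b - a + 1L)
    if (type[k] == -1L) {         # trough -> peak: -pi .. 0
      phase[a:b] <- -pi + ramp * pi
    } else {                      # peak -> trough: 0 .. +pi
      phase[a:b] <- ramp * pi
    }
  }
  phase[idx[type == -1L]] <- -pi
  phase[idx[type == 1L]] <- 0
  structure(list(phase = phase, peaks = idx[type == 1L], troughs = idx[type == -1L]),
            class = "resp_phase")
}

#' Respiratory phase at event samples
#'
#' @param rp a \code{resp_phase}.
#' @param event_samples integer sample indices of events (e.g. target onsets).
#' @return numeric vector of phase angles; events in the undefined region
#'   (before the first / after the last extremum) are \code{NA} with a
#'   message reporting how many were excluded.
#' @export
phase_at_events <- function(rp, event_samples) {
  stopifnot(inherits(rp, "resp_phase"))
  ev <- as.integer(round(event_samples))
  out <- rep(NA_real_, length(ev))
  inside <- ev >= 1L & ev <= length(rp$phase)
  out[inside] <- rp$phase[ev[inside]]
  n_missing <- sum(!is.finite(out))
  if (n_missing > 0L) {
    message(sprintf("phase_at_events: %d of %d events fall in undefined phase region",
                    n_missing, length(ev)))
  }
  out
}

#' Breathing rate from inspiratory peaks
#'
#' @param peaks integer sample indices of inspiratory peaks.
#' @param fs sampling rate in Hz.
#' @return breathing rate in breaths/min (60 / mean inter-peak interval).
#' @export
breathing_rate <- function(peaks, fs) {
  if (length(peaks) < 2L) stop("breathing_rate: need at least 2 peaks")
  60 / mean(diff(sort(peaks)) / fs)
}

#' Full respiration preprocessing
#'
#' Convenience wrapper: normalize/clip, detect extrema, interpolate phase.
#'
#' @param x respiration \code{cont_signal}.
#' @param clip_z clipping threshold (z units).
#' @param min_prominence peak prominence (z units).
#' @return list with \code{signal} (clipped), \code{phase} (a
#'   \code{resp_phase}) and \code{rate_bpm}.
#' @export
extract_resp_phase <- function(x, clip_z = 2.5, min_prominence = 1) {
  clipped <- normalize_and_clip(x, clip_z = clip_z)
  ext <- detect_extrema(clipped, min_prominence = min_prominence)
  rp <- interpolate_phase(length(clipped$samples), ext$peaks, ext$troughs)
  list(signal = clipped, phase = rp,
       rate_bpm = breathing_rate(ext$peaks, clipped$fs))
}

#' Robust z-score
#'
#' \code{(x - median) / (1.4826 * MAD)}.
#' @param x numeric vector.
#' @return standardized vector.
#' @export
robust_z <- function(x) {
  sc <- stats::mad(x)
  if (sc == 0) sc <- stats::sd(x)
  if (!is.finite(sc) || sc == 0) return(x - stats::median(x))
  (x - stats::median(x)) / sc
}

#' Pupil area to diameter
#'
#' Linearizing conversion \code{2 * sqrt(area / pi)} (diameter of the disc
#' with the given area).
#' @param area numeric, pupil area.
#' @return pupil diameter in the square root of the area units.
#' @export
area_to_diameter <- function(area) 2 * sqrt(pmax(area, 0) / pi)

#' Pupil preprocessing configuration
#'
#' @param floor_frac samples with area below this fraction of the median are
#'   treated as dropouts.
#' @param vel_z robust-z threshold on the diameter velocity for blink onsets.
#' @param pad_s padding around detected blink samples, seconds.
#' @param second_pass_z z threshold for the relaxed second artifact pass.
#' @param band band-pass edges in Hz.
#' @param filter_order Butterworth order per section.
#' @param remove_blink_response estimate and regress out a canonical
#'   double-gamma pupil response to blink onsets.
#' @return config list.
#' @export
pupil_config <- function(floor_frac = 0.1, vel_z = 5, pad_s = 0.1,
                         second_pass_z = 6, band = c(0.01, 10),
                         filter_order = 2L, remove_blink_response = TRUE) {
  list(floor_frac = floor_frac, vel_z = vel_z, pad_s = pad_s,
       second_pass_z = second_pass_z, band = band,
       filter_order = filter_order,
       remove_blink_response = remove_blink_response)
}

## detect blink samples on an area trace; returns logical mask
detect_blinks <- function(area, fs, cfg) {
  floor_level <- cfg$floor_frac * stats::median(area)
  low <- area < floor_level
  vel <- c(0, diff(area))
  mad_v <- stats::mad(vel)
  fast <- if (mad_v > 0) abs(vel - stats::median(vel)) / mad_v > cfg$vel_z else rep(FALSE, length(vel))
  bad <- low | fast
  pad <- max(1L, round(cfg$pad_s * fs))
  if (any(bad)) {
    idx <- which(bad)
    hits <- unique(unlist(lapply(idx, function(i) max(1L, i - pad):min(length(area), i + pad))))
    bad <- logical(length(area))
    bad[hits] <- TRUE
  }
  bad
}

interp_mask <- function(v, bad) {
  if (!any(bad)) return(v)
  keep <- which(!bad)
  v[bad] <- stats::approx(keep, v[keep], xout = which(bad), rule = 2)$y
  v
}

## canonical pupil response to a blink: double-gamma style kernel
## h(t) = t^s exp(-t/tau), unit peak; amplitude and tau fit by least squares
blink_kernel <- function(fs, tau, shape = 10, dur_s = 4) {
  t <- seq(0, dur_s, by = 1 / fs)
  h <- (t / (shape * tau))^shape * exp(shape - t / tau)
  h
}

remove_blink_response <- function(v, onsets, fs) {
  if (!length(onsets)) return(v)
  imp <- numeric(length(v))
  imp[onsets] <- 1
  taus <- c(0.05, 0.1, 0.2, 0.4)
  best <- v
  best_rss <- sum((v - mean(v))^2)
  for (tau in taus) {
    h <- blink_kernel(fs, tau)
    reg <- stats::convolve(imp, rev(h), type = "open")[seq_along(v)]
    X <- cbind(1, reg)
    fit <- stats::lm.fit(X, v)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- fit$residuals + mean(v)
    }
  }
  best
}

#' Preprocess a pupil area trace
#'
#' Converts area to diameter (\code{2 * sqrt(area / pi)}), detects and
#' linearly interpolates blinks (dropout floor plus velocity criterion, padded
#' in time), applies a relaxed second artifact pass at \code{z = 6},
#' optionally regresses out a canonical blink response, band-pass filters
#' (0.01-10 Hz, second-order Butterworth, zero-phase forward-reverse), and
#' returns a robust z-scored trace.
#'
#' @param x pupil area \code{cont_signal} (fs > 20 Hz).
#' @param cfg a \code{\link{pupil_config}}.
#' @return diameter \code{cont_signal} in robust z units; attribute
#'   \code{blink_mask} carries the detected-blink logical vector.
#' @export
preprocess_pupil <- function(x, cfg = pupil_config()) {
  stopifnot(inherits(x, "cont_signal"))
  if (x$fs <= 20) stop("preprocess_pupil: sampling rate must exceed 20 Hz")
  area <- pmax(x$samples, 0)
  d <- area_to_diameter(area)
  bad <- detect_blinks(area, x$fs, cfg)
  if (mean(bad) > 0.5) stop("preprocess_pupil: more than 50% of samples flagged as blink")
  d <- interp_mask(d, bad)
  ## relaxed second pass
  s <- stats::sd(d)
  if (s > 0) {
    z <- (d - mean(d)) / s
    d <- interp_mask(d, abs(z) > cfg$second_pass_z)
  }
  if (isTRUE(cfg$remove_blink_response)) {
    onsets <- which(diff(c(FALSE, bad)) == 1L)
    d <- remove_blink_response(d, onsets, x$fs)
  }
  ## zero-phase band-pass as high-pass + low-pass Butterworth cascade
  ny <- x$fs / 2
  if (cfg$band[1] > 0) {
    hp <- signal::butter(cfg$filter_order, cfg$band[1] / ny, type = "high")
    d <- signal::filtfilt(hp, d)
  }
  if (cfg$band[2] < ny) {
    lp <- signal::butter(cfg$filter_order, cfg$band[2] / ny, type = "low")
    d <- signal::filtfilt(lp, d)
  }
  out <- cont_signal(robust_z(d), x$fs, units = "z", t0 = x$t0)
  attr(out, "blink_mask") <- bad
  out
}
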