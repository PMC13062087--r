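## Multitaper spectral estimation on epoched ROI time series, derivative
## whitening, head-motion GLM cleanup, and respiration phase-binned power.

#' Epoched ROI time series
#'
#' @param data numeric array trial x roi x time.
#' @param fs sampling rate, Hz.
#' @param time time axis in seconds relative to target onset.
#' @param roi channel/ROI labels.
#' @return object of class \code{roi_epochs}.
#' @export
roi_epochs <- function(data, fs, time, roi) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(time),
            dim(data)[2] == length(roi))
  if (any(!is.finite(data))) stop("roi_epochs: non-finite samples")
  structure(list(data = data, fs = fs, time = time, roi = roi),
            class = "roi_epochs")
}

#' @export
print.roi_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<roi_epochs> %d trials x %d channels x %d samples @ %g Hz, t = [%.2f, %.2f] s\n",
              d[1], d[2], d[3], x$fs, min(x$time), max(x$time)))
  invisible(x)
}

#' Segment continuous ROI signals into epochs
#'
#' Optionally resamples (polyphase anti-aliased, \code{signal::resample}) to
#' \code{fs_out} and cuts a fixed window around each target onset. Onsets too
#' close to the recording edges are dropped with a message.
#'
#' @param x numeric matrix samples x channels (continuous recording).
#' @param fs_in input sampling rate, Hz.
#' @param onsets_s target onset times, seconds from the first sample.
#' @param window epoch window in seconds around onset.
#' @param fs_out output sampling rate.
#' @param roi channel labels.
#' @return a \code{roi_epochs}; attribute \code{dropped} holds indices of
#'   dropped trials.
#' @export
segment_epochs <- function(x, fs_in, onsets_s, window = c(-1.85, 0.75),
                           fs_out = 300, roi = colnames(x)) {
  x <- as.matrix(x)
  if (is.null(roi)) roi <- paste0("ch", seq_len(ncol(x)))
  if (fs_in != fs_out) {
    x <- apply(x, 2, .resample_fft, fs_in = fs_in, fs_out = fs_out)
    x <- as.matrix(x)
  }
  n <- nrow(x)
  n_t <- round((window[2] - window[1]) * fs_out)
  i0 <- round(onsets_s * fs_out + window[1] * fs_out) + 1L
  ok <- i0 >= 1L & (i0 + n_t - 1L) <= n
  if (any(!ok)) {
    message(sprintf("segment_epochs: %d trial(s) dropped (too close to recording edge)",
                    sum(!ok)))
  }
  keep <- which(ok)
  dat <- array(0, dim = c(length(keep), ncol(x), n_t))
  for (j in seq_along(keep)) {
    dat[j, , ] <- t(x[i0[keep[j]]:(i0[keep[j]] + n_t - 1L), , drop = FALSE])
  }
  ep <- roi_epochs(dat, fs = fs_out,
                   time = window[1] + (seq_len(n_t) - 1L) / fs_out, roi = roi)
  attr(ep, "dropped") <- which(!ok)
  ep
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

## Fourier-domain resampling (ideal anti-alias filter); exact for
## band-limited content away from the recording edges
.resample_fft <- function(col, fs_in, fs_out) {
  n <- length(col)
  n_out <- round(n * fs_out / fs_in)
  X <- stats::fft(col)
  Y <- complex(n_out)
  keep <- min(n, n_out) %/% 2L
  Y[1] <- X[1]
  Y[2:(keep + 1L)] <- X[2:(keep + 1L)]
  Y[n_out - seq_len(keep - 1L) + 1L] <- X[n - seq_len(keep - 1L) + 1L]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Discard staircase-initiation trials
#'
#' Removes the first \code{n} trials of each run (ordering within runs is
#' preserved).
#'
#' @param trials trial table with a \code{run} column.
#' @param n trials to discard per run.
#' @return reduced trial table.
#' @export
discard_initial_trials <- function(trials, n = 10L) {
  stopifnot("run" %in% names(trials))
  if (n == 0L) return(trials)
  keep <- unlist(lapply(split(seq_len(nrow(trials)), trials$run), function(ix) {
    if (length(ix) <= n) {
      warning("discard_initial_trials: a run has no trials left", call. = FALSE)
      return(integer(0))
    }
    ix[-seq_len(n)]
  }), use.names = FALSE)
  trials[sort(keep), , drop = FALSE]
}

#' Head-motion GLM cleanup
#'
#' Regresses out head-movement-related signal components: the 6 rigid-body
#' motion signals and their first derivatives, each expanded to polynomial
#' orders 1-3 (36 regressors), plus a third-order polynomial drift term. A
#' ridge fallback is used if the design is rank deficient.
#'
#' @param x numeric vector or matrix (time x parcels).
#' @param motion matrix time x 6 of motion signals aligned with \code{x}.
#' @param poly_order drift polynomial order.
#' @return residual time series, same shape as \code{x}, with the mean
#'   retained.
#' @export
motion_glm_clean <- function(x, motion, poly_order = 3L) {
  vec_in <- is.null(dim(x))
  xm <- as.matrix(x)
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == nrow(xm), ncol(motion) == 6L)
  d <- rbind(0, diff(motion))
  Z <- cbind(motion, d)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  reg <- do.call(cbind, lapply(1:3, function(k) Z^k))   # 36 regressors
  drift <- stats::poly(seq_len(nrow(xm)), poly_order)
  X <- cbind(1, drift, reg)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("motion_glm_clean: rank-deficient design; using ridge fallback",
            call. = FALSE)
    lambda <- 1e-6 * mean(diag(crossprod(X)))
    beta <- solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, xm))
    res <- xm - X %*% beta
  } else {
    res <- qr.resid(qrX, xm)
  }
  res <- sweep(res, 2, colMeans(xm), "+")
  if (vec_in) drop(res) else res
}

#' Spectral whitening by first-order differencing
#'
#' First difference per trial and channel; the filter gain
#' \eqn{2 \sin(\pi f / f_s)} suppresses the 1/f aperiodic component as a
#' time-domain whitener. Epochs shorten by one sample.
#'
#' @param epochs a \code{roi_epochs}.
#' @return whitened \code{roi_epochs}.
#' @export
whiten_derivative <- function(epochs) {
  stopifnot(inherits(epochs, "roi_epochs"))
  d <- dim(epochs$data)
  if (d[3] < 2L) stop("whiten_derivative: epochs too short")
  out <- epochs$data[, , -1L, drop = FALSE] - epochs$data[, , -d[3], drop = FALSE]
  roi_epochs(out, fs = epochs$fs, time = epochs$time[-1L], roi = epochs$roi)
}

## ---- DPSS tapers -----------------------------------------------------------

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the tridiagonal eigenproblem; concentration eigenvalues from
#' the sinc kernel. Tapers are unit-norm, ordered by concentration. Cached per
#' (n, nw, k).
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return list with \code{tapers} (n x k) and \code{eigen} (concentrations).
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- paste(n, round(nw, 8), k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  t <- seq_len(n) - 1L
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  ## sign convention: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (sum(diff(tap[, j]) * seq_len(n - 1)) < 0) {
      tap[, j] <- -tap[, j]
    }
  }
  tap <- sweep(tap, 2, sqrt(colSums(tap^2)), "/")
  ## concentration lambda_k = t' K t with K_ij = sin(2 pi W (i-j)) / (pi (i-j))
  ij <- outer(t, t, "-")
  K <- sin(2 * pi * w * ij) / (pi * ij)
  K[ij == 0] <- 2 * w
  conc <- vapply(seq_len(k), function(j) drop(tap[, j] %*% K %*% tap[, j]),
                 numeric(1))
  res <- list(tapers = tap, eigen = pmin(conc, 1))
  .dpss_cache[[key]] <- res
  res
}

n_tapers_for <- function(n, fs, smoothing_hz) {
  nw <- smoothing_hz * n / fs
  k <- floor(2 * nw) - 1
  list(nw = nw, k = k)
}

## taper + FFT for one taper across a set of series (matrix n x m)
.taper_fft <- function(xm, taper) {
  stats::mvfft(xm * taper)
}

#' Multitaper power spectral density of epochs
#'
#' Eigenvalue-weighted DPSS multitaper PSD per trial and channel, computed on
#' a time window of the epoch (default the prestimulus \code{[-1.6, 0]} s).
#' Returns one-sided density in units^2/Hz, so summing over frequency times
#' the bin width approximates the signal variance.
#'
#' @param epochs a \code{roi_epochs}.
#' @param fmin,fmax frequency range, Hz.
#' @param smoothing_hz spectral smoothing half-bandwidth W; the number of
#'   tapers is \code{floor(2 N W / fs) - 1}.
#' @param time_window analysis window in epoch time, seconds; NULL = whole
#'   epoch.
#' @return object of class \code{spectrum_set}: list with \code{power}
#'   (trial x roi x frequency), \code{freq}, \code{n_tapers}, \code{roi},
#'   \code{fs}.
#' @export
multitaper_psd <- function(epochs, fmin = 1, fmax = 40, smoothing_hz = 2,
                           time_window = c(-1.6, 0)) {
  stopifnot(inherits(epochs, "roi_epochs"))
  sel <- if (is.null(time_window)) seq_along(epochs$time) else {
    which(epochs$time >= time_window[1] - 1e-9 & epochs$time <= time_window[2] + 1e-9)
  }
  if (!length(sel)) stop("multitaper_psd: empty time window")
  n <- length(sel)
  cfg <- n_tapers_for(n, epochs$fs, smoothing_hz)
  if (cfg$k < 1L) {
    stop(sprintf("multitaper_psd: smoothing too small for this window; need at least %.3f Hz",
                 epochs$fs / n))
  }
  dp <- dpss_tapers(n, cfg$nw, cfg$k)
  d <- dim(epochs$data)
  nfreq_all <- n
  freq_all <- (seq_len(nfreq_all) - 1L) * epochs$fs / n
  fsel <- which(freq_all >= fmin - 1e-9 & freq_all <= fmax + 1e-9 &
                  freq_all <= epochs$fs / 2 + 1e-9)
  ## series matrix: time x (trial*roi), demeaned
  xm <- matrix(aperm(epochs$data[, , sel, drop = FALSE], c(3, 1, 2)),
               nrow = n)
  xm <- sweep(xm, 2, colMeans(xm))
  w <- dp$eigen / sum(dp$eigen)
  pow <- matrix(0, length(fsel), ncol(xm))
  for (j in seq_len(cfg$k)) {
    F <- .taper_fft(xm, dp$tapers[, j])[fsel, , drop = FALSE]
    pow <- pow + w[j] * (Mod(F)^2)
  }
  pow <- pow / epochs$fs
  one_sided <- !(freq_all[fsel] %in% c(0, epochs$fs / 2))
  pow[one_sided, ] <- 2 * pow[one_sided, ]
  power <- aperm(array(pow, dim = c(length(fsel), d[1], d[2])), c(2, 3, 1))
  structure(list(power = power, freq = freq_all[fsel], n_tapers = cfg$k,
                 nw = cfg$nw, roi = epochs$roi, fs = epochs$fs),
            class = "spectrum_set")
}

#' Sliding-window multitaper time-frequency representation
#'
#' @param epochs a \code{roi_epochs}.
#' @param fmin,fmax frequency range, Hz.
#' @param win_s window length, seconds.
#' @param step_s window step, seconds.
#' @param smoothing_hz smoothing half-bandwidth per window.
#' @return list with \code{power} (roi x frequency x time, averaged across
#'   trials), \code{freq}, \code{time} (window centres).
#' @export
tfr_multitaper <- function(epochs, fmin = 2, fmax = 40, win_s = 0.5,
                           step_s = 0.1, smoothing_hz = 4) {
  stopifnot(inherits(epochs, "roi_epochs"))
  t0 <- min(epochs$time); t1 <- max(epochs$time)
  centres <- seq(t0 + win_s / 2, t1 - win_s / 2, by = step_s)
  out <- NULL
  for (ci in seq_along(centres)) {
    ps <- multitaper_psd(epochs, fmin = fmin, fmax = fmax,
                         smoothing_hz = smoothing_hz,
                         time_window = centres[ci] + c(-win_s / 2, win_s / 2))
    avg <- apply(ps$power, c(2, 3), mean)       # roi x freq
    if (is.null(out)) {
      out <- array(0, dim = c(dim(avg), length(centres)))
      freq <- ps$freq
    }
    out[, , ci] <- avg
  }
  list(power = out, freq = freq, time = centres, roi = epochs$roi)
}

#' Respiration phase-binned power spectra
#'
#' Averages per-trial spectra within respiration-phase bins: moving mode uses
#' \code{n_bins} equally spaced window centres with half width
#' \code{half_width} (a trial contributes to every window containing its
#' phase); non-overlapping mode partitions the cycle.
#'
#' @param spectra a \code{spectrum_set}.
#' @param phases respiratory phase at target onset, one per trial.
#' @param n_bins number of phase bins.
#' @param mode "moving" or "nonoverlap".
#' @param half_width moving-window half width, radians.
#' @param min_trials bins with fewer trials yield NA with a message.
#' @return object of class \code{phase_binned_spectra}: list with \code{power}
#'   (roi x frequency x bin), \code{centres}, \code{n}, \code{freq},
#'   \code{roi}.
#' @export
phase_binned_power <- function(spectra, phases, n_bins = 30L,
                               mode = c("moving", "nonoverlap"),
                               half_width = pi / 10, min_trials = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectra, "spectrum_set"))
  d <- dim(spectra$power)
  if (length(phases) != d[1]) stop("phase_binned_power: one phase per trial required")
  if (mode == "moving") {
    b <- bin_by_phase(phases, n_bins, half_width = half_width)
    members <- lapply(seq_len(n_bins), function(k) which(b$membership[, k]))
  } else {
    b <- bin_by_phase(phases, n_bins)
    members <- lapply(seq_len(n_bins), function(k) which(b$bin == k))
  }
  centres <- b$centres
  pow <- array(NA_real_, dim = c(d[2], d[3], n_bins))
  nn <- vapply(members, length, integer(1))
  empty <- 0L
  for (k in seq_len(n_bins)) {
    if (nn[k] < min_trials) { empty <- empty + 1L; next }
    pow[, , k] <- apply(spectra$power[members[[k]], , , drop = FALSE], c(2, 3), mean)
  }
  if (empty > 0L) {
    message(sprintf("phase_binned_power: %d bin(s) below %d trials -> NA", empty, min_trials))
  }
  structure(list(power = pow, centres = centres, n = nn, freq = spectra$freq,
                 roi = spectra$roi, mode = mode),
            class = "phase_binned_spectra")
}

#' Phase regression of binned power per ROI and frequency
#'
#' Regresses the phase-binned power on sine and cosine of the bin centre,
#' yielding per (roi, frequency) the modulation amplitude, preferred phase,
#' and relative depth (amplitude / intercept).
#'
#' @param pbs a \code{phase_binned_spectra}.
#' @return list of arrays \code{amplitude}, \code{preferred_phase},
#'   \code{depth}, \code{intercept} (roi x frequency), plus \code{freq},
#'   \code{roi}.
#' @export
power_phase_regression <- function(pbs) {
  stopifnot(inherits(pbs, "phase_binned_spectra"))
  d <- dim(pbs$power)
  amp <- ph <- dep <- b0 <- matrix(NA_real_, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (f in seq_len(d[2])) {
      y <- pbs$power[r, f, ]
      ok <- is.finite(y)
      if (sum(ok) < 4L) next
      pr <- phase_regression(pbs$centres[ok], y[ok])
      amp[r, f] <- pr$amplitude
      ph[r, f] <- pr$preferred_phase
      b0[r, f] <- pr$b0
      dep[r, f] <- if (pr$b0 > 0) pr$amplitude / pr$b0 else NA_real_
    }
  }
  list(amplitude = amp, preferred_phase = ph, depth = dep, intercept = b0,
       freq = pbs$freq, roi = pbs$roi)
}
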