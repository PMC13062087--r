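## Nonparametric blockwise spectral Granger causality between ROI component
## blocks, the directed asymmetry index, and respiration phase-resolved GC.

#' Principal components of an ROI's trial-based time series
#'
#' PCA across channels on the trial-concatenated (demeaned) data; the top
#' \code{n_components} projections are returned per trial.
#'
#' @param epochs a \code{roi_epochs} holding one ROI's channels.
#' @param n_components components to keep.
#' @return list with \code{components} (a \code{roi_epochs} of component
#'   scores), \code{weights} (channels x components), \code{var_explained}.
#' @export
roi_block_components <- function(epochs, n_components = 3L) {
  stopifnot(inherits(epochs, "roi_epochs"))
  d <- dim(epochs$data)
  ## concatenate trials: (trial*time) x channels
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), ncol = d[2])
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = 0)
  lambda <- sv$d^2 / nrow(X)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, rank)
  if (k < n_components) {
    warning(sprintf("roi_block_components: rank %d < %d requested components",
                    rank, n_components), call. = FALSE)
  }
  W <- sv$v[, seq_len(k), drop = FALSE]
  scores <- X %*% W
  comp <- array(0, dim = c(d[1], k, d[3]))
  for (j in seq_len(k)) {
    comp[, j, ] <- t(matrix(scores[, j], nrow = d[3]))
  }
  list(components = roi_epochs(comp, fs = epochs$fs, time = epochs$time,
                               roi = paste0("pc", seq_len(k))),
       weights = W,
       var_explained = lambda[seq_len(k)] / sum(lambda))
}

#' Multitaper cross-spectral density
#'
#' Trial- and taper-averaged CSD of all channels on the full frequency grid
#' from DC to Nyquist (needed for spectral factorization). Two-sided density
#' convention (units^2/Hz, no one-sided doubling), so a VAR process with
#' transfer function H and innovation covariance Sigma has
#' \eqn{S(f) = H(f) \Sigma H(f)^* / f_s}.
#'
#' @param epochs a \code{roi_epochs} (channels of both blocks).
#' @param smoothing_hz multitaper smoothing half-bandwidth, Hz.
#' @param time_window analysis window in epoch time, seconds (NULL = all).
#' @param trials optional trial subset (indices).
#' @return object of class \code{csd}: list with \code{S} (channel x channel
#'   x frequency complex array), \code{freq}, \code{fs}, \code{n_trials},
#'   \code{n_tapers}, \code{roi}.
#' @export
csd_multitaper <- function(epochs, smoothing_hz = 2, time_window = c(-1.6, 0),
                           trials = NULL) {
  stopifnot(inherits(epochs, "roi_epochs"))
  sel <- if (is.null(time_window)) seq_along(epochs$time) else {
    which(epochs$time >= time_window[1] - 1e-9 & epochs$time <= time_window[2] + 1e-9)
  }
  n <- length(sel)
  if (n %% 2L == 1L) { sel <- sel[-1L]; n <- n - 1L }  # even grid for factorization
  cfg <- n_tapers_for(n, epochs$fs, smoothing_hz)
  if (cfg$k < 1L) {
    stop(sprintf("csd_multitaper: smoothing too small for this window; need at least %.3f Hz",
                 epochs$fs / n))
  }
  dp <- dpss_tapers(n, cfg$nw, cfg$k)
  dat <- if (is.null(trials)) epochs$data[, , sel, drop = FALSE] else
    epochs$data[trials, , sel, drop = FALSE]
  d <- dim(dat)
  nh <- n %/% 2L + 1L
  freq <- (seq_len(nh) - 1L) * epochs$fs / n
  xm <- matrix(aperm(dat, c(3, 1, 2)), nrow = n)   # time x (trial*chan)
  xm <- sweep(xm, 2, colMeans(xm))
  w <- dp$eigen / sum(dp$eigen)
  S <- array(0 + 0i, dim = c(d[2], d[2], nh))
  for (j in seq_len(cfg$k)) {
    F <- stats::mvfft(xm * dp$tapers[, j])[seq_len(nh), , drop = FALSE]
    ## per frequency: average over trials of x x^H
    for (f in seq_len(nh)) {
      Z <- matrix(F[f, ], nrow = d[1])             # trial x chan
      ## S_ij = E[X_i conj(X_j)]
      S[, , f] <- S[, , f] + w[j] * crossprod(Z, Conj(Z)) / d[1]
    }
  }
  S <- S / epochs$fs
  structure(list(S = S, freq = freq, fs = epochs$fs, n_trials = d[1],
                 n_tapers = cfg$k, roi = epochs$roi),
            class = "csd")
}

#' Wilson spectral matrix factorization
#'
#' Factorizes the cross-spectral density as \eqn{S(f) = H(f) \Sigma H(f)^*}
#' with minimum-phase transfer function H and innovation covariance Sigma,
#' using the iterative Wilson algorithm on the full frequency grid. The input
#' spectrum is diagonally loaded by \code{loading} times the mean power
#' before factorization to guarantee positive definiteness under finite
#' trials.
#'
#' @param csd a \code{csd} (full DC-to-Nyquist grid).
#' @param tol relative reconstruction residual for convergence.
#' @param max_iter iteration cap.
#' @param loading diagonal loading factor.
#' @return list with \code{H} (channel x channel x frequency), \code{Sigma},
#'   \code{relres}, \code{iterations}, \code{freq}, \code{fs}.
#' @export
wilson_factorize <- function(csd, tol = 1e-8, max_iter = 100L,
                             loading = 1e-8) {
  stopifnot(inherits(csd, "csd"))
  S <- csd$S
  m <- dim(S)[1]
  mean_pow <- mean(Re(vapply(seq_len(dim(S)[3]),
                             function(f) sum(diag(S[, , f])), complex(1)))) / m
  for (f in seq_len(dim(S)[3])) {
    S[, , f] <- S[, , f] + diag(loading * mean_pow, m)
  }
  res <- wilson_factor_cpp(S, csd$fs, tol, as.integer(max_iter))
  if (!isTRUE(res$converged)) {
    stop(sprintf("wilson_factorize: no convergence in %d iterations (relative residual %.3g)",
                 max_iter, res$relres))
  }
  list(H = res$H, Sigma = res$Sigma, relres = res$relres,
       iterations = res$iterations, freq = csd$freq, fs = csd$fs)
}

#' Blockwise spectral Granger causality
#'
#' Geweke-style frequency-resolved directed influence between two channel
#' blocks computed from a factorized spectrum:
#' \deqn{f_{A \to B}(f) = \ln \frac{\det S_{BB}(f)}{\det (S_{BB}(f) -
#'   H_{BA}(f) \Sigma_{AA|B} H_{BA}(f)^*)}}
#' with \eqn{\Sigma_{AA|B} = \Sigma_{AA} - \Sigma_{AB}\Sigma_{BB}^{-1}
#' \Sigma_{BA}}.
#'
#' @param csd a \code{csd}.
#' @param fac factorization from \code{\link{wilson_factorize}} (computed if
#'   NULL).
#' @param block_a,block_b integer channel indices of the two blocks.
#' @param fmax restrict the returned spectrum to frequencies <= fmax.
#' @param fmin drop frequencies below fmin (the demeaned DC bin is
#'   ill-conditioned and not interpretable).
#' @return object of class \code{gc_spectra}: list with \code{freq},
#'   \code{gc} (frequency x 2 matrix, columns \code{a2b}, \code{b2a}),
#'   \code{blocks}.
#' @export
block_gc <- function(csd, fac = NULL, block_a = 1:3, block_b = 4:6,
                     fmax = NULL, fmin = NULL) {
  stopifnot(inherits(csd, "csd"))
  if (is.null(fac)) fac <- wilson_factorize(csd)
  fsel <- seq_along(csd$freq)
  if (!is.null(fmax)) fsel <- fsel[csd$freq[fsel] <= fmax + 1e-9]
  if (!is.null(fmin)) fsel <- fsel[csd$freq[fsel] >= fmin - 1e-9]
  Sw <- csd$S * csd$fs          # bin-scale spectrum: Sw = H Sigma H^*
  Sig <- fac$Sigma
  gc <- matrix(0, length(fsel), 2, dimnames = list(NULL, c("a2b", "b2a")))
  dirs <- list(list(src = block_a, dst = block_b),
               list(src = block_b, dst = block_a))
  for (di in 1:2) {
    src <- dirs[[di]]$src; dst <- dirs[[di]]$dst
    Sig_cond <- Sig[src, src, drop = FALSE] -
      Sig[src, dst, drop = FALSE] %*%
      solve(Sig[dst, dst, drop = FALSE], Sig[dst, src, drop = FALSE])
    Sig_cond <- 0.5 * (Sig_cond + t(Sig_cond))
    for (ii in seq_along(fsel)) {
      f <- fsel[ii]
      Sbb <- Sw[dst, dst, f, drop = FALSE][, , 1]
      Hba <- fac$H[dst, src, f, drop = FALSE][, , 1]
      num <- .cdet(Sbb)
      den <- .cdet(Sbb - Hba %*% Sig_cond %*% Conj(t(Hba)))
      gc[ii, di] <- if (num > 0 && den > 0) max(log(num / den), 0) else NA_real_
    }
  }
  structure(list(freq = csd$freq[fsel], gc = gc,
                 blocks = list(a = block_a, b = block_b)),
            class = "gc_spectra")
}

## determinant of a (Hermitian) complex matrix via its real eigenvalues
.cdet <- function(M) {
  if (length(M) == 1L) return(Re(M[1]))
  prod(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Directed asymmetry index
#'
#' \deqn{\mathrm{DAI}(f) = \frac{GC_{A\to B}(f) - GC_{B \to A}(f)}
#'   {GC_{A\to B}(f) + GC_{B \to A}(f)}}
#' Bounded in [-1, 1]; +1 means purely A-to-B influence. Frequencies where
#' the summed GC falls below \code{floor} are returned as NA (undefined
#' asymmetry) rather than propagating division noise.
#'
#' @param a2b,b2a nonnegative GC spectra (or a \code{gc_spectra} as first
#'   argument).
#' @param floor minimum summed GC for a defined index.
#' @return numeric DAI spectrum.
#' @export
dai <- function(a2b, b2a = NULL, floor = 1e-12) {
  if (inherits(a2b, "gc_spectra")) {
    g <- a2b$gc
    a2b <- g[, "a2b"]; b2a <- g[, "b2a"]
  }
  stopifnot(length(a2b) == length(b2a))
  if (any(a2b < 0, na.rm = TRUE) || any(b2a < 0, na.rm = TRUE)) {
    stop("dai: GC values must be nonnegative")
  }
  s <- a2b + b2a
  out <- ifelse(is.finite(s) & s > floor, (a2b - b2a) / s, NA_real_)
  out
}

#' Respiration phase-resolved Granger causality
#'
#' Sorts trials into respiration-phase bins at target onset and repeats the
#' full CSD -> factorization -> blockwise-GC chain per bin. Bins with fewer
#' than \code{min_trials} trials (or failed factorizations) are skipped with
#' a log entry.
#'
#' @param epochs a \code{roi_epochs} containing both blocks' channels.
#' @param phases respiratory phase at target onset per trial.
#' @param block_a,block_b channel indices.
#' @param n_bins number of phase bins (non-overlapping by default).
#' @param mode "nonoverlap" or "moving" (half width \eqn{\pi/10}).
#' @param min_trials minimum trials per bin.
#' @param smoothing_hz,time_window passed to \code{\link{csd_multitaper}}.
#' @param fmax restrict GC spectra to <= fmax Hz.
#' @param fmin drop frequencies below fmin Hz (default 1).
#' @param ... passed to \code{\link{wilson_factorize}}.
#' @return object of class \code{phase_gc}: list with \code{gc} (frequency x
#'   bin x 2 array), \code{freq}, \code{centres}, \code{n}, \code{skipped}.
#' @export
phase_resolved_gc <- function(epochs, phases, block_a = 1:3, block_b = 4:6,
                              n_bins = 30L, mode = c("nonoverlap", "moving"),
                              min_trials = 15L, smoothing_hz = 2,
                              time_window = c(-1.6, 0), fmax = NULL,
                              fmin = 1, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "roi_epochs"))
  if (mode == "nonoverlap") {
    b <- bin_by_phase(phases, n_bins)
    members <- lapply(seq_len(n_bins), function(k) which(b$bin == k))
  } else {
    b <- bin_by_phase(phases, n_bins, half_width = pi / 10)
    members <- lapply(seq_len(n_bins), function(k) which(b$membership[, k]))
  }
  gc_arr <- NULL
  skipped <- integer(0)
  nn <- vapply(members, length, integer(1))
  for (k in seq_len(n_bins)) {
    if (nn[k] < min_trials) { skipped <- c(skipped, k); next }
    csd_k <- csd_multitaper(epochs, smoothing_hz = smoothing_hz,
                            time_window = time_window, trials = members[[k]])
    gk <- tryCatch(
      block_gc(csd_k, fac = wilson_factorize(csd_k, ...),
               block_a = block_a, block_b = block_b, fmax = fmax, fmin = fmin),
      error = function(e) NULL)
    if (is.null(gk)) { skipped <- c(skipped, k); next }
    if (is.null(gc_arr)) {
      gc_arr <- array(NA_real_, dim = c(length(gk$freq), n_bins, 2L),
                      dimnames = list(NULL, NULL, c("a2b", "b2a")))
      freq <- gk$freq
    }
    gc_arr[, k, ] <- gk$gc
  }
  if (is.null(gc_arr)) stop("phase_resolved_gc: no bin could be estimated")
  if (length(skipped)) {
    message(sprintf("phase_resolved_gc: %d bin(s) skipped (undersized or failed)",
                    length(skipped)))
  }
  structure(list(gc = gc_arr, freq = freq, centres = b$centres, n = nn,
                 skipped = skipped),
            class = "phase_gc")
}

#' Phase regression of bin-resolved GC and DAI of the modulation
#'
#' Per frequency and direction, regresses the bin-resolved GC on sine and
#' cosine of the bin centre; the modulation magnitude is
#' \eqn{\sqrt{b_{sin}^2 + b_{cos}^2}}. The directed asymmetry index is then
#' applied to the two directions' modulation magnitudes (nonnegative by
#' construction, so the DAI denominator is well defined).
#'
#' @param pgc a \code{phase_gc}.
#' @param min_bins minimum estimated bins required.
#' @return list with \code{amplitude} (frequency x 2), \code{preferred_phase}
#'   (frequency x 2), \code{dai_mod} (frequency), \code{freq}.
#' @export
gc_phase_regression <- function(pgc, min_bins = 4L) {
  stopifnot(inherits(pgc, "phase_gc"))
  nf <- dim(pgc$gc)[1]
  amp <- ph <- matrix(NA_real_, nf, 2, dimnames = list(NULL, c("a2b", "b2a")))
  for (di in 1:2) {
    for (f in seq_len(nf)) {
      y <- pgc$gc[f, , di]
      ok <- is.finite(y)
      if (sum(ok) < min_bins) next
      pr <- phase_regression(pgc$centres[ok], y[ok])
      amp[f, di] <- pr$amplitude
      ph[f, di] <- pr$preferred_phase
    }
  }
  dm <- dai(amp[, 1], amp[, 2])
  list(amplitude = amp, preferred_phase = ph, dai_mod = dm, freq = pgc$freq)
}
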