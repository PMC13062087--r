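## Independent oracles used by the test suite. These deliberately avoid the
## package's code paths: direct formula evaluation, brute-force enumeration,
## and closed-form VAR spectra.

## circular-linear correlation: direct evaluation of the formula
oracle_circ_lin <- function(theta, x) {
  rcx <- cor(cos(theta), x)
  rsx <- cor(sin(theta), x)
  rcs <- cor(sin(theta), cos(theta))
  sqrt((rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2))
}

## Hodges-Ajne m by brute-force rotation scan (dense grid plus data anchors)
oracle_half_circle_min <- function(theta) {
  th <- theta %% (2 * pi)
  bounds <- sort(unique(c(seq(0, 2 * pi, length.out = 3601), th, th + 1e-7)))
  min(vapply(bounds, function(a) {
    d <- (th - a) %% (2 * pi)
    sum(d <= pi + 1e-12)
  }, numeric(1)))
}

## faster variant for Monte Carlo: boundaries at data anchors only
oracle_half_circle_min_fast <- function(theta) {
  th <- sort(theta %% (2 * pi))
  ext <- c(th, th + 2 * pi)
  cand <- c(th, th + 1e-9, th + pi - 1e-9, th + pi)
  min(vapply(cand, function(a) {
    sum(ext >= a - 1e-12 & ext <= a + pi + 1e-12)
  }, numeric(1)))
}

## brute-force Bayes replay of a QUEST trial history on the same grid
oracle_quest_posterior <- function(cfg, contrasts, hits) {
  grid <- seq(cfg$grid_range[1], cfg$grid_range[2], length.out = cfg$n_grid)
  prior <- dnorm(grid, cfg$prior_mean, cfg$prior_sd)
  logpost <- log(prior / sum(prior))
  for (i in seq_along(contrasts)) {
    p <- cfg$gamma + (1 - cfg$gamma - cfg$delta) *
      pnorm(cfg$beta * (log10(contrasts[i]) - grid))
    logpost <- logpost + log(if (hits[i]) p else 1 - p)
  }
  w <- exp(logpost - max(logpost))
  w / sum(w)
}

## definitional Benjamini-Hochberg: largest k with p_(k) <= k q / m
oracle_bh_mask <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  mask <- rep(FALSE, m)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}

## analytic two-sided spectral density of a VAR(p): S(f) = H Sigma H^* / fs
oracle_var_spectrum <- function(A_list, Sigma, freq, fs) {
  m <- nrow(Sigma)
  S <- array(0i, dim = c(m, m, length(freq)))
  H <- array(0i, dim = c(m, m, length(freq)))
  for (k in seq_along(freq)) {
    z <- exp(-2i * pi * freq[k] / fs)
    Az <- diag(m) + 0i
    for (l in seq_along(A_list)) Az <- Az - A_list[[l]] * z^l
    Hk <- solve(Az)
    H[, , k] <- Hk
    S[, , k] <- Hk %*% Sigma %*% Conj(t(Hk)) / fs
  }
  list(S = S, H = H, freq = freq)
}

## parametric Geweke block GC from the true VAR coefficients
oracle_var_block_gc <- function(A_list, Sigma, freq, fs, src, dst) {
  vs <- oracle_var_spectrum(A_list, Sigma, freq, fs)
  SigC <- Sigma[src, src, drop = FALSE] -
    Sigma[src, dst, drop = FALSE] %*%
    solve(Sigma[dst, dst, drop = FALSE], Sigma[dst, src, drop = FALSE])
  vapply(seq_along(freq), function(k) {
    Sw <- vs$S[, , k] * fs
    Sbb <- Sw[dst, dst, drop = FALSE]
    Hba <- vs$H[dst, src, , drop = FALSE][, , k]
    Hba <- matrix(Hba, length(dst), length(src))
    num <- Re(prod(eigen(Sbb, symmetric = TRUE, only.values = TRUE)$values))
    den <- Re(prod(eigen(Sbb - Hba %*% SigC %*% Conj(t(Hba)),
                         symmetric = TRUE, only.values = TRUE)$values))
    log(num / den)
  }, numeric(1))
}

## simulate trials from a VAR(2) given coefficient matrices
sim_var_epochs <- function(A1, A2, n_trials, n_t, fs, burn = 200, seed = 1) {
  set.seed(seed)
  m <- nrow(A1)
  total <- n_t + burn
  X <- array(0, dim = c(total, m, n_trials))
  eps <- array(rnorm(total * m * n_trials), dim = c(total, m, n_trials))
  for (t in 3:total) {
    X[t, , ] <- A1 %*% X[t - 1, , ] + A2 %*% X[t - 2, , ] + eps[t, , ]
  }
  dat <- aperm(X[(burn + 1):total, , , drop = FALSE], c(3, 2, 1))
  roi_epochs(dat, fs = fs, time = (seq_len(n_t) - 1) / fs,
             roi = paste0("ch", seq_len(m)))
}
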