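## QUEST adaptive staircase and cumulative-Gaussian psychometric fitting.
## The staircase runs on a log10-contrast grid with a Bayesian posterior over
## threshold; fitting is MAP on a (threshold, slope, lapse) grid with the
## guess rate fixed (3AFC: gamma = 1/3).

#' QUEST staircase configuration
#'
#' Internal model: \eqn{p(\mathrm{hit} \mid c, T) = \gamma + (1-\gamma-\delta)
#' \Phi(\beta (\log_{10} c - T))} over a grid of log-thresholds \eqn{T}.
#' Placement uses the posterior mean of \eqn{T} and proposes the contrast at
#' which the internal function equals \code{target_p}.
#'
#' @param grid_range range of the log10-threshold grid.
#' @param n_grid grid points.
#' @param beta internal slope (per log10 unit).
#' @param delta internal lapse.
#' @param gamma guess rate.
#' @param target_p staircase convergence criterion (hit rate), must lie in
#'   \code{(gamma, 1 - delta)}.
#' @param prior_mean,prior_sd Gaussian prior on the log10 threshold.
#' @return config list.
#' @export
quest_config <- function(grid_range = c(-2.5, 0), n_grid = 251L, beta = 3.5,
                         delta = 0.01, gamma = 1 / 3, target_p = 0.6,
                         prior_mean = -0.5, prior_sd = 1) {
  stopifnot(target_p > gamma, target_p < 1 - delta)
  list(grid_range = grid_range, n_grid = as.integer(n_grid), beta = beta,
       delta = delta, gamma = gamma, target_p = target_p,
       prior_mean = prior_mean, prior_sd = prior_sd)
}

#' Initialize a QUEST state
#'
#' @param cfg a \code{\link{quest_config}}.
#' @return object of class \code{quest_state}: list with \code{grid} (log10
#'   thresholds), \code{posterior} (normalized), and the config.
#' @export
quest_create <- function(cfg = quest_config()) {
  grid <- seq(cfg$grid_range[1], cfg$grid_range[2], length.out = cfg$n_grid)
  prior <- stats::dnorm(grid, cfg$prior_mean, cfg$prior_sd)
  prior <- prior / sum(prior)
  structure(list(grid = grid, posterior = prior, cfg = cfg),
            class = "quest_state")
}

quest_internal_p <- function(cfg, log_c, log_T) {
  cfg$gamma + (1 - cfg$gamma - cfg$delta) *
    stats::pnorm(cfg$beta * (log_c - log_T))
}

#' Propose the next test contrast
#'
#' Posterior-mean placement: the proposal is the contrast at which the
#' internal psychometric function evaluated at the posterior-mean threshold
#' equals \code{target_p}.
#'
#' @param state a \code{quest_state}.
#' @return contrast in (0, 1].
#' @export
quest_propose <- function(state) {
  post <- state$posterior
  if (any(!is.finite(post)) || sum(post) <= 0) stop("quest_propose: degenerate posterior")
  cfg <- state$cfg
  t_hat <- sum(state$grid * post)
  offset <- stats::qnorm((cfg$target_p - cfg$gamma) / (1 - cfg$gamma - cfg$delta)) / cfg$beta
  min(1, 10^(t_hat + offset))
}

#' Update the QUEST posterior with a trial outcome
#'
#' Multiplies the posterior by the likelihood of the observed outcome under
#' the internal psychometric function at every grid threshold.
#'
#' @param state a \code{quest_state}.
#' @param contrast tested contrast (> 0).
#' @param hit logical outcome.
#' @return updated \code{quest_state}; attribute \code{flags} accumulates a
#'   divergence marker when the posterior mode sits on the grid edge.
#' @export
quest_update <- function(state, contrast, hit) {
  if (contrast <= 0) stop("quest_update: contrast must be positive")
  cfg <- state$cfg
  p <- quest_internal_p(cfg, log10(contrast), state$grid)
  lik <- if (isTRUE(hit)) p else 1 - p
  post <- state$posterior * lik
  s <- sum(post)
  if (s <= 0 || !is.finite(s)) stop("quest_update: posterior collapsed")
  post <- post / s
  flags <- attr(state, "flags")
  mode_i <- which.max(post)
  if (mode_i == 1L || mode_i == length(post)) {
    flags <- unique(c(flags, "posterior_mode_at_grid_edge"))
    warning("quest_update: posterior mode at grid edge (staircase divergence?)",
            call. = FALSE)
  }
  out <- state
  out$posterior <- post
  attr(out, "flags") <- flags
  out
}

#' Cumulative-Gaussian psychometric function
#'
#' \eqn{\Psi(c) = \gamma + (1 - \gamma - \lambda) \Phi((c - m)/\sigma)}.
#'
#' @param contrast stimulus contrast.
#' @param threshold,slope location \eqn{m} and width \eqn{\sigma}.
#' @param guess_rate,lapse_rate asymptotes.
#' @return detection probability.
#' @export
psych_fun <- function(contrast, threshold, slope, guess_rate = 1 / 3,
                      lapse_rate = 0) {
  guess_rate + (1 - guess_rate - lapse_rate) *
    stats::pnorm((contrast - threshold) / slope)
}

#' MAP fit of the psychometric function
#'
#' Grid-based Bayesian fit of (threshold m, width sigma, lapse lambda) with
#' the guess rate fixed. The threshold is reported at the midpoint of the
#' unscaled sigmoid (\eqn{\Phi = 0.5}, i.e. at \eqn{c = m}). Default priors
#' are flat on m, flat on log sigma, and Beta(1, 20)-shaped on lambda;
#' Gaussian priors on m and log10 sigma can be supplied (used by the
#' phase-resolved refit). Marginal posterior SDs and 95% credible intervals
#' are returned per parameter.
#'
#' @param contrasts tested contrasts.
#' @param outcomes logical hits.
#' @param guess_rate fixed gamma.
#' @param priors optional list with elements \code{threshold = c(mean, sd)},
#'   \code{log_slope = c(mean, sd)} (log10 units) and/or \code{lapse}
#'   (fixed value).
#' @param n_m,n_s,n_l grid sizes.
#' @param m_range,s_range grid ranges (s_range in contrast units, log-spaced).
#' @return object of class \code{psych_fit}.
#' @export
fit_psychometric <- function(contrasts, outcomes, guess_rate = 1 / 3,
                             priors = NULL, n_m = 61L, n_s = 31L, n_l = 9L,
                             m_range = NULL, s_range = c(0.01, 1)) {
  stopifnot(length(contrasts) == length(outcomes))
  hits <- as.logical(outcomes)
  n <- length(hits)
  flags <- character(0)
  if (length(unique(round(contrasts, 10))) < 2L || all(hits) || !any(hits)) {
    flags <- c(flags, "degenerate_data")
  }
  if (is.null(m_range)) {
    spread <- max(diff(range(contrasts)), 0.05)
    m_range <- c(max(1e-4, min(contrasts) - spread), max(contrasts) + spread)
  }
  m_grid <- seq(m_range[1], m_range[2], length.out = n_m)
  s_grid <- 10^seq(log10(s_range[1]), log10(s_range[2]), length.out = n_s)
  lapse_fixed <- !is.null(priors$lapse)
  l_grid <- if (lapse_fixed) priors$lapse else seq(0, 0.2, length.out = n_l)

  ## log prior over (m, s) and over l
  lp_m <- if (!is.null(priors$threshold)) {
    stats::dnorm(m_grid, priors$threshold[1], priors$threshold[2], log = TRUE)
  } else numeric(n_m)
  lp_s <- if (!is.null(priors$log_slope)) {
    stats::dnorm(log10(s_grid), priors$log_slope[1], priors$log_slope[2], log = TRUE)
  } else numeric(n_s)
  lp_l <- if (lapse_fixed) 0 else stats::dbeta(pmin(l_grid / 0.5, 1 - 1e-9), 1, 20, log = TRUE)

  ## Phi((c - m)/s) for all (trial, m, s): loop slopes, vectorize (trial x m)
  nh <- sum(hits); nm <- n - nh
  logpost <- array(-Inf, dim = c(n_m, n_s, length(l_grid)))
  cm <- outer(contrasts, m_grid, "-")          # n x n_m
  for (si in seq_len(n_s)) {
    Phi <- stats::pnorm(cm / s_grid[si])       # n x n_m
    for (li in seq_along(l_grid)) {
      P <- guess_rate + (1 - guess_rate - l_grid[li]) * Phi
      P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
      ll <- colSums(log(P[hits, , drop = FALSE])) +
        colSums(log(1 - P[!hits, , drop = FALSE]))
      logpost[, si, li] <- ll + lp_m + lp_s[si] + lp_l[li]
    }
  }
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  idx <- which(post == max(post), arr.ind = TRUE)[1, ]
  m_hat <- m_grid[idx[1]]; s_hat <- s_grid[idx[2]]; l_hat <- l_grid[idx[3]]

  marg <- function(dim, grid) {
    w <- apply(post, dim, sum)
    mu <- sum(grid * w)
    sdv <- sqrt(max(sum(grid^2 * w) - mu^2, 0))
    cw <- cumsum(w)
    ci <- c(grid[which(cw >= 0.025)[1]], grid[which(cw >= 0.975)[1]])
    list(sd = sdv, ci = ci)
  }
  mm <- marg(1, m_grid)
  ms <- marg(2, log10(s_grid))
  if (m_hat <= min(contrasts) && ("degenerate_data" %in% flags) && all(hits)) {
    flags <- c(flags, "threshold_below_tested_range")
  }
  if (idx[1] == 1L || idx[1] == n_m) flags <- c(flags, "threshold_at_grid_edge")
  structure(list(
    threshold = m_hat, slope = s_hat, lapse = l_hat, guess_rate = guess_rate,
    post_sd = c(threshold = mm$sd, log_slope = ms$sd),
    ci = rbind(threshold = mm$ci, log_slope = 10^ms$ci),
    flags = flags, n = n
  ), class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  cat(sprintf("<psych_fit> m = %.4f (sd %.4f), sigma = %.4f, lambda = %.3f, gamma = %.3f, n = %d\n",
              x$threshold, x$post_sd["threshold"], x$slope, x$lapse,
              x$guess_rate, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Moving-window respiration phase-resolved threshold profile
#'
#' Walks around the respiratory cycle in increments of \code{step} and refits
#' the psychometric function to the trials presented at a respiration angle
#' within \code{centre +/- half_width} (circular wrap-around). The overall
#' fit provides Gaussian priors on threshold and log-slope (SD = \code{
#' prior_widen} times the overall marginal posterior SD) and fixes the lapse.
#' Window thresholds are z-scored across defined windows.
#'
#' @param trials trial table with columns \code{contrast}, \code{hit},
#'   \code{phase_rad}.
#' @param overall_fit optional \code{psych_fit}; fitted from all trials when
#'   NULL.
#' @param step window spacing in radians (default \eqn{\pi/30}, 60 windows).
#' @param half_width window half width (default \eqn{\pi/10}).
#' @param min_trials minimum trials to attempt a window refit.
#' @param prior_widen multiplier on the overall posterior SDs for the window
#'   priors.
#' @return object of class \code{threshold_profile}: data.frame with
#'   \code{omega} (window centre), \code{threshold}, \code{z_threshold},
#'   \code{n}; the overall fit and settings are attached as attributes.
#' @export
phase_resolved_thresholds <- function(trials, overall_fit = NULL,
                                      step = pi / 30, half_width = pi / 10,
                                      min_trials = 10L, prior_widen = 2) {
  stopifnot(all(c("contrast", "hit", "phase_rad") %in% names(trials)))
  if (any(!is.finite(trials$phase_rad))) {
    trials <- trials[is.finite(trials$phase_rad), , drop = FALSE]
  }
  if (is.null(overall_fit)) {
    overall_fit <- fit_psychometric(trials$contrast, trials$hit)
  }
  n_win <- round(2 * pi / step)
  centres <- -pi + (seq_len(n_win) - 1L) * step
  priors <- list(
    threshold = c(overall_fit$threshold,
                  max(prior_widen * overall_fit$post_sd["threshold"], 1e-3)),
    log_slope = c(log10(overall_fit$slope),
                  max(prior_widen * overall_fit$post_sd["log_slope"], 1e-3)),
    lapse = overall_fit$lapse
  )
  thr <- rep(NA_real_, n_win)
  nn <- integer(n_win)
  skipped <- integer(0)
  for (k in seq_len(n_win)) {
    sel <- circ_dist(trials$phase_rad, centres[k]) <= half_width
    nn[k] <- sum(sel)
    if (nn[k] < min_trials) {
      skipped <- c(skipped, k)
      next
    }
    fit_k <- fit_psychometric(trials$contrast[sel], trials$hit[sel],
                              guess_rate = overall_fit$guess_rate,
                              priors = priors,
                              m_range = c(max(1e-4, overall_fit$threshold - 6 * priors$threshold[2]),
                                          overall_fit$threshold + 6 * priors$threshold[2]))
    thr[k] <- fit_k$threshold
  }
  if (length(skipped)) {
    message(sprintf("phase_resolved_thresholds: %d window(s) below %d trials skipped",
                    length(skipped), min_trials))
  }
  ok <- is.finite(thr)
  z <- rep(NA_real_, n_win)
  if (sum(ok) >= 2L && stats::sd(thr[ok]) > 0) {
    z[ok] <- (thr[ok] - mean(thr[ok])) / stats::sd(thr[ok])
  } else if (sum(ok) >= 1L) {
    z[ok] <- 0
  }
  out <- data.frame(omega = centres, threshold = thr, z_threshold = z, n = nn)
  attr(out, "overall_fit") <- overall_fit
  attr(out, "step") <- step
  attr(out, "half_width") <- half_width
  attr(out, "skipped") <- skipped
  class(out) <- c("threshold_profile", "data.frame")
  out
}

#' First-harmonic summary of a threshold profile
#'
#' Fits \code{z_threshold ~ 1 + sin(omega) + cos(omega)} and reports the
#' modulation amplitude and the phase of the threshold minimum (maximal
#' sensitivity).
#'
#' @param profile a \code{threshold_profile}.
#' @return list with \code{amplitude}, \code{peak_phase} (threshold maximum),
#'   \code{min_phase} (threshold minimum).
#' @export
profile_modulation <- function(profile) {
  ok <- is.finite(profile$z_threshold)
  if (sum(ok) < 4L) {
    return(list(amplitude = NA_real_, peak_phase = NA_real_,
                min_phase = NA_real_))
  }
  pr <- phase_regression(profile$omega[ok], profile$z_threshold[ok])
  list(amplitude = pr$amplitude,
       peak_phase = pr$preferred_phase,
       min_phase = wrap_angle(pr$preferred_phase + pi))
}

#' Group-level test of phase-resolved threshold profiles
#'
#' Per window, a two-sided one-sample t-test of the z-scored thresholds
#' against zero across participants, with Benjamini-Hochberg FDR correction
#' across windows.
#'
#' @param profiles matrix participants x windows of z-scored thresholds (or a
#'   list of \code{threshold_profile}s sharing the same windows).
#' @param q FDR level.
#' @return data.frame with \code{omega} (when available), \code{mean_z},
#'   \code{t}, \code{p}, \code{p_adj}, \code{sig}.
#' @export
group_profile_test <- function(profiles, q = 0.05) {
  omega <- NULL
  if (is.list(profiles) && !is.matrix(profiles)) {
    omega <- profiles[[1]]$omega
    profiles <- do.call(rbind, lapply(profiles, function(p) p$z_threshold))
  }
  if (nrow(profiles) < 2L) stop("group_profile_test: need at least 2 participants")
  res <- apply(profiles, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2L || stats::sd(col) == 0) return(c(mean(col), NA, NA))
    tt <- stats::t.test(col)
    c(mean(col), unname(tt$statistic), tt$p.value)
  })
  p_adj <- stats::p.adjust(res[3, ], method = "BH")
  out <- data.frame(mean_z = res[1, ], t = res[2, ], p = res[3, ],
                    p_adj = p_adj, sig = !is.na(p_adj) & p_adj <= q)
  if (!is.null(omega)) out <- cbind(data.frame(omega = omega), out)
  out
}
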