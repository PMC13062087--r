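#' Wrap angles to [-pi, pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval \code{[-pi, pi)}.
#' @export
wrap_angle <- function(theta) {
  ((theta + pi) %% (2 * pi)) - pi
}

## wrap to (-pi, pi], used for right-closed binning
wrap_angle_upper <- function(theta) {
  w <- theta %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Circular distance between angles
#'
#' Absolute angular separation, always in \code{[0, pi]}.
#' @param a,b angles in radians (recycled).
#' @return numeric vector of distances.
#' @export
circ_dist <- function(a, b) {
  abs(wrap_angle(a - b))
}

#' Circular-linear correlation
#'
#' Correlation between a circular variable and a linear one, computed from the
#' Pearson correlations of the linear variable with the sine and cosine of the
#' angle:
#' \deqn{\rho = \sqrt{(r_{cx}^2 + r_{sx}^2 - 2 r_{cx} r_{sx} r_{cs})/(1 - r_{cs}^2)}}
#' The p-value uses the chi-squared approximation \eqn{n \rho^2 \sim \chi^2_2};
#' a permutation p-value is available for small samples.
#'
#' @param angles angles in radians.
#' @param x linear covariate, same length.
#' @param method "chisq" (default) or "perm".
#' @param n_perm permutations when \code{method = "perm"}.
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
circ_linear_corr <- function(angles, x, method = c("chisq", "perm"),
                             n_perm = 2000L) {
  method <- match.arg(method)
  ok <- is.finite(angles) & is.finite(x)
  angles <- angles[ok]; x <- x[ok]
  n <- length(x)
  if (n < 4L) stop("circ_linear_corr: need at least 4 paired observations")
  if (stats::sd(x) == 0) stop("circ_linear_corr: 'x' is constant")
  rho <- .circ_lin_rho(angles, x)
  if (method == "chisq") {
    p <- stats::pchisq(n * rho^2, df = 2, lower.tail = FALSE)
  } else {
    stat <- n * rho^2
    null <- vapply(seq_len(n_perm), function(i) {
      n * .circ_lin_rho(angles, sample(x))^2
    }, numeric(1))
    p <- (1 + sum(null >= stat)) / (n_perm + 1)
  }
  list(rho = rho, p = p, n = n)
}

.circ_lin_rho <- function(angles, x) {
  s <- sin(angles); c <- cos(angles)
  rcx <- stats::cor(c, x)
  rsx <- stats::cor(s, x)
  rcs <- stats::cor(s, c)
  val <- (rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2)
  sqrt(max(val, 0))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform circular distribution against a unimodal
#' alternative. Statistic \eqn{z = n \bar R^2} with the standard finite-sample
#' correction for the p-value.
#'
#' @param angles angles in radians.
#' @return list with \code{z}, \code{r} (mean resultant length), \code{p},
#'   \code{n}.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 2L) stop("rayleigh_test: need at least 2 angles")
  rbar <- Mod(mean(exp(1i * angles)))
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(z = z, r = rbar, p = p, n = n)
}

#' Hodges-Ajne test of circular uniformity
#'
#' Omnibus test based on \code{m}, the minimum number of observations falling
#' in any closed half-circle. Small \code{m} indicates clustering. The exact
#' tail probability \eqn{p = 2^{1-n} (n - 2m) \binom{n}{m}} is used for
#' \code{n <= 50} (capped at 1), and a normal-style approximation above.
#'
#' @param angles angles in radians.
#' @return list with \code{m}, \code{p}, \code{n}.
#' @export
hodges_ajne_test <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 4L) stop("hodges_ajne_test: need at least 4 angles")
  m <- .half_circle_min_count(angles)
  if (n <= 50L) {
    if (n - 2 * m <= 0) {
      p <- 1
    } else {
      p <- min(1, 2^(1 - n) * (n - 2 * m) * choose(n, m))
    }
  } else {
    if (n - 2 * m <= 0) {
      p <- 1
    } else {
      A <- pi * sqrt(n) / (2 * (n - 2 * m))
      p <- min(1, sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2)))
    }
  }
  list(m = m, p = p, n = n)
}

## minimum count over all closed half-circles; boundaries only change counts
## when the half-circle edge crosses a data point, so data-anchored candidates
## (plus a small offset just past each point) are sufficient.
.half_circle_min_count <- function(angles) {
  th <- sort(angles %% (2 * pi))
  n <- length(th)
  eps <- 1e-9
  cand <- c(th, th + eps, th - pi, th - pi + eps) %% (2 * pi)
  ext <- c(th, th + 2 * pi)
  counts <- vapply(cand, function(a) {
    ## points with (x - a) mod 2pi in [0, pi]
    lo <- a
    hi <- a + pi
    sum(ext >= lo - 1e-12 & ext <= hi + 1e-12)
  }, numeric(1))
  as.integer(min(counts))
}

#' Sine/cosine phase regression
#'
#' Ordinary least squares of a response on \code{[1, sin(theta), cos(theta)]}.
#' The fitted first harmonic is \eqn{b_0 + A\cos(\theta - \phi)} with amplitude
#' \eqn{A = \sqrt{b_{sin}^2 + b_{cos}^2}} and preferred phase
#' \eqn{\phi = \mathrm{atan2}(b_{sin}, b_{cos})}.
#'
#' @param angles angles in radians.
#' @param y numeric response.
#' @return object of class \code{phase_regression}: list with \code{b0},
#'   \code{b_sin}, \code{b_cos}, \code{amplitude}, \code{preferred_phase},
#'   \code{fitted}, \code{r_squared}, \code{n}.
#' @export
phase_regression <- function(angles, y) {
  ok <- is.finite(angles) & is.finite(y)
  angles <- angles[ok]; y <- y[ok]
  n <- length(y)
  if (n < 4L) stop("phase_regression: need at least 4 observations")
  X <- cbind(1, sin(angles), cos(angles))
  if (qr(X)$rank < 3L) stop("phase_regression: rank-deficient design (angles too concentrated)")
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  amp <- sqrt(b[2]^2 + b[3]^2)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    b0 = unname(b[1]), b_sin = unname(b[2]), b_cos = unname(b[3]),
    amplitude = unname(amp),
    preferred_phase = unname(atan2(b[2], b[3])),
    fitted = fit$fitted.values,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = n
  ), class = "phase_regression")
}

#' Assign angles to phase bins
#'
#' Non-overlapping mode partitions \code{(-pi, pi]} into \code{n_bins}
#' equal-width right-closed intervals and returns one bin index per angle.
#' Moving mode returns, for \code{n_bins} equally spaced centres, the logical
#' membership of each angle in the window \code{centre +/- half_width}
#' (circular wrap-around).
#'
#' @param angles angles in radians.
#' @param n_bins number of bins (>= 2).
#' @param half_width window half width in radians; when \code{NULL} (default)
#'   non-overlapping bins are produced.
#' @return non-overlapping: list with \code{bin} (integer vector),
#'   \code{centres}, \code{edges}, \code{n} (counts). Moving: list with
#'   \code{membership} (n x n_bins logical matrix), \code{centres}, \code{n}.
#' @export
bin_by_phase <- function(angles, n_bins, half_width = NULL) {
  if (n_bins < 2L) stop("bin_by_phase: need n_bins >= 2")
  if (is.null(half_width)) {
    w <- wrap_angle_upper(angles)
    edges <- seq(-pi, pi, length.out = n_bins + 1L)
    ## right-closed: bin j is (edges[j], edges[j+1]]
    bin <- findInterval(w, edges, left.open = TRUE, rightmost.closed = FALSE)
    bin[bin == 0L] <- 1L  # w == -pi cannot occur after wrapping, guard anyway
    centres <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
    list(bin = bin, centres = centres, edges = edges,
         n = tabulate(bin, nbins = n_bins))
  } else {
    centres <- -pi + (seq_len(n_bins) - 1L) * 2 * pi / n_bins
    membership <- vapply(centres, function(ct) circ_dist(angles, ct) <= half_width,
                         logical(length(angles)))
    if (is.null(dim(membership))) membership <- matrix(membership, nrow = length(angles))
    list(membership = membership, centres = centres, n = colSums(membership))
  }
}

#' Paired test of circular differences against zero
#'
#' Computes per-pair circular differences \code{wrap(a - b)} and tests whether
#' their mean direction differs from zero with a sign-flip permutation on the
#' statistic \eqn{|\sum \sin d_i|} (under the null of symmetry about zero the
#' sine components are exchangeable in sign). For \code{n < 5} all sign
#' patterns are enumerated.
#'
#' @param angles_a,angles_b paired angle vectors in radians.
#' @param n_perm number of sign-flip permutations.
#' @return list with \code{p}, \code{stat}, \code{mean_diff} (circular mean of
#'   the differences), \code{n}.
#' @export
circ_diff_test <- function(angles_a, angles_b, n_perm = 10000L) {
  ok <- is.finite(angles_a) & is.finite(angles_b)
  d <- wrap_angle(angles_a[ok] - angles_b[ok])
  n <- length(d)
  if (n < 2L) stop("circ_diff_test: need at least 2 pairs")
  s <- sin(d)
  obs <- abs(sum(s))
  if (n < 5L) {
    warning("circ_diff_test: n < 5, enumerating all sign patterns exactly")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- abs(as.vector(signs %*% s))
    p <- mean(null >= obs - 1e-12)
  } else {
    flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n_perm)
    null <- abs(as.vector(flips %*% s))
    p <- (1 + sum(null >= obs - 1e-12)) / (n_perm + 1)
  }
  mu <- atan2(sum(sin(d)), sum(cos(d)))
  list(p = p, stat = obs, mean_diff = mu, n = n)
}
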