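test_that("circular-linear correlation matches the direct formula and detects exact dependence", {
  set.seed(11)
  for (rep in 1:5) {
    theta <- runif(50, -pi, pi)
    x <- rnorm(50)
    res <- circ_linear_corr(theta, x)
    expect_equal(res$rho, oracle_circ_lin(theta, x), tolerance = 1e-12)
  }
  ## exact linear dependence on (sin, cos): rho = 1 for any shift
  for (phi in c(0, 1.1, -2.5)) {
    theta <- runif(40, -pi, pi)
    res <- circ_linear_corr(theta, cos(theta - phi))
    expect_equal(res$rho, 1, tolerance = 1e-8)
    expect_lt(res$p, 1e-6)
  }
  expect_error(circ_linear_corr(runif(10), rep(1, 10)), "constant")
})

test_that("Rayleigh test: concentration, symmetry, rotation invariance", {
  res <- rayleigh_test(rep(1.3, 30))
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-10)
  grid <- seq(-pi, pi - 2 * pi / 24, length.out = 24)
  res_u <- rayleigh_test(grid)
  expect_lt(res_u$z, 1e-20)
  expect_gt(res_u$p, 0.99)
  set.seed(4)
  th <- rnorm(40, 0, 1)
  r1 <- rayleigh_test(th)
  r2 <- rayleigh_test(th + 2.2)
  expect_equal(r1$z, r2$z, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("Hodges-Ajne m matches brute-force rotation scan; p matches closed forms", {
  set.seed(21)
  for (n in c(7, 10, 12)) {
    for (rep in 1:8) {
      th <- runif(n, 0, 2 * pi)
      expect_identical(hodges_ajne_test(th)$m,
                       as.integer(oracle_half_circle_min(th)))
    }
  }
  ## all in one half-circle: m = 0, p = n 2^(1-n) (classic closed form)
  th <- runif(10, 0, pi - 0.1)
  res <- hodges_ajne_test(th)
  expect_identical(res$m, 0L)
  expect_equal(res$p, 10 * 2^(1 - 10), tolerance = 1e-12)
  ## perfectly uniform grid: m = floor(n/2), p about 1
  n <- 20
  grid <- seq(0, 2 * pi - 2 * pi / n, length.out = n)
  res_u <- hodges_ajne_test(grid)
  expect_identical(res_u$m, as.integer(n %/% 2))
  expect_equal(res_u$p, 1)
  ## rotation invariance
  set.seed(5)
  th <- rnorm(25, 1, 0.8)
  expect_identical(hodges_ajne_test(th)$m, hodges_ajne_test(th + 1.7)$m)
})

test_that("Hodges-Ajne tail probability agrees with Monte Carlo under uniformity", {
  set.seed(31)
  n <- 20
  mc <- replicate(20000, oracle_half_circle_min_fast(runif(n, 0, 2 * pi)))
  for (m0 in 3:5) {
    p_mc <- mean(mc <= m0)
    p_formula <- min(1, 2^(1 - n) * (n - 2 * m0) * choose(n, m0))
    expect_lt(abs(p_mc - p_formula), 4 * sqrt(p_formula * (1 - p_formula) / 20000) + 1e-4)
  }
})

test_that("phase regression recovers noiseless sinusoids exactly and is linear in offsets", {
  theta <- seq(-pi, pi, length.out = 37)[-37]
  y <- 2 + 0.5 * cos(theta - pi / 4)
  pr <- phase_regression(theta, y)
  expect_equal(pr$b0, 2, tolerance = 1e-10)
  expect_equal(pr$amplitude, 0.5, tolerance = 1e-10)
  expect_equal(pr$preferred_phase, pi / 4, tolerance = 1e-10)
  pr2 <- phase_regression(theta, y + 3)
  expect_equal(pr2$b0, 5, tolerance = 1e-10)
  expect_equal(pr2$amplitude, pr$amplitude, tolerance = 1e-12)
  ## amplitude shrinks toward zero for phase-independent responses
  set.seed(7)
  amps <- vapply(c(100, 10000), function(n) {
    phase_regression(runif(n, -pi, pi), rnorm(n))$amplitude
  }, numeric(1))
  expect_lt(amps[2], 0.05)
  expect_error(phase_regression(rep(1, 10), rnorm(10)), "rank")
})

test_that("phase binning: widths, edge convention, moving-window membership", {
  b <- bin_by_phase(runif(500, -pi, pi), 30)
  expect_equal(unique(round(diff(b$edges), 12)), round(2 * pi / 30, 12))
  ## right-closed intervals: an angle exactly on an interior edge goes left-bin's right edge
  edge <- b$edges[16]
  bb <- bin_by_phase(c(edge, edge + 1e-9), 30)
  expect_identical(bb$bin, c(15L, 16L))
  ## uniform angles fill bins within Poisson-like bounds
  set.seed(12)
  b2 <- bin_by_phase(runif(3000, -pi, pi), 30)
  expect_true(all(abs(b2$n - 100) < 5 * sqrt(100)))
  ## moving mode: each angle belongs to width/step windows
  mv <- bin_by_phase(runif(200, -pi, pi), 30, half_width = pi / 10)
  expect_true(all(rowSums(mv$membership) == 3))
  expect_equal(sum(mv$n), 200 * 3)
})

test_that("paired circular difference test: null, shift, and von Mises cross-check", {
  set.seed(9)
  a <- runif(30, -pi, pi)
  res_null <- circ_diff_test(a, a)
  expect_gt(res_null$p, 0.99)
  b <- wrap_angle(a - pi / 2 + rnorm(30, 0, 0.3))
  res_shift <- circ_diff_test(a, b)
  expect_lt(res_shift$p, 0.01)
  expect_equal(res_shift$mean_diff, pi / 2, tolerance = 0.3)
  ## concentrated von Mises-like differences: permutation p tracks a t-test
  ## on the sine components (analytic approximation for small dispersion)
  d <- rnorm(40, 0.35, 0.45)
  pa <- circ_diff_test(d, rep(0, 40))$p
  pt <- t.test(sin(d))$p.value
  expect_lt(abs(log10(pa) - log10(pt)), 1)
})

test_that("type-I error calibration of the circular tests", {
  set.seed(77)
  n_rep <- 4000
  ## Rayleigh (continuous p): reject rate within binomial bounds of 0.05
  p_ray <- replicate(n_rep, rayleigh_test(runif(25, -pi, pi))$p)
  rate <- mean(p_ray < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
  ## circular-linear (chi-squared approximation), n = 200
  p_cl <- replicate(n_rep / 4, circ_linear_corr(runif(200, -pi, pi), rnorm(200))$p)
  rate_cl <- mean(p_cl < 0.05)
  expect_lt(abs(rate_cl - 0.05), 4 * sqrt(0.05 * 0.95 / (n_rep / 4)))
})
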