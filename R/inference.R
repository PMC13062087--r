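## Cluster-based permutation statistics, BH-FDR, Gaussian-copula mutual
## information model comparison, and group-level coefficient-threshold
## correlation with cluster correction.

## connected components among selected points; adjacency is a list of integer
## neighbour vectors (chain/grid adjacency built by helpers below)
.cluster_components <- function(selected, adjacency) {
  n <- length(selected)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!selected[i] || comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adjacency[[v]]
      nb <- nb[selected[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

chain_adjacency <- function(n) {
  lapply(seq_len(n), function(i) {
    c(if (i > 1L) i - 1L, if (i < n) i + 1L)
  })
}

grid_adjacency <- function(nr, nc) {
  idx <- function(r, c) (c - 1L) * nr + r
  out <- vector("list", nr * nc)
  for (c in seq_len(nc)) {
    for (r in seq_len(nr)) {
      nb <- integer(0)
      if (r > 1L) nb <- c(nb, idx(r - 1L, c))
      if (r < nr) nb <- c(nb, idx(r + 1L, c))
      if (c > 1L) nb <- c(nb, idx(r, c - 1L))
      if (c < nc) nb <- c(nb, idx(r, c + 1L))
      out[[idx(r, c)]] <- nb
    }
  }
  out
}

## max summed-|t| cluster statistic for one t map (clusters sign-consistent)
.max_cluster_stat <- function(tv, thresh, adjacency) {
  best <- 0
  for (sgn in c(1, -1)) {
    sel <- (sgn * tv) > thresh
    if (!any(sel)) next
    comp <- .cluster_components(sel, adjacency)
    if (max(comp) == 0L) next
    sums <- vapply(seq_len(max(comp)), function(k) sum(abs(tv[comp == k])),
                   numeric(1))
    best <- max(best, sums)
  }
  best
}

#' Cluster-based permutation test
#'
#' Paired (or one-sample against zero) test across participants over a vector
#' or matrix of features (e.g. frequencies, frequency x time). Per feature a
#' two-tailed t-statistic is thresholded at \code{alpha}; adjacent
#' suprathreshold points of the same sign form clusters whose statistic is
#' the sum of absolute t-values. The null distribution collects the maximal
#' cluster statistic over sign-flip permutations of the (paired) differences,
#' re-thresholding and re-clustering each time. Raw permutation p-values are
#' returned per cluster; the significance flag additionally applies the
#' percentile rule \code{stat > quantile(null, cluster_quantile)} (default
#' the 97.5th percentile).
#'
#' @param x participants x features matrix (or 3-d array participants x f x
#'   t) of condition A (or the quantity tested against zero).
#' @param y optional matched array for condition B (paired design).
#' @param adjacency optional adjacency list over features; defaults to chain
#'   (vector features) or 4-neighbour grid (matrix features).
#' @param n_perm number of permutations.
#' @param alpha point-wise two-tailed threshold.
#' @param cluster_quantile percentile of the null used for the significance
#'   flag.
#' @return object of class \code{cluster_result}: list with \code{t}
#'   (feature-shaped), \code{clusters} (list of index vectors), \code{stat},
#'   \code{p} (raw permutation p per cluster), \code{sig} (percentile rule),
#'   \code{sig_mask} (feature-shaped logical), \code{null_quantile},
#'   \code{n_perm}.
#' @export
cluster_perm_test <- function(x, y = NULL, adjacency = NULL, n_perm = 5000L,
                              alpha = 0.05, cluster_quantile = 0.975) {
  xd <- if (is.null(dim(x))) matrix(x, ncol = 1) else x
  shape <- dim(xd)[-1]
  n_sub <- dim(xd)[1]
  if (n_sub < 2L) stop("cluster_perm_test: need at least 2 participants")
  d <- matrix(xd, nrow = n_sub)          # flatten features
  if (!is.null(y)) {
    yd <- if (is.null(dim(y))) matrix(y, ncol = 1) else y
    stopifnot(all(dim(yd) == dim(xd)))
    d <- d - matrix(yd, nrow = n_sub)
  }
  nf <- ncol(d)
  if (is.null(adjacency)) {
    adjacency <- if (length(shape) <= 1L) chain_adjacency(nf) else
      grid_adjacency(shape[1], shape[2])
  }
  tcrit <- stats::qt(1 - alpha / 2, df = n_sub - 1L)
  col_t <- function(m) {
    mu <- colMeans(m)
    sd <- sqrt((colSums(m^2) - n_sub * mu^2) / (n_sub - 1L))
    mu / (sd / sqrt(n_sub))
  }
  tv <- col_t(d)
  tv[!is.finite(tv)] <- 0
  ## observed clusters (sign-consistent)
  clusters <- list(); stats_obs <- numeric(0)
  for (sgn in c(1, -1)) {
    sel <- (sgn * tv) > tcrit
    if (!any(sel)) next
    comp <- .cluster_components(sel, adjacency)
    for (k in seq_len(max(comp))) {
      ix <- which(comp == k)
      clusters[[length(clusters) + 1L]] <- ix
      stats_obs <- c(stats_obs, sum(abs(tv[ix])))
    }
  }
  if (n_perm < 1 / alpha) {
    warning("cluster_perm_test: n_perm too small to resolve alpha", call. = FALSE)
  }
  ## vectorized sign-flip permutations: column sums of flipped rows
  sq <- colSums(d^2)
  signs <- matrix(sample(c(-1, 1), n_sub * n_perm, replace = TRUE), n_perm, n_sub)
  mu_p <- (signs %*% d) / n_sub
  null <- numeric(n_perm)
  for (pp in seq_len(n_perm)) {
    sd_p <- sqrt(pmax(sq - n_sub * mu_p[pp, ]^2, 0) / (n_sub - 1L))
    tp <- mu_p[pp, ] / (sd_p / sqrt(n_sub))
    tp[!is.finite(tp)] <- 0
    null[pp] <- .max_cluster_stat(tp, tcrit, adjacency)
  }
  qthr <- stats::quantile(null, cluster_quantile, names = FALSE)
  pvals <- vapply(stats_obs, function(s) (1 + sum(null >= s)) / (n_perm + 1),
                  numeric(1))
  sig <- stats_obs > qthr
  mask <- rep(FALSE, nf)
  for (k in seq_along(clusters)) if (sig[k]) mask[clusters[[k]]] <- TRUE
  dim_t <- if (length(shape) > 1L) shape else NULL
  if (!is.null(dim_t)) { dim(tv) <- dim_t; dim(mask) <- dim_t }
  structure(list(t = tv, clusters = clusters, stat = stats_obs, p = pvals,
                 sig = sig, sig_mask = mask, null_quantile = qthr,
                 threshold = tcrit, n_perm = n_perm),
            class = "cluster_result")
}

#' Benjamini-Hochberg FDR mask
#'
#' @param pvals p-values.
#' @param q FDR level.
#' @return list with \code{mask} (logical), \code{p_adj}.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(mask = !is.na(p_adj) & p_adj <= q, p_adj = p_adj)
}

## Gaussian-copula MI between a predictor matrix and a binary outcome (bits).
## Continuous columns are rank-copula transformed to normal scores; entropies
## use the Gaussian formula. Constant / linearly dependent columns dropped.
gcmi_discrete <- function(X, y, copula_cols = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("gcmi: constant predictor(s) dropped", call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  if (!ncol(X)) return(0)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    ix <- qrX$pivot[seq_len(qrX$rank)]
    ix <- sort(ix[ix > 1L] - 1L)
    X <- X[, ix, drop = FALSE]
  }
  if (is.null(copula_cols)) {
    copula_cols <- which(apply(X, 2, function(col) length(unique(col)) > 8L))
  }
  for (j in copula_cols) {
    X[, j] <- stats::qnorm(rank(X[, j], ties.method = "average") / (n + 1))
  }
  dgauss_ent <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    S <- crossprod(M) / (nrow(M) - 1L)
    ld <- determinant(S, logarithm = TRUE)
    if (ld$sign <= 0) return(NA_real_)
    0.5 * (as.numeric(ld$modulus) + ncol(M) * log(2 * pi * exp(1))) / log(2)
  }
  hx <- dgauss_ent(X)
  classes <- unique(y)
  hcond <- 0
  for (cl in classes) {
    sel <- y == cl
    if (sum(sel) < ncol(X) + 2L) return(NA_real_)
    hcond <- hcond + mean(sel) * dgauss_ent(X[sel, , drop = FALSE])
  }
  hx - hcond
}

#' Mutual-information model comparison
#'
#' Quantifies, per participant, how much a set of added predictors improves
#' the prediction of a binary outcome beyond a base predictor set, using
#' Gaussian-copula mutual information with a discrete target. Estimator bias
#' is removed by subtracting the mean MI over shuffled-outcome surrogates
#' (floored at zero); the group-level test is a two-sided one-sample t of the
#' per-participant MI increments against zero.
#'
#' @param data list of per-participant data.frames.
#' @param outcome name of the logical/binary outcome column.
#' @param base character vector of base predictor columns.
#' @param added character vector of additional predictor columns.
#' @param n_shuffle surrogates for the bias correction.
#' @param seed RNG seed for the surrogates.
#' @return list with \code{delta_mi} (bits, per participant), \code{mi_base},
#'   \code{mi_full}, \code{t}, \code{p}, \code{df}.
#' @export
mi_model_compare <- function(data, outcome = "hit", base, added,
                             n_shuffle = 50L, seed = 1L) {
  if (is.data.frame(data)) data <- list(data)
  set.seed(derive_seed(seed, 97L))
  corrected_mi <- function(df, cols) {
    y <- as.integer(df[[outcome]])
    X <- as.matrix(df[, cols, drop = FALSE])
    keep <- apply(X, 2, function(col) stats::sd(col) > 0)
    if (!all(keep)) {
      warning("mi_model_compare: constant predictor(s) dropped", call. = FALSE)
      X <- X[, keep, drop = FALSE]
    }
    mi <- suppressWarnings(gcmi_discrete(X, y))
    if (!is.finite(mi)) return(NA_real_)
    bias <- mean(vapply(seq_len(n_shuffle), function(i) {
      suppressWarnings(gcmi_discrete(X, sample(y)))
    }, numeric(1)), na.rm = TRUE)
    max(mi - bias, 0)
  }
  mi_base <- vapply(data, corrected_mi, numeric(1), cols = base)
  mi_full <- vapply(data, corrected_mi, numeric(1), cols = c(base, added))
  delta <- mi_full - mi_base
  if (length(delta) >= 2L && stats::sd(delta, na.rm = TRUE) > 0) {
    tt <- stats::t.test(delta)
    t_stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
  } else {
    t_stat <- NA_real_; p <- NA_real_; df <- NA_real_
  }
  list(delta_mi = delta, mi_base = mi_base, mi_full = mi_full,
       t = t_stat, p = p, df = df)
}

#' Group correlation of coefficient spectra with behavioural thresholds
#'
#' Correlates, per frequency, a first-level coefficient spectrum (e.g. the
#' respiration phase-modulation magnitude of power or GC) with a behavioural
#' scalar (e.g. psychometric threshold) across participants, and corrects
#' over frequency with a cluster permutation that shuffles the participant
#' pairing.
#'
#' @param coefs participants x frequency matrix.
#' @param behav behavioural scalar per participant.
#' @param method "spearman" (default) or "pearson".
#' @param n_perm permutations.
#' @param alpha point-wise threshold.
#' @param cluster_quantile percentile for the significance flag.
#' @return \code{cluster_result}-style list with per-frequency \code{r} and
#'   \code{t}, clusters, raw permutation p-values and significance flags.
#' @export
coeff_threshold_correlation <- function(coefs, behav,
                                        method = c("spearman", "pearson"),
                                        n_perm = 2000L, alpha = 0.05,
                                        cluster_quantile = 0.975) {
  method <- match.arg(method)
  coefs <- as.matrix(coefs)
  n <- nrow(coefs)
  if (n < 5L) stop("coeff_threshold_correlation: need at least 5 participants")
  stopifnot(length(behav) == n)
  const_cols <- apply(coefs, 2, function(col) stats::sd(col, na.rm = TRUE) == 0)
  if (any(const_cols)) {
    message(sprintf("coeff_threshold_correlation: %d constant coefficient column(s) excluded",
                    sum(const_cols)))
  }
  nf <- ncol(coefs)
  adjacency <- chain_adjacency(nf)
  r_of <- function(b) {
    r <- suppressWarnings(stats::cor(coefs, b, method = method,
                                     use = "pairwise.complete.obs"))
    r <- as.vector(r)
    r[const_cols] <- NA
    r
  }
  t_of <- function(r) {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    tt[!is.finite(tt)] <- 0
    tt
  }
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2L)
  r_obs <- r_of(behav)
  tv <- t_of(r_obs)
  clusters <- list(); stats_obs <- numeric(0)
  for (sgn in c(1, -1)) {
    sel <- (sgn * tv) > tcrit
    if (!any(sel)) next
    comp <- .cluster_components(sel, adjacency)
    for (k in seq_len(max(comp))) {
      ix <- which(comp == k)
      clusters[[length(clusters) + 1L]] <- ix
      stats_obs <- c(stats_obs, sum(abs(tv[ix])))
    }
  }
  null <- vapply(seq_len(n_perm), function(i) {
    .max_cluster_stat(t_of(r_of(sample(behav))), tcrit, adjacency)
  }, numeric(1))
  qthr <- stats::quantile(null, cluster_quantile, names = FALSE)
  pvals <- vapply(stats_obs, function(s) (1 + sum(null >= s)) / (n_perm + 1),
                  numeric(1))
  sig <- stats_obs > qthr
  mask <- rep(FALSE, nf)
  for (k in seq_along(clusters)) if (sig[k]) mask[clusters[[k]]] <- TRUE
  structure(list(r = r_obs, t = tv, clusters = clusters, stat = stats_obs,
                 p = pvals, sig = sig, sig_mask = mask, null_quantile = qthr,
                 threshold = tcrit, n_perm = n_perm),
            class = "cluster_result")
}
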