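#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over transcripts (with
#' strictly positive counts in every sample) of the ratio of the sample's
#' count to the transcript's geometric mean across samples. This is the
#' standard normalization for NB GLM differential expression with the
#' `s_j * q_ij` mean decomposition.
#'
#' @param counts a [count_matrix()] or bare count matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  m <- if (is_count_matrix(counts)) counts$counts else as.matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no transcript has strictly positive counts in all samples; ",
         "size factors are undefined")
  lm_ <- log(m[pos, , drop = FALSE])
  loggeo <- rowMeans(lm_)
  s <- exp(apply(lm_ - loggeo, 2L, stats::median))
  stats::setNames(s, colnames(m))
}

#' Negative-binomial log-likelihood
#'
#' Sum of NB log-probabilities under the mean/dispersion parameterization
#' `Var = mu + alpha * mu^2`. Continuous in `alpha` with the Poisson
#' log-likelihood as the `alpha -> 0` limit. Optional per-observation
#' weights multiply the individual log-probability contributions.
#'
#' @param y non-negative integer counts.
#' @param mu positive means, recycled against `y`.
#' @param alpha dispersion, a single value >= 0.
#' @param weights optional non-negative per-observation weights.
#' @return The (weighted) log-likelihood, a single number.
#' @export
nb_loglik <- function(y, mu, alpha, weights = NULL) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("alpha must be a single non-negative number")
  if (any(mu <= 0)) stop("mu must be positive")
  lp <- if (alpha < 1e-12) {
    stats::dpois(y, mu, log = TRUE)
  } else {
    stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)
  }
  if (is.null(weights)) sum(lp) else sum(weights * lp)
}

#' Design matrix for a two-group comparison
#'
#' Intercept plus a 0/1 indicator for the second group level.
#'
#' @param groups factor (or coercible) of group labels with two levels.
#' @return List with `X` (n x 2 design matrix) and `coef_names`.
#' @export
design_two_group <- function(groups) {
  g <- factor(as.character(groups))
  if (nlevels(g) != 2L) stop("exactly two groups required")
  X <- cbind(intercept = 1, group = as.numeric(g == levels(g)[2L]))
  list(X = X, coef_names = c("intercept",
                             paste0("group_", levels(g)[2L])))
}

#' Fit a negative-binomial GLM with log link by IRLS
#'
#' Maximizes the (optionally observation-weighted) NB log-likelihood for a
#' single transcript over the coefficients of a full-rank design matrix,
#' with per-sample offsets, by iteratively reweighted least squares with
#' step-halving on likelihood decrease. Coefficients are on the natural-log
#' scale; the coefficient covariance is the inverse of the weighted Fisher
#' information at the optimum.
#'
#' @param y non-negative integer counts, one per sample.
#' @param design a design list from [design_two_group()] or a bare matrix.
#' @param offsets per-sample offsets on the log scale (default 0).
#' @param alpha NB dispersion (>= 0; 0 is the Poisson limit).
#' @param weights optional per-observation weights in (0, 1].
#' @param max_iter,tol IRLS controls: stop when the relative coefficient
#'   change drops below `tol` (default 1e-8) or after `max_iter` iterations.
#' @return List of class `nb_glm_fit`: `beta`, `cov_beta`, `mu`, `loglik`,
#'   `converged`, `weights_used`, `boundary` (TRUE when the fit ran into
#'   the essentially-zero-mean boundary).
#' @export
fit_nb_glm <- function(y, design, offsets = 0, alpha = 0, weights = NULL,
                       max_iter = 100L, tol = 1e-8) {
  X <- if (is.list(design)) design$X else as.matrix(design)
  n <- length(y)
  stopifnot(nrow(X) == n)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is not full column rank")
  if (alpha < 0) stop("alpha must be >= 0")
  offsets <- rep_len(offsets, n)
  w_obs <- if (is.null(weights)) rep(1, n) else weights
  if (any(w_obs <= 0)) stop("observation weights must be positive")

  mu0 <- pmax(y, 0.5)
  eta <- log(mu0) - offsets
  beta <- qr.solve(qr(X * sqrt(w_obs)), sqrt(w_obs) * eta)
  mu <- pmax(exp(drop(X %*% beta) + offsets), 1e-10)
  ll <- nb_loglik(y, mu, alpha, w_obs)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wf <- w_obs * mu / (1 + alpha * mu)        # Fisher working weights
    z <- drop(X %*% beta) + (y - mu) / mu      # working response (eta scale)
    fit <- stats::lm.wfit(X, z, wf)
    beta_new <- fit$coefficients
    step <- beta_new - beta
    # step-halving if the likelihood decreases
    for (h in 0:10) {
      cand <- beta + step / 2^h
      mu_c <- pmax(exp(drop(X %*% cand) + offsets), 1e-10)
      ll_c <- nb_loglik(y, mu_c, alpha, w_obs)
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) break
    }
    rel <- max(abs(cand - beta)) / max(1, max(abs(beta)))
    beta <- cand; mu <- mu_c; ll <- ll_c
    if (rel < tol) { converged <- TRUE; break }
  }
  wf <- w_obs * mu / (1 + alpha * mu)
  info <- crossprod(X, X * wf)
  cov_beta <- tryCatch(solve(info), error = function(e) {
    matrix(Inf, p, p)
  })
  boundary <- any(mu <= 1e-9) || max(abs(beta)) > 25
  structure(list(beta = beta, cov_beta = cov_beta, mu = mu, loglik = ll,
                 converged = converged, weights_used = w_obs,
                 boundary = boundary),
            class = "nb_glm_fit")
}

#' Wald test p-value
#'
#' Two-sided normal-approximation p-value `2 * (1 - Phi(|beta / se|))`.
#' An infinite standard error gives p = 1 (no information against the
#' null); a non-positive or non-finite-NA standard error gives `NA`.
#'
#' @param beta_hat estimate(s).
#' @param se standard error(s), positive.
#' @return p-value(s) in [0, 1], vectorized.
#' @export
wald_test <- function(beta_hat, se) {
  p <- 2 * stats::pnorm(-abs(beta_hat / se))
  p[!is.na(se) & is.infinite(se)] <- 1
  p[is.na(se) | se <= 0] <- NA_real_
  p
}

#' Likelihood-ratio test p-value
#'
#' Upper-tail chi-square p-value for `Lambda = 2 * (ll_full - ll_reduced)`.
#' Small negative `Lambda` from numerical slack (>= -1e-6) is clamped to 0;
#' larger violations of nesting raise an error.
#'
#' @param loglik_full,loglik_reduced log-likelihoods of the nested fits.
#' @param df degrees of freedom (positive integer).
#' @return p-value(s) in [0, 1], vectorized over the log-likelihood pairs.
#' @export
lrt_test <- function(loglik_full, loglik_reduced, df = 1L) {
  if (df <= 0) stop("df must be positive")
  lam <- 2 * (loglik_full - loglik_reduced)
  if (any(lam < -1e-6, na.rm = TRUE))
    stop("loglik_full < loglik_reduced beyond numerical slack; not nested?")
  lam <- pmax(lam, 0)
  stats::pchisq(lam, df = df, lower.tail = FALSE)
}
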