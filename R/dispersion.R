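#' Genewise dispersion by Cox-Reid adjusted profile likelihood
#'
#' Maximizes, over `alpha` in `[1e-8, 10]`, the NB log-likelihood at the
#' IRLS-fitted means minus the Cox-Reid adjustment
#' `0.5 * log det(X' W X)`, which corrects the profile likelihood for the
#' estimation of the mean parameters.
#'
#' @param y non-negative integer counts, one per sample.
#' @param design design list from [design_two_group()] or a matrix.
#' @param offsets per-sample log-scale offsets.
#' @param weights optional observation weights.
#' @return The dispersion estimate (single number), or `NA` with a warning
#'   for an all-zero transcript (assign the trend value downstream).
#' @export
estimate_genewise_dispersion <- function(y, design, offsets = 0,
                                         weights = NULL) {
  if (all(y == 0)) {
    warning("all-zero transcript: genewise dispersion undefined")
    return(NA_real_)
  }
  X <- if (is.list(design)) design$X else as.matrix(design)
  if (length(y) - ncol(X) < 1L) stop("no residual degrees of freedom")
  obj <- function(log_alpha) {
    a <- exp(log_alpha)
    fit <- fit_nb_glm(y, X, offsets = offsets, alpha = a, weights = weights)
    wf <- fit$weights_used * fit$mu / (1 + a * fit$mu)
    fit$loglik - 0.5 * determinant(crossprod(X, X * wf))$modulus[1]
  }
  opt <- stats::optimize(obj, interval = log(c(1e-8, 10)),
                         maximum = TRUE, tol = 1e-6)
  exp(opt$maximum)
}

# Vectorized genewise CR-APL dispersion for a two-group design.
# Returns NA for all-zero rows.
genewise_dispersion_matrix <- function(Y, gmask, O, w = NULL) {
  G <- nrow(Y)
  out <- rep(NA_real_, G)
  use <- rowSums(Y) > 0
  if (!any(use)) return(out)
  Yu <- Y[use, , drop = FALSE]
  wu <- if (is.null(w)) NULL else w[use, , drop = FALSE]
  Ou <- if (is.matrix(O)) O[use, , drop = FALSE] else O
  obj <- make_crapl_objfun(Yu, gmask, Ou, wu)
  out[use] <- disp_argmax(obj, sum(use), lo = 1e-8, hi = 10)
  out
}

#' Parametric dispersion trend
#'
#' Fits the trend `alpha_tr(mu) = a0 + a1 / mu` to genewise dispersion
#' estimates by a Gamma-family GLM with identity link on `1/mu`, with a
#' second pass that drops gross outliers (ratio to the first-pass trend
#' outside `[1e-4, 15]`) before refitting. Coefficients are constrained
#' non-negative. With fewer than 10 usable transcripts the trend falls back
#' to a flat median dispersion with a warning.
#'
#' @param means per-transcript mean normalized counts.
#' @param genewise per-transcript dispersion estimates (NA allowed).
#' @param mean_floor transcripts with mean below this are excluded from the
#'   fit (default 0.5).
#' @return Named numeric `c(a0, a1)`.
#' @export
fit_dispersion_trend <- function(means, genewise, mean_floor = 0.5) {
  use <- is.finite(means) & is.finite(genewise) &
    means > mean_floor & genewise > 0
  fallback <- function(msg) {
    warning("dispersion trend: ", msg, "; using flat median dispersion")
    med <- stats::median(genewise[is.finite(genewise) & genewise > 0])
    if (!is.finite(med)) med <- 0.1
    c(a0 = med, a1 = 0)
  }
  if (sum(use) < 10L) return(fallback("fewer than 10 usable transcripts"))

  fit_pass <- function(sel) {
    d <- genewise[sel]; x <- 1 / means[sel]
    co <- tryCatch({
      f <- stats::glm(d ~ x, family = stats::Gamma(link = "identity"),
                      start = c(stats::median(d), 0.1),
                      control = list(maxit = 100))
      stats::coef(f)
    }, error = function(e) NULL, warning = function(wn) {
      tryCatch(stats::coef(suppressWarnings(
        stats::glm(d ~ x, family = stats::Gamma(link = "identity"),
                   start = c(stats::median(d), 0.1),
                   control = list(maxit = 100)))),
        error = function(e) NULL)
    })
    if (is.null(co) || anyNA(co)) {
      # least-squares fallback on the same parametric form
      co <- stats::coef(stats::lm(d ~ x))
    }
    co
  }
  co <- fit_pass(use)
  trend <- pmax(co[1], 0) + pmax(co[2], 0) / means
  ratio <- genewise / pmax(trend, 1e-12)
  keep <- use & ratio > 1e-4 & ratio < 15
  if (sum(keep) >= 10L) co <- fit_pass(keep)
  a0 <- max(co[1], 0); a1 <- max(co[2], 0)
  if (a0 + a1 <= 0) return(fallback("degenerate non-positive trend"))
  c(a0 = unname(a0), a1 = unname(a1))
}

#' Variance of the log-dispersion prior
#'
#' The spread of `log(genewise) - log(trend)` in excess of the expected
#' sampling variance of a log dispersion estimate, `trigamma((n - p) / 2)`,
#' floored at 0.25.
#'
#' @param genewise,trend per-transcript genewise and trend dispersions.
#' @param n_samples,n_coef sample count and number of design coefficients.
#' @return A single non-negative prior variance.
#' @export
estimate_prior_var_logdisp <- function(genewise, trend, n_samples, n_coef) {
  use <- is.finite(genewise) & is.finite(trend) & genewise > 0 & trend > 0
  if (sum(use) < 3L) return(0.25)
  v <- stats::var(log(genewise[use]) - log(trend[use]))
  max(v - trigamma((n_samples - n_coef) / 2), 0.25)
}

#' Maximum a-posteriori dispersion
#'
#' Shrinks a genewise dispersion toward its trend value by maximizing the
#' Cox-Reid adjusted profile log-likelihood plus a log-normal prior centered
#' at `log(trend_value)` with variance `prior_var_logdisp`. The result lies
#' between the genewise estimate and the trend on the log scale.
#'
#' @param genewise genewise dispersion estimate (NA for an all-zero
#'   transcript, in which case the trend value is returned).
#' @param trend_value trend dispersion at the transcript's mean (> 0).
#' @param prior_var_logdisp prior variance of the log dispersion.
#' @param y,design,offsets,weights as in [estimate_genewise_dispersion()].
#' @return The moderated dispersion (single number).
#' @export
map_dispersion <- function(genewise, trend_value, prior_var_logdisp,
                           y, design, offsets = 0, weights = NULL) {
  if (trend_value <= 0) stop("trend_value must be > 0")
  if (is.na(genewise) || all(y == 0)) return(trend_value)
  X <- if (is.list(design)) design$X else as.matrix(design)
  obj <- function(log_alpha) {
    a <- exp(log_alpha)
    fit <- fit_nb_glm(y, X, offsets = offsets, alpha = a, weights = weights)
    wf <- fit$weights_used * fit$mu / (1 + a * fit$mu)
    fit$loglik - 0.5 * determinant(crossprod(X, X * wf))$modulus[1] -
      (log_alpha - log(trend_value))^2 / (2 * prior_var_logdisp)
  }
  opt <- stats::optimize(obj, interval = log(c(1e-8, 10)),
                         maximum = TRUE, tol = 1e-6)
  exp(opt$maximum)
}

# Vectorized MAP dispersion: CR-APL plus log-normal prior on a per-transcript
# trend. All-zero rows get their trend value.
map_dispersion_matrix <- function(Y, gmask, O, trend, prior_var, w = NULL) {
  G <- nrow(Y)
  out <- trend
  use <- rowSums(Y) > 0
  if (!any(use)) return(out)
  Yu <- Y[use, , drop = FALSE]
  wu <- if (is.null(w)) NULL else w[use, , drop = FALSE]
  Ou <- if (is.matrix(O)) O[use, , drop = FALSE] else O
  lt <- log(trend[use])
  crapl <- make_crapl_objfun(Yu, gmask, Ou, wu)
  obj <- function(alpha) {
    crapl(alpha) - (log(alpha) - lt)^2 / (2 * prior_var)
  }
  out[use] <- disp_argmax(obj, sum(use), lo = 1e-8, hi = 10)
  out
}

#' Empirical-Bayes shrinkage of log fold changes
#'
#' Under a zero-centered normal prior on the LFC and a quadratic
#' approximation to the likelihood, the maximum a-posteriori estimate is the
#' ridge form `lfc * prior_sd^2 / (prior_sd^2 + se^2)` with posterior
#' standard error `se * prior_sd / sqrt(prior_sd^2 + se^2)`: the less
#' information (larger `se`), the stronger the pull toward zero.
#' Transcripts with infinite `se` pass through with a final LFC of 0.
#'
#' @param lfc_mle maximum-likelihood log2 fold changes.
#' @param se their standard errors (log2 scale; `Inf` allowed).
#' @param prior_sd prior standard deviation (log2 scale), e.g. from
#'   [estimate_lfc_prior_sd()].
#' @return List with `lfc_final` and `se_final`.
#' @export
shrink_lfc <- function(lfc_mle, se, prior_sd) {
  if (prior_sd <= 0) stop("prior_sd must be positive")
  bad <- !is.finite(se) | se <= 0
  shrink <- prior_sd^2 / (prior_sd^2 + se^2)
  lfc_final <- ifelse(bad, 0, lfc_mle * shrink)
  se_final <- ifelse(bad, Inf, se * prior_sd / sqrt(prior_sd^2 + se^2))
  list(lfc_final = lfc_final, se_final = se_final)
}

#' Prior standard deviation for LFC shrinkage
#'
#' Chosen globally so that the 0.95 quantile of `|lfc|` under the prior
#' matches the observed 0.95 quantile of the finite-SE maximum-likelihood
#' LFCs, floored at 0.1 log2 units.
#'
#' @param lfc_mle maximum-likelihood log2 fold changes.
#' @param se their standard errors.
#' @return A single positive prior standard deviation (log2 scale).
#' @export
estimate_lfc_prior_sd <- function(lfc_mle, se) {
  ok <- is.finite(lfc_mle) & is.finite(se) & se > 0
  if (!any(ok)) {
    warning("no finite-SE transcripts; LFC prior sd set to the 0.1 floor")
    return(0.1)
  }
  q <- stats::quantile(abs(lfc_mle[ok]), 0.95, names = FALSE)
  max(q / stats::qnorm(0.975), 0.1)
}

#' Huber observation weights from Pearson residuals
#'
#' `r = (y - mu) / sqrt(mu + alpha * mu^2)`; weight 1 for `|r| <= k`, else
#' `k / |r|`. Observations that deviate strongly from the model fit are
#' down-weighted; weights are always in (0, 1].
#'
#' @param y counts (vector or matrix).
#' @param mu fitted means (same shape).
#' @param alpha dispersion (scalar or per-transcript vector for matrices).
#' @param k Huber tuning constant; 1.345 is the standard 95%-efficiency
#'   choice.
#' @return Weights with the same shape as `y`.
#' @export
observation_weights <- function(y, mu, alpha, k = 1.345) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(alpha < 0)) stop("alpha must be >= 0")
  r <- (y - mu) / sqrt(mu + alpha * mu^2)
  w <- ifelse(abs(r) <= k, 1, k / abs(r))
  if (is.matrix(y)) w <- matrix(w, nrow = nrow(y), dimnames = dimnames(y))
  w
}
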