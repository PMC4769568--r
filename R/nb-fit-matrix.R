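# Internal matrix-level NB GLM machinery.
#
# The engines fit thousands of transcripts at once, so the two-group IRLS is
# vectorized across transcripts: the saturated two-parameter design
# [intercept, group] lets each IRLS update reduce to weighted means of the
# working response within each group. `alpha` may be a per-transcript vector
# (recycled down columns of G x S matrices). All of this is internal; the
# documented scalar path is fit_nb_glm().

# eta matrix for (b0, b1) on a 0/1 group mask
two_group_eta <- function(b0, b1, gmask) {
  G <- length(b0)
  matrix(b0, G, length(gmask)) +
    b1 %o% as.numeric(gmask)
}

# Row-wise NB log-likelihood; alpha is a per-transcript vector.
nb_ll_rows <- function(Y, mu, alpha, w = NULL) {
  size <- 1 / pmax(alpha, 1e-12)
  lp <- stats::dnbinom(Y, size = size, mu = mu, log = TRUE)
  if (!is.null(w)) lp <- w * lp
  rowSums(lp)
}

# Vectorized IRLS for the two-group NB GLM with log link and offsets.
# Y: G x S counts; gmask: logical length S (TRUE = group B); O: offset matrix
# (G x S) or per-sample vector; alpha: per-transcript dispersion; w: optional
# G x S observation weights. Returns coefficients on the natural-log scale.
nbglm_irls_two_group <- function(Y, gmask, O, alpha, w = NULL,
                                 init = NULL, maxit = 60L, tol = 1e-8) {
  G <- nrow(Y); S <- ncol(Y)
  if (!is.matrix(O)) O <- matrix(O, G, S, byrow = TRUE)
  eO <- exp(O)
  Yn <- Y / eO
  selA <- !gmask; selB <- gmask
  if (is.null(init)) {
    mA <- rowMeans(Yn[, selA, drop = FALSE])
    mB <- rowMeans(Yn[, selB, drop = FALSE])
    b0 <- log(pmax(mA, 1e-8))
    b1 <- log(pmax(mB, 1e-8)) - b0
  } else {
    b0 <- init$b0; b1 <- init$b1
  }
  last_change <- rep(Inf, G)
  for (it in seq_len(maxit)) {
    eta <- two_group_eta(b0, b1, gmask)
    mu <- pmin(pmax(exp(eta + O), 1e-10), 1e14)
    wf <- mu / (1 + alpha * mu)
    if (!is.null(w)) wf <- w * wf
    z <- eta + (Y - mu) / mu
    wz <- wf * z
    SwA <- rowSums(wf[, selA, drop = FALSE])
    SwB <- rowSums(wf[, selB, drop = FALSE])
    SzA <- rowSums(wz[, selA, drop = FALSE])
    SzB <- rowSums(wz[, selB, drop = FALSE])
    b0n <- SzA / pmax(SwA, 1e-12)
    bBn <- SzB / pmax(SwB, 1e-12)
    b0n <- pmin(pmax(b0n, -50), 50)
    bBn <- pmin(pmax(bBn, -50), 50)
    b1n <- bBn - b0n
    d0 <- pmin(pmax(b0n - b0, -10), 10)
    d1 <- pmin(pmax(b1n - b1, -10), 10)
    b0 <- b0 + d0; b1 <- b1 + d1
    last_change <- pmax(abs(d0), abs(d1)) / pmax(1, pmax(abs(b0), abs(b1)))
    if (max(last_change) < tol) break
  }
  eta <- two_group_eta(b0, b1, gmask)
  mu <- pmin(pmax(exp(eta + O), 1e-10), 1e14)
  wf <- mu / (1 + alpha * mu)
  if (!is.null(w)) wf <- w * wf
  SwA <- rowSums(wf[, selA, drop = FALSE])
  SwB <- rowSums(wf[, selB, drop = FALSE])
  list(b0 = b0, b1 = b1, mu = mu,
       SwA = SwA, SwB = SwB,
       se_b1 = sqrt(1 / pmax(SwA, 1e-300) + 1 / pmax(SwB, 1e-300)),
       ll = nb_ll_rows(Y, mu, alpha, w),
       converged = last_change < tol)
}

# Intercept-only (reduced model) IRLS, same conventions.
nbglm_irls_null <- function(Y, O, alpha, w = NULL, maxit = 60L, tol = 1e-8) {
  G <- nrow(Y); S <- ncol(Y)
  if (!is.matrix(O)) O <- matrix(O, G, S, byrow = TRUE)
  b0 <- log(pmax(rowMeans(Y / exp(O)), 1e-8))
  for (it in seq_len(maxit)) {
    mu <- pmin(pmax(exp(b0 + O), 1e-10), 1e14)
    wf <- mu / (1 + alpha * mu)
    if (!is.null(w)) wf <- w * wf
    z <- (b0 + (Y - mu) / mu)
    b0n <- rowSums(wf * z) / pmax(rowSums(wf), 1e-12)
    b0n <- pmin(pmax(b0n, -50), 50)
    d <- pmin(pmax(b0n - b0, -10), 10)
    b0 <- b0 + d
    if (max(abs(d) / pmax(1, abs(b0))) < tol) break
  }
  mu <- pmin(pmax(exp(b0 + O), 1e-10), 1e14)
  wf <- mu / (1 + alpha * mu)
  if (!is.null(w)) wf <- w * wf
  list(b0 = b0, mu = mu, Sw = rowSums(wf),
       ll = nb_ll_rows(Y, mu, alpha, w))
}

# Maximize a per-transcript objective over dispersion on [lo, hi] by a
# coarse log-spaced grid, a local fine grid, and a final three-point
# quadratic vertex step. `objfun(alpha_vec)` must return one objective value
# per transcript when given one alpha per transcript.
disp_argmax <- function(objfun, G, lo = 1e-6, hi = 30, coarse_n = 13L) {
  lg <- seq(log(lo), log(hi), length.out = coarse_n)
  M <- vapply(lg, function(la) objfun(rep(exp(la), G)), numeric(G))
  if (G == 1L) M <- matrix(M, nrow = 1L)
  centre <- lg[max.col(M, ties.method = "first")]
  step <- lg[2L] - lg[1L]
  offs <- seq(-step, step, length.out = 9L)
  Mf <- vapply(offs, function(d) objfun(exp(pmin(pmax(centre + d, log(lo)),
                                                 log(hi)))), numeric(G))
  if (G == 1L) Mf <- matrix(Mf, nrow = 1L)
  centre <- pmin(pmax(centre + offs[max.col(Mf, ties.method = "first")],
                      log(lo)), log(hi))
  for (h in c(0.02, 0.002)) {
    f0 <- objfun(exp(centre))
    fp <- objfun(exp(pmin(centre + h, log(hi))))
    fm <- objfun(exp(pmax(centre - h, log(lo))))
    denom <- fm - 2 * f0 + fp
    shift <- ifelse(is.finite(denom) & denom < -1e-14,
                    h * (fm - fp) / (2 * denom), 0)
    shift <- pmin(pmax(shift, -step), step)
    centre <- pmin(pmax(centre + shift, log(lo)), log(hi))
  }
  exp(centre)
}

# Cox-Reid adjusted profile log-likelihood objective factory for the
# two-group design: IRLS refit at each dispersion (warm-started), then
# ll - 0.5 * log det(X' W X); for the saturated two-group parameterization
# det(X' W X) = SwA * SwB.
make_crapl_objfun <- function(Y, gmask, O, w = NULL) {
  env <- new.env(parent = emptyenv())
  env$init <- NULL
  function(alpha) {
    fit <- nbglm_irls_two_group(Y, gmask, O, alpha, w,
                                init = env$init, maxit = 25L, tol = 1e-10)
    env$init <- list(b0 = fit$b0, b1 = fit$b1)
    fit$ll - 0.5 * (log(pmax(fit$SwA, 1e-300)) +
                    log(pmax(fit$SwB, 1e-300)))
  }
}

# Conditional (quantile-adjusted style) log-likelihood objective factory.
# Requires counts already rescaled to a common library size (see
# equalize_lib_sizes). Optional observation weights enter as fractional
# observations: each sample contributes w_j of a full observation.
make_cond_ll_objfun <- function(Yeq, gmask, w = NULL) {
  sels <- list(!gmask, gmask)
  pre <- lapply(sels, function(sel) {
    Ys <- Yeq[, sel, drop = FALSE]
    ws <- if (is.null(w)) NULL else w[, sel, drop = FALSE]
    list(Y = Ys, w = ws,
         sw = if (is.null(ws)) rep(ncol(Ys), nrow(Ys)) else rowSums(ws),
         zw = if (is.null(ws)) rowSums(Ys) else rowSums(ws * Ys))
  })
  function(alpha) {
    r <- 1 / alpha
    out <- 0
    for (p in pre) {
      lgy <- lgamma(p$Y + r)
      if (!is.null(p$w)) lgy <- p$w * lgy
      out <- out + rowSums(lgy) - p$sw * lgamma(r) +
        lgamma(r * p$sw) - lgamma(p$zw + r * p$sw)
    }
    out
  }
}

# Mean-preserving rescale of counts to the geometric-mean library size,
# rounded half-away-from-zero back to integers. This is the simplification
# of quantile adjustment used before conditional-likelihood computations.
equalize_lib_sizes <- function(cm) {
  N <- cm$lib_size
  if (any(N <= 0)) stop("zero library size; cannot equalize")
  Ngeo <- exp(mean(log(N)))
  floor(sweep(cm$counts, 2L, Ngeo / N, "*") + 0.5)
}

round_half_up <- function(x) floor(x + 0.5)
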