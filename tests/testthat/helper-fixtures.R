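# Shared fixture builders and independent oracles. Fixtures are built in
# code; nothing is read from disk.

# small deterministic count matrix with known row totals
cm_from_totals <- function(totals, n_samples = 4L, groups = NULL) {
  G <- length(totals)
  counts <- t(vapply(totals, function(tt) {
    base <- rep(tt %/% n_samples, n_samples)
    base[seq_len(tt %% n_samples)] <- base[seq_len(tt %% n_samples)] + 1L
    base
  }, numeric(n_samples)))
  dimnames(counts) <- list(sprintf("t%03d", seq_len(G)),
                           sprintf("s%02d", seq_len(n_samples)))
  if (is.null(groups)) groups <- rep(c("A", "B"), length.out = n_samples)
  count_matrix(counts, groups)
}

# random NB fixture with fixed seed; mu and alpha returned for oracles
nb_fixture <- function(seed, n = 8L, mu_a = 20, mu_b = 20, alpha = 0.2,
                       libsize = rep(1, n)) {
  set.seed(seed)
  g <- rep(c(0, 1), each = n / 2)
  mu <- ifelse(g == 0, mu_a, mu_b) * libsize
  y <- rnbinom(n, mu = mu, size = 1 / alpha)
  list(y = y, g = g, mu = mu, alpha = alpha,
       offsets = log(libsize),
       design = design_two_group(rep(c("A", "B"), each = n / 2)))
}

# O(m^2) brute-force BH step-up, written from the definition (no cummin)
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (k in i:m) best <- min(best, ps[k] * m / k)
    adj[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# scalar conditional log-likelihood oracle for one transcript (two groups),
# computed directly from the NB-sum closed form
cond_ll_scalar <- function(y, gmask, alpha) {
  r <- 1 / alpha
  out <- 0
  for (sel in list(!gmask, gmask)) {
    ys <- y[sel]; n <- sum(sel); z <- sum(ys)
    out <- out + sum(lgamma(ys + r)) - n * lgamma(r) +
      lgamma(n * r) - lgamma(z + n * r)
  }
  out
}

expect_no_silent_drop <- function(res, cm) {
  expect_equal(nrow(res), nrow(cm$counts))
  expect_setequal(res$transcript_id, rownames(cm$counts))
}
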