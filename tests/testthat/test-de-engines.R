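test_that("scalar genewise dispersion matches a grid-search oracle", {
  for (seed in c(3, 8)) {
    fx <- nb_fixture(seed, n = 8, mu_a = 50, mu_b = 50, alpha = 0.5)
    est <- estimate_genewise_dispersion(fx$y, fx$design, fx$offsets)
    grid <- exp(seq(log(1e-8), log(10), length.out = 2000))
    obj <- vapply(grid, function(a) {
      fit <- fit_nb_glm(fx$y, fx$design, offsets = fx$offsets, alpha = a)
      wf <- fit$mu / (1 + a * fit$mu)
      fit$loglik -
        0.5 * determinant(crossprod(fx$design$X, fx$design$X * wf))$modulus[1]
    }, numeric(1))
    a_grid <- grid[which.max(obj)]
    expect_lt(abs(log(est) - log(a_grid)),
              2 * (log(10) - log(1e-8)) / 2000 + 1e-3)
  }
  expect_warning(est0 <- estimate_genewise_dispersion(rep(0, 8),
                                                      design_two_group(
                                                        rep(c("A", "B"), 4))),
                 "all-zero")
  expect_true(is.na(est0))
})

test_that("vectorized genewise dispersion agrees with the scalar op", {
  cm <- generate_null_counts(sim_config(n_transcripts = 60, seed = 17,
                                        logmean_location = log(50),
                                        logmean_scale = 0.8))
  gmask <- cm$groups == "g2"
  vec <- plasmodeDE:::genewise_dispersion_matrix(cm$counts, gmask,
                                                 rep(0, 8))
  des <- design_two_group(cm$groups)
  idx <- c(5, 20, 45)
  for (i in idx) {
    sc <- estimate_genewise_dispersion(cm$counts[i, ], des)
    expect_lt(abs(log(pmax(vec[i], 1e-8)) - log(pmax(sc, 1e-8))), 0.1)
  }
})

test_that("genewise dispersion recovers truth and the Poisson limit", {
  # Poisson data: most estimates collapse to ~0
  cfg <- sim_config(n_transcripts = 200, n_per_group = 50,
                    logmean_location = log(100), logmean_scale = 0.2,
                    disp_a0 = 1e-8, disp_a1 = 1e-8,
                    libsize_factors = rep(1, 100), seed = 2)
  cm <- generate_null_counts(cfg)
  a_hat <- plasmodeDE:::genewise_dispersion_matrix(
    cm$counts, cm$groups == "g2", rep(0, 100))
  expect_gte(mean(a_hat < 0.01, na.rm = TRUE), 0.95)

  # alpha = 0.4 at n = 100/group: mean estimate within 15%
  cfg2 <- sim_config(n_transcripts = 300, n_per_group = 100,
                     logmean_location = log(200), logmean_scale = 0.2,
                     disp_a0 = 0.4, disp_a1 = 1e-8,
                     libsize_factors = rep(1, 200), seed = 6)
  cm2 <- generate_null_counts(cfg2)
  a_hat2 <- plasmodeDE:::genewise_dispersion_matrix(
    cm2$counts, cm2$groups == "g2", rep(0, 200))
  expect_lt(abs(mean(a_hat2, na.rm = TRUE) / 0.4 - 1), 0.15)
})

test_that("dispersion trend fitting recovers parametric forms", {
  set.seed(9)
  mu <- exp(runif(400, log(1), log(2000)))
  gw <- 0.1 + 2 / mu
  co <- fit_dispersion_trend(mu, gw)
  expect_lt(abs(co["a0"] / 0.1 - 1), 0.05)
  expect_lt(abs(co["a1"] / 2 - 1), 0.05)

  co_flat <- fit_dispersion_trend(mu, rep(0.3, 400))
  expect_lt(abs(co_flat["a0"] - 0.3), 0.01)
  expect_lt(co_flat["a1"], 0.05)

  # single massive outlier excluded by the second pass
  gw_noisy <- gw * exp(rnorm(400, 0, 0.2))
  co_clean <- fit_dispersion_trend(mu, gw_noisy)
  gw_out <- gw_noisy; gw_out[17] <- 500
  co_out <- fit_dispersion_trend(mu, gw_out)
  expect_lt(abs(co_out["a0"] / co_clean["a0"] - 1), 0.01)
  expect_lt(abs(co_out["a1"] / co_clean["a1"] - 1), 0.01)

  expect_warning(fit_dispersion_trend(mu[1:5], gw[1:5]), "flat")
})

test_that("MAP dispersion interpolates between genewise and trend", {
  fx <- nb_fixture(13, n = 8, mu_a = 60, mu_b = 60, alpha = 0.5)
  gw <- estimate_genewise_dispersion(fx$y, fx$design, fx$offsets)
  trend <- 0.1
  near0 <- map_dispersion(gw, trend, 1e-8, fx$y, fx$design, fx$offsets)
  expect_lt(abs(log(near0) - log(trend)), 0.02)
  flat <- map_dispersion(gw, trend, 1e8, fx$y, fx$design, fx$offsets)
  expect_lt(abs(log(flat) - log(gw)), 0.02)
  for (pv in c(0.1, 0.5, 2)) {
    mid <- map_dispersion(gw, trend, pv, fx$y, fx$design, fx$offsets)
    lo <- min(log(gw), log(trend)) - 0.02
    hi <- max(log(gw), log(trend)) + 0.02
    expect_true(log(mid) >= lo && log(mid) <= hi)
  }
})

test_that("LFC shrinkage follows the ridge closed form", {
  sh <- shrink_lfc(2, 1, 1)
  expect_equal(sh$lfc_final, 1.0)
  expect_equal(shrink_lfc(0, 0.5, 1)$lfc_final, 0)
  expect_lt(abs(shrink_lfc(2, 1, 1e6)$lfc_final - 2), 1e-4)
  # infinite SE passes through as 0
  sh_inf <- shrink_lfc(c(3, -1), c(Inf, 1), 0.8)
  expect_equal(sh_inf$lfc_final[1], 0)
  expect_true(is.infinite(sh_inf$se_final[1]))
  # never increases magnitude
  set.seed(1)
  lfc <- rnorm(100); se <- rexp(100)
  sh_v <- shrink_lfc(lfc, se, 0.7)
  expect_true(all(abs(sh_v$lfc_final) <= abs(lfc) + 1e-12))
  expect_equal(sh_v$lfc_final, lfc * 0.49 / (0.49 + se^2))
  # prior sd estimator floor
  expect_warning(psd <- estimate_lfc_prior_sd(numeric(0), numeric(0)),
                 "floor")
  expect_equal(psd, 0.1)
})

test_that("common dispersion estimation recovers truth", {
  cfg <- sim_config(n_transcripts = 1000, n_per_group = 4,
                    logmean_location = log(80), logmean_scale = 0.5,
                    disp_a0 = 0.2, disp_a1 = 1e-8,
                    libsize_factors = rep(1, 8), seed = 23)
  cm <- generate_null_counts(cfg)
  common <- estimate_common_dispersion(cm)
  expect_lt(abs(common / 0.2 - 1), 0.10)

  cfg_p <- sim_config(n_transcripts = 500, n_per_group = 4,
                      logmean_location = log(100), logmean_scale = 0.3,
                      disp_a0 = 1e-8, disp_a1 = 1e-8,
                      libsize_factors = rep(1, 8), seed = 29)
  expect_lt(estimate_common_dispersion(generate_null_counts(cfg_p)), 0.01)
})

test_that("tagwise moderation endpoints and in-betweenness", {
  cfg <- sim_config(n_transcripts = 150, n_per_group = 4,
                    logmean_location = log(60), logmean_scale = 0.6,
                    disp_a0 = 0.15, disp_a1 = 0.5,
                    libsize_factors = rep(1, 8), seed = 37)
  cm <- generate_null_counts(cfg)
  common <- estimate_common_dispersion(cm)
  tag0 <- moderate_tagwise_dispersion(cm, common = common, prior_df = 0)
  tag_inf <- moderate_tagwise_dispersion(cm, common = common,
                                         prior_df = 1e8)
  usable <- rowSums(cm$counts) > 0
  expect_lt(max(abs(tag_inf[usable] - common)), 1e-4)

  # prior_df = 0 equals the per-transcript conditional MLE (scalar oracle)
  Yeq <- plasmodeDE:::equalize_lib_sizes(cm)
  gmask <- cm$groups == "g2"
  for (i in c(3, 77)) {
    if (rowSums(Yeq)[i] == 0) next
    opt <- optimize(function(la) cond_ll_scalar(Yeq[i, ], gmask, exp(la)),
                    interval = log(c(1e-6, 30)), maximum = TRUE, tol = 1e-9)
    expect_lt(abs(log(tag0[i]) - opt$maximum), 0.05)
  }
  # moderated estimates between tagwise MLE and common on the log scale
  tag10 <- moderate_tagwise_dispersion(cm, common = common, prior_df = 10)
  lo <- pmin(log(tag0[usable]), log(common)) - 0.05
  hi <- pmax(log(tag0[usable]), log(common)) + 0.05
  expect_true(all(log(tag10[usable]) >= lo & log(tag10[usable]) <= hi))
})

test_that("prior-DF estimation caps, decreases with spread, stable to scaling", {
  base <- sim_config(n_transcripts = 400, n_per_group = 4,
                     logmean_location = log(100), logmean_scale = 0.4,
                     disp_a0 = 0.2, disp_a1 = 1e-8,
                     libsize_factors = rep(1, 8), seed = 41)
  # heterogeneous dispersions via explicit NB draws around a log-normal
  make_cm <- function(spread, seed) {
    set.seed(seed)
    G <- 400
    alpha <- exp(rnorm(G, log(0.2), spread))
    mu <- exp(runif(G, log(30), log(300)))
    counts <- matrix(rnbinom(G * 8, mu = rep(mu, each = 8),
                             size = rep(1 / alpha, each = 8)),
                     nrow = G, byrow = TRUE,
                     dimnames = list(sprintf("t%03d", 1:G),
                                     sprintf("s%02d", 1:8)))
    count_matrix(counts, rep(c("A", "B"), each = 4))
  }
  dfs <- vapply(c(0.01, 0.8, 2.0),
                function(sp) estimate_prior_df(make_cm(sp, 43)), numeric(1))
  expect_true(all(diff(dfs) < 0))        # more spread -> smaller prior DF
  # per-sample count rescaling is undone by library equalization
  cm <- make_cm(0.8, 47)
  cm_scaled <- count_matrix(sweep(cm$counts, 2,
                                  c(2, 3, 1, 4, 2, 1, 3, 2), "*"),
                            cm$groups)
  d1 <- estimate_prior_df(cm)
  d2 <- estimate_prior_df(cm_scaled)
  expect_lt(abs(log(d1) - log(d2)), 0.35)
})

test_that("observation weights follow the Huber form", {
  expect_equal(observation_weights(10, 10, 0.5), 1)   # r = 0
  k <- 1.345
  mu <- 4; alpha <- 0.25
  sd_ <- sqrt(mu + alpha * mu^2)
  y_at <- mu + 2 * k * sd_                            # |r| = 2k
  expect_equal(observation_weights(y_at, mu, alpha), 0.5)
  y_seq <- mu + seq(0, 10, by = 0.5) * sd_
  w <- observation_weights(y_seq, mu, alpha)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w > 0 & w <= 1))
  expect_error(observation_weights(1, -1, 0.1), "positive")
})

test_that("engines are deterministic, complete, and order-invariant", {
  cm <- generate_null_counts(sim_config(n_transcripts = 250, seed = 53))
  for (eng in c("shrink_lfc", "robust_weights", "classic")) {
    res <- run_de(cm, config = engine_config(eng))
    expect_no_silent_drop(res, cm)
    ok <- !is.na(res$pvalue)
    expect_true(all(res$padj[ok] >= res$pvalue[ok] - 1e-12))
    expect_true(all(res$called == (!is.na(res$padj) &
                                     res$padj <= 0.05)))
    # permuting sample columns within groups leaves results identical
    perm <- c(2, 1, 3, 4, 6, 5, 8, 7)
    cm_p <- count_matrix(cm$counts[, perm], cm$groups[perm])
    res_p <- run_de(cm_p, config = engine_config(eng))
    expect_equal(res$pvalue, res_p$pvalue, tolerance = 1e-10)
  }
})

test_that("robust and classic variants agree without outliers", {
  cm <- generate_null_counts(sim_config(n_transcripts = 400, seed = 59,
                                        logmean_location = log(40),
                                        logmean_scale = 1.0))
  rob <- run_de(cm, config = engine_config("robust_weights"))
  cla <- run_de(cm, config = engine_config("classic"))
  expect_gt(mean(rob$called == cla$called), 0.95)
})

test_that("a single-sample outlier is damped by the robust engine", {
  cfg <- sim_config(n_transcripts = 300, n_per_group = 4,
                    logmean_location = log(50), logmean_scale = 0.5,
                    disp_a0 = 0.1, disp_a1 = 0.5,
                    libsize_factors = rep(1, 8), seed = 61)
  cm <- generate_null_counts(cfg)
  counts <- cm$counts
  counts[10, 1] <- counts[10, 1] * 50 + 50   # one wild observation
  cm_out <- count_matrix(counts, cm$groups)
  rob <- run_de(cm_out, config = engine_config("robust_weights"))
  cla <- run_de(cm_out, config = engine_config("classic"))
  expect_gt(rob$pvalue[10], cla$pvalue[10])
})

test_that("MLE LFC is recovered without bias at adequate counts", {
  # a sign-balanced minority of transcripts carries the effect:
  # median-of-ratios normalization assumes DE is a balanced minority
  for (delta in c(0.5, 1, 2)) {
    G <- 300
    d <- numeric(G); d[1:40] <- delta; d[41:80] <- -delta
    cfg <- sim_config(n_transcripts = G, n_per_group = 20,
                      logmean_location = log(300), logmean_scale = 0.25,
                      disp_a0 = 0.05, disp_a1 = 1e-8,
                      libsize_factors = rep(1, 40),
                      true_lfc_map = d,
                      seed = 70 + round(10 * delta))
    cm <- generate_counts(cfg)
    res <- run_de(cm, config = engine_config("shrink_lfc"))
    expect_lt(abs(mean(res$lfc_mle[1:80] - d[1:80])), 0.05)
    expect_lt(abs(mean(res$lfc_mle[81:G])), 0.05)
  }
})

test_that("compare_tests reports per-stratum agreement diagnostics", {
  # high-count data with realistic signal (pure-null data would collapse
  # the estimated LFC prior and make the shrunken-LFC Wald conservative)
  d <- numeric(250); d[1:50] <- 2 * rep(c(-1, 1), 25)
  cfg <- sim_config(n_transcripts = 250, n_per_group = 4,
                    logmean_location = log(2000), logmean_scale = 0.3,
                    disp_a0 = 0.05, disp_a1 = 1e-8,
                    libsize_factors = rep(1, 8), true_lfc_map = d,
                    seed = 83)
  cm <- generate_counts(cfg)
  ct <- compare_tests(cm)
  expect_equal(nrow(ct$table), 250)
  expect_true(all(c("p_wald", "p_lrt") %in% names(ct$table)))
  # high-count, low-dispersion data: the two approximate tests agree
  ok <- is.finite(ct$table$p_wald) & is.finite(ct$table$p_lrt) &
    ct$table$p_wald > 0 & ct$table$p_lrt > 0
  expect_lt(median(abs(log10(ct$table$p_wald[ok] / ct$table$p_lrt[ok]))),
            0.1)
  # with strata: one summary row per stratum plus "all"
  cm2 <- generate_null_counts(sim_config(n_transcripts = 300, seed = 89))
  cl <- classify_abundance(cm2)
  ct2 <- compare_tests(cm2, strata = cl)
  expect_setequal(ct2$summary$stratum, c("all", "low", "mid", "high"))
})
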