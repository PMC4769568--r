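#' Engine configuration
#'
#' Describes which DE method to run and how: the LFC-shrinkage engine
#' (`shrink_lfc`, Wald test on shrunken LFCs by default), the robust
#' observation-weights engine (`robust_weights`, LRT by default), or the
#' `classic` variant (robust engine without observation weights). The
#' `prior_df` controls how strongly per-transcript dispersions are shrunk
#' toward the common dispersion in the robust/classic engines; it can be a
#' fixed non-negative number (default 10, the conventional default) or
#' `"estimated"` for the data-driven moment-matching estimate.
#'
#' @param engine one of `"shrink_lfc"`, `"robust_weights"`, `"classic"`.
#' @param test `"wald"` or `"lrt"`; defaults to `"wald"` for the shrinkage
#'   engine and `"lrt"` otherwise.
#' @param prior_df non-negative number or `"estimated"` (robust/classic
#'   engines only).
#' @param fdr Benjamini-Hochberg false discovery rate for DE calls.
#' @param lfc_shrink logical; apply empirical-Bayes LFC shrinkage in the
#'   shrinkage engine (the tested statistic then uses the shrunken LFC).
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(engine = c("shrink_lfc", "robust_weights",
                                     "classic"),
                          test = NULL, prior_df = 10, fdr = 0.05,
                          lfc_shrink = TRUE) {
  engine <- match.arg(engine)
  if (is.null(test))
    test <- if (engine == "shrink_lfc") "wald" else "lrt"
  test <- match.arg(test, c("wald", "lrt"))
  if (is.character(prior_df)) {
    prior_df <- match.arg(prior_df, "estimated")
  } else if (!is.numeric(prior_df) || prior_df < 0) {
    stop("prior_df must be a non-negative number or \"estimated\"")
  }
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  structure(list(engine = engine, test = test, prior_df = prior_df,
                 fdr = fdr, lfc_shrink = isTRUE(lfc_shrink)),
            class = "engine_config")
}

engine_label <- function(config) {
  if (config$engine == "shrink_lfc") return("shrink_lfc")
  if (config$engine == "classic") return("classic")
  pd <- if (is.character(config$prior_df)) "est" else
    format(config$prior_df)
  paste0("robust_df", pd)
}

new_de_result <- function(df, config, extra = list()) {
  class(df) <- c("de_result", "data.frame")
  attr(df, "engine") <- config$engine
  attr(df, "test") <- config$test
  attr(df, "fdr") <- config$fdr
  attr(df, "label") <- engine_label(config)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  df
}

check_two_group <- function(cm) {
  sizes <- table(cm$groups)
  if (length(sizes) != 2L) stop("exactly two groups required")
  if (any(sizes < 2L)) stop("at least two samples per group required")
  invisible(cm)
}

# Shared core of the shrinkage engine; returns fits and dispersion pieces so
# that compare_tests() can reuse a single fit for both tests.
shrink_fit_core <- function(cm, config) {
  check_two_group(cm)
  Y <- cm$counts
  S <- ncol(Y)
  gmask <- cm$groups == levels(cm$groups)[2L]
  sf <- size_factors_median_ratio(cm)
  O <- log(sf)
  mean_norm <- rowMeans(sweep(Y, 2L, sf, "/"))

  genewise <- genewise_dispersion_matrix(Y, gmask, O)
  trend_co <- fit_dispersion_trend(mean_norm, genewise)
  trend <- pmin(pmax(trend_co["a0"] + trend_co["a1"] / pmax(mean_norm, 1e-8),
                     1e-8), 10)
  prior_var <- estimate_prior_var_logdisp(genewise, trend, S, 2L)
  disp_final <- map_dispersion_matrix(Y, gmask, O, trend, prior_var)

  fit <- nbglm_irls_two_group(Y, gmask, O, disp_final)
  fit0 <- nbglm_irls_null(Y, O, disp_final)

  totA <- rowSums(Y[, !gmask, drop = FALSE])
  totB <- rowSums(Y[, gmask, drop = FALSE])
  all_zero <- totA + totB == 0
  boundary <- !all_zero & (totA == 0 | totB == 0)

  lfc_mle <- fit$b1 / log(2)
  lfc_se <- fit$se_b1 / log(2)
  lfc_mle[all_zero] <- 0
  lfc_se[all_zero | boundary] <- Inf

  prior_sd <- estimate_lfc_prior_sd(lfc_mle, lfc_se)
  sh <- shrink_lfc(lfc_mle, lfc_se, prior_sd)

  list(gmask = gmask, sf = sf, mean_norm = mean_norm,
       genewise = genewise, trend_coef = trend_co, trend = trend,
       prior_var = prior_var, disp_final = disp_final,
       fit = fit, fit0 = fit0, all_zero = all_zero, boundary = boundary,
       lfc_mle = lfc_mle, lfc_se = lfc_se,
       prior_sd = prior_sd, lfc_final = sh$lfc_final,
       se_final = sh$se_final)
}

shrink_pvalues <- function(core, test, lfc_shrink = TRUE) {
  if (test == "wald") {
    if (lfc_shrink) {
      stat <- ifelse(is.finite(core$se_final),
                     core$lfc_final / core$se_final, 0)
      p <- wald_test(core$lfc_final, core$se_final)
    } else {
      stat <- ifelse(is.finite(core$lfc_se), core$lfc_mle / core$lfc_se, 0)
      p <- wald_test(core$lfc_mle, core$lfc_se)
    }
  } else {
    lam <- pmax(2 * (core$fit$ll - core$fit0$ll), 0)
    lam[core$all_zero] <- 0
    stat <- lam
    p <- stats::pchisq(lam, df = 1L, lower.tail = FALSE)
  }
  list(stat = stat, pvalue = p)
}

#' Run the LFC-shrinkage DE engine
#'
#' Negative-binomial GLM differential expression with median-of-ratios size
#' factors as offsets, Cox-Reid genewise dispersions shrunk toward a
#' parametric trend by an empirical-Bayes (MAP) step, empirical-Bayes
#' shrinkage of log2 fold changes toward a zero-centered normal prior, and
#' a Wald test on the shrunken LFCs (default) or a likelihood-ratio test.
#' P-values are BH-adjusted and transcripts are called DE at `config$fdr`.
#' Every input transcript appears in the output (no silent drops).
#'
#' @param counts a [count_matrix()] or bare matrix.
#' @param groups group labels (ignored when `counts` is a `count_matrix`).
#' @param config an [engine_config()] with `engine = "shrink_lfc"`.
#' @return A `de_result` data.frame with columns `transcript_id`,
#'   `mean_norm_count`, `lfc_mle`, `lfc_final`, `lfc_se`, `disp_final`,
#'   `stat`, `pvalue`, `padj`, `called`.
#' @export
run_shrink_engine <- function(counts, groups = NULL,
                              config = engine_config("shrink_lfc")) {
  cm <- as_count_input(counts, groups)
  core <- shrink_fit_core(cm, config)
  tp <- shrink_pvalues(core, config$test, config$lfc_shrink)
  padj <- bh_adjust(tp$pvalue)
  df <- data.frame(
    transcript_id = rownames(cm$counts),
    mean_norm_count = core$mean_norm,
    lfc_mle = core$lfc_mle,
    lfc_final = core$lfc_final,
    lfc_se = core$lfc_se,
    disp_final = core$disp_final,
    stat = tp$stat,
    pvalue = tp$pvalue,
    padj = padj,
    called = !is.na(padj) & padj <= config$fdr,
    row.names = NULL)
  new_de_result(df, config,
                extra = list(prior_sd = core$prior_sd,
                             trend_coef = core$trend_coef,
                             prior_var_logdisp = core$prior_var))
}

# Average conditional log-likelihood curve over usable transcripts as a
# smooth function of log(alpha), via spline interpolation of a dense grid.
build_lbar_spline <- function(Yeq, gmask, usable,
                              lo = 1e-6, hi = 30, n_grid = 61L) {
  objfun <- make_cond_ll_objfun(Yeq[usable, , drop = FALSE], gmask)
  la <- seq(log(lo), log(hi), length.out = n_grid)
  vals <- vapply(la, function(x) mean(objfun(rep(exp(x), sum(usable)))),
                 numeric(1))
  stats::splinefun(la, vals)
}

#' Common dispersion by conditional maximum likelihood
#'
#' Maximizes, over a single dispersion, the summed per-transcript
#' conditional log-likelihoods computed on counts rescaled to the
#' geometric-mean library size (a mean-preserving simplification of
#' quantile adjustment that keeps the equal-library-size conditioning
#' argument valid to first order).
#'
#' @param counts a [count_matrix()] or bare matrix.
#' @param groups group labels (ignored for a `count_matrix`).
#' @return A single common dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups = NULL) {
  cm <- as_count_input(counts, groups)
  check_two_group(cm)
  Yeq <- equalize_lib_sizes(cm)
  gmask <- cm$groups == levels(cm$groups)[2L]
  usable <- rowSums(Yeq) > 0
  if (!any(usable)) stop("no transcript with positive counts")
  lbar <- build_lbar_spline(Yeq, gmask, usable)
  opt <- stats::optimize(lbar, interval = log(c(1e-6, 30)), maximum = TRUE,
                         tol = 1e-9)
  exp(opt$maximum)
}

# Internal moderated-tagwise machinery shared by the exported op and the
# robust engine loop. lbar_fun takes log(alpha).
moderate_tagwise_internal <- function(Yeq, gmask, common, prior_df, df_res,
                                      lbar_fun, w = NULL) {
  G <- nrow(Yeq)
  out <- rep(common, G)
  usable <- rowSums(Yeq) > 0
  if (!any(usable)) return(out)
  objg <- make_cond_ll_objfun(Yeq[usable, , drop = FALSE], gmask,
                              if (is.null(w)) NULL else
                                w[usable, , drop = FALSE])
  ratio <- prior_df / df_res
  obj <- function(alpha) objg(alpha) + ratio * lbar_fun(log(alpha))
  out[usable] <- disp_argmax(obj, sum(usable), lo = 1e-6, hi = 30)
  out
}

#' Moderated tagwise dispersions
#'
#' Per transcript, maximizes `l_g(alpha) + (prior_df / df_res) *
#' lbar(alpha)`, where `l_g` is the transcript's conditional log-likelihood
#' (on library-size-equalized counts), `lbar` the average conditional
#' log-likelihood over all transcripts, and `df_res` the per-transcript
#' residual degrees of freedom. `prior_df = 0` returns the tagwise maximum
#' likelihood estimates; as `prior_df` grows all estimates approach the
#' common-likelihood maximizer. All-zero transcripts receive the common
#' dispersion.
#'
#' @param counts a [count_matrix()] or bare matrix.
#' @param groups group labels (ignored for a `count_matrix`).
#' @param common common dispersion, e.g. [estimate_common_dispersion()].
#' @param prior_df non-negative prior degrees of freedom.
#' @param weights optional transcripts x samples observation weights
#'   applied to the per-transcript likelihood contributions.
#' @return Named numeric vector of moderated dispersions.
#' @export
moderate_tagwise_dispersion <- function(counts, groups = NULL, common,
                                        prior_df, weights = NULL) {
  cm <- as_count_input(counts, groups)
  check_two_group(cm)
  if (prior_df < 0) stop("prior_df must be >= 0")
  df_res <- ncol(cm$counts) - 2L
  if (df_res <= 0) stop("no residual degrees of freedom")
  Yeq <- equalize_lib_sizes(cm)
  gmask <- cm$groups == levels(cm$groups)[2L]
  usable <- rowSums(Yeq) > 0
  lbar <- build_lbar_spline(Yeq, gmask, usable)
  out <- moderate_tagwise_internal(Yeq, gmask, common, prior_df, df_res,
                                   lbar, weights)
  stats::setNames(out, rownames(cm$counts))
}

#' Data-driven prior degrees of freedom
#'
#' Moment-matching on the spread of log tagwise dispersion estimates: the
#' observed variance of `log(alpha_hat)` is modeled as sampling variance
#' `trigamma(df_res / 2)` plus prior variance `trigamma(d0 / 2)`, and `d0`
#' is recovered by monotone root finding. When the observed spread does not
#' exceed the sampling variance the estimate is capped at 1e6 (essentially
#' complete shrinkage). Tagwise estimates are clamped to `[1e-4, 20]`
#' before taking logs so boundary estimates do not dominate the variance.
#'
#' @param counts a [count_matrix()] or bare matrix.
#' @param groups group labels (ignored for a `count_matrix`).
#' @return A single positive prior-degrees-of-freedom estimate.
#' @export
estimate_prior_df <- function(counts, groups = NULL) {
  cm <- as_count_input(counts, groups)
  check_two_group(cm)
  Yeq <- equalize_lib_sizes(cm)
  gmask <- cm$groups == levels(cm$groups)[2L]
  usable <- rowSums(Yeq) > 0
  if (sum(usable) < 30L)
    stop("need at least 30 transcripts with positive totals")
  objg <- make_cond_ll_objfun(Yeq[usable, , drop = FALSE], gmask)
  tw <- disp_argmax(objg, sum(usable), lo = 1e-4, hi = 20)
  v <- stats::var(log(tw))
  df_res <- ncol(cm$counts) - 2L
  target <- v - trigamma(df_res / 2)
  cap <- 1e6
  if (!is.finite(target) || target <= trigamma(cap / 2)) return(cap)
  root <- stats::uniroot(function(ld) trigamma(exp(ld) / 2) - target,
                         lower = log(1e-4), upper = log(cap),
                         tol = 1e-10)
  min(exp(root$root), cap)
}

#' Run the robust-weights DE engine (or its classic variant)
#'
#' Negative-binomial GLM differential expression with raw library-size
#' offsets `log(N_j)`, a common dispersion from conditional maximum
#' likelihood, tagwise dispersions moderated toward it by `prior_df`
#' (fixed or estimated from the data), and -- for the robust variant --
#' Huber observation weights computed from Pearson residuals and iterated
#' with the fits (3 cycles or until weights change by < 1e-4) so that
#' outlying observations are down-weighted in both the regression and the
#' dispersion estimation. Testing is by likelihood-ratio test (default)
#' with BH adjustment. The `classic` engine is the same pipeline with all
#' observation weights fixed at 1.
#'
#' @param counts a [count_matrix()] or bare matrix.
#' @param groups group labels (ignored for a `count_matrix`).
#' @param config an [engine_config()] with engine `"robust_weights"` or
#'   `"classic"`.
#' @return A `de_result` data.frame (see [run_shrink_engine()]).
#' @export
run_robust_engine <- function(counts, groups = NULL,
                              config = engine_config("robust_weights")) {
  cm <- as_count_input(counts, groups)
  check_two_group(cm)
  Y <- cm$counts
  S <- ncol(Y)
  gmask <- cm$groups == levels(cm$groups)[2L]
  N <- cm$lib_size
  O <- log(N)
  df_res <- S - 2L
  robust <- config$engine == "robust_weights"

  Yeq <- equalize_lib_sizes(cm)
  usable <- rowSums(Yeq) > 0
  lbar <- build_lbar_spline(Yeq, gmask, usable)
  opt <- stats::optimize(lbar, interval = log(c(1e-6, 30)), maximum = TRUE,
                         tol = 1e-9)
  common <- exp(opt$maximum)
  prior_df <- if (identical(config$prior_df, "estimated"))
    estimate_prior_df(cm) else config$prior_df

  w <- NULL
  n_cycles <- if (robust) 3L else 1L
  for (cycle in seq_len(n_cycles)) {
    disp <- moderate_tagwise_internal(Yeq, gmask, common, prior_df, df_res,
                                      lbar, w)
    fit <- nbglm_irls_two_group(Y, gmask, O, disp, w)
    if (!robust) break
    w_new <- observation_weights(Y, fit$mu, disp)
    if (!is.null(w) && max(abs(w_new - w)) < 1e-4) { w <- w_new; break }
    w <- w_new
  }
  if (robust) {
    disp <- moderate_tagwise_internal(Yeq, gmask, common, prior_df, df_res,
                                      lbar, w)
    fit <- nbglm_irls_two_group(Y, gmask, O, disp, w)
  }
  fit0 <- nbglm_irls_null(Y, O, disp, w)

  totA <- rowSums(Y[, !gmask, drop = FALSE])
  totB <- rowSums(Y[, gmask, drop = FALSE])
  all_zero <- totA + totB == 0
  bnd <- !all_zero & (totA == 0 | totB == 0)

  lfc_mle <- fit$b1 / log(2)
  lfc_se <- fit$se_b1 / log(2)
  lfc_mle[all_zero] <- 0
  lfc_se[all_zero | bnd] <- Inf

  if (config$test == "lrt") {
    lam <- pmax(2 * (fit$ll - fit0$ll), 0)
    lam[all_zero] <- 0
    stat <- lam
    p <- stats::pchisq(lam, df = 1L, lower.tail = FALSE)
  } else {
    stat <- ifelse(is.finite(lfc_se), lfc_mle / lfc_se, 0)
    p <- wald_test(lfc_mle, lfc_se)
  }
  padj <- bh_adjust(p)
  mean_norm <- rowMeans(sweep(Y, 2L, N, "/")) * exp(mean(log(N)))

  df <- data.frame(
    transcript_id = rownames(Y),
    mean_norm_count = mean_norm,
    lfc_mle = lfc_mle,
    lfc_final = lfc_mle,
    lfc_se = lfc_se,
    disp_final = disp,
    stat = stat,
    pvalue = p,
    padj = padj,
    called = !is.na(padj) & padj <= config$fdr,
    row.names = NULL)
  new_de_result(df, config,
                extra = list(common_dispersion = common,
                             prior_df_used = prior_df))
}

#' Run a DE engine chosen by configuration
#'
#' Dispatches to [run_shrink_engine()] or [run_robust_engine()].
#'
#' @param counts a [count_matrix()] or bare matrix.
#' @param groups group labels (ignored for a `count_matrix`).
#' @param config an [engine_config()].
#' @return A `de_result` data.frame.
#' @export
run_de <- function(counts, groups = NULL, config = engine_config()) {
  if (config$engine == "shrink_lfc") {
    run_shrink_engine(counts, groups, config)
  } else {
    run_robust_engine(counts, groups, config)
  }
}

#' Wald versus LRT on a single shrinkage-engine fit
#'
#' Fits the shrinkage engine once and computes both the Wald p-value (on
#' the shrunken LFC) and the LRT p-value on the identical fit, per
#' transcript, with a per-stratum summary of how often and by how much the
#' two approximate tests disagree.
#'
#' @param counts a [count_matrix()] or bare matrix.
#' @param groups group labels (ignored for a `count_matrix`).
#' @param strata optional [classify_abundance()] result for stratified
#'   summaries; when `NULL` only the `all` stratum is reported.
#' @param config an [engine_config()] (engine forced to `shrink_lfc`).
#' @return List with `table` (per-transcript `p_wald`, `p_lrt`) and
#'   `summary` (per stratum: fraction with `p_wald < p_lrt`, median log10
#'   p-value ratio).
#' @export
compare_tests <- function(counts, groups = NULL, strata = NULL,
                          config = engine_config("shrink_lfc")) {
  cm <- as_count_input(counts, groups)
  config$engine <- "shrink_lfc"
  core <- shrink_fit_core(cm, config)
  pw <- shrink_pvalues(core, "wald", config$lfc_shrink)$pvalue
  pl <- shrink_pvalues(core, "lrt")$pvalue
  tab <- data.frame(transcript_id = rownames(cm$counts),
                    p_wald = pw, p_lrt = pl, row.names = NULL)
  strat_of <- if (is.null(strata)) {
    stats::setNames(rep("all", nrow(tab)), tab$transcript_id)
  } else {
    stats::setNames(as.character(strata$label), names(strata$label))
  }
  groups_list <- c(list(all = rep(TRUE, nrow(tab))),
                   if (!is.null(strata))
                     lapply(c(low = "low", mid = "mid", high = "high"),
                            function(s) strat_of[tab$transcript_id] == s))
  summ <- do.call(rbind, lapply(names(groups_list), function(nm) {
    sel <- groups_list[[nm]] & is.finite(pw) & is.finite(pl) &
      pw > 0 & pl > 0
    if (!any(sel)) {
      return(data.frame(stratum = nm, n = 0L, frac_wald_smaller = NA_real_,
                        median_log10_ratio = NA_real_))
    }
    data.frame(stratum = nm, n = sum(sel),
               frac_wald_smaller = mean(pw[sel] < pl[sel]),
               median_log10_ratio = stats::median(log10(pw[sel] / pl[sel])))
  }))
  list(table = tab, summary = summ)
}
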