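#' Default engine grid for benchmarking
#'
#' The shrinkage engine, the classic variant, and the robust engine at
#' prior-DF 4, 10, 50 and estimated.
#'
#' @param fdr BH false discovery rate used by every engine.
#' @return Named list of [engine_config()] objects.
#' @export
default_engine_grid <- function(fdr = 0.05) {
  cfgs <- list(
    engine_config("shrink_lfc", fdr = fdr),
    engine_config("classic", fdr = fdr),
    engine_config("robust_weights", prior_df = 4, fdr = fdr),
    engine_config("robust_weights", prior_df = 10, fdr = fdr),
    engine_config("robust_weights", prior_df = 50, fdr = fdr),
    engine_config("robust_weights", prior_df = "estimated", fdr = fdr))
  stats::setNames(cfgs, vapply(cfgs, engine_label, character(1)))
}

#' Benchmark configuration
#'
#' The experiment grid: a source simulation, the engine settings, the
#' filtering rules, the spiked fraction, and the number of DE plasmode
#' replicates per null plasmode.
#'
#' The default source simulation gives 40% of transcripts a true log2 fold
#' change of magnitude `1 + Exp(rate = 2/3)` with random sign, so that the
#' pool of harvested effect sizes (transcripts declared DE by the classic
#' engine at FDR 0.05 on the source data) is comfortably larger than the
#' `round(pi * G)` effects each DE plasmode consumes.
#'
#' @param sim a [sim_config()] for the source dataset (defaults as above).
#' @param source_group group whose samples are repartitioned into null
#'   plasmodes (default `"g1"`).
#' @param engines named list of [engine_config()]s.
#' @param filters subset of `c("none", "rp", "cpm")`.
#' @param pi spiked fraction per DE plasmode.
#' @param replicates DE plasmodes per null plasmode (default 5).
#' @param fdr BH level for DE calls.
#' @param seed top-level seed; all randomness derives from it.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(sim = NULL, source_group = "g1",
                             engines = default_engine_grid(fdr),
                             filters = c("none", "rp", "cpm"),
                             pi = 0.2, replicates = 5L, fdr = 0.05,
                             seed = 1L) {
  if (is.null(sim)) {
    sim <- sim_config(seed = substream_seed(seed, "source_sim"))
    sim$true_lfc_map <- default_source_effects(sim)
  }
  filters <- match.arg(filters, c("none", "rp", "cpm"), several.ok = TRUE)
  if (length(engines) == 0L) stop("engine grid must be non-empty")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(sim = sim, source_group = source_group,
                 engines = engines, filters = filters, pi = pi,
                 replicates = as.integer(replicates), fdr = fdr,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# True effects for the default benchmark source: 40% DE, |delta| = 1 +
# Exp(rate = 2/3) (mean magnitude 2.5), random sign. Drawn from a named
# substream of the simulation seed.
default_source_effects <- function(sim) {
  G <- sim$n_transcripts
  with_substream(sim$seed, "source_effects", {
    n_de <- as.integer(floor(0.4 * G + 0.5))
    idx <- sample.int(G, n_de)
    delta <- numeric(G)
    delta[idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      (1 + stats::rexp(n_de, rate = 2 / 3))
    delta
  })
}

filter_mask <- function(cm, rule) {
  switch(rule,
         none = no_filter(cm),
         rp = rp_filter(cm),
         cpm = cpm_filter(cm),
         stop("unknown filter rule: ", rule))
}

de_calls <- function(res) stats::setNames(res$called, res$transcript_id)

#' False-positive-rate study on independent synthetic null datasets
#'
#' Generates `n_reps` independent two-group null count matrices from a
#' simulation configuration, runs every engine setting with BH adjustment,
#' and records the empirical false positive rate (fraction of transcripts
#' called DE; all calls are false by construction) on all transcripts and
#' within the low-count stratum of each dataset.
#'
#' @param n_reps number of null datasets (>= 1).
#' @param sim a [sim_config()]; its seed field is replaced per replicate.
#' @param engines named list of [engine_config()]s.
#' @param seed top-level seed.
#' @return A data.frame with columns `rep`, `engine`, `stratum`
#'   (`all`/`low`), `fpr`, `n_null`.
#' @export
null_fpr_study <- function(n_reps = 25L, sim = sim_config(),
                           engines = default_engine_grid(), seed = 1L) {
  records <- vector("list", n_reps * length(engines) * 2L)
  k <- 0L
  for (r in seq_len(n_reps)) {
    sim_r <- sim
    sim_r$seed <- substream_seed(seed, paste0("null_rep_", r))
    cm <- generate_null_counts(sim_r)
    classes <- classify_abundance(cm)
    low <- names(classes$label)[classes$label == "low"]
    for (nm in names(engines)) {
      res <- run_de(cm, config = engines[[nm]])
      calls <- de_calls(res)
      for (stratum in c("all", "low")) {
        sel <- if (stratum == "all") names(calls) else low
        k <- k + 1L
        records[[k]] <- data.frame(
          rep = r, engine = nm, stratum = stratum,
          fpr = mean(calls[sel]), n_null = length(sel))
      }
    }
  }
  do.call(rbind, records[seq_len(k)])
}

#' Run the full plasmode benchmark
#'
#' For each filtering rule: applies the filter mask to the source data,
#' builds every balanced null plasmode of the source group's samples, runs
#' every engine setting on each (null FPR records), spikes `replicates` DE
#' plasmodes per null plasmode from the pool of effect sizes harvested by
#' the classic engine on the source data, runs every engine on those (full
#' metric records), and aggregates mean and SEM across plasmodes per
#' (engine, filter, stratum, metric). Stratum membership is frozen from
#' the filtered source data's abundance classes. Component failures abort
#' the affected grid cell with a logged reason, not the whole run.
#'
#' Three directional expectations are checked softly on the aggregate
#' (robust power >= shrinkage power on the low-count stratum; shrinkage
#' precision >= robust precision; FPR non-decreasing in prior-DF over
#' 4/10/50) and reported as pass/warn in `soft_checks`, never as errors.
#'
#' @param cfg a [benchmark_config()].
#' @param quiet suppress progress messages.
#' @return A list of class `benchmark_result`: `records` (long per-plasmode
#'   data.frame), `aggregate` (mean and SEM per cell), `soft_checks`
#'   (data.frame of directional checks with pass/warn status), `pool_size`,
#'   and `provenance` (seeds and ids).
#' @export
run_benchmark <- function(cfg = benchmark_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  source_cm <- generate_counts(cfg$sim)
  say("benchmark: source data ", nrow(source_cm$counts), " transcripts")

  pool_res <- run_de(source_cm,
                     config = engine_config("classic", fdr = cfg$fdr))
  pool <- harvest_effect_sizes(pool_res, fdr = cfg$fdr)
  say("benchmark: harvested pool of ", length(pool$effects),
      " effect sizes")

  records <- list()
  for (rule in cfg$filters) {
    mask <- filter_mask(source_cm, rule)
    cm_f <- apply_filter(source_cm, mask)
    classes <- classify_abundance(cm_f)
    src_samples <- names(cm_f$groups)[cm_f$groups == cfg$source_group]
    partitions <- enumerate_null_partitions(src_samples)
    m_spike <- as.integer(floor(cfg$pi * nrow(cm_f$counts) + 0.5))
    if (length(pool$effects) < m_spike)
      stop("harvested pool (", length(pool$effects), ") smaller than ",
           m_spike, " effects needed; use source data with larger or ",
           "more abundant true effects")

    for (p in seq_along(partitions)) {
      null_pl <- build_null_plasmode(cm_f, cfg$source_group,
                                     partitions[[p]], partition_id = p)
      plasmodes <- c(list(null_pl),
                     lapply(seq_len(cfg$replicates), function(r) {
                       spike_de_plasmode(null_pl, pool, pi = cfg$pi,
                                         seed = substream_seed(
                                           cfg$seed,
                                           paste0("spike_", rule, "_",
                                                  p, "_", r)),
                                         replicate_id = r)
                     }))
      for (pl in plasmodes) {
        kind <- if (pl$replicate_id == 0L) "null" else "de"
        for (nm in names(cfg$engines)) {
          rec <- tryCatch({
            res <- run_de(pl$counts, config = cfg$engines[[nm]])
            sp <- stratified_performance(de_calls(res), pl$truth, classes,
                                         method = nm)
            sp$filter <- rule
            sp$plasmode_kind <- kind
            sp$partition_id <- pl$partition_id
            sp$replicate_id <- pl$replicate_id
            sp
          }, error = function(e) {
            say("benchmark: cell failed (", rule, "/", nm, "/", kind,
                " partition ", p, "): ", conditionMessage(e))
            NULL
          })
          if (!is.null(rec)) records[[length(records) + 1L]] <- rec
        }
      }
      say("benchmark: filter ", rule, ", partition ", p, "/",
          length(partitions), " done")
    }
  }
  records <- do.call(rbind, records)

  aggregate_tab <- aggregate_benchmark(records)
  soft <- soft_directional_checks(aggregate_tab, quiet = quiet)
  structure(list(records = records, aggregate = aggregate_tab,
                 soft_checks = soft, pool_size = length(pool$effects),
                 provenance = list(seed = cfg$seed,
                                   source_sim_seed = cfg$sim$seed,
                                   n_partitions = length(
                                     enumerate_null_partitions(
                                       names(source_cm$groups)[
                                         source_cm$groups ==
                                           cfg$source_group])),
                                   replicates = cfg$replicates)),
            class = "benchmark_result")
}

# mean and SEM of each metric across plasmodes per grid cell
aggregate_benchmark <- function(records) {
  metrics <- c("FPR", "TPR", "PPV", "NPV", "ACC")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(records[c("method", "filter", "plasmode_kind", "stratum")],
               metric = m, value = records[[m]])
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  if (nrow(long) == 0L) return(long)
  agg <- stats::aggregate(
    value ~ method + filter + plasmode_kind + stratum + metric, long,
    function(v) c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                  n = length(v)))
  out <- cbind(agg[, 1:5], as.data.frame(agg$value))
  names(out)[6:8] <- c("mean", "sem", "n")
  out
}

get_cell <- function(agg, method, kind, stratum, metric, filter = "none") {
  v <- agg$mean[agg$method == method & agg$filter == filter &
                  agg$plasmode_kind == kind & agg$stratum == stratum &
                  agg$metric == metric]
  if (length(v)) v[1] else NA_real_
}

soft_directional_checks <- function(agg, quiet = FALSE) {
  checks <- list()
  add <- function(name, lhs, rhs, cmp = `>=`) {
    ok <- if (is.na(lhs) || is.na(rhs)) NA else cmp(lhs, rhs)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, lhs = lhs, rhs = rhs,
      status = if (is.na(ok)) "na" else if (ok) "pass" else "warn")
  }
  add("robust_power_ge_shrink_low",
      get_cell(agg, "robust_df10", "de", "low", "TPR"),
      get_cell(agg, "shrink_lfc", "de", "low", "TPR"))
  add("shrink_ppv_ge_robust_all",
      get_cell(agg, "shrink_lfc", "de", "all", "PPV"),
      get_cell(agg, "robust_df10", "de", "all", "PPV"))
  f4 <- get_cell(agg, "robust_df4", "null", "all", "FPR")
  f10 <- get_cell(agg, "robust_df10", "null", "all", "FPR")
  f50 <- get_cell(agg, "robust_df50", "null", "all", "FPR")
  add("fpr_nondecreasing_df4_to_df10", f10, f4)
  add("fpr_nondecreasing_df10_to_df50", f50, f10)
  out <- do.call(rbind, checks)
  if (!quiet) {
    for (i in seq_len(nrow(out)))
      message("soft check [", out$status[i], "] ", out$check[i], ": ",
              signif(out$lhs[i], 3), " vs ", signif(out$rhs[i], 3))
  }
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d metric records, pool of %d effects\n",
              nrow(x$records), x$pool_size))
  cat("soft checks:\n")
  print(x$soft_checks, row.names = FALSE)
  invisible(x)
}

#' Overlap of DE calls between two methods
#'
#' Counts transcripts called only by A, only by B, and by both (per
#' stratum when abundance classes are supplied), plus the shared fraction
#' `n_both / |A|` -- the fraction of A's calls that B reproduces.
#'
#' @param results_a,results_b `de_result` data.frames on the identical
#'   transcript set.
#' @param classes optional [classify_abundance()] result.
#' @return A data.frame with one row per stratum: `stratum`, `n_only_a`,
#'   `n_only_b`, `n_both`, `shared_frac_of_a`.
#' @export
overlap_report <- function(results_a, results_b, classes = NULL) {
  if (!setequal(results_a$transcript_id, results_b$transcript_id))
    stop("results cover different transcript sets")
  ca <- de_calls(results_a)
  cb <- de_calls(results_b)[names(ca)]
  strat <- if (is.null(classes)) {
    stats::setNames(rep("all", length(ca)), names(ca))
  } else {
    stats::setNames(as.character(classes$label[names(ca)]), names(ca))
  }
  strata <- if (is.null(classes)) "all" else c("all", "low", "mid", "high")
  do.call(rbind, lapply(strata, function(s) {
    sel <- if (s == "all") rep(TRUE, length(ca)) else strat == s
    a <- ca[sel]; b <- cb[sel]
    n_both <- sum(a & b)
    data.frame(stratum = s,
               n_only_a = sum(a & !b),
               n_only_b = sum(b & !a),
               n_both = n_both,
               shared_frac_of_a = if (sum(a) > 0) n_both / sum(a)
                                  else NA_real_)
  }))
}

#' Impact of a filtering rule on DE calls
#'
#' Splits the unfiltered method's calls into those lost because the filter
#' removed the transcript and those lost (or gained) because inference on
#' the filtered data changed, with an optional per-stratum breakdown.
#'
#' @param unfiltered a `de_result` on the full transcript set.
#' @param filtered a `de_result` computed on the mask's kept transcripts
#'   only.
#' @param mask the `filter_result` that produced the filtered data.
#' @param classes optional [classify_abundance()] on the full set.
#' @return A data.frame with one row per stratum: calls in the unfiltered
#'   data, calls lost to filtering, calls lost to changed inference, calls
#'   gained, calls in the filtered data, overlap fraction of surviving
#'   unfiltered calls, and percent reduction in calls.
#' @export
filter_impact_report <- function(unfiltered, filtered, mask,
                                 classes = NULL) {
  if (!setequal(names(mask$kept), unfiltered$transcript_id))
    stop("mask does not match the unfiltered transcript set")
  if (!setequal(filtered$transcript_id,
                names(mask$kept)[mask$kept]))
    stop("filtered result does not match the mask's kept transcripts")
  cu <- de_calls(unfiltered)
  cf <- de_calls(filtered)
  kept <- mask$kept[names(cu)]
  strat <- if (is.null(classes)) {
    stats::setNames(rep("all", length(cu)), names(cu))
  } else {
    stats::setNames(as.character(classes$label[names(cu)]), names(cu))
  }
  strata <- if (is.null(classes)) "all" else c("all", "low", "mid", "high")
  do.call(rbind, lapply(strata, function(s) {
    sel <- if (s == "all") rep(TRUE, length(cu)) else strat == s
    u <- cu[sel]; k <- kept[sel]
    f <- cf[intersect(names(cf), names(u)[k])]
    u_surv <- u[names(f)]
    n_calls_unf <- sum(u)
    lost_filter <- sum(u & !k)
    lost_infer <- sum(u_surv & !f)
    gained <- sum(f & !u_surv)
    n_calls_f <- sum(f)
    data.frame(stratum = s,
               calls_unfiltered = n_calls_unf,
               lost_to_filtering = lost_filter,
               lost_to_inference = lost_infer,
               gained = gained,
               calls_filtered = n_calls_f,
               overlap_frac = if (sum(u_surv) > 0)
                 sum(u_surv & f) / sum(u_surv) else NA_real_,
               pct_reduction = if (n_calls_unf > 0)
                 100 * (n_calls_unf - n_calls_f) / n_calls_unf
               else NA_real_)
  }))
}

#' Data for an MA-style plot
#'
#' Per transcript: log10 mean normalized count, final LFC and the DE call
#' flag, ready for plotting fold change against abundance.
#'
#' @param results a `de_result` data.frame.
#' @return A data.frame with columns `transcript_id`, `log10_mean`, `lfc`,
#'   `called`.
#' @export
ma_data <- function(results) {
  data.frame(transcript_id = results$transcript_id,
             log10_mean = log10(results$mean_norm_count + 1e-6),
             lfc = results$lfc_final,
             called = results$called,
             row.names = NULL)
}
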