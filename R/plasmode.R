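#' Enumerate balanced null partitions
#'
#' All unordered partitions of an even set of samples into two equal
#' halves, each listed once (`choose(n, n/2) / 2` partitions). The
#' canonical order is deterministic: the lexicographically smallest sample
#' is fixed in group A and its companions are enumerated in combination
#' order.
#'
#' @param sample_ids character vector of sample ids (even length >= 2).
#' @return A list of partitions, each a list with elements `A` and `B`
#'   (character vectors of sample ids).
#' @export
enumerate_null_partitions <- function(sample_ids) {
  n <- length(sample_ids)
  if (n < 2L || n %% 2L != 0L)
    stop("need an even number (>= 2) of samples to partition")
  ids <- sort(sample_ids)
  first <- ids[1L]
  rest <- ids[-1L]
  k <- n %/% 2L - 1L
  combos <- if (k == 0L) matrix(character(0), nrow = 0, ncol = 1) else
    utils::combn(rest, k)
  n_part <- ncol(combos)
  lapply(seq_len(max(n_part, 1L)), function(i) {
    a <- if (k == 0L) first else c(first, combos[, i])
    list(A = a, B = setdiff(ids, a))
  })
}

new_plasmode <- function(cm, partition_id, replicate_id, truth, seed) {
  structure(list(counts = cm, partition_id = partition_id,
                 replicate_id = replicate_id, truth = truth, seed = seed),
            class = "plasmode_dataset")
}

#' @export
print.plasmode_dataset <- function(x, ...) {
  n_spiked <- sum(x$truth != 0)
  cat(sprintf(
    "plasmode_dataset: partition %s, replicate %s, %d/%d spiked transcripts\n",
    x$partition_id, x$replicate_id, n_spiked, length(x$truth)))
  invisible(x)
}

#' Build a null plasmode
#'
#' Restricts the counts to the samples of one condition and relabels them
#' into two arbitrary groups A/B according to a balanced partition. No
#' count is altered, so no differential expression is expected between the
#' groups beyond sample-to-sample variation; every DE call on the result is
#' a false positive.
#'
#' @param counts a [count_matrix()].
#' @param source_group the group label whose samples are repartitioned.
#' @param partition a partition (list with `A`, `B`) covering exactly the
#'   samples of `source_group`, e.g. from [enumerate_null_partitions()].
#' @param partition_id optional identifier carried in the result.
#' @return A `plasmode_dataset` with all-zero truth.
#' @export
build_null_plasmode <- function(counts, source_group, partition,
                                partition_id = NA_integer_) {
  cm <- as_count_input(counts)
  src <- names(cm$groups)[cm$groups == source_group]
  if (length(src) == 0L) stop("unknown source group: ", source_group)
  part_samples <- c(partition$A, partition$B)
  if (!setequal(part_samples, src))
    stop("partition does not cover exactly the samples of group ",
         source_group)
  sub <- cm$counts[, part_samples, drop = FALSE]
  grp <- stats::setNames(
    c(rep("A", length(partition$A)), rep("B", length(partition$B))),
    part_samples)
  out <- count_matrix(sub, grp)
  truth <- stats::setNames(numeric(nrow(sub)), rownames(sub))
  new_plasmode(out, partition_id, 0L, truth, NA_integer_)
}

#' Harvest effect sizes from a DE result
#'
#' The spiking pool: maximum-likelihood log2 fold-change estimates of the
#' transcripts declared DE at the given BH-adjusted threshold.
#'
#' @param de_result a `de_result` data.frame (needs columns `lfc_mle` and
#'   `padj`).
#' @param fdr adjusted p-value threshold for inclusion (default 0.05).
#' @return A list of class `effect_pool` with `effects` (numeric log2 fold
#'   changes) and `source_fdr`. Errors when no transcript qualifies.
#' @export
harvest_effect_sizes <- function(de_result, fdr = 0.05) {
  if (!all(c("padj", "lfc_mle") %in% colnames(de_result)))
    stop("de_result must have columns 'lfc_mle' and 'padj'")
  sel <- !is.na(de_result$padj) & de_result$padj <= fdr &
    is.finite(de_result$lfc_mle)
  if (!any(sel))
    stop("no transcripts declared DE at FDR = ", fdr,
         "; the effect pool is empty -- use source data with larger or ",
         "more abundant true effects")
  structure(list(effects = de_result$lfc_mle[sel], source_fdr = fdr),
            class = "effect_pool")
}

#' Spike known effects into a null plasmode
#'
#' Selects `m = round(pi * G)` transcripts uniformly without replacement,
#' draws `m` log2 fold changes from the pool without replacement, and
#' multiplies every group-B count of a chosen transcript by `2^delta`
#' (equivalent to adding `delta` to the log2 counts and back-transforming),
#' rounding half-away-from-zero back to integers. Zero counts stay zero,
#' so a spiked but unexpressed transcript is undetectable by construction
#' (its truth still records `delta != 0`). Group A and all non-spiked
#' transcripts are bit-identical to the null plasmode.
#'
#' @param null_pl a `plasmode_dataset` with all-zero truth.
#' @param pool an [harvest_effect_sizes()] pool with at least `m` effects.
#' @param pi fraction of transcripts to spike (default 0.2).
#' @param seed integer seed; transcript selection and effect assignment
#'   use independent substreams of it.
#' @param replicate_id identifier stored in the result.
#' @return A `plasmode_dataset` whose truth records the spiked `delta` per
#'   transcript (0 elsewhere).
#' @export
spike_de_plasmode <- function(null_pl, pool, pi = 0.2, seed = 1L,
                              replicate_id = 1L) {
  stopifnot(inherits(null_pl, "plasmode_dataset"),
            inherits(pool, "effect_pool"))
  if (any(null_pl$truth != 0)) stop("null plasmode truth must be all zero")
  cm <- null_pl$counts
  G <- nrow(cm$counts)
  m <- as.integer(floor(pi * G + 0.5))
  if (length(pool$effects) < m)
    stop("effect pool (", length(pool$effects),
         ") is smaller than the number of transcripts to spike (", m, ")")
  chosen <- with_substream(seed, paste0("spike_transcripts_",
                                        null_pl$partition_id, "_",
                                        replicate_id),
                           sort(sample.int(G, m)))
  effects <- with_substream(seed, paste0("spike_effects_",
                                         null_pl$partition_id, "_",
                                         replicate_id),
                            sample(pool$effects, m, replace = FALSE))
  counts <- cm$counts
  bsel <- cm$groups == "B"
  counts[chosen, bsel] <- round_half_up(
    counts[chosen, bsel, drop = FALSE] * 2^effects)
  truth <- null_pl$truth
  truth[chosen] <- effects
  out <- count_matrix(counts, cm$groups)
  new_plasmode(out, null_pl$partition_id, as.integer(replicate_id),
               truth, as.integer(seed))
}
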