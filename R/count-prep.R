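#' Stratify transcripts into low/mid/high abundance classes
#'
#' Transcripts are ranked from largest to smallest total read count across
#' all samples. The top `high_pctile` fraction are labeled `high`, the
#' bottom `low_pctile` fraction are labeled `low`, and the rest `mid`.
#' Percentile cutoffs are realized as total-count thresholds with ties
#' included in the respective class, so realized class sizes can exceed the
#' nominal percentiles (a threshold-at-value rule).
#'
#' @param counts a [count_matrix()].
#' @param low_pctile fraction of transcripts (from the bottom of the
#'   abundance ranking) labeled low; default 0.60.
#' @param high_pctile fraction (from the top) labeled high; default 0.03.
#' @return An object of class `abundance_classes`: list with `label` (named
#'   factor low/mid/high), `low_cutoff_total` and `high_cutoff_total` (the
#'   realized integer thresholds: low means total <= low cutoff, high means
#'   total >= high cutoff), and `cum_curve`, a data.frame of
#'   (cumulative fraction of transcripts, cumulative fraction of reads)
#'   pairs from (0,0) to (1,1) along the descending abundance ranking.
#' @export
classify_abundance <- function(counts, low_pctile = 0.60,
                               high_pctile = 0.03) {
  cm <- as_count_input(counts)
  totals <- rowSums(cm$counts)
  G <- length(totals)
  if (G < 2L) stop("need at least 2 transcripts to stratify")
  if (low_pctile + high_pctile >= 1)
    stop("low_pctile + high_pctile must be < 1")
  if (sum(totals) <= 0) stop("all counts are zero; cannot rank abundance")

  sorted <- sort(totals, decreasing = TRUE)
  k_high <- ceiling(high_pctile * G)
  # last rank above the low class; at least one transcript must be low
  k_mid_last <- min(floor((1 - low_pctile) * G), G - 1L)
  high_cutoff <- unname(sorted[k_high])
  low_cutoff <- unname(sorted[k_mid_last + 1L])
  if (low_cutoff >= high_cutoff)
    stop("abundance cutoffs collide (low >= high); ",
         "totals are too uniform to stratify")

  label <- ifelse(totals >= high_cutoff, "high",
                  ifelse(totals <= low_cutoff, "low", "mid"))
  label <- factor(label, levels = c("low", "mid", "high"))
  names(label) <- names(totals)

  cum_curve <- data.frame(
    frac_transcripts = c(0, seq_len(G) / G),
    frac_reads = c(0, cumsum(sorted) / sum(sorted)))

  structure(list(label = label,
                 low_cutoff_total = low_cutoff,
                 high_cutoff_total = high_cutoff,
                 cum_curve = cum_curve),
            class = "abundance_classes")
}

#' @export
print.abundance_classes <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("abundance_classes: %d low / %d mid / %d high\n",
              tab["low"], tab["mid"], tab["high"]))
  cat(sprintf("realized thresholds: low <= %g, high >= %g total reads\n",
              x$low_cutoff_total, x$high_cutoff_total))
  invisible(x)
}

new_filter_result <- function(rule, params, kept) {
  structure(list(rule = rule, params = params, kept = kept,
                 n_removed = sum(!kept)),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result [%s]: removed %d of %d transcripts\n",
              x$rule, x$n_removed, length(x$kept)))
  invisible(x)
}

#' Reads-present (RP) filter
#'
#' Removes a transcript when the number of samples with mapped reads present
#' (count > 0) is smaller than the number of samples per treatment group.
#' For unequal group sizes the larger group size is used as the threshold
#' (with a warning). The input matrix is never modified; a kept/removed mask
#' is returned.
#'
#' @param counts a [count_matrix()] with exactly two groups.
#' @return A `filter_result`: list with `rule`, `params`, `kept` (named
#'   logical per transcript) and `n_removed`.
#' @export
rp_filter <- function(counts) {
  cm <- as_count_input(counts)
  sizes <- table(cm$groups)
  if (length(sizes) != 2L) stop("rp_filter requires exactly two groups")
  if (length(unique(as.integer(sizes))) > 1L) {
    warning("unequal group sizes; using the larger group size (",
            max(sizes), ") as the reads-present threshold")
  }
  thr <- max(sizes)
  kept <- rowSums(cm$counts > 0) >= thr
  new_filter_result("RP", list(min_samples_present = as.integer(thr)), kept)
}

#' Counts per million
#'
#' `cpm[i, j] = counts[i, j] / lib_size[j] * 1e6`, with library sizes the
#' raw column sums of the (unfiltered) matrix.
#'
#' @param counts a [count_matrix()].
#' @return A numeric matrix of the same shape as the counts.
#' @export
compute_cpm <- function(counts) {
  cm <- as_count_input(counts)
  if (any(cm$lib_size <= 0)) stop("zero library size; CPM undefined")
  sweep(cm$counts, 2L, cm$lib_size, "/") * 1e6
}

#' CPM filter
#'
#' Removes a transcript when `min_samples_below` or more samples have fewer
#' than `min_cpm` counts per million for that transcript. Defaults follow
#' the common "two or more samples below 1 CPM" rule. Library sizes are the
#' raw column sums, fixed before any filtering.
#'
#' @param counts a [count_matrix()].
#' @param min_cpm CPM threshold below which a sample counts as "low".
#' @param min_samples_below number of low samples at or above which the
#'   transcript is removed.
#' @return A `filter_result` (see [rp_filter()]).
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples_below = 2L) {
  cm <- as_count_input(counts)
  if (min_samples_below > ncol(cm$counts))
    stop("min_samples_below exceeds the number of samples")
  cpm <- compute_cpm(cm)
  kept <- rowSums(cpm < min_cpm) < min_samples_below
  new_filter_result("CPM", list(min_cpm = min_cpm,
                                min_samples_below = as.integer(min_samples_below)),
                    kept)
}

#' No-op filter (keeps every transcript)
#'
#' @param counts a [count_matrix()].
#' @return A `filter_result` with all transcripts kept.
#' @export
no_filter <- function(counts) {
  cm <- as_count_input(counts)
  kept <- stats::setNames(rep(TRUE, nrow(cm$counts)), rownames(cm$counts))
  new_filter_result("none", list(), kept)
}

#' Apply a filter mask to a count matrix
#'
#' @param cm a [count_matrix()].
#' @param filter a `filter_result` computed on the same transcripts.
#' @return A new [count_matrix()] restricted to the kept transcripts.
#'   Library sizes are recomputed as column sums of the restricted matrix;
#'   CPM values used for filtering always come from the unfiltered matrix.
#' @export
apply_filter <- function(cm, filter) {
  stopifnot(is_count_matrix(cm), inherits(filter, "filter_result"))
  if (!identical(names(filter$kept), rownames(cm$counts)))
    stop("filter mask does not match the count matrix transcripts")
  out <- count_matrix(cm$counts[filter$kept, , drop = FALSE], cm$groups)
  tr <- attr(cm, "truth_lfc")
  if (!is.null(tr)) attr(out, "truth_lfc") <- tr[filter$kept]
  out
}
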