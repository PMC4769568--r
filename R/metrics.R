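#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th order statistic by
#' `m / i`, takes the cumulative minimum from the largest down, caps at 1,
#' and restores the input order. Missing values pass through as missing
#' (they do not count toward `m`). Adjusted values are always >= the raw
#' p-values and preserve their ordering.
#'
#' @param pvalues numeric vector in [0, 1]; `NA` allowed.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(out)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}

#' Confusion table of DE calls against spiked truth
#'
#' A transcript with nonzero truth `delta` is truly DE; one with zero
#' `delta` is null. `TP` = called and truly DE, `FP` = called and null,
#' with the margins `S1 = TP + FN` (truly DE), `S0 = FP + TN` (null),
#' `R1 = TP + FP` (declared DE), `R0 = TN + FN` and `G` the total.
#'
#' @param calls named logical vector of DE calls per transcript.
#' @param truth named numeric vector of true log2 fold changes (0 = null)
#'   on the identical transcript set.
#' @return A list of class `confusion_table` with `TP`, `FP`, `TN`, `FN`,
#'   `S0`, `S1`, `R0`, `R1`, `G`.
#' @export
confusion <- function(calls, truth) {
  if (is.null(names(calls)) || is.null(names(truth)))
    stop("calls and truth must be named by transcript id")
  if (!setequal(names(calls), names(truth)))
    stop("calls and truth cover different transcript sets")
  truth <- truth[names(calls)]
  de <- truth != 0
  TP <- sum(calls & de); FP <- sum(calls & !de)
  FN <- sum(!calls & de); TN <- sum(!calls & !de)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 S1 = TP + FN, S0 = FP + TN,
                 R1 = TP + FP, R0 = TN + FN,
                 G = TP + FP + TN + FN),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion_table: TP=%d FP=%d TN=%d FN=%d (G=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$G))
  invisible(x)
}

#' Performance metrics from a confusion table
#'
#' `FPR = FP / S0`, `TPR (power) = TP / S1`, `PPV (precision) = TP / R1`,
#' `NPV = TN / R0`, `ACC = (TP + TN) / G`. A metric whose denominator is
#' zero is flagged as undefined and reported as `NA` (never silently 0
#' or 1); the flagged names are listed in the `undefined` element.
#'
#' @param ct a [confusion()] table with `G > 0`.
#' @return A list with `FPR`, `TPR`, `PPV`, `NPV`, `ACC` and `undefined`
#'   (character vector of flagged metrics).
#' @export
performance <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct$G <= 0) stop("empty confusion table (G = 0)")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(FPR = ratio(ct$FP, ct$S0),
              TPR = ratio(ct$TP, ct$S1),
              PPV = ratio(ct$TP, ct$R1),
              NPV = ratio(ct$TN, ct$R0),
              ACC = (ct$TP + ct$TN) / ct$G)
  out$undefined <- names(out)[vapply(out, function(v)
    is.na(suppressWarnings(as.numeric(v[1]))), logical(1))]
  out
}

#' Stratified performance metrics
#'
#' Computes confusion tables and metrics on the full transcript set and
#' restricted to the low- and high-abundance strata. Stratum membership is
#' frozen from the abundance classes of the source (pre-plasmode) data so
#' that spiking cannot migrate transcripts between strata.
#'
#' @param calls named logical DE calls.
#' @param truth named numeric truth (0 = null).
#' @param classes an [classify_abundance()] result on the same transcripts
#'   (extra transcripts in `classes` are ignored; missing ones error).
#' @param method optional method label carried into the records.
#' @return A data.frame with one row per stratum (`all`, `low`, `high`) and
#'   columns `method`, `stratum`, `n`, `TP`, `FP`, `TN`, `FN`, `FPR`,
#'   `TPR`, `PPV`, `NPV`, `ACC` (undefined metrics are `NA`); empty strata
#'   yield a row with `n = 0` and all-NA metrics.
#' @export
stratified_performance <- function(calls, truth, classes,
                                   method = "unknown") {
  lab <- classes$label
  if (!all(names(calls) %in% names(lab)))
    stop("abundance classes are missing some transcripts")
  lab <- lab[names(calls)]
  one <- function(stratum, sel) {
    if (!any(sel)) {
      return(data.frame(method = method, stratum = stratum, n = 0L,
                        TP = NA, FP = NA, TN = NA, FN = NA,
                        FPR = NA, TPR = NA, PPV = NA, NPV = NA, ACC = NA))
    }
    ct <- confusion(calls[sel], truth[sel])
    pf <- performance(ct)
    data.frame(method = method, stratum = stratum, n = ct$G,
               TP = ct$TP, FP = ct$FP, TN = ct$TN, FN = ct$FN,
               FPR = pf$FPR, TPR = pf$TPR, PPV = pf$PPV, NPV = pf$NPV,
               ACC = pf$ACC)
  }
  rbind(one("all", rep(TRUE, length(calls))),
        one("low", lab == "low"),
        one("high", lab == "high"))
}
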