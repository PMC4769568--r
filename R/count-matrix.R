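#' Count matrix with sample annotation
#'
#' Container for a transcripts x samples matrix of non-negative integer read
#' counts, a two-group (or more) sample annotation, and per-sample library
#' sizes (column sums). This is the object every other function in the
#' package consumes.
#'
#' @param counts integer matrix, transcripts in rows, samples in columns.
#'   Must have unique rownames (transcript ids) and colnames (sample ids).
#' @param groups character or factor vector of group labels, one per sample,
#'   either named by sample id or in column order.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `groups` (named factor) and `lib_size` (named numeric,
#'   column sums of `counts`).
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("t", 1:5), paste0("s", 1:4)))
#' cm <- count_matrix(m, rep(c("A", "B"), each = 2))
#' @export
count_matrix <- function(counts, groups) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("t%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  if (anyDuplicated(rownames(counts))) stop("transcript ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (length(groups) != ncol(counts))
    stop("one group label per sample is required")
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(counts)))
      stop("group names do not match sample ids")
    groups <- groups[colnames(counts)]
  } else {
    names(groups) <- colnames(counts)
  }
  groups <- factor(as.character(groups))
  names(groups) <- colnames(counts)
  structure(
    list(counts = counts, groups = groups, lib_size = colSums(counts)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups: ",
      paste(sprintf("%s(%d)", levels(x$groups), table(x$groups)),
            collapse = ", "), "\n", sep = "")
  cat("library sizes: ",
      paste(format(x$lib_size, big.mark = ","), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

is_count_matrix <- function(x) inherits(x, "count_matrix")

as_count_input <- function(counts, groups = NULL) {
  if (is_count_matrix(counts)) return(counts)
  count_matrix(counts, groups)
}

#' Read / write count matrices as TSV
#'
#' The on-disk format is a tab-separated table whose first column is
#' `transcript_id` and remaining columns are sample ids with integer cells,
#' plus a companion two-column table `sample_id<TAB>group`.
#'
#' @param counts_file path to the counts TSV.
#' @param groups_file path to the sample annotation TSV.
#' @return `read_count_matrix` returns a [count_matrix()];
#'   `write_count_matrix` invisibly returns the paths written.
#' @export
read_count_matrix <- function(counts_file, groups_file) {
  tab <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "transcript_id")
    stop("first column of a counts TSV must be 'transcript_id'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$transcript_id
  ann <- utils::read.delim(groups_file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(ann)))
    stop("groups TSV needs columns 'sample_id' and 'group'")
  grp <- stats::setNames(ann$group, ann$sample_id)
  count_matrix(m, grp)
}

#' @param cm a [count_matrix()].
#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(cm, counts_file, groups_file) {
  stopifnot(is_count_matrix(cm))
  tab <- data.frame(transcript_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample_id = names(cm$groups),
                    group = as.character(cm$groups))
  utils::write.table(ann, groups_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_file, groups_file))
}

# Deterministic 31-bit sub-seed for a named stream of randomness.  One
# top-level seed expands into independent per-purpose substreams so that,
# e.g., enlarging a simulated matrix does not perturb earlier draws.
substream_seed <- function(seed, purpose) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(as.character(purpose))) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, purpose, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, purpose))
  expr
}
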