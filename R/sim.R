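#' Simulation configuration for synthetic RNA-seq counts
#'
#' Describes the statistical world the generator draws from: a log-normal
#' distribution of baseline expected counts (whose heavy right tail places
#' ~60% of transcripts in a low-count class holding only a few percent of
#' the reads), a negative-binomial dispersion trend decreasing with the
#' mean, unequal library sizes, an optional set of "group-only" transcripts
#' (all-zero counts in one group), and optional true log2 fold changes.
#'
#' With the default `logmean_scale` of 2.13 the bottom 60% of transcripts
#' (by expected abundance) hold about 3% of the reads and the top 3% hold
#' about 60% -- the shape that motivates the low-count stratification.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param n_per_group samples per group (two groups); must be >= 2.
#' @param logmean_location,logmean_scale location and scale (natural-log
#'   scale) of the log-normal distribution of baseline expected counts q_i.
#' @param disp_a0,disp_a1 dispersion trend alpha(mu) = disp_a0 + disp_a1/mu,
#'   evaluated at q_i; both non-negative, sum positive.
#' @param libsize_factors either a numeric vector of one positive multiplier
#'   per sample, or a length-2 range from which per-sample multipliers are
#'   drawn log-uniformly.
#' @param frac_group_only fraction in [0, 1) of transcripts forced to
#'   all-zero counts in one group (alternating between the two groups).
#' @param true_lfc_map optional numeric vector of true log2 fold changes:
#'   either length `n_transcripts` (in transcript order) or named by
#'   transcript id (`t00001`, ...) for a subset; absent transcripts get 0.
#' @param seed integer seed; all randomness flows from it through named
#'   substreams (transcript parameters / structure / counts).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000L,
                       n_per_group = 4L,
                       logmean_location = log(5),
                       logmean_scale = 2.13,
                       disp_a0 = 0.1,
                       disp_a1 = 1,
                       libsize_factors = c(0.5, 2),
                       frac_group_only = 0,
                       true_lfc_map = NULL,
                       seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              n_per_group = as.integer(n_per_group),
              logmean_location = logmean_location,
              logmean_scale = logmean_scale,
              disp_a0 = disp_a0, disp_a1 = disp_a1,
              libsize_factors = libsize_factors,
              frac_group_only = frac_group_only,
              true_lfc_map = true_lfc_map,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_transcripts < 1L) stop("n_transcripts must be positive")
  if (cfg$n_per_group < 2L) stop("n_per_group must be >= 2")
  if (cfg$disp_a0 < 0 || cfg$disp_a1 < 0 || cfg$disp_a0 + cfg$disp_a1 <= 0)
    stop("invalid dispersion parameters: need disp_a0, disp_a1 >= 0, sum > 0")
  if (cfg$logmean_scale < 0) stop("logmean_scale must be non-negative")
  ls <- cfg$libsize_factors
  n_samples <- 2L * cfg$n_per_group
  if (!(length(ls) == 2L || length(ls) == n_samples))
    stop("libsize_factors must be a range (length 2) or one value per sample")
  if (any(ls <= 0)) stop("libsize_factors must be positive")
  if (cfg$frac_group_only < 0 || cfg$frac_group_only >= 1)
    stop("frac_group_only must be in [0, 1)")
  invisible(cfg)
}

# Expand true_lfc_map to a per-transcript delta vector (0 where unspecified).
resolve_true_lfc <- function(cfg, ids) {
  delta <- stats::setNames(numeric(length(ids)), ids)
  m <- cfg$true_lfc_map
  if (is.null(m)) return(delta)
  if (is.null(names(m))) {
    if (length(m) != length(ids))
      stop("unnamed true_lfc_map must have one entry per transcript")
    delta[] <- m
  } else {
    unknown <- setdiff(names(m), ids)
    if (length(unknown))
      stop("true_lfc_map names unknown transcripts: ", unknown[1])
    delta[names(m)] <- m
  }
  delta
}

#' Generate a synthetic two-group count matrix
#'
#' Counts are drawn from a gamma-Poisson (negative binomial) model:
#' `counts[i, j] ~ NB(mean = s_j * q_i * 2^(delta_i * g_j),
#' dispersion = disp_a0 + disp_a1 / q_i)` with `q_i` log-normal, `s_j` the
#' library-size factor and `g_j` the 0/1 group indicator, so that
#' `Var = mu + alpha * mu^2`. Transcripts designated "group-only" have all
#' counts in one group zeroed after the draw. The generator is fully
#' deterministic given `config$seed`, and uses independent substreams for
#' transcript parameters, structural choices and count draws, so enlarging
#' `n_transcripts` leaves earlier transcripts' draws unchanged.
#'
#' @param config a [sim_config()].
#' @return A [count_matrix()] with groups `g1`/`g2` and attributes
#'   `truth_lfc` (named per-transcript true log2 fold change) and
#'   `group_only` (named character: `""`, `"g1"` or `"g2"` -- the group whose
#'   counts were zeroed).
#' @export
generate_counts <- function(config) {
  validate_sim_config(config)
  G <- config$n_transcripts
  npg <- config$n_per_group
  S <- 2L * npg
  ids <- sprintf("t%05d", seq_len(G))
  samples <- sprintf("s%02d", seq_len(S))
  groups <- rep(c("g1", "g2"), each = npg)
  g <- rep(c(0, 1), each = npg)

  q <- with_substream(config$seed, "transcript_params",
                      stats::rlnorm(G, config$logmean_location,
                                    config$logmean_scale))
  alpha <- config$disp_a0 + config$disp_a1 / q

  struct <- with_substream(config$seed, "structure", {
    s <- if (length(config$libsize_factors) == S) {
      config$libsize_factors
    } else {
      r <- range(config$libsize_factors)
      exp(stats::runif(S, log(r[1]), log(r[2])))
    }
    n_go <- as.integer(floor(config$frac_group_only * G + 0.5))
    go_idx <- if (n_go > 0L) sort(sample.int(G, n_go)) else integer(0)
    list(s = s, go_idx = go_idx)
  })

  delta <- resolve_true_lfc(config, ids)
  # mean model: transcripts x samples
  mu <- outer(q, struct$s) * 2^(delta %o% g)
  counts <- with_substream(config$seed, "counts", {
    # transcript-major draw order keeps early transcripts stable when G grows
    matrix(stats::rnbinom(G * S, mu = as.vector(t(mu)),
                          size = rep(1 / alpha, each = S)),
           nrow = G, byrow = TRUE)
  })

  group_only <- stats::setNames(character(G), ids)
  if (length(struct$go_idx)) {
    zero_grp <- rep(c("g1", "g2"), length.out = length(struct$go_idx))
    for (k in seq_along(struct$go_idx)) {
      counts[struct$go_idx[k], groups == zero_grp[k]] <- 0
    }
    group_only[struct$go_idx] <- zero_grp
  }

  dimnames(counts) <- list(ids, samples)
  cm <- count_matrix(counts, stats::setNames(groups, samples))
  attr(cm, "truth_lfc") <- delta
  attr(cm, "group_only") <- group_only
  cm
}

#' Generate a synthetic null count matrix
#'
#' As [generate_counts()] with every true log2 fold change forced to zero
#' and no group-only transcripts: the two groups are exchangeable and any
#' DE call on the result is a false positive.
#'
#' @param config a [sim_config()]; `true_lfc_map` and `frac_group_only`
#'   are ignored (forced to null).
#' @return A [count_matrix()] with all-zero `truth_lfc`.
#' @export
generate_null_counts <- function(config) {
  config$true_lfc_map <- NULL
  config$frac_group_only <- 0
  generate_counts(config)
}
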