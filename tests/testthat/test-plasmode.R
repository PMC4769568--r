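test_that("enumerate_null_partitions counts and canonical form", {
  p4 <- enumerate_null_partitions(c("s1", "s2", "s3", "s4"))
  expect_length(p4, 3)
  expect_true(all(vapply(p4, function(p) p$A[1] == "s1", logical(1))))
  expect_length(enumerate_null_partitions(c("a", "b")), 1)

  # brute-force oracle for n = 6: unordered equal splits via combn
  ids <- paste0("x", 1:6)
  all_halves <- combn(ids, 3, simplify = FALSE)
  uniq <- Filter(function(h) "x1" %in% h, all_halves)
  p6 <- enumerate_null_partitions(ids)
  expect_length(p6, length(uniq))      # C(6,3)/2 = 10
  expect_length(p6, 10)
  got <- lapply(p6, function(p) sort(p$A))
  expect_setequal(vapply(got, paste, collapse = ",", character(1)),
                  vapply(lapply(uniq, sort), paste, collapse = ",",
                         character(1)))
  expect_error(enumerate_null_partitions(paste0("s", 1:5)), "even")
})

test_that("build_null_plasmode relabels without altering counts", {
  cm <- generate_null_counts(sim_config(n_transcripts = 80, seed = 21))
  src <- names(cm$groups)[cm$groups == "g1"]
  parts <- enumerate_null_partitions(src)
  pl <- build_null_plasmode(cm, "g1", parts[[1]], partition_id = 1L)
  expect_true(all(pl$truth == 0))
  expect_equal(sort(colnames(pl$counts$counts)), sort(src))
  # conservation: per-transcript multiset of values identical to source
  for (i in c(1, 40, 80)) {
    expect_equal(sort(as.numeric(pl$counts$counts[i, ])),
                 sort(as.numeric(cm$counts[i, src])))
  }
  # different partitions are column permutations of each other
  pl2 <- build_null_plasmode(cm, "g1", parts[[2]], partition_id = 2L)
  expect_identical(pl$counts$counts[, sort(src)],
                   pl2$counts$counts[, sort(src)])
  expect_error(build_null_plasmode(cm, "g1",
                                   list(A = c("s01", "s05"),
                                        B = c("s02", "s03"))),
               "partition")
})

test_that("harvest_effect_sizes thresholds on adjusted p", {
  de <- data.frame(transcript_id = c("a", "b", "c"),
                   lfc_mle = c(1.5, 0.2, -2.0),
                   padj = c(0.01, 0.2, 0.04))
  pool <- harvest_effect_sizes(de)
  expect_setequal(pool$effects, c(1.5, -2.0))
  de_null <- transform(de, padj = c(0.2, 0.3, 0.9))
  expect_error(harvest_effect_sizes(de_null), "empty")
  pool_all <- harvest_effect_sizes(de, fdr = 1)
  expect_length(pool_all$effects, 3)
})

test_that("spike_de_plasmode bookkeeping, zeros, and conservation", {
  cm <- generate_null_counts(sim_config(n_transcripts = 1000, seed = 31))
  src <- names(cm$groups)[cm$groups == "g1"]
  pl0 <- build_null_plasmode(cm, "g1",
                             enumerate_null_partitions(src)[[1]], 1L)
  pool <- structure(list(effects = runif(400, -3, 3), source_fdr = 0.05),
                    class = "effect_pool")
  pl <- spike_de_plasmode(pl0, pool, pi = 0.2, seed = 5)
  expect_equal(sum(pl$truth != 0), 200)          # round(0.2 * 1000)
  # group A and non-spiked transcripts bit-identical
  a_cols <- names(pl$counts$groups)[pl$counts$groups == "A"]
  expect_identical(pl$counts$counts[, a_cols], pl0$counts$counts[, a_cols])
  ns <- names(pl$truth)[pl$truth == 0]
  expect_identical(pl$counts$counts[ns, ], pl0$counts$counts[ns, ])
  # spiked B-group counts follow round(y * 2^delta), zeros stay zero
  b_cols <- names(pl$counts$groups)[pl$counts$groups == "B"]
  sp <- names(pl$truth)[pl$truth != 0]
  expected <- floor(pl0$counts$counts[sp, b_cols] * 2^pl$truth[sp] + 0.5)
  expect_identical(pl$counts$counts[sp, b_cols], expected)
  expect_true(all(pl$counts$counts >= 0))
  expect_true(all(pl$counts$counts == round(pl$counts$counts)))
  zero_before <- pl0$counts$counts[sp, b_cols] == 0
  expect_true(all(pl$counts$counts[sp, b_cols][zero_before] == 0))
  # determinism and explicit spot values
  pl_again <- spike_de_plasmode(pl0, pool, pi = 0.2, seed = 5)
  expect_identical(pl$counts$counts, pl_again$counts$counts)
  expect_identical(pl$truth, pl_again$truth)
  # pool too small errors
  small_pool <- structure(list(effects = runif(10), source_fdr = 0.05),
                          class = "effect_pool")
  expect_error(spike_de_plasmode(pl0, small_pool, pi = 0.2, seed = 1),
               "smaller")
})

test_that("spiking arithmetic matches the log2 definition", {
  counts <- matrix(c(100, 50, 0, 7), nrow = 2, byrow = TRUE,
                   dimnames = list(c("t1", "t2"), c("sA", "sB")))
  cm <- count_matrix(counts, c(sA = "A", sB = "B"))
  pl0 <- structure(list(counts = cm, partition_id = 1L, replicate_id = 0L,
                        truth = c(t1 = 0, t2 = 0), seed = NA_integer_),
                   class = "plasmode_dataset")
  pool <- structure(list(effects = c(1, 1), source_fdr = 0.05),
                    class = "effect_pool")
  pl <- spike_de_plasmode(pl0, pool, pi = 1, seed = 2)  # spike both rows
  expect_equal(unname(pl$counts$counts[, "sA"]), c(100, 0))  # A untouched
  expect_equal(unname(pl$counts$counts["t1", "sB"]), 100)    # 50 * 2^1
  expect_equal(unname(pl$counts$counts["t2", "sB"]), 14)     # 7 * 2^1
})
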