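test_that("bh_adjust matches hand computation and the brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.05, 0.2)),
               c(0.04, 0.04, 0.2 / 3, 0.2))
  set.seed(12)
  for (i in 1:1000) {
    m <- sample(1:25, 1)
    p <- round(runif(m), 3)
    expect_equal(bh_adjust(p), brute_force_bh(p))
  }
})

test_that("bh_adjust properties: monotone, order-preserving, NA-passthrough", {
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))                          # never below raw
  expect_true(all(diff(adj[order(p)]) >= -1e-15))     # order preserved
  # re-adjusting never decreases (BH is not idempotent in general:
  # p = (0.1, 0.9) -> (0.2, 0.9) -> (0.4, 0.9))
  expect_true(all(bh_adjust(adj) >= adj - 1e-15))
  expect_equal(bh_adjust(c(0.1, 0.9)), c(0.2, 0.9))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])       # permutation-equivariant
  p_na <- c(0.01, NA, 0.5)
  out <- bh_adjust(p_na)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_adjust(c(0.01, 0.5)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("confusion counts and margins follow the classification rules", {
  calls <- c(a = TRUE, b = TRUE, c = FALSE, d = TRUE, e = FALSE, f = FALSE)
  truth <- c(a = 2, b = 1.5, c = -1, d = 0, e = 0, f = 0)
  ct <- confusion(calls, truth)     # 3 spiked: 2 called; 1 null called
  expect_equal(ct$TP, 2); expect_equal(ct$FN, 1)
  expect_equal(ct$FP, 1); expect_equal(ct$TN, 2)
  expect_equal(ct$S1, 3); expect_equal(ct$S0, 3)
  expect_equal(ct$R1, 3); expect_equal(ct$R0, 3)
  expect_equal(ct$G, 6)
  # degenerate corners
  ct0 <- confusion(c(x = FALSE, y = FALSE), c(x = 0, y = 0))
  expect_equal(ct0$TN, 2); expect_equal(ct0$TP + ct0$FP + ct0$FN, 0)
  ct1 <- confusion(c(x = TRUE, y = TRUE), c(x = 1, y = 2))
  expect_equal(performance(ct1)$ACC, 1)
  expect_error(confusion(calls, truth[1:5]), "different")
})

test_that("performance applies the metric formulas and flags undefined", {
  ct <- structure(list(TP = 30, FP = 20, TN = 940, FN = 10,
                       S1 = 40, S0 = 960, R1 = 50, R0 = 950, G = 1000),
                  class = "confusion_table")
  pf <- performance(ct)
  expect_equal(pf$FPR, 20 / 960)
  expect_equal(pf$TPR, 0.75)
  expect_equal(pf$PPV, 0.6)
  expect_equal(pf$NPV, 940 / 950)
  expect_equal(pf$ACC, 0.97)
  expect_length(pf$undefined, 0)

  ct_r1 <- structure(list(TP = 0, FP = 0, TN = 5, FN = 1,
                          S1 = 1, S0 = 5, R1 = 0, R0 = 6, G = 6),
                     class = "confusion_table")
  pf_r1 <- performance(ct_r1)
  expect_true(is.na(pf_r1$PPV))
  expect_true("PPV" %in% pf_r1$undefined)
  expect_false(is.na(pf_r1$FPR))
  ct_empty <- structure(list(TP = 0, FP = 0, TN = 0, FN = 0, S1 = 0,
                             S0 = 0, R1 = 0, R0 = 0, G = 0),
                        class = "confusion_table")
  expect_error(performance(ct_empty), "G = 0")
})

test_that("stratified_performance restricts confusion to frozen strata", {
  ids <- sprintf("t%02d", 1:10)
  calls <- setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE,
                      FALSE, FALSE, TRUE, FALSE, FALSE), ids)
  truth <- setNames(c(2, 0, 1, 0, 0, 0, 1.5, 0, 0, 0), ids)
  lab <- setNames(factor(c(rep("low", 4), rep("mid", 4), rep("high", 2)),
                         levels = c("low", "mid", "high")), ids)
  classes <- structure(list(label = lab), class = "abundance_classes")
  sp <- stratified_performance(calls, truth, classes, method = "toy")
  low <- sp[sp$stratum == "low", ]
  # hand enumeration over t01..t04: TP=1 (t01), FP=1 (t02), FN=1 (t03), TN=1
  expect_equal(low$TP, 1); expect_equal(low$FP, 1)
  expect_equal(low$FN, 1); expect_equal(low$TN, 1)
  expect_equal(low$n + sp[sp$stratum == "high", ]$n + sum(lab == "mid"), 10)
  # all transcripts in one stratum: stratum record equals the "all" record
  lab_all_low <- setNames(factor(rep("low", 10),
                                 levels = c("low", "mid", "high")), ids)
  cls2 <- structure(list(label = lab_all_low), class = "abundance_classes")
  sp2 <- stratified_performance(calls, truth, cls2)
  low2 <- sp2[sp2$stratum == "low", -2]
  all2 <- sp2[sp2$stratum == "all", -2]
  rownames(low2) <- rownames(all2) <- NULL
  expect_equal(low2, all2)
  # empty stratum flagged with n = 0
  expect_equal(sp2[sp2$stratum == "high", ]$n, 0)
})
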