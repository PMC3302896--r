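contacts_df <- function(...) {
  m <- rbind(...)
  if (is.null(m)) {
    return(data.frame(i = integer(), j = integer(),
                      orientation = character()))
  }
  data.frame(i = m[, 1], j = m[, 2],
             orientation = if (ncol(m) > 2) c("A", "P")[m[, 3]] else "A")
}

test_that("confusion counts cover all strand pairs", {
  native <- contacts_df(c(1, 2), c(2, 3), c(3, 4))
  cf <- confusion(native, native, n_strands = 4)
  expect_equal(unlist(cf[c("tp", "fp", "fn", "tn")]), c(tp = 3, fp = 0, fn = 0, tn = 3))

  empty <- contacts_df()
  cf2 <- confusion(empty, native, n_strands = 4)
  expect_equal(unlist(cf2[c("tp", "fn", "tn", "fp")]), c(tp = 0, fn = 3, tn = 3, fp = 0))

  pred <- contacts_df(c(1, 3), c(2, 4))
  nat <- contacts_df(c(1, 2), c(3, 4))
  cf3 <- confusion(pred, nat, n_strands = 4)
  expect_equal(unlist(cf3[c("tp", "fp", "fn", "tn")]), c(tp = 0, fp = 2, fn = 2, tn = 2))

  # pair-mode counts always total C(N, 2); independent per-pair recount
  set.seed(5)
  for (trial in 1:25) {
    n <- sample(3:7, 1)
    ap <- t(combn(n, 2))
    pred <- ap[sample(nrow(ap), sample(0:(n - 1), 1)), , drop = FALSE]
    nat <- ap[sample(nrow(ap), sample(1:(n - 1), 1)), , drop = FALSE]
    pd <- data.frame(i = pred[, 1], j = pred[, 2],
                     orientation = rep("A", nrow(pred)))
    nd <- data.frame(i = nat[, 1], j = nat[, 2],
                     orientation = rep("A", nrow(nat)))
    cf <- confusion(pd, nd, n_strands = n)
    expect_equal(cf$tp + cf$fp + cf$tn + cf$fn, choose(n, 2))
    # direct double loop over the pair universe
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      inp <- any(pred[, 1] == a & pred[, 2] == b)
      inn <- any(nat[, 1] == a & nat[, 2] == b)
      if (inp && inn) tp <- tp + 1
      else if (inp) fp <- fp + 1
      else if (inn) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unlist(cf[c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
  }
})

test_that("orientation-strict mode double-counts orientation mismatches", {
  pred <- contacts_df(c(1, 2, 1), c(2, 3, 2))    # (1,2) A, (2,3) P
  nat <- contacts_df(c(1, 2, 1), c(2, 3, 1))     # (1,2) A, (2,3) A
  cf <- confusion(pred, nat, n_strands = 4, mode = "pair_orientation")
  expect_equal(unlist(cf[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 1, fn = 1, tn = 4))
  # same pairs in agnostic mode: both true positives
  cf2 <- confusion(pred, nat, n_strands = 4, mode = "pair")
  expect_equal(cf2$tp, 2)
})

test_that("metrics follow the formulas and zero-denominator conventions", {
  m <- metrics(list(tp = 3, fp = 1, tn = 5, fn = 1))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$mcc, (3 * 5 - 1 * 1) / sqrt(4 * 4 * 6 * 6))

  perfect <- metrics(list(tp = 3, fp = 0, tn = 3, fn = 0))
  expect_equal(perfect$precision, 1); expect_equal(perfect$recall, 1)
  expect_equal(perfect$mcc, 1)

  z <- metrics(list(tp = 0, fp = 0, tn = 6, fn = 2))
  expect_equal(z$precision, 0)
  expect_match(paste(attr(z, "flags"), collapse = ";"), "precision")
  expect_equal(z$mcc, 0)

  # systematic check over enumerated confusion tables
  for (tp in 0:3) for (fp in 0:3) for (tn in 0:3) for (fn in 0:3) {
    m <- metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den > 0) {
      expect_equal(m$mcc, (tp * tn - fp * fn) / sqrt(den))
      expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    } else expect_equal(m$mcc, 0)
    expect_gte(m$precision, 0); expect_lte(m$precision, 1)
    # MCC is symmetric under swapping prediction and truth (fp <-> fn)
    ms <- metrics(list(tp = tp, fp = fn, tn = tn, fn = fp))
    expect_equal(ms$mcc, m$mcc)
  }
})

test_that("weighted average equals the spec arithmetic and the plain mean", {
  df <- data.frame(n_strands = c(3, 4, 4, 4),
                   precision = c(1.0, 0.5, 0.5, 0.5))
  expect_equal(unname(weighted_average(df)["precision"]), 0.625)
  one <- data.frame(n_strands = 5, precision = 0.7, mcc = 0.4)
  expect_equal(unname(weighted_average(one)), c(0.7, 0.4))
  expect_error(weighted_average(one[0, ]), "no per-protein")
  # equals the unweighted per-protein mean on random tables
  set.seed(31)
  for (trial in 1:20) {
    df <- data.frame(n_strands = sample(3:6, 12, replace = TRUE),
                     mcc = runif(12))
    expect_equal(unname(weighted_average(df)["mcc"]), mean(df$mcc))
  }
})

test_that("best_of_top_k picks the best rank and is monotone in k", {
  p <- toy_protein(rep("VIVIV", 4))
  native <- mk_edge_topology(p, rbind(c(1, 2), c(2, 3), c(3, 4)))
  wrong <- mk_edge_topology(p, rbind(c(1, 3), c(2, 4), c(1, 2)))
  half <- mk_edge_topology(p, rbind(c(1, 2), c(2, 4), c(3, 4)))
  ranked <- list(wrong, half, native, half, wrong)
  m5 <- best_of_top_k(ranked, native, 5)
  expect_equal(m5$precision, 1); expect_equal(attr(m5, "rank"), 3L)
  m1 <- best_of_top_k(ranked, native, 1)
  expect_equal(m1$mcc, metrics(confusion(wrong, native))$mcc)
  prev <- -Inf
  for (k in 1:5) {
    mk <- best_of_top_k(ranked, native, k)
    expect_gte(mk$mcc, prev - 1e-12)
    prev <- mk$mcc
  }
})

test_that("strand mapping is greedy, one-to-one and overlap-driven", {
  pred <- data.frame(start = c(4, 10), end = c(9, 14))
  nat <- data.frame(start = c(3, 10), end = c(7, 14))
  mp <- map_strands(pred, nat)
  expect_equal(mp$native[mp$predicted == 1], 1)   # overlap 4 beats 0
  expect_equal(mp$native[mp$predicted == 2], 2)

  ident <- map_strands(nat, nat)
  expect_equal(ident$predicted, ident$native)

  # two predicted strands over one native: only the larger-overlap one maps
  pred2 <- data.frame(start = c(1, 5), end = c(4, 10))
  nat2 <- data.frame(start = 3, end = 10)
  mp2 <- map_strands(pred2, nat2)
  expect_equal(nrow(mp2), 1L)
  expect_equal(mp2$predicted, 2L)
})

test_that("aligned-pair accuracy scores exact register matches only", {
  p <- toy_protein(c("VIVIV", "IVIVI", "VIVIV"))
  native <- sheet_topology(list(
    manual_contact(p, 1, 2, "A", 1:4, 4:1),
    manual_contact(p, 2, 3, "A", 1:4, 4:1)), n_strands = 3L)
  expect_equal(aligned_pair_accuracy(native, native), 1.0)

  shifted <- sheet_topology(list(
    manual_contact(p, 1, 2, "A", 1:4, 5:2),    # register off by one
    manual_contact(p, 2, 3, "A", 1:4, 4:1)), n_strands = 3L)
  expect_equal(aligned_pair_accuracy(shifted, native), 0.5)

  only_bad <- sheet_topology(list(
    manual_contact(p, 1, 2, "A", 1:4, 5:2)), n_strands = 3L)
  expect_equal(aligned_pair_accuracy(only_bad, native), 0.0)

  none <- sheet_topology(list(manual_contact(p, 1, 3, "A", 1:4, 4:1)),
                         n_strands = 3L)
  expect_true(is.na(aligned_pair_accuracy(none, native)))
})
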