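test_that("confusion counts follow the inclusive threshold convention", {
  ct <- confusion_at(c(0.9, 0.1), c(TRUE, FALSE), 0.5)
  expect_equal(unlist(ct[c("TP", "TN", "FP", "FN")]),
               c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # threshold 0 calls everything disordered
  ct0 <- confusion_at(runif(20), rnd_labels(20), 0)
  expect_equal(ct0$FN, 0L)
  expect_equal(ct0$TN, 0L)
  ct2 <- confusion_at(c(0.6, 0.6, 0.2), c(TRUE, FALSE, TRUE), 0.5)
  expect_equal(unlist(ct2[c("TP", "FP", "TN", "FN")]),
               c(TP = 1L, FP = 1L, TN = 0L, FN = 1L))
  # strict flag flips the boundary call
  expect_equal(confusion_at(c(0.5), c(TRUE, FALSE)[1], 0.5, strict = TRUE)$TP, 0L)
  expect_error(confusion_at(numeric(0), logical(0), 0.5), "length|no scored")
})

test_that("Sw hits its analytic endpoints", {
  w <- class_weights(rep(c(TRUE, FALSE), c(20, 80)))
  expect_equal(sw(confusion_counts(20, 80, 0, 0), w), 1.0)
  # everything called disordered scores exactly 0
  expect_equal(sw(confusion_counts(20, 0, 80, 0), w), 0.0)
  expect_equal(sw(confusion_counts(30, 40, 10, 20),
                  class_weights(rep(c(TRUE, FALSE), each = 50))), 0.4)
})

test_that("the printed-denominator Sw variant is available but differs", {
  w <- class_weights(rep(c(TRUE, FALSE), c(20, 80)))
  perfect <- confusion_counts(20, 80, 0, 0)
  expect_equal(sw(perfect, w), 1.0)
  expect_lt(sw(perfect, w, denominator = "printed"), 1.0)
})

test_that("MCC matches hand arithmetic and degenerate conventions", {
  expect_equal(mcc(confusion_counts(30, 40, 10, 20)),
               1000 / sqrt(40 * 50 * 50 * 60))
  expect_equal(mcc(confusion_counts(25, 25, 25, 25)), 0)
  expect_equal(mcc(confusion_counts(10, 10, 0, 0)), 1.0)
  expect_warning(val <- mcc(confusion_counts(5, 0, 5, 0)), "degenerate")
  expect_equal(val, 0)
})

test_that("MCC is invariant under simultaneous TP<->TN, FP<->FN swap", {
  set.seed(3)
  for (i in 1:50) {
    ct <- sample(1:50, 4)
    expect_equal(mcc(confusion_counts(ct[1], ct[2], ct[3], ct[4])),
                 mcc(confusion_counts(ct[2], ct[1], ct[4], ct[3])))
  }
})

test_that("Sw and MCC equal brute-force recomputation on random instances", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    y <- rnd_labels(n)
    s <- round(runif(n), 2)
    t <- sample(seq(0, 1, 0.01), 1)
    w <- class_weights(y)
    expect_equal(sw(confusion_at(s, y, t), w), bf_sw(s, y, t))
    expect_equal(suppressWarnings(mcc(confusion_at(s, y, t))),
                 bf_mcc(s, y, t))
  }
})

test_that("ROC/AUC: endpoints, ties, hand example, concordance oracle", {
  y <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), y)$auc, 0.75)
  expect_equal(roc_auc(c(0.9, 0.1, 0.8, 0.2), y)$auc, 1.0)
  expect_equal(roc_auc(rep(0.4, 4), y)$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "both classes")
  curve <- roc_auc(runif(50), rnd_labels(50))$curve
  expect_equal(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
  expect_equal(c(curve$fpr[nrow(curve)], curve$tpr[nrow(curve)]), c(1, 1))
  expect_false(is.unsorted(curve$fpr))
  expect_false(is.unsorted(curve$tpr))
  set.seed(23)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    y <- rnd_labels(n)
    s <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    expect_equal(roc_auc(s, y)$auc, bf_auc(s, y))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(29)
  for (i in 1:20) {
    y <- rnd_labels(100)
    s <- runif(100)
    a <- roc_auc(s, y)$auc
    expect_equal(roc_auc(exp(s) / exp(1), y)$auc, a)
    expect_equal(roc_auc(rank(s) / 101, y)$auc, a)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:10) {
    y <- rnd_labels(300)
    s <- round(runif(300), 2)
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
      y, s, quiet = TRUE, direction = "<", levels = c(FALSE, TRUE)))))
    expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("Sww equals the grid-mean oracle exactly", {
  set.seed(37)
  for (i in 1:30) {
    n <- sample(10:120, 1)
    y <- rnd_labels(n)
    s <- runif(n)
    w <- class_weights(y)
    expect_equal(sww(s, y, w), bf_sww(s, y))
  }
  # constant mid-range score: every threshold gives a one-class call, Sw = 0
  y <- rnd_labels(30)
  expect_equal(sww(rep(0.5, 30), y, class_weights(y)), 0)
  # perfectly separating 0/1 scores: perfect split at thresholds in (0, 1]
  y2 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(sww(c(1, 1, 0, 0), y2, class_weights(y2)), 100 / 101)
  expect_lte(abs(sww(runif(40), y <- rnd_labels(40), class_weights(y))), 1)
})

test_that("a label-independent random predictor has Sw near zero", {
  set.seed(41)
  y <- rnd_labels(100000, 0.2)
  w <- class_weights(y)
  for (p in c(0.1, 0.5, 0.9)) {
    calls <- as.numeric(runif(100000) < p)
    expect_lt(abs(sw(confusion_at(calls, y, 0.5), w)), 0.02)
  }
})

test_that("unknown-label residues never influence the metrics", {
  set.seed(43)
  y <- rnd_labels(200)
  s <- runif(200)
  w <- class_weights(y)
  y_u <- c(y, rep(NA, 50)); s_u <- c(s, runif(50))
  expect_equal(sw(confusion_at(s_u, y_u, 0.4), class_weights(y_u)),
               sw(confusion_at(s, y, 0.4), w))
  expect_equal(roc_auc(s_u, y_u)$auc, roc_auc(s, y)$auc)
  expect_equal(sww(s_u, y_u, w), sww(s, y, w))
})

test_that("bootstrap MAE: identical targets give zero, seeds reproduce", {
  targets <- rep(list(list(scores = c(0.9, 0.1), labels = c(TRUE, FALSE))), 6)
  met <- function(tt) {
    s <- unlist(lapply(tt, `[[`, "scores"))
    l <- unlist(lapply(tt, `[[`, "labels"))
    roc_auc(s, l)$auc
  }
  b <- bootstrap_mae(targets, met, reps = 50, seed = 5)
  expect_equal(b$mae, 0)
  b1 <- bootstrap_mae(targets, met, reps = 50, seed = 9)
  b2 <- bootstrap_mae(targets, met, reps = 50, seed = 9)
  expect_identical(b1$values, b2$values)
})

test_that("bootstrap subsample values come from the exhaustive subset set", {
  set.seed(47)
  targets <- lapply(1:5, function(i)
    list(scores = runif(30), labels = rnd_labels(30)))
  met <- function(tt) {
    s <- unlist(lapply(tt, `[[`, "scores"))
    l <- unlist(lapply(tt, `[[`, "labels"))
    roc_auc(s, l)$auc
  }
  # fraction 0.8 of 5 targets = subsets of size 4: enumerate all 5 of them
  subsets <- utils::combn(5, 4)
  enum <- apply(subsets, 2, function(idx) met(targets[idx]))
  full <- met(targets)
  b <- bootstrap_mae(targets, met, fraction = 0.8, reps = 400, seed = 13)
  expect_true(all(vapply(b$values, function(v)
    any(abs(v - enum) < 1e-12), logical(1))))
  expect_equal(b$mae, mean(abs(enum - full)), tolerance = 0.05)
})

test_that("Wilcoxon comparison: exact small-sample p-values and symmetry", {
  a <- c(2, 3, 4, 5, 6, 7); b <- c(1, 2, 3, 4, 5, 6)
  expect_equal(wilcoxon_paired(a, b), 2 / 64)
  expect_equal(wilcoxon_paired(a, a), 1.0)
  set.seed(53)
  x <- runif(12); y <- runif(12)
  expect_equal(wilcoxon_paired(x, y), wilcoxon_paired(y, x))
  # large-sample path with ties runs and gives a valid p
  x2 <- round(runif(40), 1); y2 <- round(runif(40), 1)
  p <- wilcoxon_paired(x2, y2)
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("exact signed-rank enumeration matches the reference implementation", {
  set.seed(59)
  for (i in 1:40) {
    n <- sample(5:25, 1)
    x <- runif(n); y <- runif(n)       # continuous draws: tie-free
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = TRUE))$p.value
    expect_equal(wilcoxon_paired(x, y), unname(ref))
  }
})

test_that("cross-validation bins are balanced and reproducible", {
  b <- kfold_residue_bins(100, k = 10, seed = 2)
  expect_equal(as.vector(table(b)), rep(10L, 10))
  b2 <- kfold_residue_bins(101, k = 10, seed = 2)
  expect_equal(sort(as.vector(table(b2))), c(rep(10L, 9), 11L))
  expect_identical(kfold_residue_bins(57, seed = 4),
                   kfold_residue_bins(57, seed = 4))
  expect_error(kfold_residue_bins(100, k = 1), "at least 2")
  expect_error(kfold_residue_bins(5, k = 10), "fewer residues")
})

test_that("the evaluation table has the standard benchmark layout", {
  fx <- tiny_fixture(n_targets = 6, seed = 19)
  sets <- list(
    m_strong = lapply(fx$profiles, function(p) p$scores[, 13]),
    m_weak   = lapply(fx$profiles, function(p) p$scores[, 4]))
  tab <- evaluate_predictors(sets, fx$labels, reps = 30, seed = 3)
  expect_named(tab, c("method", "Sw", "Sw_mae", "MCC", "AUC", "AUC_mae",
                      "sensitivity", "specificity"))
  expect_gt(tab$AUC[tab$method == "m_strong"],
            tab$AUC[tab$method == "m_weak"])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation_tsv(tab, path)
  back <- read.delim(path)
  expect_equal(back$AUC, tab$AUC)
})
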