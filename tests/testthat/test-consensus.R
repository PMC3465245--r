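test_that("binary encoding maps calls to 1 / 0.01 and guards bad symbols", {
  m <- cbind(bin = c(1, 0, NA), cont = c(0.73, 0.2, 0.9))
  p <- make_profile("t1", m, is_binary = c(bin = TRUE, cont = FALSE))
  enc <- encode_binary(p, consensus_config(mode = "continuous"))
  expect_equal(enc$scores[, "bin"], c(1, 0.01, NA))
  expect_equal(enc$scores[, "cont"], c(0.73, 0.2, 0.9))
  # binary mode discards continuous magnitude: 0.73 >= 0.5 is a disorder call
  enc2 <- encode_binary(p, consensus_config(mode = "binary"))
  expect_equal(enc2$scores[, "cont"], c(1, 0.01, 1))
  bad <- make_profile("t1", cbind(bin = c(0.5, 1, 0)),
                      is_binary = c(bin = TRUE))
  expect_error(encode_binary(bad), "non 0/1")
  expect_error(consensus_config(binary_negative = 0), "division-by-zero")
  expect_error(consensus_config(repair_max_run = 5, repair_window = 5),
               "smaller than")
})

test_that("weighted consensus is the weight-normalised score sum", {
  m <- cbind(a = c(1.0), b = c(0.5))
  p <- make_profile("t", m, is_binary = c(a = FALSE, b = FALSE))
  expect_equal(weighted_consensus(p, c(a = 0.6, b = 0.4)), 0.8)
  # single method: identity
  p1 <- make_profile("t", cbind(a = runif(10)), is_binary = c(a = FALSE))
  expect_equal(weighted_consensus(p1, c(a = 0.7)), p1$scores[, "a"])
  # all zeros stay zero
  p0 <- make_profile("t", cbind(a = rep(0, 4), b = rep(0, 4)))
  expect_equal(weighted_consensus(p0, c(a = 1, b = 2)), rep(0, 4))
  expect_error(weighted_consensus(p0, c(a = 0, b = 0)), "positive")
})

test_that("missing methods renormalise; all-missing residues stay missing", {
  m <- cbind(a = c(0.8, NA, NA), b = c(0.2, 0.6, NA))
  p <- make_profile("t", m, is_binary = c(a = FALSE, b = FALSE))
  out <- weighted_consensus(p, c(a = 1, b = 1))
  expect_equal(out, c(0.5, 0.6, NA))
})

test_that("consensus output stays in [0,1] and is invariant to method duplication", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    m <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    w <- runif(3, 0.1, 1); names(w) <- c("a", "b", "c")
    p <- make_profile("t", m, is_binary = rep(FALSE, 3))
    out <- weighted_consensus(p, w)
    expect_true(all(out >= 0 & out <= 1))
    # duplicate column a at half weight twice: consensus unchanged
    m2 <- cbind(m, a2 = m[, "a"])
    w2 <- c(w, a2 = unname(w["a"]) / 2); w2["a"] <- w["a"] / 2
    p2 <- make_profile("t", m2, is_binary = rep(FALSE, 4))
    expect_equal(weighted_consensus(p2, w2), out)
  }
})

test_that("terminal correction factors are disorder-frequency ratios", {
  # uniform positional disorder: all factors 1
  set.seed(67)
  labs <- lapply(1:400, function(i)
    disorder_labels(paste0("t", i), runif(80) < 0.4))
  corr <- estimate_terminal_correction(labs)
  expect_true(all(abs(corr$factors_nterm - 1) < 0.25))
  expect_true(all(abs(corr$factors_cterm - 1) < 0.25))
  # first residue always disordered, interior 50%: N factor at offset 1 is 2
  labs2 <- lapply(1:200, function(i) {
    y <- runif(61) < 0.5
    y[1] <- TRUE
    disorder_labels(paste0("u", i), y)
  })
  corr2 <- estimate_terminal_correction(labs2)
  p_int <- mean(unlist(lapply(labs2, function(l) l$states[16:46])))
  expect_equal(corr2$factors_nterm[1],
               1 / p_int, tolerance = 1e-12)
  expect_equal(corr2$factors_nterm[1], 2, tolerance = 0.1)
  # short chains are skipped with a warning
  expect_warning(
    estimate_terminal_correction(c(labs, list(disorder_labels("s", rep(c(TRUE, FALSE), 10))))),
    "skipped")
  expect_error(
    estimate_terminal_correction(lapply(1:5, function(i)
      disorder_labels(paste0("o", i), rep(c(TRUE, FALSE), c(15, 25))))),
    "interior disorder frequency is zero|uninformative")
})

test_that("terminal correction multiplies, clips and leaves the interior alone", {
  corr <- terminal_correction(c(2, rep(1, 14)), rep(1, 15))
  s <- c(0.3, rep(0.5, 40))
  out <- apply_terminal_correction(s, corr)
  expect_equal(out[1], 0.6)
  expect_equal(out[-1], s[-1])
  expect_equal(apply_terminal_correction(c(0.7, rep(0.5, 40)), corr)[1], 1.0)
  ident <- terminal_correction()
  x <- runif(50)
  expect_equal(apply_terminal_correction(x, ident), x)
})

test_that("on short chains the nearer terminus wins, ties to N", {
  corr <- terminal_correction(rep(2, 15), rep(0.5, 15))
  s <- rep(0.4, 21)   # offsets: N 1..11, C 11..1; position 11 ties
  out <- apply_terminal_correction(s, corr)
  expect_equal(out[1:11], rep(0.8, 11))    # N side including the tie
  expect_equal(out[12:21], rep(0.2, 10))   # C side
})

test_that("threshold selection maximises Sw on the grid, ties to the lowest", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  w <- class_weights(y)
  expect_equal(select_threshold(c(0.7, 0.7, 0.3, 0.3), y, w), 0.31)
  expect_equal(select_threshold(rep(0.4, 4), y, w), 0.0)
  s <- runif(100); y2 <- rnd_labels(100); w2 <- class_weights(y2)
  expect_identical(select_threshold(s, y2, w2), select_threshold(s, y2, w2))
})

test_that("repair removes short interior disorder runs only", {
  expect_equal(repair("DDD---D--"), "DDD------")
  expect_equal(repair("----DDDD----"), "----DDDD----")
  expect_equal(repair("-D-DD-DDD-"), "----------")
  # terminal runs survive on both ends
  expect_equal(repair("D---DD"), "D---DD")
  # order symbols are preserved as given; interior singleton removed
  expect_equal(repair(c("D", "O", "D", "O", "O")), c("D", "O", "O", "O", "O"))
  expect_equal(repair(c(TRUE, FALSE, TRUE, FALSE, FALSE)),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("repair is idempotent and one-sided on random strings", {
  set.seed(71)
  for (i in 1:10000) {
    x <- paste(sample(c("D", "-"), sample(5:30, 1), replace = TRUE,
                      prob = c(0.4, 0.6)), collapse = "")
    r1 <- repair(x)
    expect_identical(repair(r1), r1)
    # one-sided: no position gains disorder
    gained <- strsplit(r1, "")[[1]] == "D" & strsplit(x, "")[[1]] != "D"
    if (any(gained)) fail(paste("repair created disorder in", x))
  }
})

test_that("the full prediction chain reduces to its parts in edge cases", {
  y <- rep(c(TRUE, FALSE), c(10, 30))
  p <- make_profile("t", cbind(only = as.numeric(y)),
                    is_binary = c(only = TRUE))
  cfg <- consensus_config(mode = "binary", threshold = 0.5)
  out <- predict_consensus(p, c(only = 0.8), corr = NULL, cfg = cfg)
  expect_equal(out$calls, repair(y))
  # equal weights give the plain normalised mean
  m <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  p2 <- make_profile("t", m, is_binary = rep(FALSE, 3))
  out2 <- predict_consensus(p2, c(a = 1, b = 1, c = 1), corr = NULL,
                            cfg = consensus_config(threshold = 0.5))
  expect_equal(out2$scores, rowMeans(m))
  expect_error(predict_consensus(p2, c(a = 1, b = 1, c = 1),
                                 cfg = consensus_config()),
               "threshold")
})

test_that("fitted consensus improves on every constituent on synthetic data", {
  fx <- tiny_fixture(n_targets = 15, L = c(80, 200), seed = 73)
  fit <- fit_consensus(fx$profiles, fx$labels, mode = "continuous", seed = 73)
  y <- unlist(lapply(fx$labels, `[[`, "states"))
  cons <- unlist(lapply(predict(fit, fx$profiles), `[[`, "scores"))
  auc_cons <- roc_auc(cons, y)$auc
  big <- do.call(rbind, lapply(fx$profiles, `[[`, "scores"))
  for (j in seq_len(ncol(big)))
    expect_gte(auc_cons, roc_auc(big[, j], y)$auc - 0.01)
})

test_that("consensus model prints, summarises and round-trips its artifact", {
  fx <- tiny_fixture(n_targets = 6, seed = 79)
  fit <- fit_consensus(fx$profiles, fx$labels, seed = 79)
  expect_output(print(fit), "Consensus disorder predictor")
  expect_output(summary(fit), "calibration")
  expect_length(coef(fit), 13)
  path <- withr::local_tempfile(fileext = ".model")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$config$threshold, fit$config$threshold)
  expect_equal(back$correction$factors_nterm, fit$correction$factors_nterm)
  # restored model predicts identically
  p <- fx$profiles[[1]]
  expect_equal(predict(back, p)$scores, predict(fit, p)$scores)
})
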