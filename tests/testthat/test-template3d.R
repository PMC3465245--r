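test_that("tier classification follows the method-specific cutoff directions", {
  expect_equal(classify_tier("psiblast_default", 1e-8), "good")
  expect_equal(classify_tier("psiblast_nofilter", 1e-8), "good")
  expect_equal(classify_tier("psiblast_default", 0.01), "medium")
  expect_equal(classify_tier("ffas", -10.0), "medium")
  expect_equal(classify_tier("ffas", -40), "good")
  expect_equal(classify_tier("hhsearch_pdb70", 50), "poor")
  expect_equal(classify_tier("hhsearch_cdd", 96), "good")
  expect_equal(classify_tier("mgenthreader", 0.6), "medium")
  expect_equal(classify_tier("pcons", 2.5), "good")
  expect_equal(classify_tier("phyre", 0.5), "poor")
  # boundary values fall to the worse tier (strict comparisons)
  expect_equal(classify_tier("psiblast_default", 2e-06), "medium")
  expect_equal(classify_tier("psiblast_default", 0.023), "poor")
  expect_equal(classify_tier("hhsearch_pdb70", 95), "medium")
  expect_equal(classify_tier("hhsearch_pdb70", 80), "poor")
  expect_error(classify_tier("nosuch", 1), "unknown method")
})

test_that("coverage evidence accumulates hit weights over intervals", {
  w <- rep(0, 24); names(w) <- tier24_names <- weight_vector(rep(1, 24), "tier24")$names
  tw <- weight_vector(rep(1, 24), "tier24")
  ev0 <- coverage_evidence(list(), 10, tw)
  expect_equal(ev0$evidence, rep(0, 10))
  expect_equal(ev0$total_possible, 0)
  # one good psiblast hit with weight 0.9 on residues 1-10 of 20
  w9 <- rep(0, 24); w9[1] <- 0.9
  h <- alignment_hit("psiblast_default", 1e-9, rbind(c(1, 10)))
  ev <- coverage_evidence(list(h), 20, w9)
  expect_equal(ev$evidence, c(rep(0.9, 10), rep(0, 10)))
  expect_equal(ev$total_possible, 0.9)
  # duplicating the hit doubles evidence and normaliser alike
  ev2 <- coverage_evidence(list(h, h), 20, w9)
  expect_equal(ev2$evidence, 2 * ev$evidence)
  expect_equal(ev2$total_possible, 2 * ev$total_possible)
  expect_equal(predict_gs3d(list(h, h), 20, w9), predict_gs3d(list(h), 20, w9))
  expect_error(coverage_evidence(list(alignment_hit("ffas", -40, rbind(c(5, 30)))),
                                 20, tw), "beyond")
})

test_that("gs3d scores are one minus normalised coverage", {
  tw <- weight_vector(rep(0.5, 24), "tier24")
  expect_equal(predict_gs3d(list(), 7, tw), rep(1, 7))
  h_all <- alignment_hit("ffas", -40, rbind(c(1, 20)))
  expect_equal(predict_gs3d(list(h_all), 20, tw), rep(0, 20))
  # good-weight 0.9 on 1-10 plus poor-weight 0.1 on 5-20
  w <- rep(0, 24)
  w[tier_idx <- which(weight_vector(rep(1, 24), "tier24")$names ==
                        "psiblast_default.good")] <- 0.9
  w[which(weight_vector(rep(1, 24), "tier24")$names == "ffas.poor")] <- 0.1
  hits <- list(alignment_hit("psiblast_default", 1e-9, rbind(c(1, 10))),
               alignment_hit("ffas", -2, rbind(c(5, 20))))
  s <- predict_gs3d(hits, 20, w)
  expect_equal(s, c(rep(0.1, 4), rep(0, 6), rep(0.9, 10)))
  # configurable no-hit floor
  expect_equal(predict_gs3d(list(), 5, tw, no_hit_score = 0.8), rep(0.8, 5))
})

test_that("adding a covering hit never raises a residue's disorder score", {
  set.seed(83)
  tw <- runif(24)
  for (i in 1:20) {
    L <- 50
    hits <- replicate(sample(1:6, 1), {
      a <- sort(sample(1:L, 2))
      alignment_hit(sample(fold_method_modes(), 1), 1.5,
                    rbind(a), rank = sample(1:10, 1))
    }, simplify = FALSE)
    s0 <- predict_gs3d(hits, L, tw)
    a <- sort(sample(1:L, 2))
    extra <- alignment_hit("pcons", 3.0, rbind(a), rank = 9)
    s1 <- predict_gs3d(c(hits, list(extra)), L, tw)
    expect_true(all(s1[a[1]:a[2]] <= s0[a[1]:a[2]] + 1e-12))
  }
})

test_that("gs3d scores are invariant to rescaling all 24 weights", {
  set.seed(89)
  tw <- runif(24, 0.1, 1)
  hits <- list(alignment_hit("ffas", -40, rbind(c(1, 15))),
               alignment_hit("pcons", 2.5, rbind(c(10, 30))),
               alignment_hit("phyre", 4, rbind(c(20, 40))))
  expect_equal(predict_gs3d(hits, 40, 3.7 * tw), predict_gs3d(hits, 40, tw))
})

test_that("only the ten top-ranked hits per method mode are retained", {
  tw <- rep(1, 24)
  mk <- function(rank) alignment_hit("ffas", -40, rbind(c(rank, rank)),
                                     rank = rank)
  hits <- lapply(1:12, mk)   # ranks 1..12 each covering their own residue
  s <- predict_gs3d(hits, 12, tw)
  expect_true(all(s[1:10] < 1))
  expect_equal(s[11:12], c(1, 1))   # ranks 11, 12 dropped
})

test_that("GA training recovers informative tiers and is deterministic", {
  # generative truth: only good-tier psiblast_default hits track structure
  w_true <- rep(0, 24)
  w_true[1] <- 0.9
  cfg <- sim_config(n_targets = 25, length_range = c(60L, 150L),
                    hits_per_mode = 3L, seed = 97)
  ch <- gen_labels(cfg, seed = 97)
  training <- lapply(ch, function(x)
    list(hits = sim_hits(x$labels, w_true, cfg), labels = x$labels))
  ctrl <- ga_control(pop_size = 30L, generations = 30L)
  tr <- train_tier_weights(training, fitness = "sw", ga_cfg = ctrl, seed = 7)
  w <- tr$weights$values
  expect_length(w, 24L)
  expect_gt(w["psiblast_default.good"], w["psiblast_default.medium"])
  expect_gt(w["psiblast_default.good"], w["psiblast_default.poor"])
  expect_false(is.unsorted(tr$trace))   # elitism: non-decreasing fitness
  tr2 <- train_tier_weights(training, fitness = "sw", ga_cfg = ctrl, seed = 7)
  expect_identical(tr$weights$values, tr2$weights$values)
})

test_that("fitted template model predicts, prints and round-trips", {
  cfg <- sim_config(n_targets = 12, length_range = c(60L, 120L), seed = 101)
  ch <- gen_labels(cfg, seed = 101)
  training <- lapply(ch, function(x)
    list(hits = sim_hits(x$labels, default_true_tier_weights(), cfg),
         labels = x$labels))
  fit <- fit_template3d(training, ga_cfg = ga_control(pop_size = 20L,
                                                      generations = 15L),
                        seed = 11)
  expect_s3_class(fit, "template3d_model")
  expect_length(coef(fit), 24L)
  expect_output(print(fit), "Template-coverage")
  out <- predict(fit, training[[1]]$hits,
                 L = length(training[[1]]$labels$states))
  expect_true(all(out$scores >= 0 & out$scores <= 1))
  expect_type(out$calls, "logical")
  path <- withr::local_tempfile(fileext = ".model")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(coef(back), coef(fit))
  out2 <- predict(back, training[[1]]$hits,
                  L = length(training[[1]]$labels$states))
  expect_equal(out2$scores, out$scores)
})
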