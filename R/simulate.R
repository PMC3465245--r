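# Synthetic fixture generators: planted-segment disorder labels, primary
# predictor score profiles of controlled discriminative power (Beta score
# models), and fold-recognition hit lists whose coverage avoids disordered
# regions.  Every generator is a pure function of (cfg, seed).

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of the calibration data this
#' family of predictors is built on: ~23.45% disordered residues overall,
#' segmental (not i.i.d.) disorder with geometric run lengths, and a roughly
#' two-fold disorder enrichment in the 15 residues at either chain terminus.
#'
#' @param n_targets number of chains to simulate.
#' @param length_range integer range of chain lengths (uniform).
#' @param disorder_fraction target overall disordered fraction (0, 1).
#' @param mean_disorder_run mean disordered run length (geometric).
#' @param terminal_enrichment multiplier on the disorder probability within
#'   the 15 terminal residues at each end (1 = no positional signal).
#' @param score_models named list of per-method Beta score models, see
#'   [default_score_models()].
#' @param missing_rate per-cell probability that a method reports no score.
#' @param hits_per_mode fold-recognition hits simulated per method mode.
#' @param tier_probs probabilities that a simulated hit is a good / medium /
#'   poor alignment.
#' @param leak_rate probability that a hit also covers a disordered segment.
#' @param seed integer seed used by the generators.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_targets = 100L, length_range = c(60L, 300L),
                       disorder_fraction = 0.2345, mean_disorder_run = 12,
                       terminal_enrichment = 2.0,
                       score_models = default_score_models(),
                       missing_rate = 0, hits_per_mode = 3L,
                       tier_probs = c(good = 0.3, medium = 0.4, poor = 0.3),
                       leak_rate = 0.05, seed = 1L) {
  stopifnot(disorder_fraction > 0, disorder_fraction < 1,
            mean_disorder_run >= 1, terminal_enrichment > 0,
            length_range[1L] >= 2L, length_range[2L] >= length_range[1L],
            missing_rate >= 0, missing_rate < 1, leak_rate >= 0,
            leak_rate <= 1)
  structure(list(n_targets = as.integer(n_targets),
                 length_range = as.integer(length_range),
                 disorder_fraction = disorder_fraction,
                 mean_disorder_run = mean_disorder_run,
                 terminal_enrichment = terminal_enrichment,
                 score_models = score_models, missing_rate = missing_rate,
                 hits_per_mode = as.integer(hits_per_mode),
                 tier_probs = tier_probs / sum(tier_probs),
                 leak_rate = leak_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default Beta score models for 13 simulated primary predictors
#'
#' Disordered residues score `Beta(2 + d, 2)` and ordered residues the mirror
#' `Beta(2, 2 + d)`; the separation `d` varies across methods, giving a
#' heterogeneous panel with AUCs from roughly 0.63 to 0.83 — the accuracy
#' range primary disorder predictors realistically span.  Three methods
#' are binary (they emit 0/1 calls obtained by thresholding their latent
#' score at 0.5), mirroring the mix of binary and continuous primary
#' predictors the consensus is built over.
#'
#' @param n_methods number of methods (default 13).
#' @param separations optional numeric vector of Beta separations.
#' @param n_binary how many of the methods are binary (default 3).
#' @return named list of score models (fields `alpha_dis`, `beta_dis`,
#'   `alpha_ord`, `beta_ord`, `binary`).
#' @export
default_score_models <- function(n_methods = 13L, separations = NULL,
                                 n_binary = 3L) {
  if (is.null(separations))
    separations <- seq(0.45, 1.45, length.out = n_methods)
  stopifnot(length(separations) == n_methods, n_binary <= n_methods)
  binary <- rep(FALSE, n_methods)
  if (n_binary > 0L)
    binary[seq(1L, n_methods, length.out = n_binary)] <- TRUE
  models <- lapply(seq_len(n_methods), function(i) {
    d <- separations[i]
    list(alpha_dis = 2 + d, beta_dis = 2, alpha_ord = 2, beta_ord = 2 + d,
         binary = binary[i])
  })
  names(models) <- sprintf("method%02d", seq_len(n_methods))
  models
}

#' Closed-form AUC of a Beta score model
#'
#' The AUC a continuous method with disordered scores `Beta(a_d, b_d)` and
#' ordered scores `Beta(a_o, b_o)` attains in the infinite-sample limit:
#' `P(X_dis > X_ord)` by numerical integration (the score distributions are
#' continuous, so ties have probability zero).
#'
#' @param model one element of [default_score_models()].
#' @return theoretical AUC.
#' @export
score_model_auc <- function(model) {
  stats::integrate(function(x) {
    stats::dbeta(x, model$alpha_dis, model$beta_dis) *
      stats::pbeta(x, model$alpha_ord, model$beta_ord)
  }, 0, 1, rel.tol = 1e-10)$value
}

# expected fraction of residues inside the two 15-residue terminal windows
terminal_weight <- function(length_range, n_proximal = 15L) {
  ls <- seq(length_range[1L], length_range[2L])
  mean(pmin(2L * n_proximal, ls) / ls)
}

#' Generate labelled synthetic chains with planted disorder segments
#'
#' Chains alternate geometric ordered and disordered runs whose means are
#' calibrated so that, after terminal enrichment is applied, the realised
#' overall disordered fraction matches `cfg$disorder_fraction` in
#' expectation.  Terminal enrichment flips ordered residues within 15
#' residues of either end to disordered so that the terminal disorder
#' probability is `terminal_enrichment` times the baseline.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return list with one element per target: `sequence` (a
#'   [sequence_record()]) and `labels` (a [disorder_labels()]).
#' @export
gen_labels <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  w_t <- terminal_weight(cfg$length_range)
  f <- cfg$disorder_fraction / (1 + w_t * (cfg$terminal_enrichment - 1))
  if (f >= 1) stop("infeasible configuration: baseline fraction >= 1")
  m_d <- cfg$mean_disorder_run
  m_o <- m_d * (1 - f) / f
  if (m_o < 1)
    stop("infeasible configuration: disorder fraction ", cfg$disorder_fraction,
         " cannot be reached with mean run length ", m_d)
  q_flip <- f * (cfg$terminal_enrichment - 1) / (1 - f)
  if (q_flip > 1)
    stop("infeasible configuration: terminal enrichment too large")
  aa20 <- setdiff(AA_ALPHABET, "X")
  lapply(seq_len(cfg$n_targets), function(i) {
    L <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
    states <- logical(0)
    state <- stats::runif(1) < f
    while (length(states) < L) {
      m <- if (state) m_d else m_o
      run <- 1L + stats::rgeom(1L, 1 / m)
      states <- c(states, rep(state, run))
      state <- !state
    }
    states <- states[seq_len(L)]
    near <- pmin(seq_len(L), L + 1L - seq_len(L)) <= 15L
    flip <- near & !states & stats::runif(L) < q_flip
    states[flip] <- TRUE
    id <- sprintf("synth%04d", i)
    list(sequence = sequence_record(
           id, paste(sample(aa20, L, replace = TRUE), collapse = "")),
         labels = disorder_labels(id, states))
  })
}

#' Simulate a primary-predictor score profile for labelled chains
#'
#' Continuous methods draw disordered residues from
#' `Beta(alpha_dis, beta_dis)` and ordered residues from
#' `Beta(alpha_ord, beta_ord)`; binary methods threshold their latent score
#' at 0.5 and report the 0/1 call.  Unknown-label residues draw from the
#' ordered model.
#'
#' @param labels a [disorder_labels()] (or logical vector) for one chain.
#' @param cfg a [sim_config()]; `cfg$score_models` defines the methods.
#' @param seed optional integer seed (set it when simulating a single chain;
#'   leave `NULL` inside a larger seeded simulation).
#' @return a [prediction_profile()].
#' @export
sim_profile <- function(labels, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as_disorder_logical(labels)
  L <- length(y)
  dis <- !is.na(y) & y
  sc <- vapply(cfg$score_models, function(m) {
    s <- stats::rbeta(L, m$alpha_ord, m$beta_ord)
    s[dis] <- stats::rbeta(sum(dis), m$alpha_dis, m$beta_dis)
    if (m$binary) s <- as.numeric(s >= 0.5)
    s
  }, numeric(L))
  if (cfg$missing_rate > 0)
    sc[stats::runif(length(sc)) < cfg$missing_rate] <- NA_real_
  id <- if (inherits(labels, "disorder_labels")) labels$id else "sim"
  prediction_profile(id, sc,
                     is_binary = vapply(cfg$score_models, `[[`, TRUE, "binary"))
}

# raw-score bands per base method and tier; each band lies strictly inside
# its tier region of the default thresholds, so classify_tier recovers the
# generating tier exactly.
tier_score_bands <- function() {
  list(
    psiblast     = list(good = c(-12, -6.8), medium = c(-4, -1.7),
                        poor = c(-1.2, 0.7), log10 = TRUE),
    ffas         = list(good = c(-60, -35), medium = c(-30, -9),
                        poor = c(-8, 0), log10 = FALSE),
    mgenthreader = list(good = c(0.66, 0.95), medium = c(0.55, 0.64),
                        poor = c(0.1, 0.5), log10 = FALSE),
    hhsearch     = list(good = c(95.5, 100), medium = c(80.5, 94.5),
                        poor = c(5, 79.5), log10 = FALSE),
    pcons        = list(good = c(2.2, 4), medium = c(1.05, 2.15),
                        poor = c(0, 1.0), log10 = FALSE),
    phyre        = list(good = c(0.001, 0.08), medium = c(0.09, 0.26),
                        poor = c(0.3, 5), log10 = FALSE))
}

draw_tier_score <- function(method_mode, tier) {
  b <- tier_score_bands()[[mode_base_method(method_mode)]]
  r <- b[[tier]]
  x <- stats::runif(1L, r[1L], r[2L])
  if (b$log10) 10^x else x
}

#' Default generative tier weights for hit simulation
#'
#' Good alignments track structure strongly, medium ones moderately, poor
#' ones barely; two modes are configured as unreliable throughout, giving
#' the trainer something to down-weight.
#'
#' @return a [weight_vector()] of kind `tier24`.
#' @export
default_true_tier_weights <- function() {
  w <- rep(c(0.9, 0.45, 0.1), times = 8L)
  weak <- fold_method_modes() %in% c("psiblast_nofilter", "phyre")
  w[rep(weak, each = 3L)] <- w[rep(weak, each = 3L)] * 0.3
  weight_vector(w, kind = "tier24")
}

#' Simulate fold-recognition hits for one labelled chain
#'
#' For every method mode, `cfg$hits_per_mode` hits are drawn.  Each hit gets
#' a tier from `cfg$tier_probs` and a raw score inside that tier's band of
#' the default thresholds.  The hit covers each maximal ordered segment with
#' probability equal to its (mode, tier) generative weight — so strongly
#' weighted classes align well with structure — and each disordered segment
#' with probability `cfg$leak_rate`.  Hits that end up covering nothing are
#' dropped.
#'
#' @param labels a [disorder_labels()] (or logical vector) for one chain.
#' @param tier_weights_true generative weights (a [weight_vector()] of kind
#'   `tier24` or a 24-vector); entries must lie in [0, 1] as they are used
#'   as coverage probabilities.
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return list of [alignment_hit()].
#' @export
sim_hits <- function(labels, tier_weights_true = default_true_tier_weights(),
                     cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- tier24_values(tier_weights_true)
  if (any(w > 1)) stop("generative tier weights must lie in [0, 1]")
  y <- as_disorder_logical(labels)
  y[is.na(y)] <- FALSE
  L <- length(y)
  r <- rle(y)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  seg_dis <- r$values
  tiers <- c("good", "medium", "poor")
  hits <- list()
  for (mode in fold_method_modes()) {
    for (rank in seq_len(cfg$hits_per_mode)) {
      tier <- sample(tiers, 1L, prob = cfg$tier_probs)
      p_cov <- w[tier_class_index(mode, tier)]
      covered <- ifelse(seg_dis, stats::runif(length(seg_dis)) < cfg$leak_rate,
                        stats::runif(length(seg_dis)) < p_cov)
      if (!any(covered)) next
      iv <- cbind(seg_start[covered], seg_end[covered])
      # merge segments that touch (an excluded run between two included ones)
      keep <- c(TRUE, iv[-1L, 1L] > iv[-nrow(iv), 2L] + 1L)
      grp <- cumsum(keep)
      iv <- cbind(tapply(iv[, 1L], grp, min), tapply(iv[, 2L], grp, max))
      hits[[length(hits) + 1L]] <-
        alignment_hit(mode, draw_tier_score(mode, tier), iv, rank = rank,
                      L = L)
    }
  }
  hits
}

#' Simulate a complete fixture bundle
#'
#' Generates labelled chains, a score profile and a hit list per chain, and
#' optionally writes the bundle (FASTA, labels, profile TSV, hit TSV and a
#' YAML manifest recording the generative truth) into a directory.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; created if missing.
#' @param tier_weights_true generative tier weights for the hit channel.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return invisibly, a list with `targets` (per-chain `sequence`, `labels`,
#'   `profile`, `hits`) and `truth` (the generative parameters).
#' @export
sim_dataset <- function(cfg = sim_config(), dir = NULL,
                        tier_weights_true = default_true_tier_weights(),
                        seed = cfg$seed) {
  set.seed(seed)
  chains <- gen_labels(cfg, seed = seed)
  targets <- lapply(chains, function(ch) {
    list(sequence = ch$sequence, labels = ch$labels,
         profile = sim_profile(ch$labels, cfg),
         hits = sim_hits(ch$labels, tier_weights_true, cfg))
  })
  truth <- list(seed = seed, n_targets = cfg$n_targets,
                disorder_fraction = cfg$disorder_fraction,
                terminal_enrichment = cfg$terminal_enrichment,
                leak_rate = cfg$leak_rate,
                true_tier_weights = as.list(
                  stats::setNames(tier_weights_true$values,
                                  tier_weights_true$names)),
                method_auc = lapply(cfg$score_models, score_model_auc))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(lapply(targets, `[[`, "sequence"),
                file.path(dir, "sequences.fasta"))
    write_labels(lapply(targets, `[[`, "labels"),
                 file.path(dir, "labels.txt"))
    profs <- lapply(targets, `[[`, "profile")
    for (i in seq_along(profs))
      attr(profs[[i]], "residues") <- targets[[i]]$sequence$residues
    write_profile_tsv(profs, file.path(dir, "profiles.tsv"))
    hits <- lapply(targets, `[[`, "hits")
    names(hits) <- vapply(targets, function(t) t$sequence$id, "")
    write_hits_tsv(hits, file.path(dir, "hits.tsv"))
    yaml::write_yaml(truth, file.path(dir, "manifest.yaml"))
  }
  invisible(list(targets = targets, truth = truth))
}
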