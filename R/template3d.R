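# Template-coverage disorder prediction: residues never covered by
# fold-recognition alignments to known structures are candidate disordered
# residues.  Hits are classified into good/medium/poor alignment-quality
# tiers from their raw scores, each (method mode, tier) class carries a
# trainable weight, and the per-residue disorder score is one minus the
# normalised accumulated coverage evidence.

#' Default alignment-quality tier thresholds
#'
#' Score cutoffs classifying each fold-recognition hit as a potentially good,
#' medium or poor alignment.  E-value-like methods (PSI-BLAST, FFAS, PHYRE)
#' improve downwards, score-like methods (mGenThreader, HHsearch, PCONS)
#' upwards; boundary values classify to the worse tier (strict comparisons).
#' PSI-BLAST and HHsearch run in two modes each; both modes of a method share
#' its thresholds, giving the 8 method modes of [fold_method_modes()].
#'
#' @return data frame of class `tier_thresholds` with one row per base
#'   method: `method`, `good_cutoff`, `medium_cutoff`, `direction`.
#' @export
default_tier_thresholds <- function() {
  structure(data.frame(
    method        = c("psiblast", "ffas", "mgenthreader", "hhsearch",
                      "pcons", "phyre"),
    good_cutoff   = c(2e-06, -34.5, 0.65, 95, 2.17, 0.085),
    medium_cutoff = c(0.023, -8.5, 0.546, 80, 1.03, 0.27),
    direction     = c("lower_is_better", "lower_is_better",
                      "higher_is_better", "higher_is_better",
                      "higher_is_better", "lower_is_better"),
    stringsAsFactors = FALSE),
    class = c("tier_thresholds", "data.frame"))
}

# method mode -> base method of the threshold table
mode_base_method <- function(mode) {
  sub("_(default|nofilter|pdb70|cdd)$", "", mode)
}

#' Classify a fold-recognition hit into an alignment-quality tier
#'
#' @param method_mode one of [fold_method_modes()].
#' @param raw_score the hit's score in the method's native scale.
#' @param thresholds a [default_tier_thresholds()]-style table.
#' @return `"good"`, `"medium"` or `"poor"`.
#' @examples
#' classify_tier("psiblast_default", 1e-8)    # good
#' classify_tier("ffas", -10)                 # medium
#' classify_tier("hhsearch_pdb70", 50)        # poor
#' @export
classify_tier <- function(method_mode, raw_score,
                          thresholds = default_tier_thresholds()) {
  if (!method_mode %in% fold_method_modes())
    stop("unknown method mode '", method_mode, "'")
  row <- thresholds[thresholds$method == mode_base_method(method_mode), ]
  if (nrow(row) != 1L)
    stop("no tier thresholds for method '", mode_base_method(method_mode), "'")
  better <- if (row$direction == "lower_is_better")
    function(x, cut) x < cut else function(x, cut) x > cut
  if (better(raw_score, row$good_cutoff)) "good"
  else if (better(raw_score, row$medium_cutoff)) "medium"
  else "poor"
}

# index of (mode, tier) in the 24-element weight vector (mode-major,
# tiers in order good, medium, poor)
tier_class_index <- function(method_mode, tier) {
  im <- match(method_mode, fold_method_modes())
  it <- match(tier, c("good", "medium", "poor"))
  (im - 1L) * 3L + it
}

# Reduce a target's hits to per-residue coverage counts per (mode, tier)
# class: an L x 24 count matrix plus the 24-vector of retained hit counts.
# At most max_hits hits per method mode are retained, by rank.
coverage_counts <- function(hits, L, thresholds = default_tier_thresholds(),
                            max_hits = 10L) {
  C <- matrix(0, nrow = L, ncol = 24L)
  n <- numeric(24L)
  if (length(hits) == 0L) return(list(C = C, n = n))
  modes <- vapply(hits, `[[`, "", "method_mode")
  ranks <- vapply(hits, function(h) h$rank, integer(1))
  keep <- unlist(lapply(split(seq_along(hits), modes), function(idx) {
    idx[order(ranks[idx])][seq_len(min(length(idx), max_hits))]
  }), use.names = FALSE)
  for (i in keep) {
    h <- hits[[i]]
    if (nrow(h$intervals) > 0L && max(h$intervals[, 2L]) > L)
      stop("hit interval beyond sequence end (L = ", L, ")")
    k <- tier_class_index(h$method_mode,
                          classify_tier(h$method_mode, h$raw_score, thresholds))
    n[k] <- n[k] + 1
    for (r in seq_len(nrow(h$intervals)))
      C[h$intervals[r, 1L]:h$intervals[r, 2L], k] <-
        C[h$intervals[r, 1L]:h$intervals[r, 2L], k] + 1
  }
  list(C = C, n = n)
}

#' Accumulated coverage evidence for one target
#'
#' Each retained hit contributes the weight of its (method mode, tier) class
#' to every residue its alignment covers.  `total_possible` is the evidence a
#' residue covered by every retained hit would accumulate.
#'
#' @param hits list of [alignment_hit()] for one target.
#' @param L target length.
#' @param tier_weights a [weight_vector()] of kind `tier24` (or a 24-vector).
#' @param thresholds tier threshold table.
#' @param max_hits hits retained per method mode, by rank (default 10).
#' @return list of class `coverage_evidence`: `evidence` (length-L vector)
#'   and `total_possible` (scalar).
#' @export
coverage_evidence <- function(hits, L, tier_weights,
                              thresholds = default_tier_thresholds(),
                              max_hits = 10L) {
  w <- tier24_values(tier_weights)
  cc <- coverage_counts(hits, L, thresholds, max_hits)
  structure(list(evidence = as.vector(cc$C %*% w),
                 total_possible = sum(cc$n * w)),
            class = "coverage_evidence")
}

tier24_values <- function(tier_weights) {
  w <- if (inherits(tier_weights, "weight_vector")) tier_weights$values
       else as.numeric(tier_weights)
  if (length(w) != 24L) stop("tier weights must have 24 entries (8 modes x 3 tiers)")
  if (any(w < 0)) stop("tier weights must be non-negative")
  w
}

#' Per-residue disorder scores from fold-recognition coverage
#'
#' `score(r) = 1 - evidence(r) / total_possible`: residues covered by every
#' retained (positively weighted) hit score 0, residues never covered score
#' 1.  A target with no retained hits at all (or all-zero class weights) has
#' no structural counterpart detected and scores `no_hit_score` everywhere
#' (default 1, fully disordered).
#'
#' @inheritParams coverage_evidence
#' @param no_hit_score score assigned when no evidence exists (default 1).
#' @return numeric vector of length L in [0, 1].
#' @export
predict_gs3d <- function(hits, L, tier_weights,
                         thresholds = default_tier_thresholds(),
                         max_hits = 10L, no_hit_score = 1.0) {
  ev <- coverage_evidence(hits, L, tier_weights, thresholds, max_hits)
  if (ev$total_possible <= 0) return(rep(no_hit_score, L))
  1 - ev$evidence / ev$total_possible
}

# Pooled fitness of a 24-gene tier-weight genome over precomputed coverage
# counts.  cc_list: per-target list(C, n); y: pooled labels; no_hit_score as
# in predict_gs3d.
tier_fitness_fun <- function(cc_list, labels_list, fitness = c("sw", "sww"),
                             no_hit_score = 1.0) {
  fitness <- match.arg(fitness)
  y <- pool_labels(labels_list)
  w_cls <- class_weights(y)
  lens <- vapply(cc_list, function(cc) nrow(cc$C), integer(1))
  function(w) {
    scores <- unlist(lapply(cc_list, function(cc) {
      tot <- sum(cc$n * w)
      if (tot <= 0) rep(no_hit_score, nrow(cc$C))
      else 1 - as.vector(cc$C %*% w) / tot
    }), use.names = FALSE)
    g <- sw_grid(scores, y, w_cls)
    if (fitness == "sw") max(g) else mean(g)
  }
}

#' Train the 24 tier weights with a genetic algorithm
#'
#' Optimises the 8 x 3 = 24 class weights (one per method mode and
#' alignment-quality tier, genome bounded to [0, 1]) so that the pooled
#' weighted score of the resulting coverage predictor is maximal over the
#' training targets.  With `fitness = "sw"` the criterion is Sw at the best
#' grid threshold; with `"sww"` it is the threshold-averaged Sww of the raw
#' scores.
#'
#' @param training list with one element per target, each a list with
#'   components `hits` (list of [alignment_hit()]) and `labels`.
#' @param fitness `"sw"` (default) or `"sww"`.
#' @param ga_cfg a [ga_control()].
#' @param seed optional integer seed (GA initialisation and operators).
#' @param thresholds tier threshold table.
#' @param max_hits hits retained per method mode.
#' @return list with `weights` (a [weight_vector()] of kind `tier24`),
#'   `fitness_value` and the GA `trace`.
#' @export
train_tier_weights <- function(training, fitness = c("sw", "sww"),
                               ga_cfg = ga_control(), seed = NULL,
                               thresholds = default_tier_thresholds(),
                               max_hits = 10L) {
  fitness <- match.arg(fitness)
  if (length(training) < 2L) stop("need at least two training targets")
  labels_list <- lapply(training, `[[`, "labels")
  cc_list <- lapply(training, function(t) {
    coverage_counts(t$hits, length(as_disorder_logical(t$labels)),
                    thresholds, max_hits)
  })
  f <- tier_fitness_fun(cc_list, labels_list, fitness)
  res <- ga_optimize(f, n_genes = 24L, lower = 0, upper = 1,
                     control = ga_cfg, seed = seed)
  list(weights = weight_vector(res$par, kind = "tier24"),
       fitness_value = res$value, trace = res$trace)
}

#' Fit the template-coverage disorder predictor
#'
#' Trains the 24 tier weights by genetic algorithm on reference-labelled
#' targets with fold-recognition hit lists, then selects the Sw-optimal
#' decision threshold on the pooled training scores.
#'
#' @inheritParams train_tier_weights
#' @return An object of class `template3d_model` with fields `weights`,
#'   `threshold`, `thresholds` (tier cutoffs), `fitness_kind`,
#'   `fitness_value`, `trace`.
#' @export
fit_template3d <- function(training, fitness = c("sw", "sww"),
                           ga_cfg = ga_control(), seed = NULL,
                           thresholds = default_tier_thresholds(),
                           max_hits = 10L) {
  fitness <- match.arg(fitness)
  tr <- train_tier_weights(training, fitness, ga_cfg, seed, thresholds,
                           max_hits)
  labels_list <- lapply(training, `[[`, "labels")
  y <- pool_labels(labels_list)
  scores <- unlist(lapply(training, function(t) {
    predict_gs3d(t$hits, length(as_disorder_logical(t$labels)),
                 tr$weights, thresholds, max_hits)
  }), use.names = FALSE)
  thr <- select_threshold(scores, y, class_weights(y))
  structure(list(weights = tr$weights, threshold = thr,
                 thresholds = thresholds, fitness_kind = fitness,
                 fitness_value = tr$fitness_value, trace = tr$trace,
                 max_hits = max_hits, n_targets = length(training)),
            class = "template3d_model")
}

#' @export
print.template3d_model <- function(x, ...) {
  cat("Template-coverage disorder predictor\n")
  cat("  tier weights: 24 (8 method modes x 3 tiers), GA-trained (",
      x$fitness_kind, ")\n", sep = "")
  cat("  threshold:   ", format(x$threshold), "\n")
  cat("  fitted on:   ", x$n_targets, " targets, final fitness ",
      format(round(x$fitness_value, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
coef.template3d_model <- function(object, ...) object$weights$values

#' @export
summary.template3d_model <- function(object, ...) {
  print(object)
  m <- matrix(object$weights$values, ncol = 3L, byrow = TRUE,
              dimnames = list(fold_method_modes(),
                              c("good", "medium", "poor")))
  cat("\nTier weights:\n")
  print(round(m, 3))
  invisible(object)
}

#' Predict disorder from hit lists with a fitted template model
#'
#' @param object a `template3d_model`.
#' @param newdata a list of [alignment_hit()] for one target, or a named list
#'   of such hit lists.
#' @param L target length (vector when `newdata` is a list of targets).
#' @param ... unused.
#' @return list with `scores` and thresholded, repaired `calls`; or a list of
#'   such results for multiple targets.
#' @export
predict.template3d_model <- function(object, newdata, L, ...) {
  one <- function(hits, len) {
    s <- predict_gs3d(hits, len, object$weights, object$thresholds,
                      object$max_hits)
    list(scores = s, calls = repair(s >= object$threshold))
  }
  single <- length(newdata) == 0L ||
    inherits(newdata[[1L]], "alignment_hit")
  if (single) return(one(newdata, L))
  stopifnot(length(L) == length(newdata))
  Map(one, newdata, L)
}
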