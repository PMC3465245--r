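# Two-channel combined predictor: convex combination of the consensus
# (FloatCons) channel and the template-coverage channel, with the 24 tier
# weights and the two channel weights trained jointly as one 26-gene genome.
# The "MD" variant optimises Sw, the "MD2" variant optimises Sww.

#' Combine consensus and template-coverage scores
#'
#' Convex combination `(a * consensus + b * template) / (a + b)`.
#'
#' @param consensus_scores,template_scores equal-length score vectors in
#'   [0, 1].
#' @param a,b non-negative channel weights; `a + b` must be positive.
#' @return combined score vector in [0, 1].
#' @export
combine_scores <- function(consensus_scores, template_scores, a, b) {
  stopifnot(length(consensus_scores) == length(template_scores))
  if (a < 0 || b < 0) stop("channel weights must be non-negative")
  if (a + b <= 0) stop("at least one channel weight must be positive")
  (a * consensus_scores + b * template_scores) / (a + b)
}

#' Train the combined two-channel model
#'
#' The genome holds the 24 tier weights of the template channel plus the two
#' channel weights (26 genes, each in [0, 1]).  Fitness is the pooled Sw at
#' the best grid threshold (`fitness = "sw"`, the MD criterion) or the pooled
#' threshold-averaged Sww (`"sww"`, the MD2 criterion).  Genomes whose two
#' channel weights are both (numerically) zero are assigned the worst
#' fitness.
#'
#' @param training list with one element per target, each a list with
#'   components `consensus` (consensus score vector), `hits` (list of
#'   [alignment_hit()]) and `labels`.
#' @param fitness `"sw"` (MD, default) or `"sww"` (MD2).
#' @param ga_cfg a [ga_control()].
#' @param seed optional integer seed.
#' @param thresholds tier threshold table.
#' @param max_hits hits retained per method mode.
#' @return list with `weights` (a [weight_vector()] of kind
#'   `tier24_plus_components`), `fitness_value`, `trace`.
#' @export
train_combined <- function(training, fitness = c("sw", "sww"),
                           ga_cfg = ga_control(), seed = NULL,
                           thresholds = default_tier_thresholds(),
                           max_hits = 10L) {
  fitness <- match.arg(fitness)
  if (length(training) < 2L) stop("need at least two training targets")
  labels_list <- lapply(training, `[[`, "labels")
  y <- pool_labels(labels_list)
  w_cls <- class_weights(y)
  cons <- lapply(training, `[[`, "consensus")
  cc_list <- lapply(training, function(t) {
    coverage_counts(t$hits, length(as_disorder_logical(t$labels)),
                    thresholds, max_hits)
  })
  f <- function(genome) {
    w24 <- genome[1:24]; a <- genome[25L]; b <- genome[26L]
    if (a + b <= .Machine$double.eps) return(-Inf)
    scores <- unlist(Map(function(cc, cs) {
      tot <- sum(cc$n * w24)
      tmpl <- if (tot <= 0) rep(1, nrow(cc$C))
              else 1 - as.vector(cc$C %*% w24) / tot
      (a * cs + b * tmpl) / (a + b)
    }, cc_list, cons), use.names = FALSE)
    g <- sw_grid(scores, y, w_cls)
    if (fitness == "sw") max(g) else mean(g)
  }
  res <- ga_optimize(f, n_genes = 26L, lower = 0, upper = 1,
                     control = ga_cfg, seed = seed)
  list(weights = weight_vector(res$par, kind = "tier24_plus_components"),
       fitness_value = res$value, trace = res$trace)
}

#' Fit the combined consensus + template disorder predictor
#'
#' Trains the 26-gene genome by genetic algorithm and selects the Sw-optimal
#' decision threshold on the pooled combined training scores.  Thresholding
#' and the repair filter are applied after combination, reusing the consensus
#' machinery.
#'
#' @inheritParams train_combined
#' @return An object of class `combined_model` with fields `weights`,
#'   `component_weights`, `threshold`, `fitness_kind`, `fitness_value`,
#'   `trace`.
#' @export
fit_combined <- function(training, fitness = c("sw", "sww"),
                         ga_cfg = ga_control(), seed = NULL,
                         thresholds = default_tier_thresholds(),
                         max_hits = 10L) {
  fitness <- match.arg(fitness)
  tr <- train_combined(training, fitness, ga_cfg, seed, thresholds, max_hits)
  g <- tr$weights$values
  w24 <- weight_vector(g[1:24], kind = "tier24")
  a <- unname(g[25L]); b <- unname(g[26L])
  labels_list <- lapply(training, `[[`, "labels")
  y <- pool_labels(labels_list)
  scores <- unlist(lapply(training, function(t) {
    tmpl <- predict_gs3d(t$hits, length(as_disorder_logical(t$labels)),
                         w24, thresholds, max_hits)
    combine_scores(t$consensus, tmpl, a, b)
  }), use.names = FALSE)
  thr <- select_threshold(scores, y, class_weights(y))
  structure(list(weights = tr$weights, tier_weights = w24,
                 component_weights = c(a_consensus = a, b_template = b),
                 threshold = thr, thresholds = thresholds,
                 fitness_kind = fitness, fitness_value = tr$fitness_value,
                 trace = tr$trace, max_hits = max_hits,
                 n_targets = length(training)),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat("Combined consensus + template disorder predictor (fitness: ",
      x$fitness_kind, ")\n", sep = "")
  ab <- x$component_weights
  cat(sprintf("  channel weights: consensus %.3f, template %.3f (template share %.2f)\n",
              ab[1L], ab[2L], ab[2L] / sum(ab)))
  cat("  threshold:      ", format(x$threshold), "\n")
  cat("  fitted on:      ", x$n_targets, " targets, final fitness ",
      format(round(x$fitness_value, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
coef.combined_model <- function(object, ...) object$weights$values

#' Predict disorder with a fitted combined model
#'
#' @param object a `combined_model`.
#' @param consensus_scores consensus score vector for one target, or a list
#'   of vectors.
#' @param hits hit list for one target, or a list of hit lists.
#' @param ... unused.
#' @return list with combined `scores` and thresholded, repaired `calls`; or
#'   a list of such results.
#' @export
predict.combined_model <- function(object, consensus_scores, hits, ...) {
  one <- function(cs, h) {
    tmpl <- predict_gs3d(h, length(cs), object$tier_weights,
                         object$thresholds, object$max_hits)
    s <- combine_scores(cs, tmpl, object$component_weights[1L],
                        object$component_weights[2L])
    list(scores = s, calls = repair(s >= object$threshold))
  }
  if (is.numeric(consensus_scores)) return(one(consensus_scores, hits))
  stopifnot(length(consensus_scores) == length(hits))
  Map(one, consensus_scores, hits)
}
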