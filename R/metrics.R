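# Evaluation statistics used for training and assessing disorder predictors:
# the class-weighted score Sw, its threshold-averaged variant Sww, Matthews
# correlation, ROC/AUC, bootstrap error estimates, paired Wilcoxon comparison
# and the residue-level cross-validation splitter.
#
# All functions skip residues whose reference state is unknown (NA).

#' Confusion counts of a score vector at a decision threshold
#'
#' A residue is predicted disordered when its score is `>= threshold` (the
#' default convention; with `strict = TRUE` the comparison is `>`).  The
#' inclusive convention makes threshold 0 the all-disordered degenerate case,
#' which anchors one end of the ROC curve.
#'
#' @param scores numeric vector of per-residue scores in [0, 1] (NA allowed;
#'   such residues are skipped together with unknown labels).
#' @param labels reference labels (any form accepted by
#'   [as_disorder_logical()]).
#' @param threshold decision threshold in [0, 1].
#' @param strict call disordered only when score is strictly above threshold.
#' @return A [confusion_counts()] object.
#' @examples
#' confusion_at(c(0.9, 0.1), c(TRUE, FALSE), 0.5)   # TP=1 TN=1
#' @export
confusion_at <- function(scores, labels, threshold, strict = FALSE) {
  y <- pool_labels(labels)
  if (length(scores) != length(y))
    stop("scores (", length(scores), ") and labels (", length(y),
         ") differ in length")
  keep <- !is.na(y) & !is.na(scores)
  if (!any(keep)) stop("no scored residues with known labels")
  s <- scores[keep]; y <- y[keep]
  pred <- if (strict) s > threshold else s >= threshold
  confusion_counts(tp = sum(pred & y), tn = sum(!pred & !y),
                   fp = sum(pred & !y), fn = sum(!pred & y))
}

#' Weighted score Sw
#'
#' The class-weighted accuracy score used in CASP disorder assessment,
#' rewarding a correct call of the rarer disordered class more than a correct
#' order call:
#' \deqn{S_w = \frac{w_{dis} TP - w_{ord} FP + w_{ord} TN - w_{dis} FN}{S_{max}}}
#' with `w_dis` the fraction of ordered and `w_ord` the fraction of disordered
#' residues in the reference.  The normaliser is
#' `S_max = w_dis (TP + FN) + w_ord (TN + FP)` — the numerator of a perfect
#' prediction — so that Sw spans [-1, 1], equals 1 for a perfect predictor and
#' has expectation 0 for any label-independent one.  A widely circulated
#' variant of the formula normalises by `w_dis (TN + FN) + w_ord (TN + FP)`;
#' it does not reach 1 for a perfect predictor and is provided only behind
#' `denominator = "printed"` for comparison.
#'
#' @param counts a [confusion_counts()] object.
#' @param weights a [class_weights()] object.
#' @param denominator `"smax"` (default) or `"printed"` (compatibility).
#' @return Sw as a numeric scalar.
#' @export
sw <- function(counts, weights, denominator = c("smax", "printed")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(counts, "confusion_counts"),
            inherits(weights, "class_weights"))
  wd <- weights$w_disorder; wo <- weights$w_order
  num <- wd * counts$TP - wo * counts$FP + wo * counts$TN - wd * counts$FN
  den <- switch(denominator,
                smax    = wd * (counts$TP + counts$FN) + wo * (counts$TN + counts$FP),
                printed = wd * (counts$TN + counts$FN) + wo * (counts$TN + counts$FP))
  if (den <= 0) stop("Sw denominator is zero; no residues of either class?")
  num / den
}

#' Matthews correlation coefficient
#'
#' @param counts a [confusion_counts()] object.
#' @return MCC in [-1, 1]; by the standard convention 0 is returned (with a
#'   warning) when any marginal of the confusion table is empty.
#' @export
mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  if (tp + tn + fp + fn == 0) stop("empty confusion table")
  f <- as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (any(f == 0)) {
    warning("degenerate confusion table (empty margin); MCC set to 0")
    return(0)
  }
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(prod(f))
}

#' ROC curve and area under it
#'
#' The curve is traced over all distinct score values taken as inclusive
#' thresholds, in decreasing order, with the degenerate endpoints (0, 0) and
#' (1, 1) always present.  The AUC is computed by trapezoidal integration and
#' equals the tie-aware probability that a randomly chosen disordered residue
#' outscores a randomly chosen ordered one (ties counted 1/2).
#'
#' @inheritParams confusion_at
#' @return A list of class `roc_result`: `curve` (a `roc_curve` data frame
#'   with columns `threshold`, `fpr`, `tpr`) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c("D", "O", "D", "O"))$auc   # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- pool_labels(labels)
  if (length(scores) != length(y))
    stop("scores and labels differ in length")
  keep <- !is.na(y) & !is.na(scores)
  s <- scores[keep]; y <- y[keep]
  n_dis <- sum(y); n_ord <- sum(!y)
  if (n_dis == 0L || n_ord == 0L)
    stop("ROC requires both classes in the reference")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  last <- !duplicated(s, fromLast = TRUE)   # last index of each distinct score
  tpr <- cumsum(y)[last] / n_dis
  fpr <- cumsum(!y)[last] / n_ord
  thr <- s[last]
  # prepend the empty prediction; the final distinct score already gives (1,1)
  thr <- c(Inf, thr); tpr <- c(0, tpr); fpr <- c(0, fpr)
  curve <- structure(data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                     class = c("roc_curve", "data.frame"))
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f over %d curve points\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ylab = "Sensitivity", ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) plot(x$curve, ...)

# Sw at every threshold of the 0.01 grid, vectorised.  Predicted disordered
# iff score >= t; identical comparison semantics to confusion_at.
sw_grid <- function(scores, labels, weights,
                    thresholds = seq(0, 1, by = 0.01)) {
  y <- pool_labels(labels)
  keep <- !is.na(y) & !is.na(scores)
  s <- scores[keep]; y <- y[keep]
  n_dis <- sum(y); n_ord <- sum(!y)
  if (n_dis == 0L || n_ord == 0L) stop("both classes required")
  k <- length(thresholds)
  # idx_i = largest j with thresholds[j] <= s_i, so s_i >= t_j iff j <= idx_i
  tp <- rev(cumsum(rev(tabulate(findInterval(s[y], thresholds), nbins = k))))
  fp <- rev(cumsum(rev(tabulate(findInterval(s[!y], thresholds), nbins = k))))
  tn <- n_ord - fp; fn <- n_dis - tp
  wd <- weights$w_disorder; wo <- weights$w_order
  num <- wd * tp - wo * fp + wo * tn - wd * fn
  den <- wd * n_dis + wo * n_ord
  num / den
}

#' Threshold-averaged weighted score Sww
#'
#' Sw recomputed with the decision threshold swept from 0 to 1 in steps of
#' 0.01 (101 thresholds, endpoints included) and averaged — a threshold-free
#' analogue of Sw that blends ranking quality into the weighted score.
#'
#' @inheritParams confusion_at
#' @param weights a [class_weights()] object.
#' @return mean Sw over the grid, in [-1, 1].
#' @export
sww <- function(scores, labels, weights) {
  mean(sw_grid(scores, labels, weights))
}

#' Bootstrap mean absolute error of an evaluation score
#'
#' Draws `reps` subsamples of `ceiling(fraction * n)` targets without
#' replacement, recomputes the metric on the pooled residues of each
#' subsample, and reports the mean score over subsamples together with the
#' mean absolute deviation from the full-data score.  A subsample on which
#' the metric fails (for example a single-class draw) is redrawn, up to
#' `max_retries` extra draws in total.
#'
#' @seealso [wilcoxon_paired()] for comparing two methods' per-target scores.
#'
#' @param per_target_data list with one element per target; passed subset to
#'   `metric`.
#' @param metric function taking a list of targets and returning a scalar.
#' @param fraction subsample fraction (default 0.8).
#' @param reps number of subsamples (default 1000).
#' @param seed optional integer for reproducibility.
#' @param max_retries total cap on redraws of failing subsamples.
#' @return list with `score` (full-data value), `mean` (mean over subsamples),
#'   `mae` and the vector of subsample `values`.
#' @export
bootstrap_mae <- function(per_target_data, metric, fraction = 0.8,
                          reps = 1000L, seed = NULL, max_retries = 1000L) {
  n <- length(per_target_data)
  if (n < 2L) stop("need at least two targets")
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- ceiling(fraction * n)
  full <- metric(per_target_data)
  values <- numeric(reps)
  retries <- 0L
  for (r in seq_len(reps)) {
    repeat {
      v <- tryCatch(metric(per_target_data[sample.int(n, m)]),
                    error = function(e) NULL)
      if (!is.null(v)) break
      retries <- retries + 1L
      if (retries > max_retries)
        stop("metric failed on too many subsamples (", max_retries, " redraws)")
    }
    values[r] <- v
  }
  list(score = full, mean = mean(values), mae = mean(abs(values - full)),
       values = values)
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on per-target score differences.  Zero
#' differences are dropped first; if all differences are zero the methods are
#' indistinguishable and p = 1 is returned by convention.  For n <= 25 the
#' exact null distribution of the rank sum is enumerated (midranks under
#' ties); beyond that the normal approximation with tie correction is used.
#'
#' @param scores_a,scores_b equal-length numeric vectors of per-target scores.
#' @return two-sided p-value.
#' @export
wilcoxon_paired <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  d <- scores_a - scores_b
  d <- d[d != 0]
  if (length(d) == 0L) return(1.0)
  n <- length(d)
  if (n < 5L)
    stop("fewer than 5 non-zero differences; test uninformative")
  r <- rank(abs(d))                      # midranks under ties
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 25L) {
    # exact null: enumerate the distribution of 2V by dynamic programming
    # over the doubled midranks (integers even with tied magnitudes)
    r2 <- as.integer(round(2 * r))
    ways <- c(1, numeric(sum(r2)))       # ways[s + 1] = #assignments with 2V = s
    for (ri in r2) {
      shifted <- c(numeric(ri), ways[seq_len(length(ways) - ri)])
      ways <- ways + shifted
    }
    probs <- ways / 2^n
    v2 <- round(2 * v)
    p_side <- if (v > mu) sum(probs[(v2 + 1L):length(probs)])
              else sum(probs[1:(v2 + 1L)])
    return(min(1, 2 * p_side))
  }
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  2 * stats::pnorm(-abs(v - mu) / sqrt(sigma2))
}

#' Random assignment of residues to cross-validation bins
#'
#' Residues are assigned to `k` bins of nearly equal size (sizes differ by at
#' most one) uniformly at random.
#'
#' @param total_residues number of residues to assign.
#' @param k number of bins (default 10).
#' @param seed optional integer for reproducibility.
#' @return integer vector of bin indices in `1:k`, one per residue.
#' @export
kfold_residue_bins <- function(total_residues, k = 10L, seed = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (total_residues < k) stop("fewer residues than bins")
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(k), total_residues))
}

#' Protein-level cross-validation folds
#'
#' Leakage-safe alternative to [kfold_residue_bins()]: whole proteins are
#' assigned to bins, so no chain contributes residues to both training and
#' validation.
#'
#' @param n_targets number of proteins.
#' @inheritParams kfold_residue_bins
#' @return integer vector of bin indices, one per protein.
#' @export
kfold_protein_bins <- function(n_targets, k = 10L, seed = NULL) {
  kfold_residue_bins(n_targets, k = k, seed = seed)
}

#' Benchmark a set of score vectors against pooled reference labels
#'
#' Produces the standard comparison table: one row per method with Sw (at the
#' method's best grid threshold), its bootstrap MAE, MCC, AUC and its
#' bootstrap MAE, sensitivity and specificity.  Class weights are computed
#' once from the pooled reference.
#'
#' @param score_sets named list; each element is a list of per-target score
#'   vectors (one method).
#' @param labels_list list of per-target labels aligned with each score set.
#' @param reps bootstrap replicates (default 200; raise for publication-grade
#'   error bars).
#' @param seed optional integer seed.
#' @return data frame with columns `method`, `Sw`, `Sw_mae`, `MCC`, `AUC`,
#'   `AUC_mae`, `sensitivity`, `specificity`.
#' @export
evaluate_predictors <- function(score_sets, labels_list, reps = 200L,
                                seed = NULL) {
  stopifnot(is.list(score_sets), length(score_sets) > 0L,
            !is.null(names(score_sets)))
  if (!is.null(seed)) set.seed(seed)
  y_pool <- pool_labels(labels_list)
  w <- class_weights(y_pool)
  rows <- lapply(names(score_sets), function(m) {
    sc <- score_sets[[m]]
    stopifnot(length(sc) == length(labels_list))
    s_pool <- unlist(sc, use.names = FALSE)
    thr <- select_threshold(s_pool, y_pool, w)
    cm <- confusion_at(s_pool, y_pool, thr)
    targets <- Map(function(s, l) list(scores = s, labels = as_disorder_logical(l)),
                   sc, labels_list)
    met_sw <- function(tt) {
      s <- unlist(lapply(tt, `[[`, "scores"), use.names = FALSE)
      l <- unlist(lapply(tt, `[[`, "labels"), use.names = FALSE)
      sw(confusion_at(s, l, thr), w)
    }
    met_auc <- function(tt) {
      s <- unlist(lapply(tt, `[[`, "scores"), use.names = FALSE)
      l <- unlist(lapply(tt, `[[`, "labels"), use.names = FALSE)
      roc_auc(s, l)$auc
    }
    b_sw <- bootstrap_mae(targets, met_sw, reps = reps)
    b_auc <- bootstrap_mae(targets, met_auc, reps = reps)
    data.frame(method = m,
               Sw = b_sw$score, Sw_mae = b_sw$mae,
               MCC = mcc(cm),
               AUC = b_auc$score, AUC_mae = b_auc$mae,
               sensitivity = cm$TP / (cm$TP + cm$FN),
               specificity = cm$TN / (cm$TN + cm$FP))
  })
  do.call(rbind, rows)
}

#' Write an evaluation table as TSV
#'
#' @param tab data frame from [evaluate_predictors()].
#' @param path output file.
#' @export
write_evaluation_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
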