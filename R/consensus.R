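# Accuracy-weighted consensus over primary-predictor score columns:
# binary 1/0.01 encoding, weighted normalised sum, terminal correction,
# Sw-optimal threshold selection and the short-run repair filter.

#' Consensus configuration
#'
#' @param mode `"continuous"` uses continuous scores where a method provides
#'   them; `"binary"` reduces every column to its two-state call first.
#' @param binary_positive encoded value of a disorder call (default 1).
#' @param binary_negative encoded value of an order call; strictly positive
#'   (default 0.01) so that weighted sums can never be divided by zero.
#' @param threshold decision threshold; `NULL` until selected from data.
#' @param repair_max_run longest disorder run the repair filter removes
#'   (default 3).
#' @param repair_window repair filter window (default 5); must exceed
#'   `repair_max_run`.
#' @param native_threshold threshold at which a continuous column is read as
#'   its native two-state call in binary mode (default 0.5).
#' @return An object of class `consensus_config`.
#' @export
consensus_config <- function(mode = c("continuous", "binary"),
                             binary_positive = 1.0, binary_negative = 0.01,
                             threshold = NULL, repair_max_run = 3L,
                             repair_window = 5L, native_threshold = 0.5) {
  mode <- match.arg(mode)
  if (binary_negative <= 0)
    stop("binary_negative must be > 0 (division-by-zero guard)")
  if (repair_max_run >= repair_window)
    stop("repair_max_run must be smaller than repair_window")
  structure(list(mode = mode, binary_positive = binary_positive,
                 binary_negative = binary_negative, threshold = threshold,
                 repair_max_run = as.integer(repair_max_run),
                 repair_window = as.integer(repair_window),
                 native_threshold = native_threshold),
            class = "consensus_config")
}

#' Encode two-state calls on the consensus score scale
#'
#' Binary columns (0/1 calls) are mapped to `binary_negative`/`binary_positive`
#' (0.01 and 1 by default; order is encoded as a small positive value rather
#' than 0 to keep weighted sums strictly positive whenever any method calls
#' disorder).  In continuous mode, continuous columns pass through unchanged;
#' in binary mode they are first reduced to their native call at
#' `native_threshold` and then encoded the same way.  Missing values stay
#' missing.
#'
#' @param profile a [prediction_profile()].
#' @param cfg a [consensus_config()].
#' @return A [prediction_profile()] with encoded scores.
#' @export
encode_binary <- function(profile, cfg = consensus_config()) {
  stopifnot(inherits(profile, "prediction_profile"),
            inherits(cfg, "consensus_config"))
  sc <- profile$scores
  for (j in seq_len(ncol(sc))) {
    col <- sc[, j]
    if (profile$is_binary[j]) {
      ok <- is.na(col) | col %in% c(0, 1)
      if (!all(ok))
        stop("column '", colnames(sc)[j], "' of profile '", profile$id,
             "' flagged binary but holds non 0/1 value at row ",
             which(!ok)[1L])
      sc[, j] <- ifelse(col == 1, cfg$binary_positive, cfg$binary_negative)
    } else if (cfg$mode == "binary") {
      sc[, j] <- ifelse(col >= cfg$native_threshold,
                        cfg$binary_positive, cfg$binary_negative)
    }
  }
  prediction_profile(profile$id, sc, is_binary = profile$is_binary)
}

#' Accuracy-weighted consensus score
#'
#' Per-residue weighted mean of the method columns: each method's score is
#' multiplied by that method's weight (its calibration Sw) and the sum is
#' normalised by the maximal possible score, i.e. the sum of the weights.
#' Methods missing at a residue are dropped from both numerator and
#' denominator; a residue with no prediction at all gets a missing consensus
#' score.
#'
#' @param profile a [prediction_profile()] (already encoded if binary).
#' @param method_weights a [weight_vector()] of kind `consensus_method_weights`
#'   naming every profile column, or a named numeric vector.
#' @return numeric vector of consensus scores in [0, 1] (NA where no method
#'   reported).
#' @export
weighted_consensus <- function(profile, method_weights) {
  stopifnot(inherits(profile, "prediction_profile"))
  w <- if (inherits(method_weights, "weight_vector")) method_weights$values
       else method_weights
  if (is.null(names(w)) || !all(profile$methods %in% names(w)))
    stop("method_weights must name every profile column")
  w <- w[profile$methods]
  if (any(w < 0)) stop("weights must be non-negative")
  if (sum(w) <= 0) stop("at least one weight must be positive")
  sc <- profile$scores
  present <- !is.na(sc)
  num <- rowSums(sweep(ifelse(present, sc, 0), 2L, w, "*"))
  den <- as.vector(present %*% w)
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Terminal correction factors
#'
#' Multiplicative per-offset factors applied to scores within 15 residues of
#' either chain terminus, capturing the elevated disorder frequency of chain
#' ends.
#'
#' @param factors_nterm,factors_cterm positive numeric vectors of
#'   `n_proximal` factors, offset 1 = terminal residue.
#' @param n_proximal window depth (default 15).
#' @return An object of class `terminal_correction`.
#' @export
terminal_correction <- function(factors_nterm = rep(1, 15),
                                factors_cterm = rep(1, 15),
                                n_proximal = 15L) {
  n_proximal <- as.integer(n_proximal)
  stopifnot(length(factors_nterm) == n_proximal,
            length(factors_cterm) == n_proximal)
  if (any(factors_nterm <= 0) || any(factors_cterm <= 0))
    stop("correction factors must be positive")
  structure(list(n_proximal = n_proximal,
                 factors_nterm = as.numeric(factors_nterm),
                 factors_cterm = as.numeric(factors_cterm)),
            class = "terminal_correction")
}

#' @export
print.terminal_correction <- function(x, ...) {
  cat("<terminal_correction> offsets 1 -", x$n_proximal, "\n")
  cat("  N:", paste(sprintf("%.2f", x$factors_nterm), collapse = " "), "\n")
  cat("  C:", paste(sprintf("%.2f", x$factors_cterm), collapse = " "), "\n")
  invisible(x)
}

#' Estimate terminal correction factors from reference labels
#'
#' The factor at terminal offset i (1..15 from each end) is the ratio of the
#' disorder frequency at that offset to the interior disorder frequency,
#' floored at `eps`.  Chains shorter than `2 * n_proximal + 1` residues have
#' no interior and are skipped with a warning.
#'
#' @param labels list of [disorder_labels()] (or label vectors).
#' @param n_proximal window depth (default 15).
#' @param eps positive floor for the factors.
#' @return A [terminal_correction()].
#' @export
estimate_terminal_correction <- function(labels, n_proximal = 15L,
                                         eps = 1e-6) {
  n_proximal <- as.integer(n_proximal)
  if (inherits(labels, "disorder_labels") || !is.list(labels))
    labels <- list(labels)
  dis_n <- tot_n <- dis_c <- tot_c <- numeric(n_proximal)
  dis_i <- tot_i <- 0
  skipped <- 0L
  for (lab in labels) {
    y <- as_disorder_logical(lab)
    L <- length(y)
    if (L < 2L * n_proximal + 1L) { skipped <- skipped + 1L; next }
    nt <- y[seq_len(n_proximal)]
    ct <- y[L + 1L - seq_len(n_proximal)]
    it <- y[(n_proximal + 1L):(L - n_proximal)]
    dis_n <- dis_n + ifelse(is.na(nt), 0, nt); tot_n <- tot_n + !is.na(nt)
    dis_c <- dis_c + ifelse(is.na(ct), 0, ct); tot_c <- tot_c + !is.na(ct)
    dis_i <- dis_i + sum(it, na.rm = TRUE);    tot_i <- tot_i + sum(!is.na(it))
  }
  if (skipped > 0L)
    warning(skipped, " chain(s) shorter than ", 2L * n_proximal + 1L,
            " residues skipped in terminal-correction estimation")
  if (tot_i == 0 || any(tot_n == 0) || any(tot_c == 0))
    stop("reference too small to estimate terminal correction")
  p_int <- dis_i / tot_i
  if (p_int == 0)
    stop("interior disorder frequency is zero; reference uninformative")
  terminal_correction(pmax(dis_n / tot_n / p_int, eps),
                      pmax(dis_c / tot_c / p_int, eps),
                      n_proximal = n_proximal)
}

#' Apply a terminal correction to a score vector
#'
#' Scores within `n_proximal` residues of either terminus are multiplied by
#' the factor of their offset and clipped back to [0, 1]; interior scores are
#' returned unchanged.  On chains short enough for the two windows to
#' overlap, the nearer terminus wins; ties go to the N-terminal factor.
#'
#' @param scores numeric vector in [0, 1].
#' @param corr a [terminal_correction()].
#' @return corrected score vector.
#' @export
apply_terminal_correction <- function(scores, corr) {
  stopifnot(inherits(corr, "terminal_correction"))
  L <- length(scores)
  off_n <- seq_len(L)
  off_c <- L + 1L - off_n
  fac <- rep(1, L)
  use_n <- off_n <= corr$n_proximal & off_n <= off_c
  use_c <- off_c <= corr$n_proximal & off_c < off_n
  fac[use_n] <- corr$factors_nterm[off_n[use_n]]
  fac[use_c] <- corr$factors_cterm[off_c[use_c]]
  pmin(pmax(scores * fac, 0), 1)
}

#' Select the Sw-optimal decision threshold
#'
#' Scans the 0.01 threshold grid and returns the threshold maximising Sw of
#' the resulting two-state prediction; ties are broken toward the lowest
#' threshold.
#'
#' @inheritParams confusion_at
#' @param weights a [class_weights()] object.
#' @return threshold in [0, 1].
#' @export
select_threshold <- function(scores, labels, weights) {
  grid <- seq(0, 1, by = 0.01)
  grid[which.max(sw_grid(scores, labels, weights, thresholds = grid))]
}

#' Repair filter: remove short isolated disorder stretches
#'
#' Post-processing smoother: every maximal run of predicted disorder of
#' length at most `max_run` (3 by default, i.e. shorter than the 5-residue
#' window) that is flanked by predicted order on *both* sides is converted to
#' order.  Runs touching a chain terminus are preserved.  The filter is
#' one-sided (never converts order to disorder) and idempotent.
#'
#' @param calls two-state prediction: a string or character vector over `D`
#'   (disorder) and `-`/`O` (order), or a logical vector.
#' @param max_run longest run removed (default 3).
#' @return repaired calls, same representation as the input.
#' @examples
#' repair("DDD---D--")   # "DDD------"
#' @export
repair <- function(calls, max_run = 3L) {
  as_string <- is.character(calls) && length(calls) == 1L && nchar(calls) > 1L
  v <- if (as_string) strsplit(calls, "")[[1]] else calls
  d <- if (is.logical(v)) v else toupper(v) == "D"
  order_sym <- if (is.logical(v)) FALSE else {
    syms <- unique(v[!d])
    if (length(syms) > 1L) stop("mixed order symbols: ",
                                paste(syms, collapse = ", "))
    if (length(syms) == 0L) "-" else syms
  }
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  drop <- r$values & r$lengths <= max_run &
    starts > 1L & ends < length(d)
  r$values[drop] <- FALSE
  d2 <- inverse.rle(r)
  out <- if (is.logical(v)) d2 else ifelse(d2, "D", order_sym)
  if (as_string) paste(out, collapse = "") else out
}

#' Full consensus prediction chain
#'
#' Encode (binary columns, and all columns in binary mode), compute the
#' weighted consensus, apply the terminal correction, threshold, and repair.
#'
#' @param profile a [prediction_profile()].
#' @param method_weights per-method weights (see [weighted_consensus()]).
#' @param corr a [terminal_correction()]; `NULL` for no correction.
#' @param cfg a [consensus_config()]; its `threshold` must be set.
#' @return list with `scores` (continuous, after correction) and `calls`
#'   (logical two-state prediction after repair; NA where no method reported).
#' @export
predict_consensus <- function(profile, method_weights, corr = NULL,
                              cfg = consensus_config(threshold = 0.5)) {
  if (is.null(cfg$threshold))
    stop("cfg$threshold is not set; fit or choose a threshold first")
  enc <- encode_binary(profile, cfg)
  scores <- weighted_consensus(enc, method_weights)
  if (!is.null(corr)) scores <- apply_terminal_correction(scores, corr)
  calls <- scores >= cfg$threshold
  known <- !is.na(calls)
  calls[known] <- repair(calls[known], max_run = cfg$repair_max_run)
  list(scores = scores, calls = calls)
}

#' Fit an accuracy-weighted consensus disorder predictor
#'
#' Calibrates the consensus model on reference-labelled targets:
#' each method's weight is its weighted score Sw on the pooled calibration
#' residues (evaluated at that method's own Sw-optimal grid threshold;
#' methods with negative Sw are floored at weight 0 and thereby excluded),
#' the terminal correction is estimated from the calibration labels, and the
#' decision threshold is selected by 10-fold residue-level cross-validation:
#' the Sw-optimal threshold of each training split is averaged (snapped back
#' to the 0.01 grid).
#'
#' @param profiles list of [prediction_profile()], one per target.
#' @param labels list of [disorder_labels()] aligned with `profiles`.
#' @param mode `"continuous"` (FloatCons-style, default) or `"binary"`
#'   (BinCons-style).
#' @param cfg a [consensus_config()]; its `mode` is overridden by `mode`.
#' @param terminal estimate and apply the terminal correction (default TRUE).
#' @param cv_folds folds for threshold cross-validation; 1 = single fit on
#'   all residues.
#' @param seed optional integer seed (drives the CV split).
#' @return An object of class `consensus_model` with fields `weights`
#'   (a [weight_vector()]), `correction`, `config` (threshold set), `mode`
#'   and per-method calibration statistics in `calibration`.
#' @export
fit_consensus <- function(profiles, labels, mode = c("continuous", "binary"),
                          cfg = consensus_config(), terminal = TRUE,
                          cv_folds = 10L, seed = NULL) {
  mode <- match.arg(mode)
  cfg$mode <- mode
  stopifnot(length(profiles) == length(labels), length(profiles) > 0L)
  methods <- profiles[[1L]]$methods
  for (p in profiles)
    if (!identical(p$methods, methods))
      stop("all profiles must share the same method columns")
  if (!is.null(seed)) set.seed(seed)

  enc <- lapply(profiles, encode_binary, cfg = cfg)
  y <- pool_labels(labels)
  big <- do.call(rbind, lapply(enc, `[[`, "scores"))
  stopifnot(nrow(big) == length(y))
  w_cls <- class_weights(y)

  # per-method accuracy weight: Sw at the method's own best grid threshold
  calib <- vapply(seq_along(methods), function(j) {
    s <- big[, j]
    thr <- select_threshold(s, y, w_cls)
    c(sw = sw(confusion_at(s, y, thr), w_cls), threshold = thr)
  }, numeric(2))
  colnames(calib) <- methods
  w_m <- pmax(calib["sw", ], 0)
  if (sum(w_m) <= 0)
    stop("every method has non-positive calibration Sw; nothing to weight")
  weights <- weight_vector(w_m, kind = "consensus_method_weights")

  corr <- if (terminal) estimate_terminal_correction(labels) else NULL
  cons_per_target <- lapply(enc, weighted_consensus, method_weights = weights)
  if (!is.null(corr))
    cons_per_target <- lapply(cons_per_target, apply_terminal_correction, corr = corr)
  cons <- unlist(cons_per_target, use.names = FALSE)

  if (cv_folds > 1L) {
    bins <- kfold_residue_bins(length(y), k = cv_folds)
    thrs <- vapply(seq_len(cv_folds), function(b) {
      idx <- bins != b
      select_threshold(cons[idx], y[idx], class_weights(y[idx]))
    }, numeric(1))
    cfg$threshold <- round(mean(thrs) / 0.01) * 0.01
  } else {
    cfg$threshold <- select_threshold(cons, y, w_cls)
  }

  structure(list(weights = weights, correction = corr, config = cfg,
                 mode = mode,
                 calibration = as.data.frame(t(calib)),
                 n_targets = length(profiles), n_residues = length(y)),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("Consensus disorder predictor (", x$mode, " mode)\n", sep = "")
  cat("  methods:   ", length(x$weights$values), "\n")
  cat("  threshold: ", format(x$config$threshold), "\n")
  cat("  fitted on: ", x$n_targets, " targets / ", x$n_residues,
      " residues\n", sep = "")
  invisible(x)
}

#' @export
summary.consensus_model <- function(object, ...) {
  print(object)
  cat("\nPer-method calibration (Sw used as weight, floored at 0):\n")
  tab <- object$calibration
  tab$weight <- object$weights$values[rownames(tab)]
  print(round(tab[order(-tab$weight), ], 4))
  invisible(object)
}

#' @export
coef.consensus_model <- function(object, ...) object$weights$values

#' Predict disorder for new profiles with a fitted consensus model
#'
#' @param object a `consensus_model`.
#' @param newdata a [prediction_profile()] or list of them.
#' @param ... unused.
#' @return for one profile, a list with `scores` and `calls`; for a list of
#'   profiles, a named list of such results.
#' @export
predict.consensus_model <- function(object, newdata, ...) {
  one <- function(p) predict_consensus(p, object$weights,
                                       corr = object$correction,
                                       cfg = object$config)
  if (inherits(newdata, "prediction_profile")) return(one(newdata))
  out <- lapply(newdata, one)
  names(out) <- vapply(newdata, `[[`, "", "id")
  out
}
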