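# Core domain types: sequences, two-state disorder labels, per-residue score
# profiles, fold-recognition hits, confusion counts and weight vectors.
# Conventions used throughout the package:
#   * residue coordinates are 1-based, intervals are closed;
#   * disorder labels are logical vectors (TRUE = disordered, FALSE = ordered,
#     NA = unknown/unobservable); unknowns are excluded from every metric.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

#' Protein sequence record
#'
#' A minimal container for one protein chain: an identifier and a string of
#' one-letter amino-acid codes.  Only the 20 standard codes plus `X` are
#' accepted.  Sequences longer than `max_length` are processed with a warning
#' rather than rejected: the usual limit of 1000 residues stems from upstream
#' predictor tools, not from anything in this package.
#'
#' @param id character identifier (non-empty scalar).
#' @param residues character scalar, one-letter amino-acid codes.
#' @param max_length soft length policy; longer sequences warn.
#' @return An object of class `sequence_record` with fields `id`, `residues`
#'   and `length`.
#' @examples
#' sequence_record("t1", "ACDEFGHIKL")
#' @export
sequence_record <- function(id, residues, max_length = 1000L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("sequence '", id, "' is empty")
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L)
    stop("sequence '", id, "' contains illegal residue codes: ",
         paste(bad, collapse = ", "))
  if (nchar(residues) > max_length)
    warning("sequence '", id, "' is ", nchar(residues),
            " residues long (policy limit ", max_length, "); processing anyway")
  structure(list(id = id, residues = residues, length = nchar(residues)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat("<sequence_record>", x$id, "-", x$length, "residues\n")
  invisible(x)
}

#' Two-state disorder reference labels
#'
#' Per-residue reference states for one chain.  States may be given as a
#' logical vector (TRUE = disordered, FALSE = ordered, NA = unknown) or as a
#' character vector over `D` (disordered), `O`/`-` (ordered) and `U`/`.`
#' (unknown).  Unknown residues are skipped by every metric in the package.
#'
#' @param id identifier matching the paired [sequence_record()].
#' @param states logical or character vector of per-residue states.
#' @return An object of class `disorder_labels` with fields `id` and `states`
#'   (logical vector).
#' @examples
#' disorder_labels("t1", c("D", "D", "O", "O", "U"))
#' @export
disorder_labels <- function(id, states) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  states <- as_disorder_logical(states)
  if (length(states) == 0L) stop("labels for '", id, "' are empty")
  structure(list(id = id, states = states), class = "disorder_labels")
}

#' Coerce label encodings to the internal logical form
#'
#' @param x a `disorder_labels` object, a logical vector, or a character
#'   vector over `D`, `O`, `-`, `U`, `.`.
#' @return logical vector: TRUE disordered, FALSE ordered, NA unknown.
#' @export
as_disorder_logical <- function(x) {
  if (inherits(x, "disorder_labels")) return(x$states)
  if (is.logical(x)) return(x)
  if (is.character(x)) {
    if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
    x <- toupper(x)
    out <- rep(NA, length(x))
    out[x %in% c("D", "1")] <- TRUE
    out[x %in% c("O", "-", "0")] <- FALSE
    bad <- !(x %in% c("D", "1", "O", "-", "0", "U", "."))
    if (any(bad))
      stop("unrecognised label symbols: ", paste(unique(x[bad]), collapse = ", "))
    return(out)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as disorder labels")
}

#' @export
print.disorder_labels <- function(x, ...) {
  n <- length(x$states)
  cat("<disorder_labels>", x$id, "-", n, "residues (",
      sum(x$states, na.rm = TRUE), "disordered,",
      sum(!x$states, na.rm = TRUE), "ordered,",
      sum(is.na(x$states)), "unknown )\n")
  invisible(x)
}

#' Per-residue prediction profile
#'
#' An L x M matrix of per-residue scores from M primary predictor methods for
#' one sequence.  Scores lie in [0, 1]; `NA` marks a missing prediction.
#' Binary methods store their calls as 0/1; which columns are binary is
#' recorded in `is_binary` (auto-detected as columns whose non-missing values
#' are all 0 or 1 when not supplied).
#'
#' @param id sequence identifier.
#' @param scores numeric matrix, rows = residues, named columns = method modes.
#' @param is_binary optional named logical, one entry per column.
#' @return An object of class `prediction_profile` with fields `id`, `methods`,
#'   `scores`, `is_binary`.
#' @export
prediction_profile <- function(id, scores, is_binary = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.matrix(scores))
  if (ncol(scores) < 1L) stop("profile '", id, "' has no method columns (M >= 1 required)")
  if (nrow(scores) < 1L) stop("profile '", id, "' has no residues")
  if (is.null(colnames(scores)) || anyDuplicated(colnames(scores)))
    stop("profile '", id, "' needs unique column (method) names")
  rng <- range(scores, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("profile '", id, "' has scores outside [0, 1]")
  if (is.null(is_binary)) {
    is_binary <- apply(scores, 2L, function(col) {
      v <- col[!is.na(col)]
      length(v) > 0L && all(v %in% c(0, 1))
    })
  } else {
    stopifnot(is.logical(is_binary), length(is_binary) == ncol(scores))
    if (is.null(names(is_binary))) names(is_binary) <- colnames(scores)
  }
  structure(list(id = id, methods = colnames(scores), scores = scores,
                 is_binary = is_binary),
            class = "prediction_profile")
}

#' @export
print.prediction_profile <- function(x, ...) {
  cat("<prediction_profile>", x$id, "-", nrow(x$scores), "residues x",
      ncol(x$scores), "methods (", sum(x$is_binary), "binary )\n")
  invisible(x)
}

#' One fold-recognition hit
#'
#' A single match of the target sequence against a template of known
#' structure: the method mode that produced it, its raw score in the method's
#' native scale (e-value, probability, method-specific score), the 1-based
#' closed target-sequence intervals covered by non-gap alignment columns, and
#' the hit's rank in the method's hit list.
#'
#' @param method_mode one of [fold_method_modes()].
#' @param raw_score numeric scalar, native scale.
#' @param intervals two-column matrix (start, end), 1-based closed; rows must
#'   be sorted and non-overlapping.
#' @param rank integer >= 1, position in the method's hit list.
#' @param L optional target length; when given, intervals are checked against
#'   `[1, L]`.
#' @return An object of class `alignment_hit`.
#' @export
alignment_hit <- function(method_mode, raw_score, intervals, rank = 1L, L = NULL) {
  stopifnot(is.character(method_mode), length(method_mode) == 1L,
            is.numeric(raw_score), length(raw_score) == 1L)
  if (!method_mode %in% fold_method_modes())
    stop("unknown method mode '", method_mode, "'")
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2L) stop("intervals must have two columns (start, end)")
  storage.mode(intervals) <- "integer"
  if (nrow(intervals) > 0L) {
    if (any(intervals[, 1L] > intervals[, 2L])) stop("interval start > end")
    if (any(intervals[, 1L] < 1L)) stop("interval start < 1")
    if (!is.null(L) && any(intervals[, 2L] > L))
      stop("interval beyond sequence end (L = ", L, ")")
    if (nrow(intervals) > 1L) {
      if (is.unsorted(intervals[, 1L], strictly = TRUE))
        stop("intervals must be sorted by start")
      if (any(intervals[-1L, 1L] <= intervals[-nrow(intervals), 2L]))
        stop("intervals must be non-overlapping")
    }
  }
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be >= 1")
  structure(list(method_mode = method_mode, raw_score = raw_score,
                 intervals = intervals, rank = rank),
            class = "alignment_hit")
}

#' The eight configured fold-recognition method modes
#'
#' Six base methods, of which PSI-BLAST and HHsearch are run in two modes
#' each, giving eight modes in total.
#'
#' @return character vector of the eight mode names.
#' @export
fold_method_modes <- function() {
  c("psiblast_default", "psiblast_nofilter", "ffas", "mgenthreader",
    "hhsearch_pdb70", "hhsearch_cdd", "pcons", "phyre")
}

#' Confusion counts at a fixed threshold
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  if (any(v < 0)) stop("confusion counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Class weights for the weighted score Sw
#'
#' Deliberately cross-assigned, so that the rarer disordered class is rewarded
#' more: `w_disorder` is the fraction of *ordered* residues in the reference
#' and `w_order` the fraction of *disordered* residues.  Computed over
#' non-unknown residues of a single reference or a collection.
#'
#' @param labels a `disorder_labels` object, logical vector, or list of either.
#' @return An object of class `class_weights` with fields `w_disorder`,
#'   `w_order`.
#' @examples
#' class_weights(c(TRUE, TRUE, FALSE, FALSE))           # balanced: 0.5 / 0.5
#' @export
class_weights <- function(labels) {
  states <- pool_labels(labels)
  n_dis <- sum(states, na.rm = TRUE)
  n_ord <- sum(!states, na.rm = TRUE)
  if (n_dis == 0L || n_ord == 0L)
    stop("reference contains a single class (", n_dis, " disordered, ",
         n_ord, " ordered); class weights are undefined")
  n <- n_dis + n_ord
  structure(list(w_disorder = n_ord / n, w_order = n_dis / n),
            class = "class_weights")
}

#' @export
print.class_weights <- function(x, ...) {
  cat(sprintf("<class_weights> w_disorder=%.4f w_order=%.4f\n",
              x$w_disorder, x$w_order))
  invisible(x)
}

# Pool one labels object or a list of them into a single logical vector.
pool_labels <- function(labels) {
  if (is.list(labels) && !inherits(labels, "disorder_labels"))
    unlist(lapply(labels, as_disorder_logical), use.names = FALSE)
  else as_disorder_logical(labels)
}

#' Trained weight vector
#'
#' @param values numeric vector of non-negative finite weights.
#' @param kind one of `consensus_method_weights` (one weight per primary
#'   method), `tier24` (8 fold-recognition modes x 3 alignment-quality tiers)
#'   or `tier24_plus_components` (tier24 plus the two channel weights of the
#'   combined model).
#' @param names optional labels; defaults are generated for tier kinds.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(values, kind = c("consensus_method_weights",
                                           "tier24",
                                           "tier24_plus_components"),
                          names = NULL) {
  kind <- match.arg(kind)
  nm_in <- base::names(values)
  values <- as.numeric(values)
  base::names(values) <- nm_in
  if (any(!is.finite(values)) || any(values < 0))
    stop("weights must be finite and non-negative")
  need <- switch(kind, consensus_method_weights = NA_integer_,
                 tier24 = 24L, tier24_plus_components = 26L)
  if (!is.na(need) && length(values) != need)
    stop("kind '", kind, "' requires ", need, " weights, got ", length(values))
  if (is.null(names)) {
    names <- if (kind == "consensus_method_weights") base::names(values)
             else tier24_names(kind == "tier24_plus_components")
  }
  if (!is.null(names)) {
    stopifnot(length(names) == length(values))
    base::names(values) <- names
  }
  structure(list(names = base::names(values), values = values, kind = kind),
            class = "weight_vector")
}

tier24_names <- function(with_components = FALSE) {
  nm <- as.vector(t(outer(fold_method_modes(), c("good", "medium", "poor"),
                          paste, sep = ".")))
  if (with_components) nm <- c(nm, "w_consensus", "w_template")
  nm
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>", x$kind, "-", length(x$values), "weights\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Check that a sequence, its labels and its profile belong together
#'
#' @param seq a [sequence_record()].
#' @param labels a [disorder_labels()].
#' @param profile a [prediction_profile()].
#' @return Invisibly, a list with the validated triple; errors name the id and
#'   offending lengths on any mismatch.
#' @export
validate_pairing <- function(seq, labels, profile) {
  stopifnot(inherits(seq, "sequence_record"),
            inherits(labels, "disorder_labels"),
            inherits(profile, "prediction_profile"))
  if (seq$id != labels$id || seq$id != profile$id)
    stop("id mismatch: sequence '", seq$id, "', labels '", labels$id,
         "', profile '", profile$id, "'")
  L <- seq$length
  if (length(labels$states) != L)
    stop("record '", seq$id, "': sequence has ", L, " residues but labels have ",
         length(labels$states))
  if (nrow(profile$scores) != L)
    stop("record '", seq$id, "': sequence has ", L, " residues but profile has ",
         nrow(profile$scores), " rows")
  invisible(list(seq = seq, labels = labels, profile = profile))
}
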