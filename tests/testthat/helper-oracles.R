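# Independent brute-force oracles used to validate the vectorised metric
# implementations, plus small fixture builders.  The oracles deliberately
# share no code with the functions they check.

# confusion counts by explicit residue-by-residue enumeration
bf_counts <- function(scores, labels, threshold) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(scores)) {
    if (is.na(labels[i]) || is.na(scores[i])) next
    pred <- scores[i] >= threshold
    if (pred && labels[i]) tp <- tp + 1L
    else if (!pred && !labels[i]) tn <- tn + 1L
    else if (pred && !labels[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Sw straight from its definition (weights recomputed from the labels)
bf_sw <- function(scores, labels, threshold) {
  ct <- bf_counts(scores, labels, threshold)
  n_dis <- ct["tp"] + ct["fn"]; n_ord <- ct["tn"] + ct["fp"]
  wd <- n_ord / (n_dis + n_ord); wo <- n_dis / (n_dis + n_ord)
  num <- wd * ct["tp"] - wo * ct["fp"] + wo * ct["tn"] - wd * ct["fn"]
  unname(num / (wd * n_dis + wo * n_ord))
}

bf_mcc <- function(scores, labels, threshold) {
  ct <- as.numeric(bf_counts(scores, labels, threshold))
  names(ct) <- c("tp", "tn", "fp", "fn")
  den <- sqrt((ct["tp"] + ct["fp"]) * (ct["tp"] + ct["fn"]) *
              (ct["tn"] + ct["fp"]) * (ct["tn"] + ct["fn"]))
  if (den == 0) return(0)
  unname((ct["tp"] * ct["tn"] - ct["fp"] * ct["fn"]) / den)
}

# AUC as pairwise concordance over all (disordered, ordered) residue pairs
bf_auc <- function(scores, labels) {
  sd_ <- scores[labels]; so <- scores[!labels]
  tot <- 0
  for (a in sd_) for (b in so)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sd_) * length(so))
}

# Sww as the literal mean of per-threshold Sw over the 0.01 grid
bf_sww <- function(scores, labels) {
  mean(vapply(seq(0, 1, by = 0.01), function(t) bf_sw(scores, labels, t),
              numeric(1)))
}

# random labels guaranteed to contain both classes
rnd_labels <- function(n, p = 0.3) {
  repeat {
    y <- stats::runif(n) < p
    if (any(y) && any(!y)) return(y)
  }
}

make_profile <- function(id, scores, is_binary = NULL) {
  prediction_profile(id, scores, is_binary = is_binary)
}

# tiny labelled fixture set: profiles + labels lists
tiny_fixture <- function(n_targets = 8, L = c(60, 120), seed = 1,
                         cfg = sim_config(n_targets = n_targets,
                                          length_range = as.integer(L),
                                          seed = seed)) {
  ch <- gen_labels(cfg, seed = seed)
  labs <- lapply(ch, `[[`, "labels")
  profs <- lapply(labs, sim_profile, cfg = cfg)
  list(cfg = cfg, chains = ch, labels = labs, profiles = profs)
}
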