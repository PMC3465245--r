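# Readers and writers for the package's plain-text formats.
#
# Coordinates are 1-based and intervals closed in every format, matching
# PDB/CASP conventions.
#
# Formats:
#   * FASTA                   - input sequences
#   * label FASTA             - per-residue states as D / O (or -) / U lines
#   * profile TSV             - id, index, residue, one column per method mode
#   * hit-table TSV           - target_id, method_mode, rank, raw_score,
#                               intervals ("start-end;start-end", 1-based closed)
#   * DR prediction records   - "index residue call score", score to 2 decimals
#   * PDB (SEQRES/REMARK 465) - reference disorder labels from missing residues
#   * model artifact          - human-readable key-value file, format-tagged
#   * YAML configuration      - flat, schema-checked

#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased; the ambiguity/rare codes U, B, Z, J are mapped
#' to X with a warning.
#'
#' @param path FASTA file.
#' @return named list of [sequence_record()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in '", path, "'")
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  mapped <- grepl("[UBZJ]", seqs)
  if (any(mapped)) {
    warning("mapped U/B/Z/J to X in: ", paste(ids[mapped], collapse = ", "))
    seqs <- gsub("[UBZJ]", "X", seqs)
  }
  out <- Map(sequence_record, ids, seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param seqs list of [sequence_record()].
#' @param path output file.
#' @param width line width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    writeLines(substring(s$residues, seq(1L, s$length, width),
                         pmin(seq(1L, s$length, width) + width - 1L, s$length)),
               con)
  }
  invisible(path)
}

#' Read two-state disorder labels
#'
#' FASTA-like layout: a `>id` header followed by lines of per-residue state
#' symbols, `D` disordered, `O` or `-` ordered, `U` or `.` unknown.
#'
#' @param path label file.
#' @return named list of [disorder_labels()].
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty label file '", path, "'")
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("label file '", path, "' must start with a '>' header")
  grp <- cumsum(hdr)
  out <- lapply(split(lines, grp), function(block) {
    id <- sub("^>\\s*", "", block[1L])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    disorder_labels(id, paste(block[-1L], collapse = ""))
  })
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate ids in label file '", path, "'")
  names(out) <- ids
  out
}

#' Write two-state disorder labels
#'
#' @param labels list of [disorder_labels()].
#' @param path output file.
#' @param width line width (default 60).
#' @export
write_labels <- function(labels, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (lab in labels) {
    writeLines(paste0(">", lab$id), con)
    sym <- ifelse(is.na(lab$states), "U", ifelse(lab$states, "D", "O"))
    s <- paste(sym, collapse = "")
    L <- nchar(s)
    writeLines(substring(s, seq(1L, L, width),
                         pmin(seq(1L, L, width) + width - 1L, L)), con)
  }
  invisible(path)
}

# three-letter -> one-letter amino acid map (nonstandard -> X downstream)
three_to_one <- function(codes) {
  map <- Biostrings::AMINO_ACID_CODE          # one -> Three
  inv <- stats::setNames(names(map), toupper(map))
  out <- unname(inv[toupper(codes)])
  out[is.na(out) | !(out %in% AA_ALPHABET)] <- "X"
  out
}

#' Extract disorder labels from a PDB file's REMARK 465 records
#'
#' The chain sequence is taken from SEQRES (three-letter codes mapped to
#' one-letter, nonstandard residues to X).  Residues listed under REMARK 465
#' for the chain are labelled disordered (missing coordinates); all other
#' SEQRES residues are labelled ordered.  REMARK 465 entries are matched to
#' SEQRES positions by their (residue number, insertion code) key via
#' `numbering`, which defaults to sequential numbering "1".."L"; pass the
#' author numbering explicitly when it differs.
#'
#' @param pdb a file path or a character vector of PDB-format lines.
#' @param chain one-character chain identifier.
#' @param id identifier for the returned labels (default `"<basename>_<chain>"`
#'   or `"pdb_<chain>"`).
#' @param numbering character vector, one residue key per SEQRES position.
#' @return list with `sequence` (a [sequence_record()]) and `labels`
#'   (a [disorder_labels()]).
#' @export
labels_from_remark465 <- function(pdb, chain, id = NULL, numbering = NULL) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    if (is.null(id)) id <- paste0(sub("\\.[^.]*$", "", basename(pdb)), "_", chain)
    readLines(pdb)
  } else {
    if (is.null(id)) id <- paste0("pdb_", chain)
    unlist(strsplit(pdb, "\n"))
  }
  stopifnot(is.character(chain), nchar(chain) == 1L)

  seqres <- lines[startsWith(lines, "SEQRES")]
  seqres <- seqres[substr(seqres, 12L, 12L) == chain]
  if (length(seqres) == 0L)
    stop("no SEQRES records for chain '", chain, "'")
  codes <- unlist(strsplit(trimws(substr(seqres, 20L, 80L)), "\\s+"))
  seq1 <- paste(three_to_one(codes), collapse = "")
  L <- nchar(seq1)
  if (is.null(numbering)) numbering <- as.character(seq_len(L))
  if (length(numbering) != L)
    stop("numbering has ", length(numbering), " keys but SEQRES has ", L,
         " residues")

  rem <- lines[startsWith(lines, "REMARK 465")]
  body <- trimws(substr(rem, 11L, nchar(rem)))
  # entries: optional model number, residue name, chain id, resseq[+icode]
  pat <- "^([0-9]+\\s+)?[A-Z0-9]{1,3}\\s+[A-Za-z0-9]\\s+(-?[0-9]+[A-Za-z]?)$"
  ent <- body[grepl(pat, body)]
  keys <- character(0)
  for (e in ent) {
    tok <- strsplit(e, "\\s+")[[1L]]
    if (grepl("^[0-9]+$", tok[1L]) && length(tok) == 4L) tok <- tok[-1L]
    if (length(tok) != 3L) next
    if (tok[2L] == chain) keys <- c(keys, tok[3L])
  }
  states <- rep(FALSE, L)
  if (length(keys) > 0L) {
    pos <- match(keys, numbering)
    if (anyNA(pos))
      stop("REMARK 465 residues with no SEQRES counterpart in chain '",
           chain, "': ", paste(keys[is.na(pos)], collapse = ", "))
    states[pos] <- TRUE
  }
  list(sequence = sequence_record(id, seq1),
       labels = disorder_labels(id, states))
}

#' Read per-residue score profiles from TSV
#'
#' Header: `id`, `index`, `residue`, then one column per method mode.  `NA`
#' marks a missing prediction.  Scores outside [0, 1] by no more than 1e-6
#' are clipped with a warning; larger excursions are errors.
#'
#' @param path TSV file (may hold several targets, grouped by id).
#' @return named list of [prediction_profile()]; each carries the residue
#'   string in attribute `"residues"`.
#' @export
read_profile_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "index", "residue")
  if (!all(need %in% names(tab)[1:3]))
    stop("profile TSV '", path, "' must start with columns id, index, residue")
  methods <- setdiff(names(tab), need)
  if (length(methods) == 0L) stop("profile TSV '", path, "' has no method columns")
  out <- lapply(split(tab, factor(tab$id, levels = unique(tab$id))), function(d) {
    d <- d[order(d$index), , drop = FALSE]
    if (!identical(as.integer(d$index), seq_len(nrow(d))))
      stop("profile for '", d$id[1L], "' has non-contiguous indices")
    m <- as.matrix(d[, methods, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- NULL
    low <- m < 0 & m >= -1e-6; high <- m > 1 & m <= 1 + 1e-6
    if (any(low | high, na.rm = TRUE)) {
      warning("clipped ", sum(low | high, na.rm = TRUE),
              " score(s) marginally outside [0, 1] in '", d$id[1L], "'")
      m[which(low)] <- 0; m[which(high)] <- 1
    }
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop("profile for '", d$id[1L], "' has scores far outside [0, 1]")
    p <- prediction_profile(d$id[1L], m)
    attr(p, "residues") <- paste(d$residue, collapse = "")
    p
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write per-residue score profiles as TSV
#'
#' @param profiles list of [prediction_profile()].
#' @param path output file.
#' @param residues optional list/vector of residue strings per profile; falls
#'   back to each profile's `"residues"` attribute, then to `X`.
#' @export
write_profile_tsv <- function(profiles, path, residues = NULL) {
  if (inherits(profiles, "prediction_profile")) profiles <- list(profiles)
  methods <- profiles[[1L]]$methods
  for (p in profiles)
    if (!identical(p$methods, methods))
      stop("all profiles in one TSV must share the same method columns")
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    res <- if (!is.null(residues)) residues[[i]] else attr(p, "residues")
    if (is.null(res)) res <- strrep("X", nrow(p$scores))
    data.frame(id = p$id, index = seq_len(nrow(p$scores)),
               residue = strsplit(res, "")[[1L]],
               p$scores, check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read fold-recognition hit tables
#'
#' Columns: `target_id`, `method_mode`, `rank`, `raw_score`, `intervals`
#' (semicolon-separated `start-end` pairs, 1-based closed).
#'
#' @param path TSV file.
#' @return named list (by target id) of lists of [alignment_hit()].
#' @export
read_hits_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("target_id", "method_mode", "rank", "raw_score", "intervals")
  if (!all(need %in% names(tab)))
    stop("hit table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  parse_intervals <- function(s, line) {
    if (is.na(s) || !nzchar(s)) return(matrix(integer(0), 0L, 2L))
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    ok <- grepl("^[0-9]+-[0-9]+$", parts)
    if (!all(ok))
      stop("malformed interval string '", s, "' at line ", line, " of '",
           path, "'")
    m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE), as.integer))
    m[order(m[, 1L]), , drop = FALSE]
  }
  hits <- lapply(seq_len(nrow(tab)), function(i) {
    if (!tab$method_mode[i] %in% fold_method_modes())
      stop("unknown method_mode '", tab$method_mode[i], "' at line ", i + 1L,
           " of '", path, "'")
    alignment_hit(tab$method_mode[i], tab$raw_score[i],
                  parse_intervals(tab$intervals[i], i + 1L),
                  rank = tab$rank[i])
  })
  split(hits, factor(tab$target_id, levels = unique(tab$target_id)))
}

#' Write fold-recognition hit tables
#'
#' @param hits named list (by target id) of lists of [alignment_hit()].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  rows <- lapply(names(hits), function(id) {
    do.call(rbind, lapply(hits[[id]], function(h) {
      data.frame(target_id = id, method_mode = h$method_mode, rank = h$rank,
                 raw_score = h$raw_score,
                 intervals = paste(paste0(h$intervals[, 1L], "-",
                                          h$intervals[, 2L]),
                                   collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-residue prediction in DR style
#'
#' One whitespace-separated line per residue: 1-based index, one-letter
#' residue code, two-state call (`D`/`O`) and the continuous score printed
#' with two decimals.
#'
#' @param scores numeric vector in [0, 1].
#' @param residues residue string (or vector) of matching length.
#' @param path output file.
#' @param threshold decision threshold used for the calls (score >= threshold
#'   is `D`); ignored when `calls` is given.
#' @param calls optional explicit logical calls (e.g. after repair).
#' @export
write_dr <- function(scores, residues, path, threshold = 0.5, calls = NULL) {
  res <- if (length(residues) == 1L) strsplit(residues, "")[[1L]] else residues
  stopifnot(length(res) == length(scores))
  if (is.null(calls)) calls <- scores >= threshold
  lines <- sprintf("%d %s %s %.2f", seq_along(scores), res,
                   ifelse(calls, "D", "O"), scores)
  writeLines(lines, path)
  invisible(path)
}

#' Read a DR-style prediction file
#'
#' @param path file written by [write_dr()].
#' @return data frame with columns `index`, `residue`, `call`, `score`.
#' @export
read_dr <- function(path) {
  tab <- utils::read.table(path, col.names = c("index", "residue", "call",
                                               "score"),
                           stringsAsFactors = FALSE)
  if (!identical(tab$index, seq_len(nrow(tab))))
    stop("DR file '", path, "' indices are not contiguous from 1")
  if (!all(tab$call %in% c("D", "O")))
    stop("DR file '", path, "' has calls outside {D, O}")
  tab
}

## ---- trained-model artifact (key-value text, format-tagged) ----

MODEL_FORMAT_TAG <- "dismeta-model v1"

kv_line <- function(key, value) {
  if (is.numeric(value)) value <- sprintf("%.17g", value)
  paste0(key, ": ", paste(value, collapse = ","))
}

kv_parse <- function(lines) {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed model artifact line: ", lines[bad][1L])
  stats::setNames(vapply(m, `[[`, "", 3L), trimws(vapply(m, `[[`, "", 2L)))
}

kv_num <- function(kv, key) as.numeric(strsplit(kv[[key]], ",")[[1L]])
kv_chr <- function(kv, key) strsplit(kv[[key]], ",")[[1L]]

#' Write a trained model as a human-readable key-value artifact
#'
#' Serialises `consensus_model`, `template3d_model` and `combined_model`
#' objects to a versioned plain-text file that [read_model()] restores
#' exactly.
#'
#' @param model a fitted model object.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  ln <- c(kv_line("format", MODEL_FORMAT_TAG),
          kv_line("class", class(model)[1L]))
  if (inherits(model, "consensus_model")) {
    cfg <- model$config
    ln <- c(ln,
            kv_line("mode", model$mode),
            kv_line("threshold", cfg$threshold),
            kv_line("binary_positive", cfg$binary_positive),
            kv_line("binary_negative", cfg$binary_negative),
            kv_line("native_threshold", cfg$native_threshold),
            kv_line("repair_max_run", cfg$repair_max_run),
            kv_line("repair_window", cfg$repair_window),
            kv_line("methods", model$weights$names),
            kv_line("method_weights", model$weights$values))
    if (!is.null(model$correction))
      ln <- c(ln,
              kv_line("factors_nterm", model$correction$factors_nterm),
              kv_line("factors_cterm", model$correction$factors_cterm))
  } else if (inherits(model, "template3d_model") ||
             inherits(model, "combined_model")) {
    th <- model$thresholds
    ln <- c(ln,
            kv_line("fitness_kind", model$fitness_kind),
            kv_line("threshold", model$threshold),
            kv_line("max_hits", model$max_hits),
            kv_line("genome_names", model$weights$names),
            kv_line("genome", model$weights$values),
            kv_line("tier_methods", th$method),
            kv_line("tier_good", th$good_cutoff),
            kv_line("tier_medium", th$medium_cutoff),
            kv_line("tier_direction", th$direction))
  } else stop("cannot serialise object of class ",
              paste(class(model), collapse = "/"))
  writeLines(ln, path)
  invisible(path)
}

#' Read a trained-model artifact
#'
#' @param path file written by [write_model()].
#' @return the restored model object.
#' @export
read_model <- function(path) {
  kv <- kv_parse(readLines(path))
  if (!identical(kv[["format"]], MODEL_FORMAT_TAG))
    stop("'", path, "' is not a ", MODEL_FORMAT_TAG, " artifact")
  cls <- kv[["class"]]
  if (cls == "consensus_model") {
    cfg <- consensus_config(mode = kv[["mode"]],
                            binary_positive = kv_num(kv, "binary_positive"),
                            binary_negative = kv_num(kv, "binary_negative"),
                            threshold = kv_num(kv, "threshold"),
                            repair_max_run = kv_num(kv, "repair_max_run"),
                            repair_window = kv_num(kv, "repair_window"),
                            native_threshold = kv_num(kv, "native_threshold"))
    corr <- if ("factors_nterm" %in% names(kv))
      terminal_correction(kv_num(kv, "factors_nterm"),
                          kv_num(kv, "factors_cterm"))
    else NULL
    w <- weight_vector(stats::setNames(kv_num(kv, "method_weights"),
                                       kv_chr(kv, "methods")),
                       kind = "consensus_method_weights")
    return(structure(list(weights = w, correction = corr, config = cfg,
                          mode = kv[["mode"]], calibration = NULL,
                          n_targets = NA_integer_, n_residues = NA_integer_),
                     class = "consensus_model"))
  }
  if (cls %in% c("template3d_model", "combined_model")) {
    th <- structure(data.frame(method = kv_chr(kv, "tier_methods"),
                               good_cutoff = kv_num(kv, "tier_good"),
                               medium_cutoff = kv_num(kv, "tier_medium"),
                               direction = kv_chr(kv, "tier_direction"),
                               stringsAsFactors = FALSE),
                    class = c("tier_thresholds", "data.frame"))
    g <- stats::setNames(kv_num(kv, "genome"), kv_chr(kv, "genome_names"))
    base <- list(threshold = kv_num(kv, "threshold"), thresholds = th,
                 fitness_kind = kv[["fitness_kind"]],
                 fitness_value = NA_real_, trace = NULL,
                 max_hits = as.integer(kv_num(kv, "max_hits")),
                 n_targets = NA_integer_)
    if (cls == "template3d_model") {
      base$weights <- weight_vector(g, kind = "tier24")
      return(structure(base, class = "template3d_model"))
    }
    base$weights <- weight_vector(g, kind = "tier24_plus_components")
    base$tier_weights <- weight_vector(unname(g[1:24]), kind = "tier24")
    base$component_weights <- c(a_consensus = unname(g[25L]),
                                b_template = unname(g[26L]))
    return(structure(base, class = "combined_model"))
  }
  stop("unknown model class '", cls, "' in '", path, "'")
}

#' Read a flat YAML configuration
#'
#' Recognised keys: `seed`, `mode`, `threshold`, `max_hits`, `fitness`,
#' `repair_max_run`, `repair_window`, GA parameters (`pop_size`,
#' `generations`, `p_crossover`, `p_mutation`, `mutation_sd`, `elitism`,
#' `tournament`) and `paths` (a named list of file paths).  Unknown keys are
#' an error.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(list())
  allowed <- c("seed", "mode", "threshold", "max_hits", "fitness",
               "repair_max_run", "repair_window", "pop_size", "generations",
               "p_crossover", "p_mutation", "mutation_sd", "elitism",
               "tournament", "paths")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra) > 0L)
    stop("unknown configuration keys in '", path, "': ",
         paste(extra, collapse = ", "))
  cfg
}
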