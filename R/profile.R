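#' Build a position-specific log-odds profile from a seed alignment
#'
#' Columns with more than 50% gap characters (`-` or `.`) are dropped; the
#' remaining match columns get per-residue natural-log odds scores from
#' pseudocounted column frequencies over a background composition:
#' `log_odds[c][a] = ln((count_ca + pc * bg_a) / (n_c + pc) / bg_a)` with
#' `n_c` the number of non-gap residues in column c. `X` scores 0 in every
#' column.
#'
#' @param seed_alignment character vector of equal-length aligned rows
#'   (gap characters `-` and `.`), or an `annotated_seqs` data frame whose
#'   `residues` hold the aligned rows.
#' @param pseudocount positive pseudocount mass (default 1).
#' @param background named residue frequency vector over [AMINO_ACIDS], or
#'   `"from-alignment"` to pool the observed non-gap residues (with a small
#'   floor so no frequency is zero). Default: Robinson-Robinson background.
#' @return A `profile_model`: list with `length`, `log_odds` (length x 21
#'   matrix, columns `c(AMINO_ACIDS, "X")`), `background`, and
#'   `score_threshold` (`NA` until calibrated).
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = aa_background()) {
  if (is.data.frame(seed_alignment)) seed_alignment <- seed_alignment$residues
  rows <- toupper(seed_alignment)
  if (length(rows) < 2) stop("seed alignment needs at least 2 rows", call. = FALSE)
  if (length(unique(nchar(rows))) != 1) {
    stop("ragged alignment: rows differ in length", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ok <- chars %in% c(AMINO_ACIDS, "X", "-", ".")
  if (!all(ok)) {
    stop("alphabet violation in seed alignment: ",
         paste(unique(chars[!ok]), collapse = ", "), call. = FALSE)
  }
  is_gap <- chars == "-" | chars == "."
  gap_frac <- colMeans(is_gap)
  keep <- which(gap_frac <= 0.5)
  if (!length(keep)) stop("no match columns after the 50% gap rule", call. = FALSE)

  if (identical(background, "from-alignment")) {
    pooled <- table(factor(chars[!is_gap & chars != "X"], levels = AMINO_ACIDS))
    bg <- as.numeric(pooled) + 0.01
    background <- setNames(bg / sum(bg), AMINO_ACIDS)
  }
  background <- background[AMINO_ACIDS]
  stopifnot(abs(sum(background) - 1) < 1e-6, all(background > 0))

  L <- length(keep)
  lo <- matrix(0, L, 21, dimnames = list(NULL, c(AMINO_ACIDS, "X")))
  for (i in seq_len(L)) {
    col <- chars[, keep[i]]
    col <- col[!(col %in% c("-", ".", "X"))]
    counts <- table(factor(col, levels = AMINO_ACIDS))
    n_eff <- length(col)
    freqs <- (as.numeric(counts) + pseudocount * background) /
      (n_eff + pseudocount)
    lo[i, AMINO_ACIDS] <- log(freqs / background)
  }
  structure(list(length = L, log_odds = lo, background = background,
                 pseudocount = pseudocount, score_threshold = NA_real_),
            class = "profile_model")
}

#' Consensus sequence of a profile (per-column maximal log-odds residue)
#' @param profile `profile_model`.
#' @return residue string of length `profile$length`.
#' @export
profile_consensus <- function(profile) {
  idx <- apply(profile$log_odds[, AMINO_ACIDS, drop = FALSE], 1, which.max)
  paste0(AMINO_ACIDS[idx], collapse = "")
}

# Run expr with a local RNG state seeded by `seed`; global .Random.seed
# is restored on exit.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Calibrate a profile hit threshold against an empirical null
#'
#' Draws `n_samples` random sequences i.i.d. from the profile's background
#' composition, records each one's best sliding-window score, and returns the
#' `1 - fpr` quantile of that null distribution. Deterministic given `seed`.
#'
#' @param profile `profile_model`.
#' @param n_samples number of null sequences (>= 1000).
#' @param fpr target per-sequence false-positive rate, in (0, 0.5).
#' @param seed RNG seed.
#' @param null_length length of each null sequence (default 500).
#' @return numeric score threshold.
#' @export
calibrate_threshold <- function(profile, n_samples = 1000, fpr = 1e-3,
                                seed = 1, null_length = 500) {
  if (fpr <= 0 || fpr >= 0.5) stop("fpr must lie in (0, 0.5)", call. = FALSE)
  if (n_samples < 1000) stop("n_samples must be >= 1000", call. = FALSE)
  bg <- profile$background
  best <- with_local_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      idx <- sample.int(20, null_length, replace = TRUE, prob = bg) - 1L
      max(profile_window_scores_cpp(idx, profile$log_odds))
    }, numeric(1))
  })
  unname(quantile(best, 1 - fpr))
}

#' @rdname calibrate_threshold
#' @description `calibrate_profile()` returns the profile with
#'   `score_threshold` set.
#' @export
calibrate_profile <- function(profile, n_samples = 1000, fpr = 1e-3,
                              seed = 1, null_length = 500) {
  profile$score_threshold <- calibrate_threshold(profile, n_samples, fpr,
                                                 seed, null_length)
  profile
}

#' Scan one sequence for domain hits
#'
#' Slides the profile over all windows, keeps windows scoring at or above the
#' calibrated threshold, and resolves overlaps best-first (ties on score
#' broken by smaller start). Coordinates are 0-based half-open.
#'
#' @param profile calibrated `profile_model`.
#' @param residues residue string (or one-row `annotated_seqs`).
#' @param seq_id identifier carried into the result.
#' @return data.frame with columns `seq_id`, `start`, `end`, `score`,
#'   sorted by `start`; zero rows when the sequence is shorter than the
#'   profile or nothing scores above threshold.
#' @export
scan_sequence <- function(profile, residues, seq_id = "") {
  if (is.data.frame(residues)) {
    seq_id <- residues$seq_id[1]
    residues <- residues$residues[1]
  }
  if (is.na(profile$score_threshold)) {
    stop("profile is not calibrated; run calibrate_profile() first", call. = FALSE)
  }
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0))
  idx <- aa_encode(residues, seq_id)
  scores <- profile_window_scores_cpp(idx, profile$log_odds)
  cand <- which(scores >= profile$score_threshold)
  if (!length(cand)) return(empty)
  ord <- cand[order(-scores[cand], cand)]
  L <- profile$length
  accepted <- integer(0)
  for (w in ord) {
    if (!any(abs(accepted - w) < L)) accepted <- c(accepted, w)
  }
  accepted <- sort(accepted)
  data.frame(seq_id = seq_id, start = accepted - 1L,
             end = accepted - 1L + L, score = scores[accepted])
}

#' Scan many sequences
#' @param profile calibrated `profile_model`.
#' @param seqs `annotated_seqs` data frame.
#' @return one combined hit data.frame (see [scan_sequence()]).
#' @export
scan_sequences <- function(profile, seqs) {
  hits <- lapply(seq_len(nrow(seqs)), function(i) {
    scan_sequence(profile, seqs$residues[i], seqs$seq_id[i])
  })
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

#' Exclude sequences with multiple homeodomains
#'
#' Sequences with two or more domain hits are removed (the mis-annotation /
#' concatenation filter); sequences with zero or one hit are kept. Zero-hit
#' sequences are retained but flagged via the `n_domain_hits` column, since a
#' candidate set that came from a domain search should not contain them.
#'
#' @param seqs `annotated_seqs` data frame.
#' @param profile calibrated `profile_model`.
#' @return list with `kept` and `removed` `annotated_seqs` data frames, both
#'   carrying an `n_domain_hits` column; `kept` and `removed` partition the
#'   input.
#' @export
filter_multidomain <- function(seqs, profile) {
  if (nrow(seqs) == 0) return(list(kept = seqs, removed = seqs))
  hits <- scan_sequences(profile, seqs)
  n_hits <- vapply(seqs$seq_id, function(id) sum(hits$seq_id == id), integer(1))
  seqs$n_domain_hits <- unname(n_hits)
  list(kept = seqs[n_hits <= 1, , drop = FALSE],
       removed = seqs[n_hits >= 2, , drop = FALSE])
}

#' Write a domain hit table as TSV (1-based closed coordinates)
#'
#' Internal coordinates are 0-based half-open; the TSV reports
#' `start_1based = start + 1` and `end_1based = end`, so the round trip back
#' to internal coordinates is exact.
#'
#' @param hits hit data.frame from [scan_sequences()].
#' @param path output path.
#' @return `path` (write) or the internal-coordinate hits (read), invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(seq_id = hits$seq_id,
                    start_1based = hits$start + 1L,
                    end_1based = hits$end,
                    score = sprintf("%.17g", hits$score))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer", "integer", "numeric"))
  data.frame(seq_id = df$seq_id, start = df$start_1based - 1L,
             end = df$end_1based, score = df$score)
}
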