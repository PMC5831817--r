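#' Global-alignment percent identity between two protein sequences
#'
#' Identity is matches / alignment length of a global alignment scored with
#' match = 1, mismatch = 0 and a simple linear gap cost (default 1 per gap
#' column), with a deterministic traceback.
#'
#' @param a,b residue strings.
#' @param gap_cost linear per-column gap penalty.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, gap_cost = 1) {
  res <- nw_identity_cpp(aa_encode(a), aa_encode(b), gap_cost)
  res[1] / res[2]
}

#' Greedy redundancy clustering (CD-hit style)
#'
#' Sequences are visited longest-first (ties on length broken by lexicographic
#' `seq_id`); each joins the first previously accepted representative whose
#' global pairwise identity is at least `identity_threshold`, otherwise it
#' becomes a new representative. Deterministic given the tie rule.
#'
#' @param seqs `annotated_seqs` data frame.
#' @param identity_threshold fraction in (0.5, 1].
#' @return A `redundancy_map`: list with `representative_of` (named character
#'   vector, member id -> representative id; representatives map to
#'   themselves) and `identity_threshold`.
#' @export
cluster_redundant <- function(seqs, identity_threshold = 0.95) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1)
  ord <- order(-nchar(seqs$residues), seqs$seq_id, method = "radix")
  ids <- seqs$seq_id[ord]
  residues <- seqs$residues[ord]
  reps <- character(0)
  rep_res <- character(0)
  rep_of <- setNames(character(length(ids)), ids)
  for (k in seq_along(ids)) {
    assigned <- NA_character_
    for (r in seq_along(reps)) {
      if (pairwise_identity(residues[k], rep_res[r]) >= identity_threshold) {
        assigned <- reps[r]
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, ids[k])
      rep_res <- c(rep_res, residues[k])
      assigned <- ids[k]
    }
    rep_of[ids[k]] <- assigned
  }
  structure(list(representative_of = rep_of,
                 identity_threshold = identity_threshold),
            class = "redundancy_map")
}

#' Representatives of a redundancy map
#' @param map `redundancy_map`.
#' @return character vector of representative seq_ids.
#' @export
representatives <- function(map) {
  unique(unname(map$representative_of))
}

#' Re-inflate a filtered set of representatives back to all members
#'
#' Reverses the redundancy clustering: every sequence whose representative is
#' in `kept` is returned (including the representatives themselves).
#'
#' @param kept character vector of representative seq_ids to keep.
#' @param map `redundancy_map` built from `all_seqs`.
#' @param all_seqs the full `annotated_seqs` data frame the map was built from.
#' @return `annotated_seqs` subset, in `all_seqs` order.
#' @export
reinflate <- function(kept, map, all_seqs) {
  reps <- representatives(map)
  bad <- setdiff(kept, reps)
  if (length(bad)) {
    stop("not representative(s) in the redundancy map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  members <- names(map$representative_of)[map$representative_of %in% kept]
  out <- all_seqs[all_seqs$seq_id %in% members, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a redundancy map as two-column TSV (member, representative)
#' @param map `redundancy_map`.
#' @param path file path.
#' @return `path` (write) or a `redundancy_map` (read).
#' @export
write_redundancy_tsv <- function(map, path) {
  df <- data.frame(member = names(map$representative_of),
                   representative = unname(map$representative_of))
  hdr <- sprintf("# identity_threshold=%.17g", map$identity_threshold)
  writeLines(c(hdr, paste(df$member, df$representative, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_redundancy_tsv
#' @export
read_redundancy_tsv <- function(path) {
  lines <- readLines(path)
  thr <- as.numeric(sub("# identity_threshold=", "", lines[1], fixed = TRUE))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  rep_of <- setNames(vapply(body, `[`, "", 2), vapply(body, `[`, "", 1))
  structure(list(representative_of = rep_of, identity_threshold = thr),
            class = "redundancy_map")
}
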