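#' Scoring scheme for local alignment and E-value statistics
#'
#' Bundles the substitution matrix, affine gap penalties (a gap of length k
#' costs `gap_open + k * gap_extend`) and the Karlin-Altschul parameters used
#' to convert raw scores to E-values. Defaults mirror common BLASTP settings:
#' BLOSUM62, gap open 11, gap extend 1, and the gapped-scheme constants
#' lambda = 0.267, K = 0.041. The constants are fixed per scheme, not
#' estimated per query; E-values are used comparatively throughout.
#'
#' @param matrix symmetric substitution matrix over `c(AMINO_ACIDS, "X")`.
#' @param gap_open,gap_extend positive integers, `gap_open >= gap_extend >= 1`.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(matrix = blosum62(), gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(isSymmetric(unname(matrix)), gap_open >= gap_extend,
            gap_extend >= 1, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Smith-Waterman local alignment score
#'
#' Exact maximal local alignment score under affine gaps (Gotoh recursion);
#' no heuristics, so the score is symmetric and deterministic. `X` scores 0
#' against every residue; any other non-standard code is an error.
#'
#' @param a,b residue strings (non-empty).
#' @param scheme `scoring_scheme`.
#' @return non-negative raw score.
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(nzchar(a), nzchar(b))
  sw_score_cpp(aa_encode(a), aa_encode(b), scheme$matrix,
               scheme$gap_open, scheme$gap_extend)
}

# E-value floor: keeps E strictly positive and -log10(E) finite for
# near-identical long sequences whose exp(-lambda*S) underflows.
EVALUE_FLOOR <- 1e-300

#' Karlin-Altschul E-value for a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`, computed in log space and floored at
#' 1e-300 so it stays a positive double. Monotone decreasing in S, monotone
#' increasing in `m * n`.
#'
#' @param S raw score (>= 0).
#' @param m,n query and subject lengths.
#' @param scheme `scoring_scheme`.
#' @return positive E-value.
#' @export
evalue <- function(S, m, n, scheme = scoring_scheme()) {
  stopifnot(all(S >= 0), m > 0, n > 0)
  log_e <- log(scheme$K) + log(m) + log(n) - scheme$lambda * S
  pmax(exp(log_e), EVALUE_FLOOR)
}

#' All-against-all directed local-alignment hits
#'
#' Computes the exact Smith-Waterman score for every unordered sequence pair
#' once (scores are symmetric) and reports one directed hit per ordered pair
#' whose E-value is at or below `report_cutoff`. Self-hits are excluded. The
#' permissive default report cutoff (1e-2) means later cutoff tightening
#' never requires re-alignment.
#'
#' @param seqs `annotated_seqs` data frame with >= 2 rows and unique ids.
#' @param scheme `scoring_scheme`.
#' @param report_cutoff E-value reporting threshold.
#' @return data.frame of directed hits: `query_id`, `subject_id`, `score`,
#'   `evalue`.
#' @export
all_against_all <- function(seqs, scheme = scoring_scheme(),
                            report_cutoff = 1e-2) {
  if (nrow(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (anyDuplicated(seqs$seq_id)) stop("duplicate seq_ids", call. = FALSE)
  ids <- seqs$seq_id
  enc <- lapply(seqs$residues, aa_encode)
  lens <- nchar(seqs$residues)
  n <- length(ids)
  res_q <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- sw_score_cpp(enc[[i]], enc[[j]], scheme$matrix,
                        scheme$gap_open, scheme$gap_extend)
      E <- evalue(S, lens[i], lens[j], scheme)
      if (E <= report_cutoff) {
        k <- k + 1L
        res_q[[k]] <- data.frame(query_id = c(ids[i], ids[j]),
                                 subject_id = c(ids[j], ids[i]),
                                 score = S, evalue = E)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), evalue = numeric(0)))
  }
  do.call(rbind, c(res_q[seq_len(k)], list(make.row.names = FALSE)))
}

#' Symmetric similarity edges from directed hits
#'
#' An unordered pair becomes an edge when at least one direction has
#' `E <= cutoff` (the comparison is inclusive); the symmetric attraction
#' weight is the mean of `-log10(E)` over the directions present in the hit
#' list. Output is sorted by `(id_a, id_b)`.
#'
#' @param hits directed hit data.frame from [all_against_all()] (whose
#'   `report_cutoff` must be >= `cutoff`).
#' @param cutoff E-value cutoff for edge materialisation.
#' @return data.frame of edges: `id_a`, `id_b` (with `id_a < id_b`),
#'   `evalue_ab`, `evalue_ba` (`NA` when that direction is absent), `weight`.
#' @export
build_edges <- function(hits, cutoff) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      evalue_ab = numeric(0), evalue_ba = numeric(0),
                      weight = numeric(0))
  if (nrow(hits) == 0) return(empty)
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  key <- paste(a, b, sep = "\r")
  rows <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    ia <- idx[hits$query_id[idx] == a[idx[1]]]
    ib <- idx[hits$query_id[idx] == b[idx[1]]]
    e_ab <- if (length(ia)) hits$evalue[ia[1]] else NA_real_
    e_ba <- if (length(ib)) hits$evalue[ib[1]] else NA_real_
    present <- c(e_ab, e_ba)
    present <- present[!is.na(present)]
    if (!any(present <= cutoff)) return(NULL)
    data.frame(id_a = a[idx[1]], id_b = b[idx[1]], evalue_ab = e_ab,
               evalue_ba = e_ba, weight = mean(-log10(present)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$id_a, out$id_b), , drop = FALSE]
}
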