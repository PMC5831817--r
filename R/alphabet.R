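#' @title Amino-acid alphabet helpers
#' @description The 20 canonical residues, ordered as in BLOSUM62; `X` is
#'   accepted as an unknown residue and scores 0 against everything.
#' @name alphabet
NULL

#' The 20 canonical amino acids (one-letter codes)
#' @export
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson & Robinson (1991) background amino-acid frequencies, the
# composition HMMER and BLAST use as a protein null model.
AA_BACKGROUND <- c(
  A = 0.078047, R = 0.051269, N = 0.044873, D = 0.053640, C = 0.019246,
  Q = 0.042644, E = 0.062949, G = 0.073772, H = 0.021992, I = 0.051420,
  L = 0.090191, K = 0.057438, M = 0.022425, F = 0.038556, P = 0.052028,
  S = 0.071198, T = 0.058413, W = 0.013298, Y = 0.032165, V = 0.064409)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

#' Background amino-acid frequencies
#'
#' Robinson-Robinson residue frequencies over the 20 canonical amino acids,
#' normalised to sum to 1 and ordered as [AMINO_ACIDS].
#'
#' @return Named numeric vector of length 20.
#' @export
aa_background <- function() {
  AA_BACKGROUND[AMINO_ACIDS]
}

# Map residues to 0-based indices (0..19, X -> 20); errors on anything else.
aa_encode <- function(residues, what = "sequence") {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, c(AMINO_ACIDS, "X")) - 1L
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(sprintf("unknown residue code(s) %s in %s",
                 paste0("'", bad, "'", collapse = ", "), what), call. = FALSE)
  }
  idx
}

aa_decode <- function(idx) {
  paste0(c(AMINO_ACIDS, "X")[idx + 1L], collapse = "")
}

check_residues <- function(residues, id = "sequence") {
  invisible(aa_encode(residues, what = id))
}

#' BLOSUM62 substitution matrix over the 20 amino acids plus X
#'
#' The standard BLOSUM62 scores (taken from the matrix shipped with
#' Biostrings), restricted to the 20 canonical residues and augmented with an
#' `X` row/column that scores 0 against everything, the convention used by
#' the alignment routines here.
#'
#' @return 21 x 21 integer matrix with dimnames `c(AMINO_ACIDS, "X")`.
#' @export
blosum62 <- function() {
  b <- get_blosum62_cache()
  b
}

.pkg_cache <- new.env(parent = emptyenv())

get_blosum62_cache <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    full <- e$BLOSUM62
    m <- matrix(0, 21, 21, dimnames = list(c(AMINO_ACIDS, "X"), c(AMINO_ACIDS, "X")))
    m[AMINO_ACIDS, AMINO_ACIDS] <- full[AMINO_ACIDS, AMINO_ACIDS]
    .pkg_cache$blosum62 <- m
  }
  .pkg_cache$blosum62
}
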