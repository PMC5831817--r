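#' Construct a set of annotated protein sequences
#'
#' The central sequence container is a plain data frame with one row per
#' protein and columns `seq_id`, `residues`, `common_name`, `species` (and,
#' once [annotate_groups()] has run, `group_category` and `group_name`).
#' Identifiers must be unique, residues non-empty and uppercase over the
#' 20-letter amino-acid alphabet (`X` allowed).
#'
#' @param seq_id character vector of unique identifiers.
#' @param residues character vector of protein sequences.
#' @param common_name,species optional annotation vectors (recycled "" if
#'   missing).
#' @return A `data.frame` of class `annotated_seqs`.
#' @export
annotated_seqs <- function(seq_id, residues, common_name = "", species = "") {
  n <- length(seq_id)
  df <- data.frame(seq_id = as.character(seq_id),
                   residues = toupper(as.character(residues)),
                   common_name = rep_len(as.character(common_name), n),
                   species = rep_len(as.character(species), n),
                   stringsAsFactors = FALSE)
  validate_seqs(df)
  class(df) <- c("annotated_seqs", "data.frame")
  df
}

validate_seqs <- function(df) {
  if (anyDuplicated(df$seq_id)) {
    stop("duplicate seq_ids: ",
         paste(unique(df$seq_id[duplicated(df$seq_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$residues))) {
    stop("empty sequence for id(s): ",
         paste(df$seq_id[!nzchar(df$residues)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(df))) check_residues(df$residues[i], df$seq_id[i])
  invisible(df)
}

# Header convention: "id|common_name|species"; fields after the first optional.
parse_fasta_header <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  list(seq_id = if (length(parts) >= 1) trimws(parts[1]) else "",
       common_name = if (length(parts) >= 2) trimws(parts[2]) else "",
       species = if (length(parts) >= 3) trimws(parts[3]) else "")
}

#' Read annotated protein sequences from FASTA
#'
#' Headers follow the `id|common_name|species` convention with `|` as the
#' delimiter; fields after the identifier are optional. Record order is
#' preserved.
#'
#' @param path FASTA file path.
#' @return An `annotated_seqs` data frame (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(annotated_seqs(character(0), character(0)))
  }
  set <- Biostrings::readAAStringSet(path)
  widths <- Biostrings::width(set)
  if (any(widths == 0)) {
    bad <- names(set)[widths == 0][1]
    lines <- readLines(path, warn = FALSE)
    at <- which(lines == paste0(">", bad))
    stop(sprintf("malformed FASTA: empty sequence for record '%s'%s", bad,
                 if (length(at)) sprintf(" (line %d)", at[1]) else ""),
         call. = FALSE)
  }
  meta <- lapply(names(set), parse_fasta_header)
  annotated_seqs(seq_id = vapply(meta, `[[`, "", "seq_id"),
                 residues = as.character(set),
                 common_name = vapply(meta, `[[`, "", "common_name"),
                 species = vapply(meta, `[[`, "", "species"))
}

#' Write annotated sequences to FASTA
#'
#' The inverse of [read_fasta()]: headers are `id|common_name|species` when
#' either annotation field is non-empty, bare `id` otherwise, so that a
#' write/read round trip preserves sequence content and parsed annotations.
#'
#' @param seqs `annotated_seqs` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  headers <- ifelse(nzchar(seqs$common_name) | nzchar(seqs$species),
                    paste(seqs$seq_id, seqs$common_name, seqs$species, sep = "|"),
                    seqs$seq_id)
  set <- Biostrings::AAStringSet(setNames(seqs$residues, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write the annotation table as TSV
#'
#' Columns: seq_id, common_name, species, canonical group category and name
#' (computed with [canonical_group()] if not already present).
#'
#' @param seqs `annotated_seqs` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(seqs, path) {
  if (is.null(seqs$group_category)) seqs <- annotate_groups(seqs)
  out <- seqs[, c("seq_id", "common_name", "species",
                  "group_category", "group_name")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach canonical group labels to a sequence table
#'
#' Maps each sequence's `common_name` through the Hox/ParaHox synonym table
#' (see [canonical_group()]) into `group_category`
#' (HOX/PARAHOX/OTHER) and `group_name` columns.
#'
#' @param seqs `annotated_seqs` data frame.
#' @return The same data frame with group columns added.
#' @export
annotate_groups <- function(seqs) {
  labs <- lapply(seqs$common_name, canonical_group)
  seqs$group_category <- vapply(labs, `[[`, "", "category")
  seqs$group_name <- vapply(labs, `[[`, "", "name")
  seqs
}
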