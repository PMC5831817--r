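# Shared hand-built fixtures.

# one row per direction of an unordered pair, with chosen E-values
dir_hits <- function(a, b, e_ab, e_ba = e_ab) {
  data.frame(query_id = c(a, b), subject_id = c(b, a),
             score = NA_real_, evalue = c(e_ab, e_ba))
}

# three fully-connected groups with no between-group edges
three_clique_graph <- function(per_group = 5, w_intra = 1e-50) {
  ids <- paste0(rep(c("A", "B", "C"), each = per_group), seq_len(per_group))
  seqs <- annotated_seqs(ids, strrep("M", 30))
  hits <- list()
  for (g in c("A", "B", "C")) {
    members <- ids[startsWith(ids, g)]
    for (i in seq_along(members)[-length(members)]) {
      for (j in (i + 1):length(members)) {
        hits[[length(hits) + 1L]] <- dir_hits(members[i], members[j], w_intra)
      }
    }
  }
  similarity_graph(seqs, do.call(rbind, hits), cutoff = 1e-10)
}
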