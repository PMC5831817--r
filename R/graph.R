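#' Build a thresholded similarity graph
#'
#' Nodes are the input sequences; edges come from [build_edges()] applied to
#' the directed hits at `cutoff`. The hit list is retained inside the graph
#' so cutoffs can later be tightened without re-alignment.
#'
#' @param seqs `annotated_seqs` data frame (graph nodes).
#' @param hits directed hits from [all_against_all()].
#' @param cutoff E-value cutoff at which the edge set is materialised.
#' @return A `similarity_graph`: list with `nodes`, `hits`, `edges`, `cutoff`.
#' @export
similarity_graph <- function(seqs, hits, cutoff) {
  known <- hits$query_id %in% seqs$seq_id & hits$subject_id %in% seqs$seq_id
  hits <- hits[known & hits$query_id != hits$subject_id, , drop = FALSE]
  structure(list(nodes = seqs, hits = hits,
                 edges = build_edges(hits, cutoff), cutoff = cutoff),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d edges at E-value cutoff %g\n",
              nrow(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Tighten the E-value cutoff of a similarity graph
#'
#' Re-materialises the edge set at a more stringent cutoff from the stored
#' hits; nodes are unchanged, so isolated nodes remain in the graph.
#' Loosening beyond the graph's cutoff is an error (it would require
#' re-alignment at a higher report cutoff).
#'
#' @param graph `similarity_graph`.
#' @param new_cutoff E-value, `<= graph$cutoff`.
#' @return a `similarity_graph` at the new cutoff.
#' @export
apply_cutoff <- function(graph, new_cutoff) {
  if (new_cutoff > graph$cutoff) {
    stop(sprintf(paste0("cannot loosen cutoff from %g to %g without ",
                        "re-alignment"), graph$cutoff, new_cutoff),
         call. = FALSE)
  }
  graph$edges <- build_edges(graph$hits, new_cutoff)
  graph$cutoff <- new_cutoff
  graph
}

as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(graph$nodes), name = graph$nodes$seq_id)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(graph$edges$id_a, graph$edges$id_b),
                           weight = graph$edges$weight)
  }
  g
}

#' Connected components of the similarity graph
#'
#' Standard undirected connectivity; components are sorted by decreasing
#' size, ties broken by their lexicographically smallest member.
#'
#' @param graph `similarity_graph`.
#' @return list of character vectors of seq_ids (each sorted).
#' @export
connected_components <- function(graph) {
  comp <- igraph::components(as_igraph(graph))
  sets <- split(graph$nodes$seq_id, comp$membership)
  sets <- lapply(sets, sort)
  smallest <- vapply(sets, `[`, "", 1)
  ord <- order(-vapply(sets, length, integer(1)), smallest)
  unname(sets[ord])
}

#' Select all clusters containing at least one seed sequence
#'
#' The generous family-retrieval step: the union of every connected
#' component that intersects the seed set.
#'
#' @param components list of components from [connected_components()].
#' @param seed_ids non-empty character vector of seed seq_ids.
#' @return character vector of selected seq_ids (sorted).
#' @export
select_seed_clusters <- function(components, seed_ids) {
  if (!length(seed_ids)) stop("empty seed set", call. = FALSE)
  hit <- vapply(components, function(cc) any(seed_ids %in% cc), logical(1))
  sort(unique(unlist(components[hit])))
}
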