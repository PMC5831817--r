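#' Group-to-group connectivity statistics
#'
#' Quantifies the visual cues of the similarity map — number of connections
#' and darkness of the lines — for every (ParaHox group, Hox group) pair at a
#' given E-value cutoff. For groups A and B: `edge_count` edges between them,
#' `possible_pairs = |A| * |B|`, `density = edge_count / possible_pairs`,
#' `mean_weight` over existing edges (`NA` when there are none), and the
#' primary statistic `score = sum(weights) / possible_pairs`
#' (density-weighted weight mass per possible pair). OTHER-labelled nodes are
#' excluded from all pair counts; groups with no members are simply absent
#' from the table.
#'
#' @param graph `similarity_graph`.
#' @param labels data.frame with columns `seq_id`, `group_category`,
#'   `group_name`; defaults to the graph's node annotations (computed from
#'   common names if needed), with Hox paralog groups collapsed to the
#'   PG1/PG2/PG3/central/posterior classes.
#' @param cutoff E-value cutoff at which to compute the statistics (the graph
#'   is tightened with [apply_cutoff()]); default: the graph's cutoff.
#' @param collapse collapse PG4-8 to central and PG9-13 to posterior first?
#' @return data.frame of class `group_connectivity` with one row per
#'   (parahox_group, hox_group) pair present in the graph.
#' @export
connectivity <- function(graph, labels = NULL, cutoff = graph$cutoff,
                         collapse = TRUE) {
  labels <- resolve_labels(graph, labels, collapse)
  g <- apply_cutoff(graph, cutoff)
  lab_of <- setNames(labels$group_name, labels$seq_id)
  cat_of <- setNames(labels$group_category, labels$seq_id)
  ph_groups <- sort(unique(labels$group_name[labels$group_category == "PARAHOX"]))
  hox_groups <- sort(unique(labels$group_name[labels$group_category == "HOX"]))
  e <- g$edges
  ga <- lab_of[e$id_a]
  gb <- lab_of[e$id_b]
  rows <- list()
  for (p in ph_groups) {
    np <- sum(labels$group_category == "PARAHOX" & labels$group_name == p)
    for (h in hox_groups) {
      nh <- sum(labels$group_category == "HOX" & labels$group_name == h)
      between <- (ga == p & gb == h) | (ga == h & gb == p)
      between[is.na(between)] <- FALSE
      w <- e$weight[between]
      rows[[length(rows) + 1L]] <- data.frame(
        parahox_group = p, hox_group = h, cutoff = cutoff,
        edge_count = length(w), possible_pairs = np * nh,
        density = length(w) / (np * nh),
        mean_weight = if (length(w)) mean(w) else NA_real_,
        score = sum(w) / (np * nh))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("group_connectivity", "data.frame")
  out
}

resolve_labels <- function(graph, labels, collapse) {
  if (is.null(labels)) {
    nodes <- graph$nodes
    if (is.null(nodes$group_name)) nodes <- annotate_groups(nodes)
    labels <- nodes[, c("seq_id", "group_category", "group_name")]
  }
  if (collapse) {
    hx <- labels$group_category == "HOX"
    labels$group_name[hx] <- collapse_hox_class(labels$group_name[hx])
  }
  labels[labels$group_category != "OTHER", , drop = FALSE]
}

#' Rank Hox groups for one ParaHox group, with tie detection
#'
#' Hox groups are sorted by descending `score`; walking down the ranking, a
#' group joins the previous tie set when its score is within `tie_margin`
#' (relative) of the preceding score, otherwise it starts a new tie set.
#' Deterministic: equal scores are ordered by group name.
#'
#' @param conn `group_connectivity` table from [connectivity()].
#' @param parahox ParaHox group name present in `conn`.
#' @param tie_margin relative margin (default 0.10) under which adjacent
#'   scores are considered indistinguishable.
#' @return data.frame with `hox_group`, `score`, `density`, `mean_weight`,
#'   `rank` and `tie_set` (tie set 1 holds the top-ranked, possibly tied,
#'   groups).
#' @export
rank_hox <- function(conn, parahox, tie_margin = 0.10) {
  sub <- conn[conn$parahox_group == parahox, , drop = FALSE]
  if (!nrow(sub)) {
    stop("no connectivity rows for ParaHox group: ", parahox, call. = FALSE)
  }
  sub <- sub[order(-sub$score, sub$hox_group), , drop = FALSE]
  tie_set <- integer(nrow(sub))
  tie_set[1] <- 1L
  for (i in seq_len(nrow(sub))[-1]) {
    same <- sub$score[i] >= (1 - tie_margin) * sub$score[i - 1] &&
      sub$score[i - 1] > 0
    tie_set[i] <- if (same) tie_set[i - 1] else tie_set[i - 1] + 1L
  }
  data.frame(hox_group = sub$hox_group, score = sub$score,
             density = sub$density, mean_weight = sub$mean_weight,
             rank = seq_len(nrow(sub)), tie_set = tie_set)
}

#' Top tie set of a ranking
#' @param ranking data.frame from [rank_hox()].
#' @return character vector of Hox groups in tie set 1 (sorted).
#' @export
top_group <- function(ranking) {
  sort(ranking$hox_group[ranking$tie_set == 1L])
}

#' Full ParaHox-to-Hox assignment report
#'
#' For each analysis cutoff (defaults 1e-33 and 1e-40, in decreasing
#' stringency order of exploration) computes the connectivity table and
#' per-ParaHox-group rankings; adds sequence-divergence ranks (per-group mean
#' distance from the map centre) and provenance. A non-converged layout is
#' recorded as a warning in the report, but distances are still reported.
#'
#' @param graph `similarity_graph` built at a report-level cutoff at least as
#'   permissive as every analysis cutoff.
#' @param labels label data.frame (see [connectivity()]) or `NULL`.
#' @param cutoffs non-empty numeric vector of analysis E-value cutoffs.
#' @param layout optional `layout_state` for the divergence ranking.
#' @param tie_margin relative tie margin passed to [rank_hox()].
#' @return An `assignment_report`: list with `rankings` (per cutoff, per
#'   ParaHox group), `connectivity` (combined table), `divergence`,
#'   `warnings`, `provenance`.
#' @export
assignment_report <- function(graph, labels = NULL,
                              cutoffs = c(1e-33, 1e-40), layout = NULL,
                              tie_margin = 0.10) {
  if (!length(cutoffs)) stop("empty cutoff list", call. = FALSE)
  warns <- character(0)
  labels_res <- resolve_labels(graph, labels, collapse = TRUE)
  conn_all <- list()
  rankings <- list()
  for (cf in cutoffs) {
    conn <- connectivity(graph, labels, cutoff = cf)
    conn_all[[length(conn_all) + 1L]] <- conn
    per_ph <- lapply(sort(unique(conn$parahox_group)), function(p) {
      rank_hox(conn, p, tie_margin)
    })
    names(per_ph) <- sort(unique(conn$parahox_group))
    rankings[[sprintf("%g", cf)]] <- per_ph
  }
  divergence <- NULL
  if (!is.null(layout)) {
    if (!isTRUE(layout$converged)) {
      warns <- c(warns, "layout did not converge; distances reported anyway")
    }
    grp <- setNames(labels_res$group_name, labels_res$seq_id)
    divergence <- center_distance(layout, grp)
  }
  structure(list(
    rankings = rankings,
    connectivity = do.call(rbind, conn_all),
    divergence = divergence,
    warnings = warns,
    provenance = list(cutoffs = cutoffs, tie_margin = tie_margin,
                      graph_cutoff = graph$cutoff,
                      layout_seed = if (!is.null(layout)) layout$rng_seed,
                      edge_weight = "mean of -log10(E) over present directions")),
    class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  for (cf in names(x$rankings)) {
    cat(sprintf("E-value cutoff %s:\n", cf))
    for (p in names(x$rankings[[cf]])) {
      r <- x$rankings[[cf]][[p]]
      top <- top_group(r)
      tag <- if (length(top) > 1) sprintf("tie {%s}", paste(top, collapse = ", "))
             else top
      cat(sprintf("  %s -> %s\n", p, tag))
    }
  }
  if (!is.null(x$divergence)) {
    cat("divergence (distance from map centre), most divergent first: ",
        paste(x$divergence$group, collapse = " > "), "\n", sep = "")
  }
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Serialize an assignment report
#'
#' Writes the connectivity matrix as TSV and a human-readable Markdown
#' summary (rankings with tie sets, divergence ranks, provenance; the tie
#' criterion is this package's formalisation of "roughly equal in number and
#' quality" and is labelled as such).
#'
#' @param report `assignment_report`.
#' @param tsv_path,md_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_assignment_report <- function(report, tsv_path = NULL, md_path = NULL) {
  if (!is.null(tsv_path)) {
    tab <- report$connectivity
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(md_path)) {
    lines <- c("# ParaHox-to-Hox assignment report", "")
    for (cf in names(report$rankings)) {
      lines <- c(lines, sprintf("## E-value cutoff %s", cf), "")
      for (p in names(report$rankings[[cf]])) {
        r <- report$rankings[[cf]][[p]]
        top <- top_group(r)
        lines <- c(lines, sprintf(
          "- **%s** -> %s%s", p, paste(top, collapse = " / "),
          if (length(top) > 1) " (tie)" else ""))
        lines <- c(lines, sprintf(
          "    - %s", paste(sprintf("%s: score %.3g (tie set %d)",
                                    r$hox_group, r$score, r$tie_set),
                            collapse = "; ")))
      }
      lines <- c(lines, "")
    }
    if (!is.null(report$divergence)) {
      lines <- c(lines, "## Divergence (mean distance from map centre)", "",
                 sprintf("%d. %s (%.4g)", report$divergence$rank,
                         report$divergence$group,
                         report$divergence$mean_center_distance), "")
    }
    lines <- c(lines,
               "## Provenance", "",
               sprintf("- analysis cutoffs: %s",
                       paste(sprintf("%g", report$provenance$cutoffs),
                             collapse = ", ")),
               sprintf("- tie margin (relative): %g  (this package's formal tie criterion)",
                       report$provenance$tie_margin),
               sprintf("- edge weight: %s", report$provenance$edge_weight))
    for (w in report$warnings) lines <- c(lines, sprintf("- warning: %s", w))
    writeLines(lines, md_path)
  }
  invisible(c(tsv = tsv_path, md = md_path))
}
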