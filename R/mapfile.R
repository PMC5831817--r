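#' Write a similarity map file
#'
#' Plain-text, human-diffable map dialect with CLANS-like sections: a
#' parameter header, a `<seq>` block (FASTA-like, headers as in
#' [write_fasta()]), a `<pos>` block (one line per node:
#' `index x y [z]`, 0-based indices) and an `<hsp>` block
#' (`index_a index_b:evalue_ab;evalue_ba`). All numbers are printed with
#' `%.17g`, so a write/read round trip is bit-exact on coordinates and
#' E-values.
#'
#' @param graph `similarity_graph`.
#' @param layout `layout_state` over the same nodes, or `NULL` to omit
#'   coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(graph, layout, path) {
  g <- function(x) sprintf("%.17g", x)
  nodes <- graph$nodes
  idx <- setNames(seq_len(nrow(nodes)) - 1L, nodes$seq_id)
  lines <- c("# parahoxmap map v1", "<param>",
             paste0("cutoff=", g(graph$cutoff)))
  if (!is.null(layout)) {
    stopifnot(identical(sort(rownames(layout$coords)), sort(nodes$seq_id)))
    lines <- c(lines,
               paste0("dims=", layout$dims),
               paste0("rng_seed=", g(layout$rng_seed)),
               paste0("iterations_run=", layout$iterations_run),
               paste0("converged=", layout$converged))
  }
  lines <- c(lines, "</param>", "<seq>")
  headers <- ifelse(nzchar(nodes$common_name) | nzchar(nodes$species),
                    paste(nodes$seq_id, nodes$common_name, nodes$species,
                          sep = "|"),
                    nodes$seq_id)
  lines <- c(lines, rbind(paste0(">", headers), nodes$residues), "</seq>")
  if (!is.null(layout)) {
    coords <- layout$coords[nodes$seq_id, , drop = FALSE]
    lines <- c(lines, "<pos>",
               paste(seq_len(nrow(nodes)) - 1L,
                     apply(coords, 1, function(r) paste(g(r), collapse = " "))),
               "</pos>")
  }
  lines <- c(lines, "<hsp>")
  if (nrow(graph$edges)) {
    e <- graph$edges
    fmt_e <- function(x) ifelse(is.na(x), "NA", g(x))
    lines <- c(lines, paste0(idx[e$id_a], " ", idx[e$id_b], ":",
                             fmt_e(e$evalue_ab), ";", fmt_e(e$evalue_ba)))
  }
  lines <- c(lines, "</hsp>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a similarity map file
#'
#' Inverse of [write_map()]; unknown section tags raise a parse error naming
#' the offending line.
#'
#' @param path map file path.
#' @return list with `graph` (a `similarity_graph`; its `hits` are rebuilt
#'   from the stored directional E-values, with `NA` scores) and `layout`
#'   (a `layout_state`, or `NULL` when the file has no `<pos>` block).
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  known <- c("<param>", "</param>", "<seq>", "</seq>", "<pos>", "</pos>",
             "<hsp>", "</hsp>")
  tags <- grep("^</?[a-z]+>$", lines)
  bad <- tags[!(lines[tags] %in% known)]
  if (length(bad)) {
    stop(sprintf("unknown section tag '%s' at line %d", lines[bad[1]], bad[1]),
         call. = FALSE)
  }
  section <- function(tag) {
    open <- which(lines == paste0("<", tag, ">"))
    close <- which(lines == paste0("</", tag, ">"))
    if (!length(open)) return(NULL)
    if (open[1] + 1 > close[1] - 1) return(character(0))
    lines[(open[1] + 1):(close[1] - 1)]
  }
  params <- section("param")
  kv <- strsplit(params, "=", fixed = TRUE)
  pv <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))

  seq_lines <- section("seq")
  hdr_at <- grep("^>", seq_lines)
  meta <- lapply(sub("^>", "", seq_lines[hdr_at]), parse_fasta_header)
  nodes <- annotated_seqs(
    seq_id = vapply(meta, `[[`, "", "seq_id"),
    residues = seq_lines[hdr_at + 1L],
    common_name = vapply(meta, `[[`, "", "common_name"),
    species = vapply(meta, `[[`, "", "species"))

  hsp_lines <- section("hsp")
  hits <- data.frame(query_id = character(0), subject_id = character(0),
                     score = numeric(0), evalue = numeric(0))
  if (length(hsp_lines)) {
    parts <- regmatches(hsp_lines,
                        regexec("^([0-9]+) ([0-9]+):([^;]+);(.+)$", hsp_lines))
    bad <- which(vapply(parts, length, integer(1)) != 5)
    if (length(bad)) {
      stop(sprintf("malformed hsp line: '%s'", hsp_lines[bad[1]]),
           call. = FALSE)
    }
    ia <- as.integer(vapply(parts, `[`, "", 2)) + 1L
    ib <- as.integer(vapply(parts, `[`, "", 3)) + 1L
    e_ab <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 4)))
    e_ba <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 5)))
    rows <- list(
      data.frame(query_id = nodes$seq_id[ia], subject_id = nodes$seq_id[ib],
                 score = NA_real_, evalue = e_ab)[!is.na(e_ab), ],
      data.frame(query_id = nodes$seq_id[ib], subject_id = nodes$seq_id[ia],
                 score = NA_real_, evalue = e_ba)[!is.na(e_ba), ])
    hits <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  graph <- similarity_graph(nodes, hits, as.numeric(pv[["cutoff"]]))

  layout <- NULL
  pos_lines <- section("pos")
  if (!is.null(pos_lines)) {
    fields <- strsplit(pos_lines, " ", fixed = TRUE)
    ord <- as.integer(vapply(fields, `[`, "", 1)) + 1L
    coords <- do.call(rbind, lapply(fields, function(f) as.numeric(f[-1])))
    coords <- coords[order(ord), , drop = FALSE]
    rownames(coords) <- nodes$seq_id
    layout <- structure(list(dims = as.integer(pv[["dims"]]), coords = coords,
                             rng_seed = as.numeric(pv[["rng_seed"]]),
                             iterations_run = as.integer(pv[["iterations_run"]]),
                             converged = as.logical(pv[["converged"]])),
                        class = "layout_state")
  }
  list(graph = graph, layout = layout)
}

# palette roles matching the published map colouring
GROUP_COLORS <- c(PG1 = "gold", PG2 = "darkorange", anterior = "gold",
                  PG3 = "red2", central = "royalblue3",
                  posterior = "forestgreen",
                  Gsx = "grey35", Pdx = "grey50", Cdx = "grey20",
                  OTHER = "grey80")

#' Export a 2D scatter of the similarity map
#'
#' Nodes are coloured by collapsed group class (anterior yellow/orange, Hox3
#' red, central blue, posterior green); ParaHox proteins are drawn as grey
#' squares. Edges are drawn darker the larger their attraction weight.
#'
#' @param graph `similarity_graph` with annotated (grouped) nodes.
#' @param layout 2D `layout_state`.
#' @param path output file path.
#' @param format one of `"svg"`, `"png"`, `"pdf"`; devices needing cairo
#'   fall back to pdf when the capability is missing.
#' @return `path`, invisibly.
#' @export
plot_map <- function(graph, layout, path, format = c("svg", "png", "pdf")) {
  format <- match.arg(format)
  if (format %in% c("svg", "png") && !capabilities("cairo")) {
    warning("cairo device unavailable; writing PDF instead", call. = FALSE)
    format <- "pdf"
    path <- sub("\\.(svg|png)$", ".pdf", path)
  }
  switch(format,
         svg = grDevices::svg(path, width = 7, height = 7),
         png = grDevices::png(path, width = 700, height = 700, type = "cairo"),
         pdf = grDevices::pdf(path, width = 7, height = 7))
  on.exit(grDevices::dev.off())
  nodes <- graph$nodes
  if (is.null(nodes$group_name)) nodes <- annotate_groups(nodes)
  cls <- collapse_hox_class(nodes$group_name)
  col <- GROUP_COLORS[cls]
  col[is.na(col)] <- GROUP_COLORS[["OTHER"]]
  pch <- ifelse(nodes$group_category == "PARAHOX", 15, 16)
  coords <- layout$coords[nodes$seq_id, , drop = FALSE]
  graphics::plot(coords[, 1], coords[, 2], type = "n", axes = FALSE,
                 xlab = "", ylab = "", asp = 1,
                 main = sprintf("similarity map, E-value cutoff %g",
                                graph$cutoff))
  e <- graph$edges
  if (nrow(e)) {
    shade <- grDevices::grey(1 - 0.8 * pmin(e$weight / max(e$weight), 1))
    graphics::segments(coords[e$id_a, 1], coords[e$id_a, 2],
                       coords[e$id_b, 1], coords[e$id_b, 2], col = shade)
  }
  graphics::points(coords[, 1], coords[, 2], col = col, pch = pch, cex = 1.1)
  invisible(path)
}
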