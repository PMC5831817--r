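test_that("similarity_graph keeps hits and drops self/unknown rows", {
  seqs <- annotated_seqs(c("a", "b"), c("MKV", "MKW"))
  hits <- rbind(dir_hits("a", "b", 1e-12),
                data.frame(query_id = "a", subject_id = "a",
                           score = NA_real_, evalue = 1e-50),
                data.frame(query_id = "a", subject_id = "ghost",
                           score = NA_real_, evalue = 1e-50))
  g <- similarity_graph(seqs, hits, cutoff = 1e-10)
  expect_equal(nrow(g$hits), 2)   # the two real directions
  expect_equal(nrow(g$edges), 1)
  expect_output(print(g), "2 nodes, 1 edges")
})

test_that("apply_cutoff tightens but never loosens", {
  seqs <- annotated_seqs(c("a", "b", "c"), rep("MKV", 3))
  hits <- rbind(dir_hits("a", "b", 1e-45), dir_hits("b", "c", 1e-35))
  g <- similarity_graph(seqs, hits, cutoff = 1e-33)
  expect_equal(nrow(g$edges), 2)
  g40 <- apply_cutoff(g, 1e-40)
  expect_equal(nrow(g40$edges), 1)
  expect_equal(g40$edges$id_a, "a")
  # nodes survive as isolated vertices
  expect_equal(nrow(g40$nodes), 3)
  expect_error(apply_cutoff(g40, 1e-33), "loosen")
})

test_that("tightening the cutoff never adds edges (pairwise containment)", {
  withr::local_seed(21)
  seqs <- random_seqs(8, c(40, 70))
  hits <- all_against_all(seqs, report_cutoff = 1)
  cuts <- c(1, 1e-2, 1e-5, 1e-10, 1e-20)
  prev <- NULL
  for (cf in cuts) {
    e <- build_edges(hits, cf)
    key <- paste(e$id_a, e$id_b)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("connected_components sorts by size then smallest member", {
  seqs <- annotated_seqs(c("a", "b", "c", "d", "e", "z"), rep("MKV", 6))
  hits <- rbind(dir_hits("d", "e", 1e-40),
                dir_hits("a", "b", 1e-40), dir_hits("b", "c", 1e-40))
  g <- similarity_graph(seqs, hits, 1e-33)
  comps <- connected_components(g)
  expect_equal(comps, list(c("a", "b", "c"), c("d", "e"), "z"))
})

test_that("select_seed_clusters unions seed-bearing components", {
  comps <- list(c("a", "b", "c"), c("d", "e"), "z")
  expect_equal(select_seed_clusters(comps, c("e", "q")),
               c("d", "e"))
  expect_equal(select_seed_clusters(comps, c("a", "z")),
               c("a", "b", "c", "z"))
  expect_error(select_seed_clusters(comps, character(0)), "empty seed")
})

test_that("layout is deterministic given a seed and sensitive to it", {
  g <- three_clique_graph(4)
  l1 <- layout_graph(g, seed = 3)
  l2 <- layout_graph(g, seed = 3)
  l3 <- layout_graph(g, seed = 4)
  expect_identical(l1$coords, l2$coords)
  expect_false(identical(l1$coords, l3$coords))
  expect_equal(rownames(l1$coords), g$nodes$seq_id)
  expect_true(l1$converged)
})

test_that("layout does not disturb the caller's RNG stream", {
  g <- three_clique_graph(3)
  set.seed(123)
  before <- .Random.seed
  layout_graph(g, seed = 5)
  expect_identical(.Random.seed, before)
})

test_that("connected groups contract relative to unconnected ones", {
  g <- three_clique_graph(5)
  l <- layout_graph(g, seed = 2)
  co <- l$coords
  grp <- substr(rownames(co), 1, 1)
  dm <- as.matrix(dist(co))
  same <- outer(grp, grp, "==")
  up <- upper.tri(dm)
  intra <- mean(dm[same & up])
  inter <- mean(dm[!same & up])
  expect_lt(intra, inter)
})

test_that("center_distance ranks groups and is rigid-motion invariant", {
  g <- three_clique_graph(4)
  l <- layout_graph(g, seed = 9)
  grp <- setNames(substr(g$nodes$seq_id, 1, 1), g$nodes$seq_id)
  cd <- center_distance(l, grp)
  expect_equal(sort(cd$group), c("A", "B", "C"))
  expect_equal(cd$rank, 1:3)
  expect_true(all(diff(cd$mean_center_distance) <= 0))
  # rotate + translate the embedding: statistics unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  l2 <- l
  l2$coords <- l$coords %*% R + matrix(c(5, -3), nrow(l$coords), 2,
                                       byrow = TRUE)
  cd2 <- center_distance(l2, grp)
  expect_equal(cd2$group, cd$group)
  expect_equal(cd2$mean_center_distance, cd$mean_center_distance)
  # OTHER and unknown nodes are ignored; empty requested groups warn
  grp_other <- grp
  grp_other[1] <- "OTHER"
  expect_silent(center_distance(l, grp_other))
  grp_ghost <- c(grp, ghost = "D")
  expect_warning(center_distance(l, grp_ghost), "D")
})

test_that("map files round trip bit-exactly", {
  withr::local_seed(5)
  seqs <- annotated_seqs(c("a", "b", "c"),
                         c(random_protein(30), random_protein(31),
                           random_protein(32)),
                         common_name = c("Hox3", "", "Cdx"),
                         species = c("Mus musculus", "", ""))
  hits <- rbind(dir_hits("a", "b", 1.2345678901234567e-41, 3e-45),
                dir_hits("b", "c", 7e-36))
  g <- similarity_graph(seqs, hits, 1e-33)
  l <- layout_graph(g, seed = 8)
  path <- withr::local_tempfile(fileext = ".clansmap")
  write_map(g, l, path)
  back <- read_map(path)
  expect_identical(back$layout$coords, l$coords)
  expect_identical(back$graph$edges$evalue_ab, g$edges$evalue_ab)
  expect_identical(back$graph$edges$evalue_ba, g$edges$evalue_ba)
  expect_identical(back$graph$cutoff, g$cutoff)
  expect_equal(as.data.frame(back$graph$nodes), as.data.frame(seqs))
  expect_identical(back$layout$rng_seed, l$rng_seed)
  expect_identical(back$layout$converged, l$converged)
  # a second write of the re-read map is byte-identical
  path2 <- withr::local_tempfile(fileext = ".clansmap")
  write_map(back$graph, back$layout, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("map without layout omits <pos> and still round trips", {
  seqs <- annotated_seqs(c("a", "b"), c("MKV", "MKW"))
  g <- similarity_graph(seqs, dir_hits("a", "b", 1e-40), 1e-33)
  path <- withr::local_tempfile(fileext = ".clansmap")
  write_map(g, NULL, path)
  back <- read_map(path)
  expect_null(back$layout)
  expect_equal(nrow(back$graph$edges), 1)
})

test_that("unknown map section tags raise a parse error with the line", {
  path <- withr::local_tempfile(fileext = ".clansmap")
  writeLines(c("# parahoxmap map v1", "<param>", "cutoff=1", "</param>",
               "<seq>", ">a", "MKV", "</seq>", "<bogus>", "</bogus>",
               "<hsp>", "</hsp>"), path)
  expect_error(read_map(path), "<bogus>.*line 9")
})

test_that("plot_map writes a figure file", {
  g <- three_clique_graph(3)
  g$nodes <- annotate_groups(g$nodes)
  l <- layout_graph(g, seed = 1)
  path <- withr::local_tempfile(fileext = ".svg")
  out <- suppressWarnings(plot_map(g, l, path))
  expect_true(file.exists(out) || file.exists(sub("svg$", "pdf", path)))
})
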