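make_alignment <- function() {
  # 8 slightly diverged copies of a 30-mer with a gappy column block
  base <- "MKWVLRAEYWQHNDFGIKLNPQRSTVWYAC"
  rows <- vapply(1:8, function(i) {
    chars <- strsplit(base, "")[[1]]
    chars[(i %% 5) + 1] <- "A"
    paste0(chars, collapse = "")
  }, character(1))
  # append 2 columns that are >50% gaps (6 of 8 rows gapped)
  paste0(rows, c("KL", "--", "--", "--", "--", "--", "--", "KL"))
}

test_that("build_profile drops majority-gap columns and validates input", {
  p <- build_profile(make_alignment())
  expect_s3_class(p, "profile_model")
  expect_equal(p$length, 30)       # 2 gappy columns dropped
  expect_equal(ncol(p$log_odds), 21)
  expect_true(is.na(p$score_threshold))
  expect_error(build_profile("MKV"), "at least 2")
  expect_error(build_profile(c("MKV", "MK")), "ragged")
  expect_error(build_profile(c("MKZ", "MKV")), "alphabet")
  expect_error(build_profile(c("--", "--")), "no match columns")
})

test_that("profile log-odds favour the observed residue; X scores zero", {
  p <- build_profile(c("WWWW", "WWWW", "WWWW"))
  expect_true(all(p$log_odds[, "W"] > 0))
  expect_true(all(p$log_odds[, "A"] < 0))
  expect_equal(unname(p$log_odds[, "X"]), rep(0, 4))
  expect_equal(profile_consensus(p), "WWWW")
})

test_that("pseudocounted frequencies follow the documented formula", {
  bg <- aa_background()
  p <- build_profile(c("AW", "AW"), pseudocount = 1, background = bg)
  expected <- log(((2 + 1 * bg[["A"]]) / (2 + 1)) / bg[["A"]])
  expect_equal(unname(p$log_odds[1, "A"]), expected)
})

test_that("from-alignment background pools observed residues", {
  p <- build_profile(c("AW", "AW"), background = "from-alignment")
  expect_true(all(p$background > 0))
  expect_equal(sum(p$background), 1)
})

test_that("calibration is deterministic, seed-sensitive and validated", {
  p <- build_profile(make_alignment())
  t1 <- calibrate_threshold(p, n_samples = 1000, fpr = 1e-2, seed = 5)
  t2 <- calibrate_threshold(p, n_samples = 1000, fpr = 1e-2, seed = 5)
  t3 <- calibrate_threshold(p, n_samples = 1000, fpr = 1e-2, seed = 6)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  # tighter fpr -> larger threshold
  expect_gt(calibrate_threshold(p, fpr = 1e-3, seed = 5),
            calibrate_threshold(p, fpr = 1e-1, seed = 5))
  expect_error(calibrate_threshold(p, fpr = 0.7), "fpr")
  expect_error(calibrate_threshold(p, n_samples = 10), "n_samples")
})

test_that("calibration leaves the caller's RNG stream untouched", {
  p <- build_profile(make_alignment())
  set.seed(99)
  before <- .Random.seed
  calibrate_threshold(p, seed = 5)
  expect_identical(.Random.seed, before)
})

test_that("scan_sequence finds an implanted domain at its true location", {
  aln <- make_alignment()
  p <- calibrate_profile(build_profile(aln), fpr = 1e-3, seed = 1)
  withr::local_seed(11)
  domain <- substr(aln[1], 1, 30)
  host <- paste0(random_protein(40), domain, random_protein(25))
  hits <- scan_sequence(p, host, "h1")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 40)       # 0-based
  expect_equal(hits$end, 70)         # half-open
  expect_equal(hits$seq_id, "h1")
})

test_that("scan requires calibration and handles short sequences", {
  p <- build_profile(make_alignment())
  expect_error(scan_sequence(p, "MKV"), "not calibrated")
  pc <- calibrate_profile(p, seed = 1)
  expect_equal(nrow(scan_sequence(pc, "MKV")), 0)
})

test_that("overlapping windows are resolved best-first", {
  p <- calibrate_profile(build_profile(c("WWWWWWWW", "WWWWWWWW")), seed = 1)
  hits <- scan_sequence(p, strrep("W", 12), "w")
  # every window passes; non-overlap resolution keeps at most floor(12/8)=1
  expect_equal(nrow(hits), 1)
  # and the kept window is the best-scoring (all equal -> smallest start)
  expect_equal(hits$start, 0)
})

test_that("filter_multidomain partitions by hit count", {
  aln <- make_alignment()
  p <- calibrate_profile(build_profile(aln), fpr = 1e-3, seed = 1)
  withr::local_seed(3)
  domain <- substr(aln[1], 1, 30)
  seqs <- annotated_seqs(
    c("none", "one", "two"),
    c(random_protein(80),
      paste0(random_protein(20), domain, random_protein(20)),
      paste0(random_protein(10), domain, random_protein(12), domain,
             random_protein(10))))
  f <- filter_multidomain(seqs, p)
  expect_setequal(f$kept$seq_id, c("none", "one"))
  expect_equal(f$removed$seq_id, "two")
  expect_equal(f$kept$n_domain_hits[f$kept$seq_id == "none"], 0)
  expect_equal(f$removed$n_domain_hits, 2)
})

test_that("hit TSV round trip restores 0-based half-open coordinates", {
  hits <- data.frame(seq_id = c("a", "b"), start = c(0L, 17L),
                     end = c(30L, 47L), score = c(12.25, 40.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, path)
  expect_equal(read_hits_tsv(path), hits)
  # 1-based closed coordinates on disk
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$start_1based, c(1, 18))
  expect_equal(tab$end_1based, c(30, 47))
})

test_that("redundancy clustering is greedy longest-first and reversible", {
  s <- annotated_seqs(
    c("long", "copy", "short", "other"),
    c(strrep("MKWVLRAEYW", 8),
      paste0(strrep("MKWVLRAEYW", 8), "A"),   # longer, 98.8% identical
      "MKWVLRAEYW",
      random_protein(70)))
  m <- cluster_redundant(s, 0.95)
  # the longest member of the near-identical pair is the representative
  expect_equal(unname(m$representative_of[["long"]]), "copy")
  expect_equal(unname(m$representative_of[["copy"]]), "copy")
  reps <- representatives(m)
  expect_true(all(c("copy", "other") %in% reps))
  expect_false("long" %in% reps)
  # re-inflation restores members of kept representatives, in input order
  back <- reinflate(reps, m, s)
  expect_equal(back$seq_id, s$seq_id)
  expect_error(reinflate("long", m, s), "not representative")
  expect_error(cluster_redundant(s, 0.4), "identity_threshold")
})

test_that("redundancy TSV round trips including the threshold", {
  s <- random_seqs(5)
  m <- cluster_redundant(s, 0.9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_redundancy_tsv(m, path)
  back <- read_redundancy_tsv(path)
  expect_equal(back$representative_of, m$representative_of)
  expect_equal(back$identity_threshold, 0.9)
})
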