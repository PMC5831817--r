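small_design <- function(seed = 1, ...) {
  groups <- data.frame(name = c("g1", "g2", "g3"),
                       category = c("HOX", "HOX", "PARAHOX"),
                       common_name = c("Hox1", "Hox2", "Cdx"),
                       n_species = 2, rate_multiplier = 1)
  family_design(groups, "((g1:0.1,g2:0.1):0.05,g3:0.2);",
                rng_seed = seed, ...)
}

test_that("family_design validates topology tips and parameters", {
  expect_s3_class(small_design(), "family_design")
  groups <- data.frame(name = "gX", category = "HOX", common_name = "Hox1",
                       n_species = 1, rate_multiplier = 1)
  expect_error(family_design(groups, "((g1:0.1,g2:0.1):0.05,g3:0.2);"),
               "tips do not match")
  bad <- data.frame(name = c("g1", "g2"), category = "HOX",
                    common_name = "Hox1", n_species = 0, rate_multiplier = 1)
  expect_error(family_design(bad, "(g1:0.1,g2:0.1);"))
})

test_that("evolve_sequence preserves length and is rate-sensitive", {
  withr::local_seed(2)
  parent <- random_protein(200)
  child0 <- evolve_sequence(parent, 0)
  expect_equal(as.character(child0), parent)
  expect_equal(attr(child0, "n_events"), 0)
  child <- evolve_sequence(parent, 0.5)
  expect_equal(nchar(child), 200)
  expect_gt(attr(child, "n_events"), 0)
  # slow sites change less than fast sites, in expectation
  slow <- replicate(20, attr(evolve_sequence(parent, 0.5, 0.1), "n_events"))
  fast <- replicate(20, attr(evolve_sequence(parent, 0.5, 2.0), "n_events"))
  expect_lt(mean(slow), mean(fast))
  expect_error(evolve_sequence(parent, -1))
})

test_that("simulate_family is reproducible and truth-annotated", {
  d <- small_design(seed = 11)
  s1 <- simulate_family(d)
  s2 <- simulate_family(d)
  expect_identical(s1$sequences$residues, s2$sequences$residues)
  seqs <- s1$sequences
  expect_equal(nrow(seqs), 6)    # 3 groups x 2 species
  expect_equal(seqs$seq_id[1:2], c("g1_s1", "g1_s2"))
  expect_setequal(unique(seqs$group_name), c("g1", "g2", "g3"))
  # true domain window really is domain-like: conserved across the family
  doms <- substr(seqs$residues, seqs$domain_start + 1,
                 seqs$domain_start + seqs$domain_length)
  expect_true(all(nchar(doms) == 60))
  ident <- outer(doms, doms, Vectorize(function(x, y) {
    mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  }))
  expect_gt(min(ident), 0.7)     # domain stays alignable family-wide
  # flanks diverge much faster than the domain
  flanks <- substr(seqs$residues, 1, seqs$domain_start)
  expect_lt(mean(strsplit(flanks[1], "")[[1]][1:50] ==
                 strsplit(flanks[3], "")[[1]][1:50]), min(ident))
  # lineage bookkeeping matches the sequence table
  expect_setequal(s1$lineage$seq_id, seqs$seq_id)
  expect_true(all(s1$lineage$n_substitutions >= 0))
})

test_that("different seeds give different datasets", {
  s1 <- simulate_family(small_design(seed = 1))
  s2 <- simulate_family(small_design(seed = 2))
  expect_false(identical(s1$sequences$residues, s2$sequences$residues))
})

test_that("rate multipliers lengthen realised group branches", {
  groups <- data.frame(name = c("slow", "fast", "out"),
                       category = "HOX", common_name = "Hox1",
                       n_species = 4, rate_multiplier = c(1, 6, 1))
  d <- family_design(groups, "((slow:0.1,fast:0.1):0.05,out:0.2);",
                     rng_seed = 3)
  sim <- simulate_family(d)
  subs <- tapply(sim$lineage$n_substitutions, sim$lineage$group, mean)
  expect_gt(subs[["fast"]], 2 * subs[["slow"]])
})

test_that("scenario presets are validated and encode the LBA contrast", {
  expect_error(hox_parahox_scenario("nonsense"), "paper_supported")
  expect_error(hox_parahox_scenario("lba", severity = 0.5))
  ds <- hox_parahox_scenario("paper_supported", rng_seed = 4)
  expect_equal(nrow(ds$sequences), 48)    # 8 groups x 6 species
  expect_setequal(unique(ds$sequences$group_name),
                  c("PG1", "PG2", "PG3", "central", "posterior",
                    "Gsx", "Pdx", "Cdx"))
  expect_equal(sum(ds$sequences$group_category == "PARAHOX"), 18)
  lba <- hox_parahox_scenario("lba", severity = 8, rng_seed = 4)
  fast <- lba$truth$groups$rate_multiplier[
    lba$truth$groups$name %in% c("Cdx", "posterior")]
  expect_equal(fast, c(8, 8))
  # the traditional topology is a genuinely different hypothesis
  expect_false(identical(
    ape::read.tree(text = hox_parahox_scenario("traditional",
                                               rng_seed = 1)$truth$guide_topology),
    ape::read.tree(text = ds$truth$guide_topology)))
})

test_that("seed alignment extracts one true domain row per group", {
  ds <- hox_parahox_scenario("paper_supported", rng_seed = 6)
  seed <- seed_alignment_from_dataset(ds)
  expect_equal(nrow(seed$alignment), 8)
  expect_true(all(nchar(seed$alignment$residues) == 60))
  expect_equal(length(seed$seed_ids), 8)
  expect_true(all(seed$seed_ids %in% ds$sequences$seq_id))
  # rows are the true domain windows of the source sequences
  src <- ds$sequences[match(seed$seed_ids, ds$sequences$seq_id), ]
  expect_equal(seed$alignment$residues,
               substr(src$residues, src$domain_start + 1,
                      src$domain_start + 60))
})

test_that("design YAML round trips the generator settings", {
  d <- small_design(seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_design_yaml(d, path)
  y <- yaml::read_yaml(path)
  expect_equal(y$guide_topology, d$guide_topology)
  expect_equal(y$rng_seed, 9)
  expect_equal(y$domain_length, 60)
  expect_equal(as.data.frame(y$groups)$name, d$groups$name)
})
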