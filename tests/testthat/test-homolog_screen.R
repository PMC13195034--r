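test_that("reciprocal top hits apply strict thresholds and mutual-best logic", {
  fwd <- hit_table(data.frame(query = c("q1", "q1"), subject = c("s1", "s2"),
                              evalue = c(1e-30, 1e-25), bitscore = c(200, 180)))
  rev <- hit_table(data.frame(query = "s1", subject = "q1",
                              evalue = 1e-28, bitscore = 190))
  got <- reciprocal_top_hits(fwd, rev)
  expect_equal(got, data.frame(query = "q1", subject = "s1"))

  # "less than" is strict: a best forward hit at exactly 1e-20 is excluded
  fwd_edge <- hit_table(data.frame(query = "q1", subject = "s1",
                                   evalue = 1e-20, bitscore = 100))
  expect_equal(nrow(reciprocal_top_hits(fwd_edge, rev)), 0L)
  # ... and exactly 1e-10 on the reciprocal side is excluded too
  rev_edge <- hit_table(data.frame(query = "s1", subject = "q1",
                                   evalue = 1e-10, bitscore = 100))
  expect_equal(nrow(reciprocal_top_hits(fwd, rev_edge)), 0L)

  expect_equal(nrow(reciprocal_top_hits(fwd[0, ], rev)), 0L)
})

test_that("planted ortholog bijections are recovered exactly over decoys", {
  for (seed in 1:20) {
    map <- setNames(paste0("b", sample(1:15)), paste0("a", 1:15))
    ht <- gen_hit_tables(list("A->B" = map), decoy_count = 25,
                         decoy_evalue_factor = 10, seed = seed)
    pairs <- reciprocal_top_hits(ht[["A->B"]], ht[["B->A"]])
    expect_equal(nrow(pairs), 15L)
    expect_true(all(map[pairs$query] == pairs$subject))   # precision 1
    # one-to-one: no subject (or query) appears twice
    expect_false(anyDuplicated(pairs$subject) > 0)
    expect_false(anyDuplicated(pairs$query) > 0)
  }
})

test_that("screening is deterministic and iterates across species", {
  map_ab <- setNames(paste0("b", 1:5), paste0("a", 1:5))
  map_bc <- setNames(paste0("c", 1:5), paste0("b", 1:5))
  tabs <- c(gen_hit_tables(list("SEED->B" = map_ab), seed = 1),
            gen_hit_tables(list("B->C" = map_bc), seed = 2))
  res <- iterative_screen(paste0("a", 1:5), tabs, species = c("B", "C"),
                          seed_db = "SEED")
  expect_length(res$rounds, 2L)                 # B in round 1, C in round 2
  expect_setequal(res$accepted$B, paste0("b", 1:5))
  expect_setequal(res$accepted$C, paste0("c", 1:5))
  expect_length(res$uncovered, 0L)

  # transitive detection beats a single round
  res1 <- iterative_screen(paste0("a", 1:5), tabs, species = c("B", "C"),
                           seed_db = "SEED", cfg = screen_config(max_rounds = 1))
  expect_gt(sum(lengths(res$accepted) > 0), sum(lengths(res1$accepted) > 0))

  # determinism: identical inputs give identical results
  res_again <- iterative_screen(paste0("a", 1:5), tabs, species = c("B", "C"),
                                seed_db = "SEED")
  expect_identical(res, res_again)

  # missing tables are recorded, not fatal
  res_m <- iterative_screen(paste0("a", 1:5), tabs[c("SEED->B", "B->SEED")],
                            species = c("B", "C"), seed_db = "SEED")
  expect_true(length(res_m$missing_tables) > 0)
  expect_equal(res_m$uncovered, "C")

  empty <- iterative_screen(character(0), tabs, species = c("B", "C"),
                            seed_db = "SEED")
  expect_length(empty$rounds, 0L)
  expect_equal(empty$uncovered, c("B", "C"))
})

test_that("clade validation accepts inside supported clades only", {
  gt <- parse_newick("(((ref1,ref2)95,cand1)90,(cand2,out1));")
  cfg <- screen_config(reference_ids = c("ref1", "ref2"))
  val <- clade_validate(gt, c("cand1", "cand2"), cfg)
  expect_equal(val$rejected$id, c("cand1", "cand2"))
  expect_setequal(unique(val$rejected$reason), "outside-clade")

  # candidate nested in the reference clade with high support
  gt2 <- parse_newick("(((ref1,(ref2,cand1))95,cand2)90,out1);")
  val2 <- clade_validate(gt2, c("cand1", "cand2"), cfg)
  expect_equal(val2$accepted, "cand1")
  expect_equal(val2$rejected$reason[val2$rejected$id == "cand2"], "outside-clade")

  # support below the default 70 flags everything low-support
  gt3 <- parse_newick("(((ref1,(ref2,cand1))60,cand2)90,out1);")
  val3 <- clade_validate(gt3, c("cand1"), cfg)
  expect_length(val3$accepted, 0L)
  expect_equal(val3$rejected$reason, "low-support")

  # references spanning the root: accept-all flagged low confidence
  gt4 <- parse_newick("((ref1,cand1),(ref2,out1));")
  expect_warning(val4 <- clade_validate(gt4, "cand1", cfg), "low-confidence")
  expect_equal(val4$accepted, "cand1")
  expect_true(val4$low_confidence)
})
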