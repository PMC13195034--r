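test_that("newick parsing preserves leaves, supports, and clade names", {
  tr <- parse_newick("(A,B);")
  expect_setequal(tree_leaves(tr), c("A", "B"))
  expect_equal(tr$n_tip, 2L)

  tr2 <- parse_newick("((A,B)95,C);")
  inner <- setdiff(seq_len(tr2$n_node), c(seq_len(tr2$n_tip), tr2$root))
  expect_equal(unname(tr2$support[inner]), 95)

  tr3 <- parse_newick("((A,B)CladeX,C);")
  expect_setequal(tree_leaves(tr3)[moltloss:::tree_subtree_leaves(tr3, tree_node_id(tr3, "CladeX"))],
                  c("A", "B"))
})

test_that("malformed newick is rejected with diagnostics", {
  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("(A,B))(;"), "character 6")
  expect_error(parse_newick("(A,B)"), "end in ';'")
  expect_error(parse_newick("(A,A);"), "duplicate leaf")
  expect_error(parse_newick(""), "empty")
})

test_that("newick write/parse round-trip is the identity on canonical form", {
  set.seed(42)
  for (i in 1:100) {
    tr <- random_tree(sample(3:64, 1))
    nwk <- write_newick(tr)
    tr2 <- parse_newick(nwk)
    expect_identical(write_newick(tr2), nwk)
    # independent serializer: ape agrees on the topology
    phy1 <- ape::read.tree(text = nwk)
    expect_true(ape::all.equal.phylo(phy1, ape::read.tree(text = write_newick(tr2)),
                                     use.edge.length = FALSE))
  }
})

test_that("presence matrix IO maps {1,0,?} bijectively and rejects junk", {
  f <- withr::local_tempfile(fileext = ".tsv")
  mat <- matrix(c("present", "absent", "missing", "present"), 2, 2,
                dimnames = list(c("s1", "s2"), c("ecr", "usp")))
  write_presence_matrix(mat, f)
  expect_identical(read_presence_matrix(f), mat)

  writeLines(c("taxon\tecr", "s1\t2"), f)
  expect_error(read_presence_matrix(f), "malformed presence symbols")
})

test_that("orthogroup table parses the OrthoFinder dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tspA\tspB\tspC",
               "OG0000005\tg1, g2\t\tg3"), f)
  tab <- read_orthogroups(f)
  expect_equal(tab$OG0000005$spA, c("g1", "g2"))
  expect_equal(tab$OG0000005$spB, character(0))
  expect_equal(tab$OG0000005$spC, "g3")

  writeLines("Orthogroup\tspA\tspB", f)
  empty <- read_orthogroups(f)
  expect_length(empty, 0L)
  expect_equal(attr(empty, "species"), c("spA", "spB"))

  writeLines(c("Orthogroup\tspA\tspB",
               "OG1\tg1\tg2", "OG2\tg1\tg3"), f)
  expect_warning(dup <- read_orthogroups(f), "earlier orthogroup")
  expect_equal(dup$OG2$spA, character(0))
  expect_equal(dup$OG2$spB, "g3")
})

test_that("orthogroup write/read round-trips a 50-OG synthetic table", {
  sim <- gen_orthogroups(taxa_tree5(),
                         c(Rhabditina = 2, Tylenchina = 2, Spirurina = 1,
                           Trichinellida = 1, Enoplida = 1),
                         n_ogs = 50,
                         origin_probs = c(Nematoda = 0.4, Rhabditida = 0.3,
                                          Rhabditina = 0.3),
                         within_taxon_loss = 0.3, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_orthogroups(sim$table, f)
  back <- read_orthogroups(f)
  expect_equal(unclass(back)[], unclass(sim$table)[],
               ignore_attr = TRUE)
  expect_equal(attr(back, "species"), attr(sim$table, "species"))
})

test_that("hit tables keep only the best record per (query, subject) pair", {
  df <- data.frame(query = c("q1", "q1", "q1"),
                   subject = c("s1", "s1", "s2"),
                   evalue = c(1e-30, 1e-10, 1e-25),
                   bitscore = c(200, 50, 150))
  ht <- hit_table(df)
  expect_equal(nrow(ht), 2L)
  expect_equal(ht$evalue[ht$subject == "s1"], 1e-30)
  expect_error(hit_table(transform(df, evalue = -1)), "negative")
})

test_that("CA traces read back from PDB with format precision", {
  pdb_lines <- c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       7.000   8.000   9.500  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, f)
  ch <- read_structure_ca(f, chain = "A")
  expect_equal(length(ch), 3L)
  expect_equal(ch$xyz, matrix(1:9 + c(0, 0, 0, 0, 0, 0, 0, 0, 0.5), 3, 3,
                              byrow = TRUE))
  expect_error(read_structure_ca(f, chain = "B"), "not found")

  # residue_range slicing on a 20-residue chain
  tmpl <- fold_template("three_helix", 160)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(structure_chain(tmpl$xyz[1:20, ]), f2)
  sub <- read_structure_ca(f2, residue_range = c(10, 12))
  expect_equal(length(sub), 3L)
  expect_equal(sub$resno, 10:12)

  # round-trip through the synthetic generator within PDB precision
  copies <- gen_structure_pair(tmpl, 1, coord_noise = 0.2, seed = 4)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(copies$chains[[1]], f3)
  back <- read_structure_ca(f3)
  expect_lt(max(abs(back$xyz - copies$chains[[1]]$xyz)), 1e-3)
})
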