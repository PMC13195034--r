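mk_table <- function(lst, species) orthogroup_table(lst, species = species)

test_that("orthogroup intersection keeps only fully covered orthogroups", {
  tab <- mk_table(list(OG1 = list(sp1 = "a1", sp2 = "b1"),
                       OG2 = list(sp1 = "a2", sp2 = character(0))),
                  species = c("sp1", "sp2"))
  cand <- list(sp1 = c("a1", "a2"), sp2 = "b1")
  expect_equal(intersect_candidate_ogs(cand, tab), "OG1")

  # an empty candidate set annihilates the result (with a warning)
  expect_warning(out <- intersect_candidate_ogs(list(sp1 = character(0), sp2 = "b1"), tab),
                 "empty candidate")
  expect_length(out, 0L)

  # the candidate gene must be in the OG, not just any gene of the species
  cand2 <- list(sp1 = "a1", sp2 = "zzz")
  expect_length(intersect_candidate_ogs(cand2, tab), 0L)
})

test_that("adding a species never enlarges the intersection (50 random tables)", {
  set.seed(14)
  for (i in 1:50) {
    n_sp <- sample(3:7, 1)
    sp <- paste0("sp", seq_len(n_sp))
    n_og <- sample(5:15, 1)
    lst <- lapply(seq_len(n_og), function(o) {
      e <- lapply(sp, function(s)
        if (runif(1) < 0.7) paste0("g", o, "_", s, "_", 1:sample(1:2, 1)) else character(0))
      names(e) <- sp
      e
    })
    names(lst) <- paste0("OG", seq_len(n_og))
    tab <- mk_table(lst, sp)
    cand <- lapply(setNames(sp, sp), function(s) {
      pool <- unlist(lapply(lst, `[[`, s), use.names = FALSE)
      if (!length(pool)) return("none")
      sample(pool, max(1, round(0.8 * length(pool))))
    })
    fewer <- suppressWarnings(intersect_candidate_ogs(cand[-n_sp], tab))
    full <- suppressWarnings(intersect_candidate_ogs(cand, tab))
    expect_true(all(full %in% fewer))
    # brute-force re-evaluation agrees
    brute <- names(lst)[vapply(lst, function(e)
      all(vapply(sp, function(s) any(e[[s]] %in% cand[[s]]), logical(1))), logical(1))]
    expect_setequal(full, brute)
  }
})

test_that("species gene lists are sorted de-duplicated unions", {
  tab <- mk_table(list(OG1 = list(sp = c("g2", "g1")), OG2 = list(sp = "g2")),
                  species = "sp")
  expect_equal(species_gene_list(c("OG1", "OG2"), tab, "sp"), c("g1", "g2"))
  expect_equal(species_gene_list(character(0), tab, "sp"), character(0))
  set.seed(3)
  for (i in 1:10) {
    ogs <- sample(names(tab), sample(0:2, 1))
    brute <- sort(unique(unlist(lapply(tab[ogs], `[[`, "sp"))))
    if (is.null(brute)) brute <- character(0)
    expect_equal(species_gene_list(ogs, tab, "sp"), brute)
  }
})

test_that("transcription factors are called from panel domains below 1e-5", {
  dom <- data.frame(
    gene = c("nr1", "nr1", "col1", "weak", "hox1"),
    domain_accession = c("PF00104.26", "PF00105", "PF01391", "PF00104", "PF00046.25"),
    evalue = c(1e-12, 1e-8, 1e-30, 1e-5, 1e-9))
  genes <- c("nr1", "col1", "weak", "hox1", "nodata")
  got <- filter_transcription_factors(genes, dom)
  expect_setequal(got$tf_genes, c("nr1", "hox1"))   # 1e-5 exactly is out
  # idempotent and order-independent
  again <- filter_transcription_factors(rev(genes), dom)
  expect_identical(got$tf_genes, again$tf_genes)
  expect_identical(filter_transcription_factors(got$tf_genes, dom)$tf_genes,
                   got$tf_genes)
  # orthogroup mapping of kept genes
  tab <- mk_table(list(OGa = list(sp = "nr1"), OGb = list(sp = "col1")),
                  species = "sp")
  expect_equal(filter_transcription_factors(genes, dom, table = tab)$tf_ogs, "OGa")

  # planted TF subset recovered exactly from a synthetic table
  set.seed(21)
  all_genes <- paste0("g", 1:50)
  tf_true <- sample(all_genes, 12)
  dom2 <- rbind(
    data.frame(gene = tf_true,
               domain_accession = sample(unname(tf_domain_panel()), 12, replace = TRUE),
               evalue = 10^runif(12, -30, -6)),
    data.frame(gene = setdiff(all_genes, tf_true),
               domain_accession = "PF01391", evalue = 10^runif(38, -30, -6)))
  expect_setequal(filter_transcription_factors(all_genes, dom2)$tf_genes, tf_true)
})

test_that("nuclear receptors are counted once per collapsed gene", {
  dom <- data.frame(gene = c("geneA.1", "geneA.2", "geneA.3"),
                    domain_accession = "PF00104.26", evalue = 1e-20)
  expect_equal(count_nuclear_receptors(dom), 1L)
  expect_equal(count_nuclear_receptors(dom[0, ]), 0L)

  # explicit map overrides the suffix rule
  dom2 <- data.frame(gene = c("x1", "x2", "y1"),
                     domain_accession = "PF00104", evalue = 1e-10)
  expect_equal(count_nuclear_receptors(dom2,
                                       isoform_map = c(x1 = "X", x2 = "X", y1 = "Y")), 2L)

  # planted NR count recovered from a synthetic scan
  set.seed(30)
  nr_genes <- paste0("nr", 1:17)
  iso <- paste0(rep(nr_genes, each = 2), ".", 1:2)
  other <- paste0("o", 1:40)
  dom3 <- rbind(data.frame(gene = iso, domain_accession = "PF00104.26",
                           evalue = 10^runif(length(iso), -40, -6)),
                data.frame(gene = other, domain_accession = "PF00096",
                           evalue = 10^runif(40, -40, -6)))
  expect_equal(count_nuclear_receptors(dom3), 17L)
  expect_true("Hormone_recep" %in% names(tf_domain_panel()))
})
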