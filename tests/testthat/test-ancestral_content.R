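tree5 <- taxa_tree5()
taxa5 <- c("Enoplida", "Trichinellida", "Spirurina", "Tylenchina", "Rhabditina")

# species map: two species per taxon, suffix _a/_b
taxon_of2 <- setNames(rep(taxa5, each = 2), paste0(rep(taxa5, each = 2), c("_a", "_b")))

og_entry <- function(sp_with_genes) {
  entry <- setNames(vector("list", length(taxon_of2)), names(taxon_of2))
  for (s in names(entry)) entry[[s]] <- if (s %in% sp_with_genes) paste0(s, "_g") else character(0)
  entry
}

test_that("orthogroup origins follow the all-taxa coverage rule", {
  all5 <- assign_og_origin(og_entry(paste0(taxa5, "_a")), taxon_of2, tree5)
  expect_equal(all5$origin, "Nematoda")
  expect_false(all5$patchy)

  rhab <- assign_og_origin(og_entry(c("Rhabditina_a", "Rhabditina_b")), taxon_of2, tree5)
  expect_equal(rhab$origin, "Rhabditina")

  rhabditida <- assign_og_origin(og_entry(c("Spirurina_a", "Tylenchina_a", "Rhabditina_b")),
                                 taxon_of2, tree5)
  expect_equal(rhabditida$origin, "Rhabditida")

  patchy <- assign_og_origin(og_entry(c("Enoplida_a", "Rhabditina_a")), taxon_of2, tree5)
  expect_true(patchy$patchy)
  expect_true(is.na(patchy$origin))
  expect_setequal(patchy$taxa, c("Enoplida", "Rhabditina"))

  expect_error(assign_og_origin(og_entry("Enoplida_a"), taxon_of2["Rhabditina_a"], tree5),
               "without taxon mapping")
})

test_that("node content sizes are hand-computable on a toy table", {
  tab <- orthogroup_table(list(
    OG1 = og_entry(paste0(taxa5, "_a")),                                 # all 5
    OG2 = og_entry(c("Spirurina_a", "Tylenchina_a", "Rhabditina_a")),    # Rhabditida
    OG3 = og_entry(c("Tylenchina_a", "Rhabditina_b")),                   # Rhab+Tyl
    OG4 = og_entry(c("Rhabditina_a", "Rhabditina_b")),                   # Rhabditina
    OG5 = og_entry(c("Enoplida_a", "Rhabditina_a"))),                    # patchy
    species = names(taxon_of2))
  rec <- reconstruct_node_content(tab, taxon_of2, tree5)
  sizes <- setNames(rec$nodes$content_size, rec$nodes$node)
  expect_equal(sizes[["Nematoda"]], 1L)                # OG1
  expect_equal(sizes[["Rhabditida"]], 2L)              # + OG2
  expect_equal(sizes[["Rhabditina_Tylenchina"]], 3L)   # + OG3
  expect_equal(sizes[["Rhabditina"]], 5L)              # + OG4, OG5 (per-taxon)
  expect_equal(sizes[["Tylenchina"]], 3L)
  expect_equal(rec$patchy, "OG5")
  # gains reconcile along the chain: size = parent size + gain - loss
  for (i in seq_len(nrow(rec$nodes))) {
    par <- rec$nodes$parent[i]
    if (is.na(par)) next
    psize <- sizes[[par]]
    expect_equal(rec$nodes$content_size[i],
                 psize + rec$nodes$gain[i] - rec$nodes$loss[i])
  }
  # species content: Rhabditina_a has OG1, OG2, OG4, OG5
  sp <- rec$species[rec$species$species == "Rhabditina_a", ]
  expect_equal(sp$content_size, 4L)
})

test_that("saturated tables give equal contents and zero deltas below the root", {
  tab <- orthogroup_table(list(OG1 = og_entry(names(taxon_of2)),
                               OG2 = og_entry(paste0(taxa5, "_b"))),
                          species = names(taxon_of2))
  rec <- reconstruct_node_content(tab, taxon_of2, tree5)
  expect_true(all(rec$nodes$content_size == 2L))
  below <- !is.na(rec$nodes$parent)
  expect_true(all(rec$nodes$gain[below] == 0L))
  expect_true(all(rec$nodes$loss[below] == 0L))
})

test_that("planted origins are recovered exactly for clean synthetic tables", {
  sim <- gen_orthogroups(tree5,
                         c(Rhabditina = 4, Tylenchina = 3, Spirurina = 2,
                           Trichinellida = 1, Enoplida = 1),
                         n_ogs = 100,
                         origin_probs = c(Nematoda = 0.2, Rhabditida = 0.2,
                                          Rhabditina_Tylenchina = 0.2,
                                          Rhabditina = 0.2, Tylenchina = 0.2),
                         within_taxon_loss = 0.3, seed = 17)
  rec <- reconstruct_node_content(sim$table, sim$taxon_of, tree5)
  merged <- merge(rec$origins, sim$truth, by = "og", suffixes = c("_inferred", "_planted"))
  expect_false(any(merged$patchy))
  expect_equal(merged$origin_inferred, merged$origin_planted)
})

test_that("content is monotone in membership and species removal", {
  base <- list(OG1 = og_entry(c("Enoplida_a", "Trichinellida_a", "Spirurina_a",
                                "Tylenchina_a", "Rhabditina_a")),
               OG2 = og_entry(c("Tylenchina_a", "Rhabditina_a")))
  tab <- orthogroup_table(base, species = names(taxon_of2))
  rec <- reconstruct_node_content(tab, taxon_of2, tree5)
  # adding genes to OG2 never removes it from any node's content
  grown <- base
  grown$OG2 <- og_entry(c("Tylenchina_a", "Rhabditina_a", "Spirurina_b"))
  rec2 <- reconstruct_node_content(orthogroup_table(grown, species = names(taxon_of2)),
                                   taxon_of2, tree5)
  for (node in names(rec$content))
    expect_true(all(rec$content[[node]] %in%
                      union(rec2$content[[node]], rec2$patchy)))
  # removing a species never enlarges a multi-taxon node's content
  keep <- setdiff(names(taxon_of2), "Enoplida_a")
  shrunk <- lapply(base, function(e) e[keep])
  rec3 <- reconstruct_node_content(orthogroup_table(shrunk, species = keep),
                                   taxon_of2[keep], tree5)
  for (node in c("Nematoda", "Rhabditida", "Rhabditina_Tylenchina"))
    expect_true(all(rec3$content[[node]] %in% rec$content[[node]]))
})
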