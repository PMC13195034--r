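#!/usr/bin/env Rscript
# Cross-species regulator screen on the simulated candidates from 05:
# intersect the per-species candidate sets through a shared orthogroup
# table, extract the representative species' gene list, and filter to
# transcription factors by domain content. A Hormone_recep-bearing
# nuclear receptor planted among the pre-molt genes must survive to the
# final TF orthogroup set; collagen-like background genes must not.

suppressPackageStartupMessages(library(moltloss))

species <- paste0("sp", 1:4)
cands <- lapply(setNames(species, species), function(s) {
  g <- readLines(file.path("results/candidates", paste0(s, ".txt")))
  paste0(s, "_", g)
})

# one orthogroup per gene index, one member per species
genes <- sprintf("g%04d", 1:300)
tab <- orthogroup_table(
  setNames(lapply(genes, function(g)
    lapply(setNames(species, species), function(s) paste0(s, "_", g))),
    paste0("OG_", genes)),
  species = species)

kept <- intersect_candidate_ogs(cands, tab)
message(length(kept), " orthogroups contain a pre-molt candidate from all ",
        length(species), " species")

rep_genes <- species_gene_list(kept, tab, "sp1")
message(length(rep_genes), " sp1 genes assigned to those orthogroups")

# synthetic domain scan for sp1: one planted NR regulator (g0005, with the
# NR ligand-binding + zinc-finger domains), one planted homeobox TF
# (g0010), collagen-like domains elsewhere
domains <- rbind(
  data.frame(gene = "sp1_g0005", domain_accession = c("PF00104.26", "PF00105.14"),
             evalue = c(1e-25, 1e-18)),
  data.frame(gene = "sp1_g0010", domain_accession = "PF00046.25", evalue = 1e-12),
  data.frame(gene = paste0("sp1_", sprintf("g%04d", 11:40)),
             domain_accession = "PF01391", evalue = 1e-30))
tf <- filter_transcription_factors(rep_genes, domains, table = tab)
message("transcription-factor genes among them: ",
        paste(tf$tf_genes, collapse = ", "),
        " in orthogroups ", paste(tf$tf_ogs, collapse = ", "))
stopifnot("OG_g0005" %in% tf$tf_ogs)
message("the planted conserved NR regulator survives the whole screen")

nr_n <- count_nuclear_receptors(domains)
message("nuclear receptors in the sp1 domain scan (isoform-collapsed): ", nr_n)

write.table(data.frame(og = kept, tf = kept %in% tf$tf_ogs),
            "results/regulator_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
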