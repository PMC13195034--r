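#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analysis drivers:
# a presence/absence matrix evolved on the packaged taxon tree, an
# 11-species-style orthogroup table with planted origins, molting-cycle
# expression time courses with planted pre-molt oscillators, reciprocal
# hit tables with a planted ortholog bijection, and noisy rigid copies of
# two fold templates. Ground truth is saved next to each artifact.

suppressPackageStartupMessages(library(moltloss))

seed <- 20260928L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
fx <- molt_fixture()

message("presence/absence: 500 families, per-edge loss 0.08, 10% hidden absences")
pres <- gen_presence_matrix(fx$tree, n_families = 500, loss_rate = 0.08,
                            missing_rate = 0.1, seed = seed)
write_presence_matrix(pres$matrix, file.path(out, "presence.tsv"))
truth <- data.frame(family = names(pres$truth),
                    loss_count = vapply(pres$truth, `[[`, integer(1), "loss_count"))
write.table(truth, file.path(out, "presence_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("orthogroups: 300 OGs over 11 species with stepwise planted origins")
ogs <- gen_orthogroups(
  fx$taxa_tree,
  species_per_taxon = c(Rhabditina = 4, Tylenchina = 3, Spirurina = 2,
                        Trichinellida = 1, Enoplida = 1),
  n_ogs = 300,
  origin_probs = c(Nematoda = 0.10, Rhabditida = 0.15,
                   Rhabditina_Tylenchina = 0.15, Rhabditina = 0.40,
                   Tylenchina = 0.20),
  within_taxon_loss = 0.2, seed = seed)
write_orthogroups(ogs$table, file.path(out, "orthogroups.tsv"))
write.table(data.frame(species = names(ogs$taxon_of), taxon = ogs$taxon_of),
            file.path(out, "taxa.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ogs$truth, file.path(out, "orthogroup_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("expression: 4 species-like datasets, 30% pre-molt genes, noise 0.1")
time <- seq(0, 40, by = 1); molts <- c(10, 20, 30, 40)
for (i in 1:4) {
  sim <- gen_expression_timecourse(300, time, molts, frac_premolt = 0.3,
                                   noise_sd = 0.1, seed = seed + i)
  df <- data.frame(gene = rownames(sim$tc$expr), sim$tc$expr, check.names = FALSE)
  write.table(df, file.path(out, sprintf("expr_sp%d.tsv", i)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$planted, file.path(out, sprintf("expr_sp%d_planted.txt", i)))
}
meta <- data.frame(column = as.character(time), time_h = time,
                   molt_event = as.integer(time %in% molts))
write.table(meta, file.path(out, "expr_meta.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message("hit tables: 20-gene ortholog bijection plus 40 decoys per direction")
map <- setNames(paste0("spB_g", 1:20), paste0("spA_g", 1:20))
hits <- gen_hit_tables(list("spA->spB" = map), decoy_count = 40,
                       decoy_evalue_factor = 10, seed = seed)
for (key in names(hits)) {
  f <- file.path(out, paste0(sub("->", "__", key), ".tsv"))
  write.table(data.frame(qseqid = hits[[key]]$query, sseqid = hits[[key]]$subject,
                         evalue = hits[[key]]$evalue, bitscore = hits[[key]]$bitscore),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
}

message("structures: 15 noisy copies of each fold template (0.5 A noise)")
for (tmpl in c("three_helix", "beta_meander")) {
  d <- file.path(out, "structures", tmpl)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  copies <- gen_structure_pair(tmpl, 15, coord_noise = 0.5, seed = seed)
  for (id in names(copies$chains))
    write_structure_pdb(copies$chains[[id]], file.path(d, paste0(id, ".pdb")))
  write_structure_pdb(fold_template(tmpl), file.path(d, paste0(tmpl, "_template.pdb")))
}

message("done; artifacts under ", out)
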