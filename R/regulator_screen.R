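#' Transcription-factor domain panel
#'
#' Fixed panel of Pfam DNA-binding/TF domain accessions used to call
#' transcription factors from domain scans; includes the nuclear-receptor
#' ligand-binding domain Hormone_recep (PF00104) and the NR zinc finger
#' zf-C4 (PF00105). Version suffixes are ignored when matching.
#'
#' @return named character vector: domain name -> Pfam accession.
#' @export
tf_domain_panel <- function() {
  c(ARID = "PF01388", AT_hook = "PF02178", Basic = "PF01586", CUT = "PF02376",
    DM = "PF00751", Ets = "PF00178", Forkhead = "PF00250", GATA = "PF00320",
    GCM = "PF03615", HLH = "PF00010", HMG_box = "PF00505",
    Hairy_orange = "PF07527", Homeobox = "PF00046", Hormone_recep = "PF00104",
    OAR = "PF03826", P53 = "PF00870", P53_tetramer = "PF07710", PAX = "PF00292",
    Pou = "PF00157", HPD = "PF05044", RHD_DNA_bind = "PF00554", Runt = "PF00853",
    SCAN = "PF02023", SIM_C = "PF06621", `SRF-TF` = "PF00319", `T-box` = "PF00907",
    TBX = "PF12598", `TF_AP-2` = "PF03299", TF_Otx = "PF03529", bZIP_1 = "PF00170",
    bZIP_2 = "PF07716", `zf-C2H2` = "PF00096", `zf-C2HC` = "PF01530",
    `zf-C4` = "PF00105")
}

.strip_pfam_version <- function(x) sub("\\.[0-9]+$", "", x)

#' Intersect per-species candidate sets through orthogroups
#'
#' An orthogroup is kept iff, for every species, it contains at least one
#' gene from that species' candidate set. Adding a species can only shrink
#' the result; a species with an empty candidate set annihilates it.
#'
#' @param candidates_by_species named list: species -> candidate gene IDs.
#' @param table an `orthogroup_table` covering those species.
#' @return character vector of kept orthogroup IDs.
#' @export
intersect_candidate_ogs <- function(candidates_by_species, table) {
  sp <- names(candidates_by_species)
  stopifnot(all(sp %in% attr(table, "species")))
  empty <- sp[lengths(candidates_by_species) == 0L]
  if (length(empty)) {
    warning("empty candidate set for: ", paste(empty, collapse = ", "),
            "; intersection is empty")
    return(character(0))
  }
  keep <- vapply(table, function(entry) {
    all(vapply(sp, function(s) any(entry[[s]] %in% candidates_by_species[[s]]),
               logical(1)))
  }, logical(1))
  names(table)[keep]
}

#' Genes of one species across a set of orthogroups
#'
#' @param ogs orthogroup IDs.
#' @param table an `orthogroup_table`.
#' @param species a species key of the table.
#' @return sorted, de-duplicated character vector of gene IDs.
#' @export
species_gene_list <- function(ogs, table, species) {
  stopifnot(species %in% attr(table, "species"))
  genes <- unlist(lapply(table[ogs], function(e) e[[species]]), use.names = FALSE)
  sort(unique(as.character(genes %||% character(0))))
}

#' Filter a gene list to transcription factors by domain content
#'
#' A gene is kept iff it carries at least one panel domain with e-value
#' strictly below `threshold`; genes absent from the domain table carry no
#' domains. The orthogroups of the kept genes are reported.
#'
#' @param genes gene IDs.
#' @param domains domain table (data.frame gene, domain_accession, evalue).
#' @param panel accession vector, default [tf_domain_panel()].
#' @param table optional `orthogroup_table` to map kept genes back to OGs.
#' @param threshold e-value threshold, default 1e-5 (strict).
#' @return list with `tf_genes` and `tf_ogs` (character vectors; `tf_ogs`
#'   empty when no table given).
#' @export
filter_transcription_factors <- function(genes, domains, panel = tf_domain_panel(),
                                         table = NULL, threshold = 1e-5) {
  panel <- .strip_pfam_version(panel)
  dom <- domains[.strip_pfam_version(domains$domain_accession) %in% panel &
                   domains$evalue < threshold, , drop = FALSE]
  tf_genes <- sort(intersect(genes, unique(dom$gene)))
  tf_ogs <- character(0)
  if (!is.null(table) && length(tf_genes)) {
    keep <- vapply(table, function(e) any(unlist(e, use.names = FALSE) %in% tf_genes),
                   logical(1))
    tf_ogs <- names(table)[keep]
  }
  list(tf_genes = tf_genes, tf_ogs = tf_ogs)
}

#' Collapse isoform IDs to gene IDs
#'
#' Default rule strips a trailing isoform suffix (".2", "a", ".t3" ...);
#' an explicit map overrides the rule where provided.
#'
#' @param ids character vector of isoform or gene IDs.
#' @param map optional named character vector isoform -> gene.
#' @param suffix_pattern regex removed from the ID tail, default
#'   `"(\\.[0-9]+|\\.t[0-9]+|[a-z])$"`.
#' @return character vector of collapsed gene IDs.
#' @export
collapse_isoforms <- function(ids, map = NULL,
                              suffix_pattern = "(\\.[0-9]+|\\.t[0-9]+|[a-z])$") {
  out <- sub(suffix_pattern, "", ids)
  if (!is.null(map)) {
    hit <- ids %in% names(map)
    out[hit] <- unname(map[ids[hit]])
  }
  out
}

#' Count nuclear receptors from a domain-scan table
#'
#' A gene counts as a nuclear receptor when at least one of its isoforms
#' hits the NR ligand-binding domain Hormone_recep (PF00104) with e-value
#' strictly below `threshold`; isoforms of one gene are counted once.
#'
#' @param domains domain table (data.frame gene, domain_accession, evalue).
#' @param isoform_map optional explicit isoform -> gene map.
#' @param threshold e-value threshold, default 1e-5.
#' @return integer count of distinct NR genes.
#' @export
count_nuclear_receptors <- function(domains, isoform_map = NULL, threshold = 1e-5) {
  hit <- .strip_pfam_version(domains$domain_accession) == "PF00104" &
    domains$evalue < threshold
  length(unique(collapse_isoforms(domains$gene[hit], map = isoform_map)))
}
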