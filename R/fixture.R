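#' Packaged nematode taxon-level fixture
#'
#' A taxon-level tree of the nematode lineages relevant to ecdysone-receptor
#' evolution, with the named clades Tylenchina, Rhabditina,
#' Rhabditina_Tylenchina, Rhabditida and Nematoda, plus a taxon x family
#' presence matrix for `ecr`, `usp` and `hr3` encoding the published
#' presence/absence pattern: `ecr` is absent exactly in Caenorhabditis,
#' Tylenchomorpha, Strongyloididae and Alloionematidae; `usp` is absent in
#' those plus Panagrolaimidae, Cephalobomorpha and Strongylida (only
#' Steinernematidae retain both within Tylenchina); `hr3` is present
#' everywhere.
#'
#' @return list with `tree` (a `taxon_tree`), `presence` (presence matrix),
#'   and `taxa_tree` (the five-major-taxon tree with named ancestors used
#'   for orthogroup-content reconstruction).
#' @export
molt_fixture <- function() {
  dir <- system.file("extdata", "fixture", package = "moltloss")
  list(tree = parse_newick(readLines(file.path(dir, "nematode_taxa.nwk"))),
       presence = read_presence_matrix(file.path(dir, "presence.tsv")),
       taxa_tree = parse_newick(readLines(file.path(dir, "nr_taxa.nwk"))))
}
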