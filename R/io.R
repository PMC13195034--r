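#' Presence/absence state codes
#'
#' Cells of a presence matrix take one of three states: `"present"`,
#' `"absent"`, `"missing"`. On disk these are encoded `1`, `0`, `?`.
#' @export
PRESENCE_STATES <- c(present = "present", absent = "absent", missing = "missing")

.state_from_symbol <- c("1" = "present", "0" = "absent", "?" = "missing")
.symbol_from_state <- c(present = "1", absent = "0", missing = "?")

#' Read a taxon-by-gene-family presence matrix
#'
#' Dialect: TSV, header row `taxon` followed by family names; cells in
#' `{1, 0, ?}` mapping bijectively to present/absent/missing. Any other
#' symbol is rejected rather than coerced.
#'
#' @param path TSV file path.
#' @return character matrix with taxon rownames and family colnames, cells
#'   in `c("present","absent","missing")`.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("presence matrix needs a taxon column plus >= 1 family")
  taxa <- df[[1L]]
  if (anyDuplicated(taxa)) stop("duplicate taxon rows in presence matrix")
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- setdiff(unique(as.vector(m)), names(.state_from_symbol))
  if (length(bad)) stop("malformed presence symbols: ", paste(bad, collapse = ", "))
  out <- matrix(.state_from_symbol[as.vector(m)], nrow = nrow(m),
                dimnames = list(taxa, colnames(m)))
  out
}

#' Write a presence matrix in the `{1,0,?}` TSV dialect
#' @param mat presence matrix as returned by [read_presence_matrix()].
#' @param path output path.
#' @export
write_presence_matrix <- function(mat, path) {
  bad <- setdiff(unique(as.vector(mat)), names(.symbol_from_state))
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  enc <- matrix(.symbol_from_state[as.vector(mat)], nrow = nrow(mat),
                dimnames = dimnames(mat))
  df <- data.frame(taxon = rownames(enc), enc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OrthoFinder-style Orthogroups.tsv table
#'
#' First column is the orthogroup ID; one column per species; cells are
#' comma+space separated gene IDs or empty. A gene ID appearing in two
#' orthogroups triggers a warning and is kept only in the first.
#'
#' @param path TSV path.
#' @return an `orthogroup_table`: named list (orthogroup ID) of named lists
#'   (species) of character vectors (gene IDs, possibly empty), with a
#'   `species` attribute.
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty orthogroup file")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  species <- header[-1L]
  out <- list()
  seen <- character(0)
  for (i in seq_along(lines)[-1L]) {
    cells <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # trailing empty cells are dropped by strsplit; pad back
    if (length(cells) < length(header)) cells <- c(cells, rep("", length(header) - length(cells)))
    if (length(cells) != length(header))
      stop("ragged orthogroup row at line ", i, ": ", length(cells), " cells")
    og <- cells[1L]
    entry <- lapply(cells[-1L], function(x) {
      if (!nzchar(trimws(x))) return(character(0))
      trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    })
    names(entry) <- species
    genes <- unlist(entry, use.names = FALSE)
    dup <- intersect(genes, seen)
    if (length(dup)) {
      warning("gene IDs seen in an earlier orthogroup, dropping here: ",
              paste(dup, collapse = ", "))
      entry <- lapply(entry, setdiff, y = dup)
    }
    seen <- c(seen, setdiff(genes, dup))
    out[[og]] <- entry
  }
  if (anyDuplicated(names(out))) stop("duplicate orthogroup IDs")
  structure(out, species = species, class = "orthogroup_table")
}

#' Write an orthogroup table in the Orthogroups.tsv dialect
#' @param tab an `orthogroup_table`.
#' @param path output path.
#' @export
write_orthogroups <- function(tab, path) {
  species <- attr(tab, "species")
  lines <- paste(c("Orthogroup", species), collapse = "\t")
  for (og in names(tab)) {
    cells <- vapply(species, function(s) paste(tab[[og]][[s]], collapse = ", "),
                    character(1))
    lines <- c(lines, paste(c(og, cells), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct an orthogroup table from a list
#' @param x named list (orthogroup) of named lists (species) of gene-ID vectors.
#' @param species species order; defaults to the union found in `x`.
#' @return an `orthogroup_table`.
#' @export
orthogroup_table <- function(x, species = NULL) {
  if (is.null(species)) species <- unique(unlist(lapply(x, names)))
  x <- lapply(x, function(e) {
    full <- setNames(vector("list", length(species)), species)
    for (s in species) full[[s]] <- if (s %in% names(e)) as.character(e[[s]]) else character(0)
    full
  })
  structure(x, species = species, class = "orthogroup_table")
}

#' Read a tabular search-hit table (BLAST outfmt-6 compatible subset)
#'
#' Columns `qseqid, sseqid, evalue, bitscore` with header. Repeated
#' (query, subject) pairs are collapsed to the best hit (lowest e-value,
#' then highest bitscore).
#'
#' @param path TSV path.
#' @param direction optional "A->B" tag recording the database pair.
#' @return a `hit_table` data.frame with columns query, subject, evalue,
#'   bitscore.
#' @export
read_hit_table <- function(path, direction = NA_character_) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  names(df)[1:4] <- c("query", "subject", "evalue", "bitscore")
  hit_table(df, direction = direction)
}

#' Construct a hit table
#' @param df data.frame with columns query, subject, evalue, bitscore.
#' @param direction optional direction tag.
#' @return a `hit_table` data.frame (best hit kept per (query, subject) pair).
#' @export
hit_table <- function(df, direction = NA_character_) {
  stopifnot(all(c("query", "subject", "evalue", "bitscore") %in% names(df)))
  if (any(df$evalue < 0)) stop("negative e-values")
  ord <- order(df$query, df$subject, df$evalue, -df$bitscore)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df[, c("query", "subject")]), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "direction") <- direction
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Read a domain-annotation table
#'
#' TSV with header `gene, domain_accession, evalue` (Pfam-style accessions,
#' version suffix optional).
#'
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  names(df)[1:3] <- c("gene", "domain_accession", "evalue")
  if (any(df$evalue < 0)) stop("negative e-values in domain table")
  ok <- grepl("^PF[0-9]+(\\.[0-9]+)?$", df$domain_accession)
  if (!all(ok)) stop("non-Pfam accession(s): ",
                     paste(unique(df$domain_accession[!ok]), collapse = ", "))
  df
}
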