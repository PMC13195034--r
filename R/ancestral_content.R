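#' Assign the node of origin of one orthogroup
#'
#' Coverage rule: the orthogroup is placed at the named node whose set of
#' major taxa exactly matches the taxa represented (>= 1 gene) in the
#' orthogroup. When the represented taxa match no named node's taxon set,
#' the orthogroup is "patchy" and is assigned to each represented taxon
#' separately.
#'
#' @param entry one orthogroup entry (named list species -> gene vector).
#' @param taxon_of named character vector species -> major taxon.
#' @param taxon_tree `taxon_tree` whose leaves are the major taxa and whose
#'   named internal nodes are the candidate ancestors.
#' @return list with `origin` (node label or `NA` when patchy), `patchy`
#'   (logical), `taxa` (represented taxa).
#' @export
assign_og_origin <- function(entry, taxon_of, taxon_tree) {
  sp <- names(entry)[vapply(entry, length, integer(1)) > 0L]
  unknown <- setdiff(sp, names(taxon_of))
  if (length(unknown)) stop("species without taxon mapping: ",
                            paste(unknown, collapse = ", "))
  taxa <- sort(unique(unname(taxon_of[sp])))
  if (!length(taxa)) return(list(origin = NA_character_, patchy = FALSE, taxa = taxa))
  named <- which(!is.na(taxon_tree$labels))
  for (v in named[order(-vapply(named, function(v) length(tree_subtree_leaves(taxon_tree, v)), integer(1)))]) {
    under <- sort(taxon_tree$labels[tree_subtree_leaves(taxon_tree, v)])
    if (identical(under, taxa))
      return(list(origin = taxon_tree$labels[v], patchy = FALSE, taxa = taxa))
  }
  list(origin = NA_character_, patchy = TRUE, taxa = taxa)
}

#' Reconstruct ancestral orthogroup content per named node
#'
#' Content of a named node N is the set of orthogroups in which every major
#' taxon under N is represented by at least one gene (within-taxon nodes
#' therefore require only one gene from that taxon). Gains and losses are
#' reported along the chain of named ancestors (root -> ... -> taxon), and
#' per-species content (>= 1 gene in that species) is reported against the
#' species' taxon. Patchy orthogroups — whose represented taxa match no
#' named node — are excluded from multi-taxon ancestors and listed.
#'
#' @param table an `orthogroup_table`.
#' @param taxon_of named character vector species -> major taxon.
#' @param taxon_tree `taxon_tree` over the major taxa with named ancestors.
#' @return a `content_reconstruction`: list with `content` (named list of
#'   orthogroup ID sets per named node), `nodes` (data.frame: node,
#'   content_size, gain, loss, parent), `species` (data.frame: species,
#'   taxon, content_size, gain, loss), `patchy` (character vector of
#'   orthogroup IDs), `origins` (data.frame og, origin, patchy).
#' @export
reconstruct_node_content <- function(table, taxon_of, taxon_tree) {
  stopifnot(length(table) > 0L)
  species <- attr(table, "species")
  named <- which(!is.na(taxon_tree$labels))
  named_labels <- taxon_tree$labels[named]
  taxa_under <- lapply(named, function(v) sort(taxon_tree$labels[tree_subtree_leaves(taxon_tree, v)]))
  names(taxa_under) <- named_labels

  rep_taxa <- lapply(table, function(entry) {
    sp <- names(entry)[vapply(entry, length, integer(1)) > 0L]
    sort(unique(unname(taxon_of[sp])))
  })
  origins <- lapply(table, assign_og_origin, taxon_of = taxon_of,
                    taxon_tree = taxon_tree)
  patchy <- names(table)[vapply(origins, `[[`, logical(1), "patchy")]

  content <- lapply(named_labels, function(lab) {
    need <- taxa_under[[lab]]
    names(table)[vapply(rep_taxa, function(t) all(need %in% t), logical(1))]
  })
  names(content) <- named_labels

  # named-ancestor chain: parent of a named node = nearest named strict ancestor
  named_parent <- vapply(named, function(v) {
    p <- taxon_tree$parent[v]
    while (!is.na(p) && is.na(taxon_tree$labels[p])) p <- taxon_tree$parent[p]
    if (is.na(p)) NA_character_ else taxon_tree$labels[p]
  }, character(1))
  names(named_parent) <- named_labels

  gain <- loss <- setNames(integer(length(named_labels)), named_labels)
  for (lab in named_labels) {
    par <- named_parent[lab]
    if (!is.na(par)) {
      gain[lab] <- length(setdiff(content[[lab]], content[[par]]))
      loss[lab] <- length(setdiff(content[[par]], content[[lab]]))
    } else {
      gain[lab] <- length(content[[lab]])
    }
  }
  nodes <- data.frame(node = named_labels,
                      content_size = lengths(content)[named_labels],
                      gain = gain, loss = loss,
                      parent = unname(named_parent), row.names = NULL)

  sp_rows <- lapply(species, function(s) {
    cont <- names(table)[vapply(table, function(e) length(e[[s]]) > 0L, logical(1))]
    tx <- unname(taxon_of[s])
    anc <- if (!is.na(tx) && tx %in% named_labels) content[[tx]] else character(0)
    data.frame(species = s, taxon = tx, content_size = length(cont),
               gain = length(setdiff(cont, anc)), loss = length(setdiff(anc, cont)))
  })
  structure(list(content = content, nodes = nodes,
                 species = do.call(rbind, sp_rows), patchy = patchy,
                 origins = data.frame(
                   og = names(table),
                   origin = vapply(origins, `[[`, character(1), "origin"),
                   patchy = vapply(origins, `[[`, logical(1), "patchy"),
                   row.names = NULL)),
            class = "content_reconstruction")
}

#' @export
print.content_reconstruction <- function(x, ...) {
  cat("content_reconstruction over", nrow(x$nodes), "named nodes,",
      length(x$patchy), "patchy orthogroup(s)\n")
  print(x$nodes)
  invisible(x)
}
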