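#' Configuration for the absence-reliability rule
#'
#' An observed absence is called a reliable loss only when every member of
#' the same group (genus, or the smallest named clade containing the leaf)
#' lacks the gene; otherwise it is demoted to missing data. This separates
#' genuine loss from assembly/annotation dropout.
#'
#' @param groups named character vector: leaf label -> group label.
#' @param min_group_size smallest group size allowed to support a reliable
#'   absence call (default 1).
#' @return a `reliability_config`.
#' @export
reliability_config <- function(groups, min_group_size = 1L) {
  stopifnot(is.character(groups), !is.null(names(groups)), min_group_size >= 1L)
  structure(list(groups = groups, min_group_size = as.integer(min_group_size)),
            class = "reliability_config")
}

#' Demote unreliable absences to missing data
#'
#' A cell is kept `absent` only if every leaf in its group is `absent` for
#' that family (and the group reaches `min_group_size`); otherwise it
#' becomes `missing`. `present` and `missing` cells are never changed.
#'
#' @param mat presence matrix (rows = tree leaves).
#' @param tree the `taxon_tree` the rows live on.
#' @param cfg a [reliability_config()].
#' @return a presence matrix of the same shape.
#' @export
apply_reliability_rule <- function(mat, tree, cfg) {
  leaves <- tree_leaves(tree)
  unknown <- setdiff(rownames(mat), leaves)
  if (length(unknown)) stop("matrix rows not on the tree: ",
                            paste(unknown, collapse = ", "))
  untagged <- setdiff(rownames(mat), names(cfg$groups))
  if (length(untagged)) stop("leaf without group tag: ",
                             paste(untagged, collapse = ", "))
  out <- mat
  grp <- cfg$groups[rownames(mat)]
  for (fam in colnames(mat)) {
    for (g in unique(grp)) {
      rows <- which(grp == g)
      absent <- mat[rows, fam] == "absent"
      reliable <- all(mat[rows, fam] == "absent") && length(rows) >= cfg$min_group_size
      if (!reliable && any(absent)) out[rows[absent], fam] <- "missing"
    }
  }
  out
}

#' Dollo-parsimony loss mapping for one gene family
#'
#' Assumes a single gain: the family originates at the most recent common
#' ancestor of the leaves where it is present, and is lost on the minimal
#' set of edges explaining the absences. Missing leaves are uninformative
#' (compatible with either state); subtrees containing only missing leaves
#' generate no loss edge, which yields "lost at least N times" lower-bound
#' semantics. Ambiguous internal states resolve toward present (losses are
#' deferred tipward).
#'
#' @param tree a `taxon_tree`.
#' @param states named character vector over the tree leaves with values in
#'   `c("present","absent","missing")` (typically one presence-matrix
#'   column).
#' @param family family name carried into the result.
#' @return a `dollo_result`: list with `family`, `origin` (node index),
#'   `origin_label`, `loss_edges` (integer child-node indices),
#'   `loss_edge_labels`, `loss_count`, and `node_state` (character vector
#'   over all nodes, `"present"`/`"absent"`).
#' @export
dollo_map <- function(tree, states, family = "family") {
  leaves <- tree_leaves(tree)
  stopifnot(all(names(states) %in% leaves))
  states <- states[leaves[leaves %in% names(states)]]
  bad <- setdiff(unique(states), PRESENCE_STATES)
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  present_ids <- match(names(states)[states == "present"], tree$labels[seq_len(tree$n_tip)])
  if (!length(present_ids)) stop("family never observed: no present leaf")
  origin <- if (length(present_ids) == 1L) present_ids else tree_mrca(tree, present_ids)

  leaf_state <- setNames(rep("missing", tree$n_tip), leaves)
  leaf_state[names(states)] <- states
  has_present <- logical(tree$n_node)
  has_absent <- logical(tree$n_node)
  for (v in tree_postorder(tree)) {
    if (tree$is_tip[v]) {
      has_present[v] <- leaf_state[tree$labels[v]] == "present"
      has_absent[v] <- leaf_state[tree$labels[v]] == "absent"
    } else {
      kids <- tree$children[[v]]
      has_present[v] <- any(has_present[kids])
      has_absent[v] <- any(has_absent[kids])
    }
  }
  # maximal subtrees within the origin's subtree with no present leaf and
  # at least one absent leaf; each such subtree's stem edge is one loss
  in_origin <- tree_subtree(tree, origin)
  loss <- integer(0)
  for (v in setdiff(in_origin, origin)) {
    if (!has_present[v] && has_absent[v] && has_present[tree$parent[v]])
      loss <- c(loss, v)
  }
  loss <- sort(loss)
  node_state <- rep("absent", tree$n_node)
  keep <- in_origin
  for (l in loss) keep <- setdiff(keep, tree_subtree(tree, l))
  node_state[keep] <- "present"
  structure(
    list(family = family, origin = origin,
         origin_label = tree$labels[origin],
         loss_edges = loss,
         loss_edge_labels = tree$labels[loss],
         loss_count = length(loss),
         node_state = setNames(node_state, tree$labels)),
    class = "dollo_result")
}

#' @export
print.dollo_result <- function(x, ...) {
  lab <- ifelse(is.na(x$loss_edge_labels), paste0("node", x$loss_edges),
                x$loss_edge_labels)
  cat("dollo_result:", x$family, "-", x$loss_count, "loss event(s)",
      if (x$loss_count) paste0("[", paste(lab, collapse = ", "), "]") else "",
      "\n")
  invisible(x)
}

#' Count loss events per named clade
#'
#' A loss edge is attributed to clade C when the edge lies strictly within
#' C's subtree (its child node is a proper descendant of C's node); edges
#' inside no named clade are reported under `"other"`.
#'
#' @param result a [dollo_map()] result.
#' @param tree the same `taxon_tree`.
#' @param clade_names character vector of named clades (internal labels or
#'   leaf labels).
#' @return named integer vector over `clade_names` plus `"other"`.
#' @export
losses_by_clade <- function(result, tree, clade_names) {
  ids <- vapply(clade_names, tree_node_id, integer(1), tree = tree)
  counts <- setNames(integer(length(clade_names) + 1L), c(clade_names, "other"))
  for (child in result$loss_edges) {
    inside <- FALSE
    for (i in seq_along(ids)) {
      if (child != ids[i] && tree_is_descendant(tree, child, ids[i])) {
        counts[clade_names[i]] <- counts[clade_names[i]] + 1L
        inside <- TRUE
      }
    }
    if (!inside) counts["other"] <- counts["other"] + 1L
  }
  counts
}
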