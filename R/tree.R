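#' @useDynLib moltloss, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Rooted taxon tree
#'
#' A light rooted-tree container used throughout the package. Nodes are
#' indexed `1..n_node` with tips first (`1..n_tip`, ape convention); every
#' non-root node has exactly one parent. Internal newick labels that parse
#' as numbers are interpreted as bootstrap support values (0-100); other
#' internal labels are clade names and can be looked up with
#' [tree_node_id()].
#'
#' @param phy an [ape::phylo] object (rooted).
#' @return An object of class `taxon_tree`: a list with elements
#'   `n_tip`, `n_node`, `labels` (length `n_node`; may be `NA` for unnamed
#'   internal nodes), `parent` (node index of each node's parent, `NA` at
#'   the root), `children` (list of integer vectors), `root`, `is_tip`,
#'   and `support` (numeric, `NA` where absent).
#' @export
as_taxon_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  labels <- character(n_node)
  labels[seq_len(n_tip)] <- phy$tip.label
  support <- rep(NA_real_, n_node)
  inner <- phy$node.label
  if (!is.null(inner)) {
    for (i in seq_along(inner)) {
      lab <- inner[i]
      idx <- n_tip + i
      if (is.na(lab) || !nzchar(lab)) {
        labels[idx] <- NA_character_
      } else {
        num <- suppressWarnings(as.numeric(lab))
        if (!is.na(num)) {
          support[idx] <- num
          labels[idx] <- NA_character_
        } else {
          labels[idx] <- lab
        }
      }
    }
  } else {
    labels[(n_tip + 1):n_node] <- NA_character_
  }
  dup <- labels[seq_len(n_tip)][duplicated(labels[seq_len(n_tip)])]
  if (length(dup)) stop("duplicate leaf labels: ", paste(unique(dup), collapse = ", "))
  bad <- support[!is.na(support)]
  if (length(bad) && (any(bad < 0) || any(bad > 100)))
    stop("support values must lie in [0, 100]")
  parent <- rep(NA_integer_, n_node)
  children <- vector("list", n_node)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c <- phy$edge[e, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- which(is.na(parent) & seq_len(n_node) > n_tip)
  if (length(root) != 1L) root <- n_tip + 1L
  structure(
    list(n_tip = n_tip, n_node = n_node, labels = labels, parent = parent,
         children = children, root = root, is_tip = seq_len(n_node) <= n_tip,
         support = support),
    class = "taxon_tree")
}

#' Parse a newick string into a taxon tree
#'
#' Numeric internal-node labels are stored as bootstrap supports; other
#' internal labels name clades. Branch lengths, if present, are discarded:
#' all downstream mapping is topological.
#'
#' @param text a newick string ending in `";"`.
#' @return a [as_taxon_tree()] `taxon_tree`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick string")
  if (!endsWith(text, ";")) stop("newick string must end in ';'")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at character ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " unclosed at end of string")
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("failed to parse newick string")
  as_taxon_tree(phy)
}

#' Write a taxon tree as a canonical newick string
#'
#' Children are emitted in stored order; supports are written back as
#' numeric internal labels, clade names verbatim. `parse_newick()` followed
#' by `write_newick()` is the identity on canonicalised newick.
#'
#' @param tree a `taxon_tree`.
#' @return a newick string ending in `";"`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  rec <- function(v) {
    if (tree$is_tip[v]) return(tree$labels[v])
    kids <- vapply(tree$children[[v]], rec, character(1))
    lab <- if (!is.na(tree$support[v])) {
      format(tree$support[v], trim = TRUE, scientific = FALSE)
    } else if (!is.na(tree$labels[v])) tree$labels[v] else ""
    paste0("(", paste(kids, collapse = ","), ")", lab)
  }
  paste0(rec(tree$root), ";")
}

#' @export
print.taxon_tree <- function(x, ...) {
  named <- sum(!is.na(x$labels[!x$is_tip]))
  cat("taxon_tree:", x$n_tip, "tips,", x$n_node - x$n_tip, "internal nodes (",
      named, "named )\n")
  invisible(x)
}

#' Leaf labels of a tree
#' @param tree a `taxon_tree`.
#' @return character vector of tip labels.
#' @export
tree_leaves <- function(tree) tree$labels[seq_len(tree$n_tip)]

#' Node index for a label
#'
#' @param tree a `taxon_tree`.
#' @param label a leaf or clade name.
#' @return integer node index.
#' @export
tree_node_id <- function(tree, label) {
  hit <- which(!is.na(tree$labels) & tree$labels == label)
  if (length(hit) == 0L) stop("no node labelled '", label, "'")
  hit[1L]
}

# postorder node sequence (children before parents)
tree_postorder <- function(tree) {
  out <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, tree$children[[v]])
  }
  rev(out)
}

# all node indices in the subtree rooted at v (including v)
tree_subtree <- function(tree, v) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, u)
    stack <- c(stack, tree$children[[u]])
  }
  out
}

# leaf indices under v
tree_subtree_leaves <- function(tree, v) {
  s <- tree_subtree(tree, v)
  s[tree$is_tip[s]]
}

# most recent common ancestor of a set of node indices
tree_mrca <- function(tree, nodes) {
  stopifnot(length(nodes) >= 1L)
  path_to_root <- function(v) {
    p <- v
    while (!is.na(tree$parent[p[length(p)]])) p <- c(p, tree$parent[p[length(p)]])
    p
  }
  common <- path_to_root(nodes[1L])
  for (v in nodes[-1L]) common <- intersect(common, path_to_root(v))
  common[1L]
}

# TRUE if node v lies in the subtree rooted at anc (v == anc counts)
tree_is_descendant <- function(tree, v, anc) {
  while (!is.na(v)) {
    if (v == anc) return(TRUE)
    v <- tree$parent[v]
  }
  FALSE
}
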