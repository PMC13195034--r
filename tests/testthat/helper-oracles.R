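# Independent oracles and small generators used across the suite.

# random rooted tree with unique tip labels (topology only)
random_tree <- function(n_tips, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n_tips, br = NULL)
  phy$tip.label <- paste0("t", seq_len(n_tips))
  as_taxon_tree(phy)
}

# Dollo minimum-loss oracle by dynamic programming, independent of the
# package's maximal-subtree construction: Sankoff-style costs with
# present->absent = 1, absent->present forbidden, minimized over all
# feasible origins (single gain).
oracle_min_losses <- function(tree, states) {
  leaves <- tree_leaves(tree)
  obs <- setNames(rep("missing", tree$n_tip), leaves)
  obs[names(states)] <- states
  pres_ids <- which(obs[tree$labels[seq_len(tree$n_tip)]] == "present")
  stopifnot(length(pres_ids) > 0)
  post <- moltloss:::tree_postorder(tree)
  best <- Inf
  for (origin in seq_len(tree$n_node)) {
    under <- moltloss:::tree_subtree_leaves(tree, origin)
    if (!all(pres_ids %in% under)) next
    cp <- rep(NA_real_, tree$n_node)  # cost with node state = present
    ca <- rep(NA_real_, tree$n_node)  # cost with node state = absent
    for (v in post) {
      if (!moltloss:::tree_is_descendant(tree, v, origin)) next
      if (tree$is_tip[v]) {
        o <- obs[tree$labels[v]]
        cp[v] <- if (o %in% c("present", "missing")) 0 else Inf
        ca[v] <- if (o %in% c("absent", "missing")) 0 else Inf
      } else {
        kids <- tree$children[[v]]
        cp[v] <- sum(pmin(cp[kids], 1 + ca[kids]))
        ca[v] <- sum(ca[kids])
      }
    }
    best <- min(best, cp[origin])
  }
  best
}

# exhaustive loss-edge-subset enumeration (tiny trees only); validates the
# DP oracle itself on a handful of cases
oracle_min_losses_enum <- function(tree, states, max_k = 4L) {
  leaves <- tree_leaves(tree)
  obs <- setNames(rep("missing", tree$n_tip), leaves)
  obs[names(states)] <- states
  pres_ids <- which(obs[tree$labels[seq_len(tree$n_tip)]] == "present")
  for (k in 0:max_k) {
    for (origin in seq_len(tree$n_node)) {
      under <- moltloss:::tree_subtree_leaves(tree, origin)
      if (!all(pres_ids %in% under)) next
      edges <- setdiff(moltloss:::tree_subtree(tree, origin), origin)
      if (k > length(edges)) next
      subsets <- if (k == 0) list(integer(0)) else
        utils::combn(edges, k, simplify = FALSE)
      for (loss in subsets) {
        ok <- TRUE
        for (tip in seq_len(tree$n_tip)) {
          covered <- any(vapply(loss, function(l)
            moltloss:::tree_is_descendant(tree, tip, l), logical(1)))
          alive <- tip %in% under && !covered
          o <- obs[tree$labels[tip]]
          if (o == "present" && !alive) { ok <- FALSE; break }
          if (o == "absent" && alive) { ok <- FALSE; break }
        }
        if (ok) return(k)
      }
    }
  }
  NA_integer_
}

# random leaf-state vector
random_states <- function(tree, p = c(present = 0.5, absent = 0.3, missing = 0.2),
                          require_present = TRUE) {
  leaves <- tree_leaves(tree)
  repeat {
    s <- sample(names(p), length(leaves), replace = TRUE, prob = p)
    names(s) <- leaves
    if (!require_present || any(s == "present")) return(s)
  }
}

# adjusted Rand index between two hard partitions (independent of any
# clustering package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# five-major-taxon tree and fixture shared by several files
taxa_tree5 <- function() molt_fixture()$taxa_tree
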