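#' Homolog-screen configuration
#'
#' Thresholds follow the screening protocol: forward hits are kept below
#' e-value 1e-20, reciprocal hits below 1e-10 (both strict, "less than"),
#' up to three rounds of query expansion, and gene-tree clades are trusted
#' at bootstrap support >= 70 by default ("high support" made explicit).
#'
#' @param forward_evalue forward e-value threshold (strict), default 1e-20.
#' @param reciprocal_evalue reciprocal threshold (strict), default 1e-10.
#' @param max_rounds maximum screening rounds, default 3.
#' @param min_support clade bootstrap minimum, default 70.
#' @param reference_ids IDs of known members defining the target clade.
#' @return a `screen_config`.
#' @export
screen_config <- function(forward_evalue = 1e-20, reciprocal_evalue = 1e-10,
                          max_rounds = 3L, min_support = 70,
                          reference_ids = character(0)) {
  stopifnot(forward_evalue > 0, reciprocal_evalue > 0, max_rounds >= 1L)
  structure(list(forward_evalue = forward_evalue,
                 reciprocal_evalue = reciprocal_evalue,
                 max_rounds = as.integer(max_rounds),
                 min_support = min_support,
                 reference_ids = reference_ids),
            class = "screen_config")
}

# best hit per query: lowest e-value, ties by higher bitscore then
# lexicographic subject ID
.best_hits <- function(tab) {
  if (!nrow(tab)) return(tab)
  ord <- order(tab$query, tab$evalue, -tab$bitscore, tab$subject)
  tab <- tab[ord, , drop = FALSE]
  tab[!duplicated(tab$query), , drop = FALSE]
}

#' Reciprocal one-to-one top hits
#'
#' A (query, subject) pair is kept iff subject is query's best forward hit
#' with e-value strictly below the forward threshold, and query is
#' subject's best reverse hit strictly below the reciprocal threshold.
#' Mutual-best-hit logic makes the result one-to-one.
#'
#' @param forward `hit_table` A -> B.
#' @param reverse `hit_table` B -> A.
#' @param cfg a [screen_config()].
#' @return data.frame with columns query, subject (possibly 0 rows).
#' @export
reciprocal_top_hits <- function(forward, reverse, cfg = screen_config()) {
  empty <- data.frame(query = character(0), subject = character(0))
  if (!nrow(forward) || !nrow(reverse)) return(empty)
  fb <- .best_hits(forward)
  fb <- fb[fb$evalue < cfg$forward_evalue, , drop = FALSE]
  rb <- .best_hits(reverse)
  rb <- rb[rb$evalue < cfg$reciprocal_evalue, , drop = FALSE]
  if (!nrow(fb) || !nrow(rb)) return(empty)
  back <- setNames(rb$subject, rb$query)  # best reverse hit of each subject
  keep <- !is.na(back[fb$subject]) & back[fb$subject] == fb$query
  data.frame(query = fb$query[keep], subject = fb$subject[keep])
}

#' Iterative multi-round homolog screen
#'
#' Round 1 searches from the seed database; later rounds reuse genes
#' accepted in the previous round as queries against the species still
#' lacking an accepted gene. Iteration stops when a round adds nothing or
#' at `cfg$max_rounds`.
#'
#' @param seed_queries character vector of seed gene IDs (live in `seed_db`).
#' @param hit_provider named list of `hit_table`s keyed `"SRC->TGT"`, for
#'   every precomputed database pair.
#' @param species character vector of target species databases.
#' @param seed_db name of the seed database.
#' @param cfg a [screen_config()].
#' @return a `screen_result`: list with `rounds` (list of per-round added
#'   data.frames: species, gene, via), `accepted` (named list species ->
#'   gene IDs), `uncovered` (species never reached), `missing_tables`
#'   (pairs that had no table).
#' @export
iterative_screen <- function(seed_queries, hit_provider, species, seed_db,
                             cfg = screen_config()) {
  accepted <- setNames(vector("list", length(species)), species)
  rounds <- list()
  missing_tables <- character(0)
  if (!length(seed_queries)) {
    return(structure(list(rounds = rounds, accepted = accepted,
                          uncovered = species, missing_tables = missing_tables),
                     class = "screen_result"))
  }
  get_tab <- function(src, tgt) {
    key <- paste0(src, "->", tgt)
    if (is.null(hit_provider[[key]])) {
      missing_tables <<- unique(c(missing_tables, key))
      return(NULL)
    }
    hit_provider[[key]]
  }
  # query sets per source db for the coming round
  queries <- list()
  queries[[seed_db]] <- seed_queries
  for (r in seq_len(cfg$max_rounds)) {
    added <- data.frame(species = character(0), gene = character(0),
                        via = character(0))
    uncovered <- species[vapply(accepted[species], is.null, logical(1))]
    for (tgt in uncovered) {
      for (src in names(queries)) {
        fwd <- get_tab(src, tgt); rev <- get_tab(tgt, src)
        if (is.null(fwd) || is.null(rev)) next
        fwd <- fwd[fwd$query %in% queries[[src]], , drop = FALSE]
        pairs <- reciprocal_top_hits(fwd, rev, cfg)
        if (nrow(pairs)) {
          added <- rbind(added, data.frame(species = tgt, gene = pairs$subject,
                                           via = pairs$query))
        }
      }
    }
    added <- added[!duplicated(added[, c("species", "gene")]), , drop = FALSE]
    if (!nrow(added)) break
    rounds[[length(rounds) + 1L]] <- added
    queries <- split(added$gene, added$species)
    for (sp in names(queries)) accepted[[sp]] <- sort(unique(c(accepted[[sp]], queries[[sp]])))
  }
  structure(list(rounds = rounds, accepted = accepted,
                 uncovered = species[vapply(accepted[species], is.null, logical(1))],
                 missing_tables = missing_tables),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", length(x$rounds), "productive round(s);",
      sum(lengths(x$accepted) > 0), "species covered,",
      length(x$uncovered), "uncovered\n")
  invisible(x)
}

#' Validate candidates against the target clade of a gene tree
#'
#' The target clade is the smallest node containing all reference members.
#' A candidate is accepted iff it descends from that node and the node's
#' bootstrap support meets the configured minimum. If the reference members
#' only resolve at the root, validation proceeds with the root (accept-all)
#' and is flagged low-confidence.
#'
#' @param gene_tree `taxon_tree` whose tips include candidates and
#'   reference members; internal numeric labels are bootstrap supports.
#' @param candidates character vector of candidate tip IDs.
#' @param cfg a [screen_config()] carrying `reference_ids` and `min_support`.
#' @return list with `accepted`, `rejected` (data.frame id, reason in
#'   `{outside-clade, low-support}`), `clade_node`, `support`,
#'   `low_confidence` (logical).
#' @export
clade_validate <- function(gene_tree, candidates, cfg) {
  tips <- tree_leaves(gene_tree)
  stopifnot(all(cfg$reference_ids %in% tips), all(candidates %in% tips))
  if (!length(cfg$reference_ids)) stop("no reference clade members configured")
  ref_ids <- match(cfg$reference_ids, gene_tree$labels[seq_len(gene_tree$n_tip)])
  node <- if (length(ref_ids) == 1L) gene_tree$parent[ref_ids] else tree_mrca(gene_tree, ref_ids)
  low_confidence <- FALSE
  if (node == gene_tree$root) {
    warning("reference members only resolve at the root; accepting all, flagged low-confidence")
    low_confidence <- TRUE
  }
  support <- gene_tree$support[node]
  clade_tips <- gene_tree$labels[tree_subtree_leaves(gene_tree, node)]
  inside <- candidates %in% clade_tips
  support_ok <- low_confidence || (!is.na(support) && support >= cfg$min_support)
  accepted <- candidates[inside & support_ok]
  reason <- character(0); rej <- character(0)
  if (any(!inside)) { rej <- c(rej, candidates[!inside]); reason <- c(reason, rep("outside-clade", sum(!inside))) }
  if (!support_ok && any(inside)) { rej <- c(rej, candidates[inside]); reason <- c(reason, rep("low-support", sum(inside))) }
  list(accepted = accepted,
       rejected = data.frame(id = rej, reason = reason),
       clade_node = node, support = support, low_confidence = low_confidence)
}
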