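#' Synthetic-data generators
#'
#' Every generator is deterministic given its parameters and `seed`, and
#' returns the generated artifact together with a `truth` record that
#' fully determines the expected output of the consuming stage (up to the
#' stated noise).
#'
#' @name synthetic
NULL

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a presence/absence matrix by single-gain/multiple-loss evolution
#'
#' Each family originates at the root; along every edge the subtree is
#' converted to absent with probability `loss_rate` (no regain by default —
#' Dollo-consistent); observed absent cells are corrupted to missing with
#' probability `missing_rate`.
#'
#' @param tree a `taxon_tree`.
#' @param n_families number of gene families (columns).
#' @param loss_rate per-edge loss probability in `[0, 1)`.
#' @param missing_rate probability an absent cell is observed as missing.
#' @param seed integer seed.
#' @param regain_rate per-edge probability that a lost family reappears
#'   (default 0; a probe for the single-gain assumption's failure mode).
#' @return list with `matrix` (presence matrix) and `truth` (list per
#'   family: `loss_edges` child-node indices of effective loss events,
#'   `loss_count`).
#' @export
gen_presence_matrix <- function(tree, n_families, loss_rate, missing_rate = 0,
                                seed = 1L, regain_rate = 0) {
  stopifnot(loss_rate >= 0, loss_rate < 1, missing_rate >= 0, missing_rate <= 1)
  leaves <- tree_leaves(tree)
  .with_seed(seed, {
    fams <- paste0("fam", seq_len(n_families))
    mat <- matrix("present", length(leaves), n_families,
                  dimnames = list(leaves, fams))
    truth <- vector("list", n_families)
    names(truth) <- fams
    preorder <- rev(tree_postorder(tree))
    for (f in seq_len(n_families)) {
      state <- rep(TRUE, tree$n_node)  # present?
      loss_edges <- integer(0)
      for (v in preorder) {
        if (v == tree$root) next
        p <- tree$parent[v]
        if (state[p]) {
          if (stats::runif(1) < loss_rate) {
            state[v] <- FALSE
            loss_edges <- c(loss_edges, v)
          } else state[v] <- TRUE
        } else {
          state[v] <- regain_rate > 0 && stats::runif(1) < regain_rate
        }
      }
      tips <- which(tree$is_tip)
      absent <- tips[!state[tips]]
      mat[tree$labels[absent], f] <- ifelse(stats::runif(length(absent)) < missing_rate,
                                            "missing", "absent")
      truth[[f]] <- list(loss_edges = sort(loss_edges),
                         loss_count = length(loss_edges))
    }
    list(matrix = mat, truth = truth, seed = seed)
  })
}

#' Simulate an orthogroup table with known nodes of origin
#'
#' Species are named `<taxon>_sp<i>`. Each orthogroup's origin is drawn
#' from `origin_probs` over the named nodes of `taxon_tree`; members are
#' placed in all species under the origin and thinned per species with
#' probability `within_taxon_loss`. "Clean" orthogroups (the default)
#' retain at least one member in every descendant major taxon so that the
#' coverage rule recovers the planted origin exactly.
#'
#' @param taxon_tree `taxon_tree` over the major taxa with named ancestors.
#' @param species_per_taxon named integer vector taxon -> species count.
#' @param n_ogs number of orthogroups.
#' @param origin_probs named numeric vector over named nodes, summing to 1.
#' @param within_taxon_loss per-species thinning probability.
#' @param seed integer seed.
#' @param clean guarantee taxon-level coverage of the origin (default TRUE).
#' @return list with `table` (an `orthogroup_table`), `taxon_of` (named
#'   species -> taxon), `truth` (data.frame og, origin).
#' @export
gen_orthogroups <- function(taxon_tree, species_per_taxon, n_ogs, origin_probs,
                            within_taxon_loss = 0, seed = 1L, clean = TRUE) {
  stopifnot(abs(sum(origin_probs) - 1) < 1e-8)
  named <- taxon_tree$labels[!is.na(taxon_tree$labels)]
  stopifnot(all(names(origin_probs) %in% named))
  taxa <- tree_leaves(taxon_tree)
  stopifnot(all(names(species_per_taxon) %in% taxa))
  species <- unlist(lapply(names(species_per_taxon), function(tx)
    paste0(tx, "_sp", seq_len(species_per_taxon[[tx]]))))
  taxon_of <- setNames(rep(names(species_per_taxon), species_per_taxon), species)
  .with_seed(seed, {
    ogs <- sprintf("OG%07d", seq_len(n_ogs))
    origins <- sample(names(origin_probs), n_ogs, replace = TRUE,
                      prob = origin_probs)
    tab <- vector("list", n_ogs)
    names(tab) <- ogs
    for (i in seq_len(n_ogs)) {
      node <- tree_node_id(taxon_tree, origins[i])
      under_taxa <- taxon_tree$labels[tree_subtree_leaves(taxon_tree, node)]
      members <- species[taxon_of[species] %in% under_taxa]
      keep <- members[stats::runif(length(members)) >= within_taxon_loss]
      if (clean) {
        for (tx in under_taxa) {
          tx_sp <- members[taxon_of[members] == tx]
          if (!any(tx_sp %in% keep)) keep <- c(keep, sample(tx_sp, 1L))
        }
      }
      entry <- lapply(setNames(species, species), function(s)
        if (s %in% keep) paste0(ogs[i], "_", s, "_g1") else character(0))
      tab[[i]] <- entry
    }
    list(table = orthogroup_table(tab, species = species),
         taxon_of = taxon_of,
         truth = data.frame(og = ogs, origin = origins), seed = seed)
  })
}

#' Simulate molting-cycle expression time courses
#'
#' A planted fraction of genes carries Gaussian expression bumps peaking
#' `peak_offset` hours before every molt event; background genes are flat
#' or carry bumps at random phases. Additive Gaussian noise with standard
#' deviation `noise_sd * amplitude` is applied and values are clipped at 0.
#'
#' @param n_genes number of genes.
#' @param time numeric time grid (hours).
#' @param molt_times ordered molt-event times within the grid.
#' @param frac_premolt planted fraction in `[0, 1]`, default 0.3.
#' @param peak_offset hours before each molt at which planted genes peak
#'   (> 0), default 2.
#' @param amplitude bump height above baseline, default 10.
#' @param noise_sd noise SD as a fraction of amplitude, default 0.1.
#' @param seed integer seed.
#' @param baseline baseline expression, default 2.
#' @param bump_sd Gaussian bump width (hours), default 1.
#' @return list with `tc` (an [expression_timecourse()]) and `truth`
#'   (list: `planted` gene IDs, `peak_offset`).
#' @export
gen_expression_timecourse <- function(n_genes, time, molt_times,
                                      frac_premolt = 0.3, peak_offset = 2,
                                      amplitude = 10, noise_sd = 0.1, seed = 1L,
                                      baseline = 2, bump_sd = 1) {
  stopifnot(frac_premolt >= 0, frac_premolt <= 1, peak_offset > 0)
  .with_seed(seed, {
    genes <- paste0("g", sprintf("%04d", seq_len(n_genes)))
    n_planted <- round(frac_premolt * n_genes)
    planted <- if (n_planted) genes[seq_len(n_planted)] else character(0)
    bumps <- function(centers) {
      rowSums(vapply(centers, function(ct) exp(-(time - ct)^2 / (2 * bump_sd^2)),
                     numeric(length(time))))
    }
    expr <- matrix(baseline, n_genes, length(time),
                   dimnames = list(genes, as.character(time)))
    for (i in seq_len(n_genes)) {
      if (i <= n_planted) {
        expr[i, ] <- baseline + amplitude * bumps(molt_times - peak_offset)
      } else if (stats::runif(1) < 0.5) {
        centers <- stats::runif(length(molt_times), min(time), max(time))
        expr[i, ] <- baseline + amplitude * bumps(centers)
      }
    }
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd * amplitude),
                          nrow = n_genes)
    expr[expr < 0] <- 0
    list(tc = expression_timecourse(expr, time, molt_times),
         truth = list(planted = planted, peak_offset = peak_offset),
         seed = seed)
  })
}

#' Idealized C-alpha fold templates
#'
#' Deterministic toy folds used by [gen_structure_pair()]: a three-helix
#' bundle and an extended beta-meander, both buildable at any length
#' >= 120 residues.
#'
#' @param name `"three_helix"` or `"beta_meander"`.
#' @param length chain length in residues, default 160.
#' @return a [structure_chain()].
#' @export
fold_template <- function(name = c("three_helix", "beta_meander"), length = 160L) {
  name <- match.arg(name)
  n <- as.integer(length)
  if (name == "three_helix") {
    seg <- n %/% 3L
    lens <- c(seg, seg, n - 2L * seg)
    # ideal alpha helix: radius 2.3 A, rise 1.5 A, 100 deg/residue
    helix <- function(len, origin, up) {
      i <- seq_len(len) - 1L
      ang <- i * 100 * pi / 180
      z <- i * 1.5 * if (up) 1 else -1
      cbind(2.3 * cos(ang) + origin[1], 2.3 * sin(ang) + origin[2], z + origin[3])
    }
    h1 <- helix(lens[1], c(0, 0, 0), TRUE)
    h2 <- helix(lens[2], c(9, 0, h1[lens[1], 3]), FALSE)
    h3 <- helix(lens[3], c(4.5, 8, 0), TRUE)
    xyz <- rbind(h1, h2, h3)
  } else {
    # beta meander: straight strands (rise 3.3 A), 4.8 A apart, alternating
    strand_len <- 20L
    xyz <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      k <- (i - 1L) %/% strand_len        # strand index
      r <- (i - 1L) %% strand_len         # position within strand
      zig <- if (r %% 2L == 0L) 0 else 0.9
      pos <- if (k %% 2L == 0L) r else strand_len - 1L - r
      xyz[i, ] <- c(4.8 * k + zig, 3.3 * pos, 1.2 * zig)
    }
  }
  structure_chain(xyz, id = name)
}

#' Simulate noisy rigid copies of a fold template
#'
#' Each copy is a uniformly random proper rotation plus translation of the
#' template with isotropic Gaussian coordinate noise.
#'
#' @param template a [structure_chain()] or a [fold_template()] name.
#' @param n_copies number of copies.
#' @param coord_noise isotropic noise SD in Angstrom.
#' @param seed integer seed.
#' @return list with `chains` (named list of [structure_chain()]s) and
#'   `truth` (data.frame id, template).
#' @export
gen_structure_pair <- function(template, n_copies, coord_noise = 0.5, seed = 1L) {
  if (is.character(template)) template <- fold_template(template)
  .with_seed(seed, {
    chains <- vector("list", n_copies)
    ids <- paste0(template$id, "_copy", seq_len(n_copies))
    for (i in seq_len(n_copies)) {
      R <- .random_rotation()
      t_vec <- stats::runif(3, -20, 20)
      xyz <- template$xyz %*% t(R) + matrix(t_vec, nrow(template$xyz), 3, byrow = TRUE)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, coord_noise), nrow(xyz))
      chains[[i]] <- structure_chain(xyz, id = ids[i])
    }
    names(chains) <- ids
    list(chains = chains,
         truth = data.frame(id = ids, template = template$id), seed = seed)
  })
}

# uniform random proper rotation (QR of a Gaussian matrix, det fixed to +1)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Simulate reciprocal-hit tables with a planted ortholog bijection
#'
#' True ortholog pairs receive reciprocal best e-values below 1e-25;
#' decoy hits receive e-values `decoy_evalue_factor` times worse. E-values
#' are reported to two significant digits, as in tabular search output, so
#' decoys only marginally worse than the true hit can collide with it and
#' steal the top rank through the deterministic tie-break.
#'
#' @param ortholog_map named list keyed `"A->B"`; each element a named
#'   character vector (names = A genes, values = B genes, a bijection).
#' @param decoy_count decoys per direction.
#' @param decoy_evalue_factor multiplicative e-value handicap (> 1).
#' @param seed integer seed.
#' @return named list of `hit_table`s keyed `"A->B"` and `"B->A"` for each
#'   mapped pair, with a `truth` attribute carrying the bijections.
#' @export
gen_hit_tables <- function(ortholog_map, decoy_count = 0,
                           decoy_evalue_factor = 10, seed = 1L) {
  stopifnot(decoy_evalue_factor > 1 || decoy_count == 0)
  .with_seed(seed, {
    out <- list()
    for (key in names(ortholog_map)) {
      ab <- strsplit(key, "->", fixed = TRUE)[[1]]
      map <- ortholog_map[[key]]
      make_dir <- function(qs, ss, dir_key) {
        ev <- signif(10^stats::runif(length(qs), -35, -26), 2)
        bits <- signif(-log10(ev) * 2, 2)
        df <- data.frame(query = qs, subject = ss, evalue = ev, bitscore = bits)
        if (decoy_count > 0) {
          qi <- sample(seq_along(qs), decoy_count, replace = TRUE)
          wrong <- vapply(qi, function(k) {
            pool <- setdiff(ss, ss[k])
            if (length(pool)) sample(pool, 1L) else ss[k]
          }, character(1))
          dv <- signif(ev[qi] * decoy_evalue_factor, 2)
          df <- rbind(df, data.frame(query = qs[qi], subject = wrong,
                                     evalue = dv, bitscore = signif(-log10(dv) * 2, 2)))
        }
        hit_table(df, direction = dir_key)
      }
      out[[key]] <- make_dir(names(map), unname(map), key)
      rkey <- paste0(ab[2], "->", ab[1])
      out[[rkey]] <- make_dir(unname(map), names(map), rkey)
    }
    attr(out, "truth") <- ortholog_map
    out
  })
}
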