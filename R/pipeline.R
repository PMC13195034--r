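#' Run the analysis pipeline from a configuration
#'
#' Executes the configured stage blocks in dependency order, writing every
#' stage's outputs plus a provenance record (package version, config hash,
#' seed) under `config$outdir`. Re-running with an identical config and
#' seed is byte-identical. On a stage error a `<stage>.failed` marker is
#' left in the output directory and the error names the stage.
#'
#' Recognized stage blocks (all optional):
#' \describe{
#'   \item{simulate}{`list(presence = list(...), expression = list(...))` —
#'     generator arguments for [gen_presence_matrix()] (plus `tree` path)
#'     and [gen_expression_timecourse()]; outputs written as TSV.}
#'   \item{losses}{`tree`, `matrix` (paths), optional `groups` (TSV
#'     leaf/group), `clades` (character); runs the reliability rule and
#'     Dollo mapping per family; writes `losses.tsv`.}
#'   \item{ancestral}{`orthogroups`, `taxa` (TSV species/taxon), `tree`
#'     (paths); writes `content.tsv`.}
#'   \item{cluster_expression}{`expr`, `meta` (paths), `clusters`,
#'     optional `smooth_w` (0 = off), `standardize`, `delta`, `majority`;
#'     writes `candidates.txt` and `clusters.tsv`.}
#'   \item{struct_classify}{`queries`, `refs` (directories of PDB files),
#'     optional `norm`, `min_len`; writes `tm_matrix.tsv`, `classes.tsv`.}
#' }
#'
#' @param config a named list, or a path to a YAML file holding one; must
#'   contain `outdir`, may contain `seed` (default 1).
#' @return invisibly, a run report: list of per-stage output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir))
  known <- c("outdir", "seed", "log_level", "simulate", "losses", "ancestral",
             "cluster_expression", "struct_classify")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  outdir <- config$outdir
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list()

  run_stage <- function(name, fn) {
    if (is.null(config[[name]])) return(invisible(NULL))
    message("[moltloss] stage: ", name)
    res <- tryCatch(fn(config[[name]]), error = function(e) {
      file.create(file.path(outdir, paste0(name, ".failed")))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report[[name]] <<- res
  }

  run_stage("simulate", function(blk) {
    outs <- character(0)
    if (!is.null(blk$presence)) {
      p <- blk$presence
      tree <- parse_newick(readLines(p$tree))
      sim <- gen_presence_matrix(tree, n_families = p$n_families,
                                 loss_rate = p$loss_rate,
                                 missing_rate = p$missing_rate %||% 0,
                                 seed = seed)
      out <- file.path(outdir, "sim_presence.tsv")
      write_presence_matrix(sim$matrix, out)
      outs <- c(outs, out)
    }
    if (!is.null(blk$expression)) {
      e <- blk$expression
      sim <- gen_expression_timecourse(
        n_genes = e$n_genes, time = e$time, molt_times = e$molt_times,
        frac_premolt = e$frac_premolt %||% 0.3,
        peak_offset = e$peak_offset %||% 2,
        noise_sd = e$noise_sd %||% 0.1, seed = seed)
      out <- file.path(outdir, "sim_expression.tsv")
      df <- data.frame(gene = rownames(sim$tc$expr), sim$tc$expr,
                       check.names = FALSE)
      utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
      meta <- data.frame(column = as.character(sim$tc$time),
                         time_h = sim$tc$time,
                         molt_event = as.integer(sim$tc$time %in% sim$tc$molts))
      utils::write.table(meta, file.path(outdir, "sim_expression_meta.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- c(outs, out)
    }
    outs
  })

  run_stage("losses", function(blk) {
    tree <- parse_newick(readLines(blk$tree))
    mat <- read_presence_matrix(blk$matrix)
    groups <- if (!is.null(blk$groups)) {
      g <- utils::read.delim(blk$groups)
      setNames(g[[2L]], g[[1L]])
    } else setNames(rownames(mat), rownames(mat))  # leaf = its own group
    mat <- apply_reliability_rule(mat, tree, reliability_config(groups))
    clades <- blk$clades %||% character(0)
    rows <- lapply(colnames(mat), function(fam) {
      res <- dollo_map(tree, mat[, fam], family = fam)
      row <- data.frame(family = fam, total_losses = res$loss_count,
                        loss_edges = paste(ifelse(is.na(res$loss_edge_labels),
                                                  paste0("node", res$loss_edges),
                                                  res$loss_edge_labels),
                                           collapse = ","))
      if (length(clades)) {
        bc <- losses_by_clade(res, tree, clades)
        for (cl in names(bc)) row[[cl]] <- bc[[cl]]
      }
      row
    })
    out <- file.path(outdir, "losses.tsv")
    utils::write.table(do.call(rbind, rows), out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out
  })

  run_stage("ancestral", function(blk) {
    tab <- read_orthogroups(blk$orthogroups)
    taxa <- utils::read.delim(blk$taxa)
    taxon_of <- setNames(taxa[[2L]], taxa[[1L]])
    tree <- parse_newick(readLines(blk$tree))
    rec <- reconstruct_node_content(tab, taxon_of, tree)
    nodes <- rec$nodes
    nodes$patchy_count <- length(rec$patchy)
    out <- file.path(outdir, "content.tsv")
    utils::write.table(nodes, out, sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  run_stage("cluster_expression", function(blk) {
    tc <- read_expression(blk$expr, blk$meta)
    tc <- collapse_replicates_and_merge(tc)
    w <- blk$smooth_w %||% 0L
    if (w >= 3L) tc <- smooth_windows(tc, w)
    X <- if (isFALSE(blk$standardize)) tc$expr else standardize_rows(tc$expr)
    fit <- fuzzy_cmeans(X, c = blk$clusters, seed = seed)
    sel <- select_premolt_clusters(fit, tc, delta = blk$delta %||% 0.25,
                                   majority = blk$majority %||% 0.5)
    out <- file.path(outdir, "candidates.txt")
    writeLines(sel$candidates, out)
    utils::write.table(sel$per_cluster, file.path(outdir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  run_stage("struct_classify", function(blk) {
    load_dir <- function(d) {
      files <- sort(list.files(d, pattern = "\\.pdb$", full.names = TRUE))
      chains <- lapply(files, read_structure_ca)
      names(chains) <- sub("\\.pdb$", "", basename(files))
      chains
    }
    queries <- lbd_length_filter(load_dir(blk$queries), blk$min_len %||% 151L)
    refs <- lbd_length_filter(load_dir(blk$refs), blk$min_len %||% 151L)
    sm <- classify_against_references(queries, refs,
                                      norm = blk$norm %||% "reference")
    out <- file.path(outdir, "tm_matrix.tsv")
    utils::write.table(data.frame(query = rownames(sm$scores), sm$scores,
                                  check.names = FALSE),
                       out, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(query = names(sm$class), class = sm$class,
                                  tied = sm$tied),
                       file.path(outdir, "classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  prov <- list(tool = "moltloss",
               version = as.character(utils::packageVersion("moltloss")),
               config_md5 = unname(tools::md5sum(cfg_file)),
               seed = seed,
               outputs = unname(unlist(report)))
  unlink(cfg_file)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
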