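#' Drop ligand-binding domains that are too short
#'
#' Chains shorter than `min_len` residues are removed; with the default of
#' 151, a 150-residue domain is the longest excluded length, focusing the
#' comparison on full-length, functional LBDs.
#'
#' @param chains list of [structure_chain()]s.
#' @param min_len minimum retained length, default 151.
#' @return the retained chains (possibly empty list).
#' @export
lbd_length_filter <- function(chains, min_len = 151L) {
  chains[vapply(chains, length, integer(1)) >= min_len]
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper-rotation superposition of `P` onto `Q` over the
#' given correspondence; reflections are excluded even for degenerate
#' noise configurations.
#'
#' @param P n x 3 coordinates (or a [structure_chain()]).
#' @param Q n x 3 coordinates (or a [structure_chain()]).
#' @param pairs 2-column integer matrix of (P-index, Q-index) pairs;
#'   default pairs residues positionally (requires equal lengths).
#' @return a `superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom over the pairs), and
#'   `transform(X)` applying the map `X %*% t(R) + t` to new coordinates.
#' @export
kabsch_superpose <- function(P, Q, pairs = NULL) {
  P <- .coords(P); Q <- .coords(Q)
  if (is.null(pairs)) {
    stopifnot(nrow(P) == nrow(Q))
    pairs <- cbind(seq_len(nrow(P)), seq_len(nrow(P)))
  }
  if (nrow(pairs) < 3L) stop("need at least 3 correspondence pairs")
  A <- P[pairs[, 1L], , drop = FALSE]
  B <- Q[pairs[, 2L], , drop = FALSE]
  ac <- colMeans(A); bc <- colMeans(B)
  Ac <- sweep(A, 2L, ac); Bc <- sweep(B, 2L, bc)
  C <- crossprod(Ac, Bc)
  sv <- svd(C)
  if (sv$d[2L] < 1e-12) stop("degenerate (collinear) configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- bc - as.vector(R %*% ac)
  moved <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Bc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd,
       transform = function(X) sweep(.coords(X) %*% t(R), 2L, t_vec, `+`))
}

.coords <- function(x) {
  if (inherits(x, "structure_chain")) x$xyz else as.matrix(x)
}

#' TM-score normalization distance scale
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at 0.5 Angstrom (the
#' clamp is active for all L <= 21).
#'
#' @param L_norm normalization length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L_norm) {
  if (L_norm < 3L) stop("normalization length below 3")
  if (L_norm <= 15) return(0.5)
  max(0.5, 1.24 * (L_norm - 15)^(1 / 3) - 1.8)
}

#' TM-score of a fixed residue correspondence
#'
#' `TM = (1/L_norm) sum_i 1 / (1 + (d_i/d0)^2)`, maximized over the rigid
#' superposition of the aligned set: the score is refined by repeatedly
#' superposing on the close-pair subset (d below a growing cutoff) and
#' keeping the best value, as in the reference TM-score procedure.
#'
#' @param P query coordinates or [structure_chain()].
#' @param Q_reference reference coordinates or [structure_chain()].
#' @param pairs 2-column correspondence matrix (default positional).
#' @param L_norm normalization length, default the reference length.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(P, Q_reference, pairs = NULL, L_norm = NULL) {
  P <- .coords(P); Q <- .coords(Q_reference)
  if (is.null(pairs)) {
    stopifnot(nrow(P) == nrow(Q))
    pairs <- cbind(seq_len(nrow(P)), seq_len(nrow(P)))
  }
  if (is.null(L_norm)) L_norm <- nrow(Q)
  d0 <- tm_d0(L_norm)
  A <- P[pairs[, 1L], , drop = FALSE]
  B <- Q[pairs[, 2L], , drop = FALSE]
  score_for <- function(sub) {
    if (length(sub) < 3L) return(NA_real_)
    sp <- tryCatch(kabsch_superpose(A, B, cbind(sub, sub)),
                   error = function(e) NULL)
    if (is.null(sp)) return(NA_real_)
    d <- sqrt(rowSums((sp$transform(A) - B)^2))
    sum(1 / (1 + (d / d0)^2)) / L_norm
  }
  best <- score_for(seq_len(nrow(A)))
  if (is.na(best)) stop("degenerate aligned set")
  # subset refinement: superpose on close pairs at growing cutoffs
  for (cut in c(d0, 2 * d0, 4 * d0)) {
    sub <- seq_len(nrow(A))
    for (it in 1:5) {
      sp <- tryCatch(kabsch_superpose(A, B, cbind(sub, sub)),
                     error = function(e) NULL)
      if (is.null(sp)) break
      d_all <- sqrt(rowSums((sp$transform(A) - B)^2))
      s <- sum(1 / (1 + (d_all / d0)^2)) / L_norm
      if (s > best) best <- s
      new_sub <- which(d_all < cut)
      if (length(new_sub) < 3L || identical(new_sub, sub)) break
      sub <- new_sub
    }
  }
  best
}

#' Iterative TM-style structural alignment of two CA traces
#'
#' A simplified TM-align-like heuristic: correspondences are seeded from
#' gapless sliding offsets and fragment superpositions (fragment length
#' `min(L, frag_len)`), then each seed is refined by alternating (i) rigid
#' superposition on the current pairs, (ii) per-pair similarity
#' `1/(1 + (d_ij/d0)^2)`, and (iii) a monotone correspondence by dynamic
#' programming with a flat gap penalty, until the correspondence is stable
#' or `max_iter` is reached. The best TM-score over all seeds is reported.
#' Deterministic for fixed inputs.
#'
#' @param P query [structure_chain()] (or coordinates).
#' @param Q_reference reference [structure_chain()] (or coordinates).
#' @param max_iter refinement cap per seed, default 20.
#' @param gap DP gap penalty, default 0.6.
#' @param frag_len seed fragment length, default 40.
#' @param L_norm normalization length, default the reference length.
#' @return a `tm_alignment`: list with `pairs` (2-column matrix, strictly
#'   increasing in both chains), `tm` (TM-score), `d0`, `n_aligned`.
#' @export
align_structures <- function(P, Q_reference, max_iter = 20L, gap = 0.6,
                             frag_len = 40L, L_norm = NULL) {
  Pc <- .coords(P); Qc <- .coords(Q_reference)
  L1 <- nrow(Pc); L2 <- nrow(Qc)
  if (is.null(L_norm)) L_norm <- L2
  d0 <- tm_d0(L_norm)
  fl <- min(frag_len, L1, L2)
  seeds <- list()
  # gapless sliding offsets: full-overlap windows at regular offsets
  offs <- unique(round(seq(-(L2 - fl), L1 - fl, length.out = 7)))
  for (o in offs) {
    i <- seq_len(L1); j <- i - o
    ok <- j >= 1 & j <= L2
    if (sum(ok) >= max(3L, fl %/% 2L)) seeds[[length(seeds) + 1L]] <- cbind(i[ok], j[ok])
  }
  # fragment seeds: superpose start/middle/end fragments pairwise
  starts1 <- unique(pmax(1L, c(1L, (L1 - fl) %/% 2L + 1L, L1 - fl + 1L)))
  starts2 <- unique(pmax(1L, c(1L, (L2 - fl) %/% 2L + 1L, L2 - fl + 1L)))
  for (s1 in starts1) for (s2 in starts2) {
    seeds[[length(seeds) + 1L]] <- cbind(s1:(s1 + fl - 1L), s2:(s2 + fl - 1L))
  }
  best_tm <- -Inf; best_pairs <- NULL
  for (seed in seeds) {
    pairs <- seed
    prev <- NULL
    for (it in seq_len(max_iter)) {
      sp <- tryCatch(kabsch_superpose(Pc, Qc, pairs), error = function(e) NULL)
      if (is.null(sp)) break
      moved <- sp$transform(Pc)
      d2 <- outer(rowSums(moved^2), rep(1, L2)) - 2 * moved %*% t(Qc) +
        outer(rep(1, L1), rowSums(Qc^2))
      d2[d2 < 0] <- 0
      sim <- 1 / (1 + d2 / d0^2)
      new_pairs <- .dp_align_cpp(sim, gap)
      if (nrow(new_pairs) < 3L) break
      if (!is.null(prev) && identical(new_pairs, prev)) { pairs <- new_pairs; break }
      prev <- pairs
      pairs <- new_pairs
    }
    if (nrow(pairs) >= 3L) {
      tm <- tryCatch(tm_score(Pc, Qc, pairs, L_norm), error = function(e) NA_real_)
      if (!is.na(tm) && tm > best_tm) { best_tm <- tm; best_pairs <- pairs }
    }
  }
  if (is.null(best_pairs)) stop("alignment failed: no seed achieved 3 pairs")
  structure(list(pairs = best_pairs, tm = best_tm, d0 = d0,
                 n_aligned = nrow(best_pairs)),
            class = "tm_alignment")
}

#' @export
print.tm_alignment <- function(x, ...) {
  cat("tm_alignment: TM =", round(x$tm, 4), "over", x$n_aligned,
      "aligned pairs (d0 =", round(x$d0, 3), ")\n")
  invisible(x)
}

#' Classify query structures against a reference panel
#'
#' Computes the full query x reference TM-score matrix (normalized by
#' reference length by default) and assigns each query to its
#' highest-scoring reference; ties break to the lexicographically first
#' reference ID and are flagged. A histogram (fixed bin width 0.02) of the
#' per-query scores against a designated reference is included.
#'
#' @param queries named list of [structure_chain()]s.
#' @param references named list of [structure_chain()]s (>= 2).
#' @param norm `"reference"` (default) or `"query"` normalization.
#' @param hist_reference reference ID for the histogram, default the first.
#' @return a `score_matrix`: list with `scores` (query x reference matrix,
#'   `NA` where alignment failed), `class` (named character), `tied`
#'   (named logical), `histogram` (hist object), `norm`.
#' @export
classify_against_references <- function(queries, references,
                                        norm = c("reference", "query"),
                                        hist_reference = NULL) {
  norm <- match.arg(norm)
  stopifnot(length(queries) >= 1L, length(references) >= 2L)
  if (is.null(names(queries))) names(queries) <- paste0("query", seq_along(queries))
  if (is.null(names(references))) names(references) <- paste0("ref", seq_along(references))
  M <- matrix(NA_real_, length(queries), length(references),
              dimnames = list(names(queries), names(references)))
  for (qi in seq_along(queries)) for (ri in seq_along(references)) {
    Ln <- if (norm == "reference") length(references[[ri]]) else length(queries[[qi]])
    al <- tryCatch(align_structures(queries[[qi]], references[[ri]], L_norm = Ln),
                   error = function(e) NULL)
    if (!is.null(al)) M[qi, ri] <- al$tm
  }
  cls <- character(nrow(M)); tied <- logical(nrow(M))
  refs_sorted <- sort(colnames(M))
  for (qi in seq_len(nrow(M))) {
    row <- M[qi, ]
    if (all(is.na(row))) { cls[qi] <- NA_character_; next }
    mx <- max(row, na.rm = TRUE)
    top <- refs_sorted[refs_sorted %in% names(row)[!is.na(row) & row == mx]]
    cls[qi] <- top[1L]
    tied[qi] <- length(top) > 1L
  }
  names(cls) <- rownames(M); names(tied) <- rownames(M)
  if (is.null(hist_reference)) hist_reference <- colnames(M)[1L]
  hv <- M[, hist_reference]
  hv <- hv[!is.na(hv)]
  breaks <- seq(0, 1.02, by = 0.02)
  h <- if (length(hv)) graphics::hist(pmin(hv, 1), breaks = breaks, plot = FALSE) else NULL
  structure(list(scores = M, class = cls, tied = tied, histogram = h,
                 norm = norm, hist_reference = hist_reference),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x$scores), "queries x", ncol(x$scores),
      "references (norm =", x$norm, ")\n")
  print(table(x$class, useNA = "ifany"))
  invisible(x)
}
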