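#' Molting-cycle expression time course
#'
#' @param expr genes x samples numeric matrix (TPM/RPKM, non-negative).
#' @param time numeric time (hours) per column; duplicates mark replicate
#'   columns at the same stage.
#' @param molts ordered times at which ecdysis occurs, within the observed
#'   range.
#' @param unit abundance unit label ("TPM" or "RPKM").
#' @return an `expression_timecourse`.
#' @export
expression_timecourse <- function(expr, time, molts, unit = "TPM") {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(time), !is.unsorted(time))
  if (!all(is.finite(expr)) || any(expr < 0)) stop("expression must be finite and non-negative")
  if (length(molts) && (min(molts) < min(time) || max(molts) > max(time)))
    stop("molt events outside the observed time range")
  structure(list(expr = expr, time = as.numeric(time),
                 molts = as.numeric(molts), unit = unit),
            class = "expression_timecourse")
}

#' @export
print.expression_timecourse <- function(x, ...) {
  cat("expression_timecourse:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples (", x$unit, "),", length(x$molts), "molt event(s)\n")
  invisible(x)
}

#' Read an expression matrix with molt-event metadata
#'
#' `expr_path`: TSV, first column gene ID, one column per sample.
#' `meta_path`: TSV with columns `column`, `time_h`, `molt_event` (0/1;
#' 1 marks a time point at which ecdysis occurs).
#'
#' @param expr_path expression TSV.
#' @param meta_path metadata TSV.
#' @param unit abundance unit label.
#' @return an [expression_timecourse()].
#' @export
read_expression <- function(expr_path, meta_path, unit = "TPM") {
  df <- utils::read.delim(expr_path, header = TRUE, sep = "\t", check.names = FALSE)
  genes <- df[[1L]]
  expr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(expr) <- genes
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t")
  stopifnot(all(c("column", "time_h", "molt_event") %in% names(meta)))
  meta <- meta[match(colnames(expr), meta$column), ]
  ord <- order(meta$time_h)
  expression_timecourse(expr[, ord, drop = FALSE], meta$time_h[ord],
                        molts = meta$time_h[ord][meta$molt_event[ord] == 1],
                        unit = unit)
}

#' Average replicates and merge split gene models
#'
#' Replicate columns sharing one time point are replaced by their
#' arithmetic mean; each merge group (e.g. a gene model split in two by
#' the assembler) is replaced by the per-time-point sum under the new ID.
#'
#' @param tc an [expression_timecourse()].
#' @param merge_groups named list: new gene ID -> character vector of
#'   existing model IDs to sum.
#' @return an [expression_timecourse()] with strictly increasing time.
#' @export
collapse_replicates_and_merge <- function(tc, merge_groups = list()) {
  ut <- unique(tc$time)
  expr <- vapply(ut, function(t) {
    cols <- which(tc$time == t)
    if (length(cols) == 1L) tc$expr[, cols] else rowMeans(tc$expr[, cols, drop = FALSE])
  }, numeric(nrow(tc$expr)))
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = nrow(tc$expr))
  rownames(expr) <- rownames(tc$expr)
  colnames(expr) <- as.character(ut)
  if (length(merge_groups)) {
    for (new_id in names(merge_groups)) {
      ids <- merge_groups[[new_id]]
      missing <- setdiff(ids, rownames(expr))
      if (length(missing)) stop("merge group references unknown ID(s): ",
                                paste(missing, collapse = ", "))
      summed <- colSums(expr[ids, , drop = FALSE])
      expr <- expr[!(rownames(expr) %in% ids), , drop = FALSE]
      expr <- rbind(expr, matrix(summed, nrow = 1, dimnames = list(new_id, colnames(expr))))
    }
  }
  expression_timecourse(expr, ut, tc$molts, tc$unit)
}

#' Smooth a time course with overlapping windows
#'
#' Each interior time point is replaced by the mean of the `w`-point window
#' centred on it (default 3: previous, current, next); the endpoints are
#' dropped, so the output is `w - 1` points shorter. This damps
#' developmental-timing jitter between independently staged samples.
#'
#' @param tc an [expression_timecourse()] with strictly increasing time.
#' @param w odd window size (default 3).
#' @return an [expression_timecourse()].
#' @export
smooth_windows <- function(tc, w = 3L) {
  stopifnot(w %% 2L == 1L, w >= 3L)
  n <- ncol(tc$expr)
  if (n < w) stop("need at least ", w, " time points, got ", n)
  h <- (w - 1L) %/% 2L
  keep <- (1L + h):(n - h)
  sm <- vapply(keep, function(i) rowMeans(tc$expr[, (i - h):(i + h), drop = FALSE]),
               numeric(nrow(tc$expr)))
  if (is.null(dim(sm))) sm <- matrix(sm, nrow = nrow(tc$expr))
  rownames(sm) <- rownames(tc$expr)
  new_time <- tc$time[keep]
  colnames(sm) <- as.character(new_time)
  molts <- tc$molts[tc$molts >= min(new_time) & tc$molts <= max(new_time)]
  expression_timecourse(sm, new_time, molts, tc$unit)
}
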