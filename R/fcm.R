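#' Fuzzy c-means clustering
#'
#' Standard alternating-update fuzzy c-means: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and centers
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`, iterated until the objective
#' `J = sum_ik u_ik^m d_ik^2` changes by less than `tol`. A point at zero
#' distance from a center takes membership 1 on that cluster (split evenly
#' if several centers coincide with it). Deterministic for a fixed seed.
#'
#' @param X genes x features numeric matrix.
#' @param c number of clusters (>= 2, < nrow(X)).
#' @param m fuzzifier (> 1), default 2.
#' @param tol objective-change convergence tolerance, default 1e-6.
#' @param max_iter iteration cap, default 500.
#' @param seed integer seed for the random initial memberships.
#' @return an `fcm_result`: list with `membership` (n x c, rows sum to 1),
#'   `centers` (c x features), `m`, `objective` (final J), `objective_trace`
#'   (per-iteration J), `iterations`, `seed`, `cluster` (crisp max-membership
#'   assignment, ties to the lowest cluster index), and `data` (the input
#'   matrix, kept for cluster diagnostics downstream).
#' @export
fuzzy_cmeans <- function(X, c, m = 2, tol = 1e-6, max_iter = 500L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!all(is.finite(X))) stop("non-finite values in input")
  if (c < 2L) stop("need at least 2 clusters")
  if (c >= n) stop("cluster count must be below the number of rows")
  if (m <= 1) stop("fuzzifier must exceed 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  U <- matrix(stats::runif(n * c), n, c)
  U <- U / rowSums(U)
  exp_mem <- 2 / (m - 1)
  J_trace <- numeric(0)
  J_prev <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Um <- U^m
    centers <- (t(Um) %*% X) / colSums(Um)
    # squared distances n x c
    d2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 0] <- 0
    J <- sum(Um * d2)
    J_trace <- c(J_trace, J)
    if (abs(J_prev - J) < tol || iter >= max_iter) {
      U <- .fcm_membership(d2, exp_mem)
      break
    }
    J_prev <- J
    U <- .fcm_membership(d2, exp_mem)
  }
  cluster <- apply(U, 1L, which.max)
  structure(list(membership = U, centers = centers, data = X, m = m,
                 objective = J_trace[length(J_trace)],
                 objective_trace = J_trace, iterations = iter, seed = seed,
                 cluster = cluster),
            class = "fcm_result")
}

.fcm_membership <- function(d2, exp_mem) {
  n <- nrow(d2); c <- ncol(d2)
  U <- matrix(0, n, c)
  zero <- d2 <= .Machine$double.eps
  has_zero <- rowSums(zero) > 0L
  if (any(has_zero)) {
    U[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  if (any(!has_zero)) {
    d <- sqrt(d2[!has_zero, , drop = FALSE])
    inv <- d^(-exp_mem)
    U[!has_zero, ] <- inv / rowSums(inv)
  }
  U
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Select clusters peaking just before molt events
#'
#' A cluster is selected when its z-scored center peaks inside the
#' pre-molt window `(molt - delta * preceding-intermolt-interval, molt]`
#' for more than `majority` of the molt events. "Peaks" is read per molt
#' cycle: the center's maximum over the cycle (previous molt, molt] must
#' fall inside the window and exceed the center's mean, so a center whose
#' cycle maximum sits elsewhere — or a flat center — is never selected
#' however many incidental local maxima it carries. Candidate genes are
#' the genes whose max-membership cluster is selected.
#'
#' Clusters must also be coherent: the center must retain at least
#' `min_coherence` of its members' typical profile amplitude. Fuzzy
#' c-means centers of clusters whose members share no common shape shrink
#' toward the grand mean, leaving a near-flat center whose z-scored
#' residual wiggle would otherwise be mistaken for peaks.
#'
#' @param result an [fuzzy_cmeans()] result fitted on `tc`'s time grid.
#' @param tc the [expression_timecourse()] that was clustered.
#' @param delta pre-molt window as a fraction of the preceding intermolt
#'   interval, default 0.25.
#' @param majority fraction of molt events that must show the pre-molt
#'   peak, default 0.5 (strictly exceeded).
#' @param min_coherence minimum ratio of center SD to the median profile
#'   SD of the cluster's members (in clustering space), default 0.3;
#'   empty clusters are never selected.
#' @return list with `selected` (cluster indices), `candidates` (gene IDs),
#'   `per_cluster` (data.frame cluster, n_premolt_peaks, n_molts, selected).
#' @export
select_premolt_clusters <- function(result, tc, delta = 0.25, majority = 0.5,
                                    min_coherence = 0.3) {
  if (!length(tc$molts)) stop("no molt events annotated")
  time <- tc$time
  stopifnot(ncol(result$centers) == length(time))
  starts <- c(min(time), utils::head(tc$molts, -1L))
  hits <- integer(nrow(result$centers))
  for (k in seq_len(nrow(result$centers))) {
    v <- as.numeric(result$centers[k, ])
    z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else rep(0, length(v))
    for (j in seq_along(tc$molts)) {
      lo <- tc$molts[j] - delta * (tc$molts[j] - starts[j])
      in_cycle <- time > starts[j] & time <= tc$molts[j]
      if (j == 1L) in_cycle <- time >= starts[j] & time <= tc$molts[j]
      if (!any(in_cycle)) next
      peak_i <- which(in_cycle)[which.max(z[in_cycle])]
      if (time[peak_i] > lo && time[peak_i] <= tc$molts[j] && z[peak_i] > 0)
        hits[k] <- hits[k] + 1L
    }
  }
  coherent <- vapply(seq_len(nrow(result$centers)), function(k) {
    members <- which(result$cluster == k)
    if (!length(members)) return(FALSE)
    if (is.null(result$data)) return(TRUE)
    ref <- stats::median(apply(result$data[members, , drop = FALSE], 1L, stats::sd))
    ref > 0 && stats::sd(result$centers[k, ]) >= min_coherence * ref
  }, logical(1))
  selected <- which(hits > majority * length(tc$molts) & coherent)
  candidates <- rownames(tc$expr)[result$cluster %in% selected]
  list(selected = selected, candidates = candidates,
       per_cluster = data.frame(cluster = seq_along(hits),
                                n_premolt_peaks = hits,
                                n_molts = length(tc$molts),
                                selected = seq_along(hits) %in% selected))
}

#' Standardize rows to zero mean, unit variance
#'
#' Shape-based clustering of expression profiles: each gene's profile is
#' z-scored so that abundance differences do not dominate. Constant rows
#' map to all-zero profiles.
#'
#' @param X genes x features matrix.
#' @return matrix of the same shape.
#' @export
standardize_rows <- function(X) {
  mu <- rowMeans(X)
  sd <- apply(X, 1L, stats::sd)
  sd[sd == 0] <- 1
  (X - mu) / sd
}
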