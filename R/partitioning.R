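#' Propagate a Markov chain
#'
#' Raises the row-stochastic transition matrix to the power `t` by repeated
#' squaring, equivalent to propagating the chain by `t` auxiliary time steps.
#'
#' @param M row-stochastic matrix.
#' @param t positive integer number of steps.
#' @return M^t (row-stochastic).
#' @export
propagate_markov <- function(M, t) {
  t <- as.numeric(t)
  stopifnot(t >= 1, t == floor(t))
  out <- NULL
  P <- M
  while (t > 0) {
    if (t %% 2 == 1) out <- if (is.null(out)) P else out %*% P
    P <- P %*% P
    t <- t %/% 2
  }
  out
}

#' Kinetic coarse-graining into metastable states and a transition-state
#' ensemble
#'
#' Propagates the Markov chain to the metastable plateau: long enough that
#' fast intra-state mixing is complete, short enough that the slow
#' inter-state transitions have barely begun. The plateau time is the
#' geometric mean of the implied time scales flanking the spectral gap,
#' \eqn{t^* = \sqrt{t_{k-1} t_k}} (capped at `t_auto`), at which the fast
#' modes have decayed like \eqn{\lambda_k^{t^*} \approx 0} while the slow
#' modes persist. At that point each row of \eqn{M^{t^*}} gives the
#' probabilities with which the corresponding sample "sinks" into the
#' long-lived regions. Rows are grouped by Ward agglomeration into
#' `k_states` clusters, the per-sample sink probability of a state is the
#' propagated mass landing in that cluster, and samples whose top two sink
#' probabilities differ by less than `delta` are assigned to the
#' transition-state ensemble (label 0).
#'
#' If fewer than `k_states` kinetically distinct row-clusters exist, the
#' achieved number is used with a warning; with fewer than 2 (a fully mixed
#' chain) every sample is maximally ambiguous and the whole batch is labeled
#' transition state.
#'
#' @param M row-stochastic Markov transition matrix (m x m).
#' @param k_states target number of metastable states (>= 2).
#' @param delta ambiguity threshold on the difference between the two largest
#'   sink probabilities; samples below it are transition-state.
#' @param t propagation time; `NULL` (default) chooses the spectral plateau
#'   time from the eigenvalues of `M` (or from `values` when supplied).
#' @param t_auto cap on the propagation time.
#' @param values optional eigenvalues of `M` (descending), e.g. from a
#'   [markov_model()], to avoid re-solving the eigenproblem.
#' @param tol_rows tolerance for treating propagated rows as kinetically
#'   identical when counting achievable states.
#' @return Object of class `cv_partition`: `labels` (integer per sample;
#'   states 1..k, 0 = transition state), `sink_probs` (m x k, rows sum to 1),
#'   `k_states` (achieved), `delta`, `t` (propagation time used).
#' @export
coarse_grain <- function(M, k_states = 2, delta = 0.1, t = NULL,
                         t_auto = 2^20, values = NULL, tol_rows = 1e-4) {
  stopifnot(k_states >= 2, delta >= 0, all(M >= 0),
            max(abs(rowSums(M) - 1)) < 1e-8)
  m <- nrow(M)
  if (is.null(t)) {
    if (is.null(values))
      values <- sort(Mod(eigen(M, only.values = TRUE)$values),
                     decreasing = TRUE)
    ts <- implied_timescales(pmin(values, 1))
    t_slow <- min(ts[k_states], t_auto, na.rm = TRUE)
    t_fast <- if (length(ts) > k_states && is.finite(ts[k_states + 1]))
      min(ts[k_states + 1], t_auto) else 0
    t <- max(1, min(t_auto, ceiling(sqrt(max(t_slow, 1) * max(t_fast, 1)))))
  }
  Mt <- propagate_markov(M, t)
  # group the plateau rows kinetically
  hc <- stats::hclust(stats::dist(Mt), method = "ward.D2")
  cl <- stats::cutree(hc, k = min(k_states, m))
  # collapse clusters whose sink rows are kinetically identical
  cl <- merge_identical_clusters(Mt, cl, tol = 10 * tol_rows)
  k_eff <- length(unique(cl))
  if (k_eff < k_states)
    warning("only ", k_eff, " kinetically distinct state(s) found ",
            "(requested ", k_states, ")")
  if (k_eff < 2) {
    sink <- matrix(1, m, 1)
    return(new_partition(rep(0L, m), sink, 1L, delta, t))
  }
  sink <- vapply(seq_len(k_eff), function(s) {
    rowSums(Mt[, cl == s, drop = FALSE])
  }, numeric(m))
  labels <- max.col(sink, ties.method = "first")
  top2 <- apply(sink, 1, function(p) -diff(sort(p, decreasing = TRUE)[1:2]))
  labels[top2 < delta] <- 0L
  new_partition(as.integer(labels), sink, k_eff, delta, t)
}

merge_identical_clusters <- function(Mt, cl, tol) {
  repeat {
    ids <- sort(unique(cl))
    if (length(ids) < 2) return(match(cl, ids))
    cent <- t(vapply(ids, function(s) {
      colMeans(Mt[cl == s, , drop = FALSE])
    }, numeric(ncol(Mt))))
    dv <- as.matrix(stats::dist(cent, method = "manhattan")) * 0.5
    diag(dv) <- Inf
    hit <- which(dv < tol, arr.ind = TRUE)
    if (nrow(hit) == 0) return(match(cl, ids))
    cl[cl == ids[hit[1, 2]]] <- ids[hit[1, 1]]
  }
}

new_partition <- function(labels, sink_probs, k_states, delta, t) {
  structure(list(labels = labels, sink_probs = sink_probs,
                 k_states = as.integer(k_states), delta = delta, t = t),
            class = "cv_partition")
}

#' @export
print.cv_partition <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:x$k_states))
  cat("<cv_partition>", length(x$labels), "samples,", x$k_states,
      "state(s), propagation t =", x$t, "\n  TS:", tab["0"],
      " states:", paste(tab[-1], collapse = "/"), "\n")
  invisible(x)
}

#' Merge per-batch partitions into global state labels
#'
#' Batch-level coarse-graining assigns cluster labels that are not consistent
#' across batches. Ward's minimum-variance agglomeration of all batch-cluster
#' centroids (in CV space) into `k_states` global clusters gives a common
#' labeling; each batch label is relabeled through its centroid's global
#' cluster, and transition-state labels (0) pass through unchanged.
#'
#' @param partitions list of `cv_partition` objects (one per batch).
#' @param centroids list of matrices, one per batch: row s is the CV-space
#'   centroid of that batch's state s (k_batch x d).
#' @param k_states number of global states.
#' @return List with `labels` (list of relabeled per-batch vectors) and
#'   `assignment` (data frame mapping batch/state to global state).
#' @export
merge_batches <- function(partitions, centroids, k_states = 2) {
  stopifnot(length(partitions) == length(centroids),
            length(partitions) >= 1)
  cent <- do.call(rbind, lapply(centroids, as.matrix))
  if (nrow(cent) < k_states)
    stop("fewer batch-cluster centroids than k_states")
  batch <- rep(seq_along(centroids),
               vapply(centroids, function(x) nrow(as.matrix(x)), 1L))
  state <- unlist(lapply(centroids,
                         function(x) seq_len(nrow(as.matrix(x)))))
  glob <- if (nrow(cent) == k_states) seq_len(k_states) else
    stats::cutree(stats::hclust(stats::dist(cent), "ward.D2"), k_states)
  assignment <- data.frame(batch = batch, state = state, global = glob)
  labels <- lapply(seq_along(partitions), function(b) {
    lab <- partitions[[b]]$labels
    map <- glob[batch == b]
    out <- lab
    nz <- lab > 0
    out[nz] <- map[lab[nz]]
    out
  })
  list(labels = labels, assignment = assignment)
}

#' Nonlinear state-boundary classifier in a 2-D reduced space
#'
#' Fits a maximum-margin-style radial-basis-function classifier to the
#' non-transition-state samples (kernel regularized least squares,
#' one-vs-rest, with the median-distance bandwidth heuristic) and returns a
#' callable decision function plus a grid-sampled class map for drawing state
#' boundaries.
#'
#' @param Z m x 2 CV samples.
#' @param labels integer labels (0 = transition state, excluded from the fit).
#' @param lambda ridge regularization.
#' @param grid_n resolution of the returned class grid.
#' @return Object of class `boundary_classifier`: `predict(Znew)` returning
#'   labels, plus `grid` (data frame x, y, class).
#' @export
fit_boundary <- function(Z, labels, lambda = 1e-3, grid_n = 60) {
  Z <- as_cv_matrix(Z)
  stopifnot(ncol(Z) == 2, nrow(Z) == length(labels))
  keep <- labels > 0
  Zs <- Z[keep, , drop = FALSE]
  y <- labels[keep]
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("need at least 2 non-transition-state classes")
  mu <- colMeans(Zs)
  sd_ <- apply(Zs, 2, stats::sd)
  sd_[sd_ < 1e-12] <- 1
  Xs <- sweep(sweep(Zs, 2, mu), 2, sd_, "/")
  D <- as.matrix(stats::dist(Xs))
  bw <- stats::median(D[upper.tri(D)])
  if (bw < 1e-12) bw <- 1
  Kmat <- exp(-D^2 / (2 * bw^2))
  Y <- outer(y, classes, "==") * 2 - 1
  A <- solve(Kmat + lambda * diag(nrow(Kmat)), Y)
  predict_fn <- function(Znew) {
    Znew <- as_cv_matrix(Znew)
    Xn <- sweep(sweep(Znew, 2, mu), 2, sd_, "/")
    cross <- exp(-sq_cross_dist(Xn, Xs) / (2 * bw^2))
    classes[max.col(cross %*% A, ties.method = "first")]
  }
  gx <- seq(min(Z[, 1]), max(Z[, 1]), length.out = grid_n)
  gy <- seq(min(Z[, 2]), max(Z[, 2]), length.out = grid_n)
  gz <- as.matrix(expand.grid(x = gx, y = gy))
  grid <- data.frame(x = gz[, 1], y = gz[, 2], class = predict_fn(gz))
  structure(list(predict = predict_fn, grid = grid, classes = classes,
                 bandwidth = bw),
            class = "boundary_classifier")
}

sq_cross_dist <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
}

#' Partition a CV trajectory via batched coarse-graining
#'
#' Convenience wrapper reproducing the end-of-training workflow: split the
#' CV samples into batches, build a Markov model and coarse-grain each batch,
#' then merge the batch partitions through Ward clustering of their state
#' centroids. Global states are ordered by their centroid along the first CV.
#'
#' @param Z CV samples (T x d or vector).
#' @param k_states number of metastable states.
#' @param config a [kernel_config()].
#' @param batch_size samples per batch.
#' @param delta transition-state ambiguity threshold.
#' @param seed RNG seed for batch assignment.
#' @return List with `labels` (length T, 0 = transition state), `batches`
#'   (per-batch partitions), and `ts_span` (range of the first CV over
#'   transition-state samples, or NULL when the TS set is empty).
#' @export
partition_cv <- function(Z, k_states = 2, config = kernel_config(),
                         batch_size = 1000, delta = 0.1, seed = 1) {
  Z <- as_cv_matrix(Z)
  T_ <- nrow(Z)
  set.seed(seed)
  m <- min(batch_size, T_)
  n_batch <- max(1L, T_ %/% m)
  perm <- sample.int(T_)
  idx_list <- split(perm[seq_len(n_batch * m)], rep(seq_len(n_batch), each = m))
  parts <- list()
  cents <- list()
  for (b in seq_len(n_batch)) {
    idx <- idx_list[[b]]
    mm <- markov_model(Z[idx, , drop = FALSE], config, k_states)
    part <- suppressWarnings(coarse_grain(mm$M, k_states, delta,
                                          values = mm$values))
    Zb <- Z[idx, , drop = FALSE]
    # sink-probability-weighted centroids are defined even for empty states
    cent <- matrix(vapply(seq_len(part$k_states), function(s) {
      w <- part$sink_probs[, s]
      colSums(Zb * w) / sum(w)
    }, numeric(ncol(Z))), ncol = ncol(Z), byrow = TRUE)
    parts[[b]] <- part
    cents[[b]] <- cent
  }
  merged <- merge_batches(parts, cents, k_states)
  labels <- rep(NA_integer_, T_)
  for (b in seq_len(n_batch)) labels[idx_list[[b]]] <- merged$labels[[b]]
  # frames left over by batching: nearest global state centroid
  if (anyNA(labels)) {
    glob_cent <- matrix(vapply(seq_len(k_states), function(s) {
      colMeans(do.call(rbind, cents)[merged$assignment$global == s, ,
                                     drop = FALSE])
    }, numeric(ncol(Z))), ncol = ncol(Z), byrow = TRUE)
    left <- which(is.na(labels))
    d2 <- sq_cross_dist(Z[left, , drop = FALSE], glob_cent)
    labels[left] <- max.col(-d2, ties.method = "first")
  }
  # order states along the first CV for reproducible naming
  ord <- order(vapply(seq_len(k_states), function(s) {
    if (any(labels == s)) mean(Z[labels == s, 1]) else Inf
  }, numeric(1)))
  labels_out <- labels
  for (s in seq_len(k_states)) labels_out[labels == ord[s]] <- s
  ts_span <- if (any(labels_out == 0))
    range(Z[labels_out == 0, 1]) else NULL
  list(labels = labels_out, batches = parts, ts_span = ts_span)
}
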