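#' Time-ordered feature matrix
#'
#' Container for T time-ordered samples of n configuration variables
#' (features), e.g. pairwise Calpha distances in nm, sampled at a uniform
#' interval `dt`. Downstream code addresses features by name, never by
#' position.
#'
#' @param values T x n numeric matrix, rows time-ordered.
#' @param dt sampling interval (time units).
#' @param names n feature identifiers; default `f000`, `f001`, ...
#' @return Object of class `feature_matrix` (a matrix with `dt` attribute and
#'   column names).
#' @export
feature_matrix <- function(values, dt = 1, names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1) stop("need at least 1 sample")
  if (any(!is.finite(values))) stop("non-finite values in feature matrix")
  stopifnot(dt > 0)
  if (is.null(names)) names <- sprintf("f%03d", seq_len(ncol(values)) - 1L)
  stopifnot(length(names) == ncol(values))
  colnames(values) <- names
  structure(values, dt = dt, class = c("feature_matrix", class(values)))
}

feature_values <- function(X) {
  v <- unclass(X)
  attr(v, "dt") <- NULL
  attr(v, "ground_truth") <- NULL
  as.matrix(v)
}

feature_names <- function(X) colnames(X)

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x), "samples x", ncol(x),
      "features, dt =", attr(x, "dt"), "\n")
  invisible(x)
}

#' Pairwise Euclidean distances between selected atoms
#'
#' Computes, per frame, the Euclidean distances between all pairs of the
#' selected atoms, yielding N(N-1)/2 features ordered lexicographically by
#' (k, l) with k > l (0-based), i.e. (1,0), (2,0), (2,1), (3,0), ...
#' Feature names record the pair as `"k-l"`.
#'
#' @param coords T x N x 3 array of positions (nm), or N x 3 matrix for a
#'   single frame.
#' @param selection optional 1-based atom indices to keep (default: all).
#' @param dt sampling interval passed to the result.
#' @return A [feature_matrix()] with T rows and N(N-1)/2 distance columns.
#' @examples
#' tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' pairwise_distances(tri) # 1, 1, sqrt(2)
#' @export
pairwise_distances <- function(coords, selection = NULL, dt = 1) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            all(is.finite(coords)))
  if (!is.null(selection)) coords <- coords[, selection, , drop = FALSE]
  N <- dim(coords)[2]
  if (N < 2) stop("invalid selection: need at least 2 atoms")
  pairs <- atom_pairs(N)
  T_ <- dim(coords)[1]
  vals <- matrix(NA_real_, T_, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    dxyz <- coords[, pairs[p, 1] + 1L, , drop = FALSE] -
      coords[, pairs[p, 2] + 1L, , drop = FALSE]
    vals[, p] <- sqrt(rowSums(matrix(dxyz, T_, 3)^2))
  }
  feature_matrix(vals, dt = dt,
                 names = sprintf("%d-%d", pairs[, 1], pairs[, 2]))
}

# 0-based pairs (k, l), k > l, ordered lexicographically by (k, l).
atom_pairs <- function(N) {
  k <- rep(seq_len(N - 1L), seq_len(N - 1L))
  l <- unlist(lapply(seq_len(N - 1L), function(i) seq_len(i) - 1L))
  cbind(k = k, l = l)
}

#' Native-contact specification from a reference structure
#'
#' Retains the atom pairs whose distance in the reference (folded) structure
#' is below `cutoff` and whose residues are separated by more than
#' `min_seq_sep` positions in sequence (strictly greater). Stores the
#' reference distances and the smoothing parameters of the native-contact
#' fraction.
#'
#' @param reference N x 3 reference positions (nm).
#' @param residue_ids integer residue index per atom (length N).
#' @param cutoff maximum native distance (nm).
#' @param min_seq_sep residues with |i - j| <= min_seq_sep are excluded.
#' @param alpha_c sigmoid steepness (1/nm).
#' @param gamma tolerance factor (dimensionless, >= 1).
#' @return Object of class `contact_spec`: `pairs` (0-based, k > l), `x0`
#'   (reference distances), and the smoothing constants.
#' @export
contact_spec <- function(reference, residue_ids = seq_len(nrow(reference)),
                         cutoff = 0.8, min_seq_sep = 3, alpha_c = 50,
                         gamma = 1.5) {
  reference <- as.matrix(reference)
  stopifnot(ncol(reference) == 3, all(is.finite(reference)), cutoff > 0,
            alpha_c > 0, gamma >= 1,
            length(residue_ids) == nrow(reference))
  fm <- pairwise_distances(reference)
  pr <- atom_pairs(nrow(reference))
  x0 <- as.numeric(feature_values(fm)[1, ])
  keep <- x0 < cutoff &
    abs(residue_ids[pr[, 1] + 1L] - residue_ids[pr[, 2] + 1L]) > min_seq_sep
  if (!any(keep))
    stop("empty contact spec: no pair passes the cutoff and sequence-",
         "separation filters (fraction of native contacts undefined)")
  structure(list(pairs = pr[keep, , drop = FALSE], x0 = x0[keep],
                 alpha_c = alpha_c, gamma = gamma, cutoff = cutoff,
                 min_seq_sep = min_seq_sep,
                 names = sprintf("%d-%d", pr[keep, 1], pr[keep, 2])),
            class = "contact_spec")
}

#' @export
print.contact_spec <- function(x, ...) {
  cat("<contact_spec>", nrow(x$pairs), "native pairs, cutoff", x$cutoff,
      "nm, |dres| >", x$min_seq_sep, "\n")
  invisible(x)
}

#' Fraction of native contacts
#'
#' Smoothed count of native contacts present in a frame:
#' \deqn{q = \frac{1}{n}\sum_{(k,l)}
#'   \frac{1}{1 + \exp[\alpha_c (x_{kl} - \gamma\, x^0_{kl})]},}
#' the standard switching form with steepness `alpha_c` (50/nm) and tolerance
#' `gamma` (1.5) relative to the reference distances \eqn{x^0_{kl}}. q lies
#' in (0, 1), is 1-like when all contacts are formed and decreases
#' monotonically as any distance grows.
#'
#' @param x distances for the spec's pairs, in the spec's ordering: a vector
#'   (one frame) or a T x n matrix / [feature_matrix()] restricted to those
#'   pairs.
#' @param spec a [contact_spec()].
#' @return Numeric vector of q, one per frame.
#' @examples
#' ref <- rbind(c(0, 0, 0), c(0.5, 0, 0))
#' sp <- contact_spec(ref, residue_ids = c(1, 10))
#' native_contacts(0.8, sp) # 1 / (1 + exp(2.5))
#' @export
native_contacts <- function(x, spec) {
  stopifnot(inherits(spec, "contact_spec"))
  n <- nrow(spec$pairs)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = length(x))
  x <- feature_values(x)
  if (ncol(x) != n)
    stop("shape error: expected ", n, " distances per frame, got ", ncol(x))
  u <- sweep(x, 2, spec$gamma * spec$x0)
  rowMeans(1 / (1 + exp(spec$alpha_c * u)))
}

#' Per-feature spectral gaps
#'
#' Scores every feature by the spectral gap of the Markov transition matrix
#' built on that feature alone (treated as a one-dimensional reduced space),
#' averaged over `n_batches` random batches. Features with (near-)zero
#' variance get `NA` with an attribute flag instead of an error.
#'
#' @param X a [feature_matrix()] or T x n matrix.
#' @param k_states metastable-state count for the gap.
#' @param config a [kernel_config()].
#' @param batch_size samples per batch (capped at T).
#' @param n_batches random batches averaged per feature.
#' @param seed RNG seed for batch sampling.
#' @return Named numeric vector of gaps in \[0, 1\] (NA for degenerate
#'   features, flagged in `attr(, "undefined")`).
#' @export
feature_spectral_gaps <- function(X, k_states = 2, config = kernel_config(),
                                  batch_size = 2000, n_batches = 5,
                                  seed = 1) {
  Xv <- feature_values(X)
  T_ <- nrow(Xv)
  m <- min(batch_size, T_)
  set.seed(seed)
  batches <- lapply(seq_len(n_batches), function(i) sample.int(T_, m))
  sds <- apply(Xv, 2, stats::sd)
  out <- rep(NA_real_, ncol(Xv))
  names(out) <- colnames(Xv) %||% sprintf("f%03d", seq_len(ncol(Xv)) - 1L)
  for (j in seq_len(ncol(Xv))) {
    if (sds[j] < 1e-12) next # undefined gap for constant feature
    sig <- vapply(batches, function(idx) {
      markov_model(Xv[idx, j], config, k_states)$sigma
    }, numeric(1))
    out[j] <- mean(sig)
  }
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Residue importance from pairwise spectral gaps
#'
#' Aggregates per-pair spectral gaps \eqn{\sigma_{kl}} of inter-residue
#' distance features into a per-residue score \eqn{r_k = \sum_l \sigma_{kl}},
#' highlighting the residues involved in the slow structural transitions.
#'
#' @param sigma_pairs data frame with columns `res_i`, `res_j`, `sigma`; or a
#'   named numeric vector with names `"i-j"` as produced by
#'   [feature_spectral_gaps()] on [pairwise_distances()] output.
#' @return Data frame with `residue`, `importance` (raw sums) and
#'   `relative` (max-normalized), sorted by residue.
#' @export
residue_importance <- function(sigma_pairs) {
  if (is.numeric(sigma_pairs) && !is.null(names(sigma_pairs))) {
    ij <- do.call(rbind, strsplit(names(sigma_pairs), "-", fixed = TRUE))
    sigma_pairs <- data.frame(res_i = as.integer(ij[, 1]),
                              res_j = as.integer(ij[, 2]),
                              sigma = as.numeric(sigma_pairs))
  }
  stopifnot(all(c("res_i", "res_j", "sigma") %in% names(sigma_pairs)))
  sp <- sigma_pairs[!is.na(sigma_pairs$sigma), ]
  res <- sort(unique(c(sp$res_i, sp$res_j)))
  imp <- vapply(res, function(k) {
    sum(sp$sigma[sp$res_i == k | sp$res_j == k])
  }, numeric(1))
  data.frame(residue = res, importance = imp,
             relative = imp / max(imp))
}
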