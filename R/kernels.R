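#' Kernel configuration for the anisotropic diffusion construction
#'
#' Bundles the tunable constants of the data-driven Markov transition matrix:
#' the anisotropic diffusion constant `alpha` (1/2 by default, the case whose
#' limiting generator is the backward Fokker--Planck operator under the
#' free-energy landscape), the neighborhood fraction `r` governing the
#' adaptive sample-dependent scales, and a numerical floor on the scales.
#'
#' @param alpha anisotropic diffusion constant in \[0, 1\]. 0 gives the
#'   normalized graph Laplacian (free energy 2F), 1 the Laplace--Beltrami
#'   limit (uniform density), 1/2 the Fokker--Planck limit with free energy F.
#' @param r neighborhood fraction in \[0, 1\]: `r` near 0 sets local scales
#'   (nearest neighbors, deep narrow states), `r` near 1 global scales
#'   (farthest neighbors, shallow wide states).
#' @param eps_floor positive lower bound on kernel scales, guarding against
#'   duplicated samples.
#' @return A list of class `kernel_config`.
#' @export
kernel_config <- function(alpha = 0.5, r = 0.65, eps_floor = 1e-12) {
  stopifnot(alpha >= 0, alpha <= 1, r >= 0, r <= 1, eps_floor > 0)
  structure(list(alpha = alpha, r = r, eps_floor = eps_floor),
            class = "kernel_config")
}

#' Adaptive sample-dependent scale matrix
#'
#' For each sample the radius \eqn{\eta_r(z_i)} is the distance to its
#' \eqn{\lceil r (m-1) \rceil}-th nearest neighbor (`r = 0` gives the nearest
#' neighbor, `r = 1` the farthest), and the pairwise scale is the sum of the
#' two squared ball radii,
#' \eqn{\epsilon_{ij} = \eta_r(z_i)^2 + \eta_r(z_j)^2}, floored at
#' `eps_floor`. Balancing local against global neighborhood sizes through `r`
#' lets the Gaussian kernel adapt to heterogeneous free-energy landscapes.
#'
#' The radius value at a tied rank is unambiguous (ties only permute equal
#' distances), so the construction is deterministic. If more than half of the
#' samples coincide with their nearest neighbor the batch is rejected as
#' degenerate.
#'
#' @param Z numeric matrix (m x d) of reduced-space samples; vectors are
#'   treated as one column.
#' @param r neighborhood fraction in \[0, 1\].
#' @param eps_floor scale floor (see [kernel_config()]).
#' @return Symmetric positive m x m matrix of scales.
#' @export
scale_matrix <- function(Z, r = 0.65, eps_floor = 1e-12) {
  Z <- as_cv_matrix(Z)
  m <- nrow(Z)
  stopifnot(m >= 3, r >= 0, r <= 1)
  dmat <- as.matrix(stats::dist(Z))
  rank <- max(1L, ceiling(r * (m - 1)))
  eta <- numeric(m)
  nn1 <- numeric(m)
  for (i in seq_len(m)) {
    di <- dmat[i, -i]
    part <- sort.int(di, partial = c(1L, rank))
    eta[i] <- part[rank]
    nn1[i] <- part[1L]
  }
  if (mean(nn1 == 0) > 0.5)
    stop("degenerate scales: more than half of the batch are duplicated samples")
  unname(pmax(outer(eta^2, eta^2, "+"), eps_floor))
}

#' Gaussian kernel with pairwise scales
#'
#' \eqn{g_{kl} = \exp(-\|z_k - z_l\|^2 / \epsilon_{kl})}.
#'
#' @param Z samples (m x d) or vector.
#' @param eps symmetric positive matrix of scales from [scale_matrix()], or a
#'   single scalar scale.
#' @return Symmetric m x m matrix with unit diagonal, entries in (0, 1\].
#' @export
gaussian_kernel <- function(Z, eps) {
  Z <- as_cv_matrix(Z)
  m <- nrow(Z)
  if (length(eps) == 1) eps <- matrix(eps, m, m)
  stopifnot(nrow(eps) == m, ncol(eps) == m, all(eps > 0),
            max(abs(eps - t(eps))) < 1e-10)
  sq <- as.matrix(stats::dist(Z))^2
  out <- exp(-sq / eps)
  dimnames(out) <- NULL
  out
}

#' Anisotropic diffusion kernel
#'
#' Density-normalizes a Gaussian kernel,
#' \eqn{K_{kl} = g_{kl} / (\varrho_k \varrho_l)^\alpha} with kernel density
#' estimate \eqn{\varrho_k = \sum_l g_{kl}}. The exponent `alpha` selects the
#' limiting diffusion operator; `alpha = 1/2` corresponds to the backward
#' Fokker--Planck equation with free energy F(z).
#'
#' @param g symmetric Gaussian kernel matrix from [gaussian_kernel()].
#' @param alpha anisotropic diffusion constant in \[0, 1\].
#' @return Symmetric positive kernel matrix K.
#' @export
anisotropic_kernel <- function(g, alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 0) return(g)
  rho <- rowSums(g)
  g / outer(rho, rho)^alpha
}

#' Row-stochastic Markov transition matrix
#'
#' \eqn{M_{ij} = K_{ij} / \sum_j K_{ij}}; row i is the probability
#' distribution of transitioning from sample i in one auxiliary time step.
#'
#' @param K nonnegative kernel matrix with positive row sums.
#' @return Row-stochastic matrix M.
#' @export
row_normalize <- function(K) {
  d <- rowSums(K)
  if (any(K < 0) || any(d <= 0))
    stop("degenerate kernel: negative entries or zero row sum")
  K / d
}

#' Symmetrized Markov transition matrix
#'
#' Conjugates the kernel by the square root of its degree,
#' \eqn{\hat M_{ij} = K_{ij} / \sqrt{d_i d_j}} with \eqn{d_i = \sum_j K_{ij}},
#' which preserves the eigenvalues of the row-stochastic matrix M while being
#' symmetric, so a stable symmetric eigensolver applies.
#'
#' @inheritParams row_normalize
#' @return Symmetric matrix with the same spectrum as `row_normalize(K)`.
#' @export
symmetrize_kernel <- function(K) {
  d <- rowSums(K)
  if (any(K < 0) || any(d <= 0))
    stop("degenerate kernel: negative entries or zero row sum")
  K / sqrt(outer(d, d))
}

#' Spectrum of the symmetrized Markov transition matrix
#'
#' @param M_sym symmetric matrix from [symmetrize_kernel()].
#' @return List with `values` (eigenvalues, descending; the leading one is 1)
#'   and `vectors` (orthonormal eigenvectors, columns matching `values`).
#' @export
markov_spectrum <- function(M_sym) {
  stopifnot(is.matrix(M_sym), max(abs(M_sym - t(M_sym))) < 1e-8)
  e <- eigen(M_sym, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Spectral gap
#'
#' For a target number of metastable states k, the spectral gap is the drop
#' after the k-th eigenvalue: \eqn{\sigma_k = \lambda_{k-1} - \lambda_k} with
#' eigenvalues indexed from 0 (\eqn{\lambda_0 = 1}). At k = 2 this is
#' \eqn{\lambda_1 - \lambda_2}. A gap near 1 indicates near-degeneracy of the
#' k dominant eigenvalues and hence strong time-scale separation into k
#' metastable states.
#'
#' @param values eigenvalues sorted descending (1-based vector, `values[1]`
#'   is \eqn{\lambda_0}).
#' @param k metastable-state count, `k >= 1`.
#' @return The gap \eqn{\sigma_k \in [0, 1]}.
#' @export
spectral_gap <- function(values, k = 2) {
  k <- as.integer(k)
  if (k < 1 || length(values) < k + 1)
    stop("k out of range: need at least k + 1 eigenvalues")
  values[k] - values[k + 1]
}

#' Implied relaxation time scales
#'
#' \eqn{t_k = -1 / \log \lambda_k}. Unit eigenvalues map to `Inf` (stationary
#' process); nonpositive eigenvalues have no associated time scale and are
#' masked as `NA`.
#'
#' @param values eigenvalues of a Markov transition matrix.
#' @return Numeric vector of time scales in auxiliary time units.
#' @export
implied_timescales <- function(values) {
  t <- rep(NA_real_, length(values))
  pos <- !is.na(values) & values > 0 & values < 1
  t[pos] <- -1 / log(values[pos])
  t[!is.na(values) & values >= 1] <- Inf
  t
}

#' Data-driven Markov model of reduced-space dynamics
#'
#' Runs the full pipeline on a batch of reduced-space samples: adaptive
#' scales, Gaussian kernel, anisotropic normalization, row-stochastic and
#' symmetrized transition matrices, spectrum, spectral gap and implied time
#' scales.
#'
#' @param Z reduced-space samples (m x d matrix or vector).
#' @param config a [kernel_config()].
#' @param k_states metastable-state count used for the reported gap.
#' @return Object of class `markov_model`: list with `K`, `M`, `M_sym`,
#'   `values`, `vectors`, `sigma`, `k_states`, `timescales`, `config`.
#' @examples
#' z <- c(rnorm(30, -1, 0.1), rnorm(30, 1, 0.1))
#' mm <- markov_model(z, kernel_config(r = 0.1))
#' mm$sigma
#' @export
markov_model <- function(Z, config = kernel_config(), k_states = 2) {
  Z <- as_cv_matrix(Z)
  eps <- scale_matrix(Z, config$r, config$eps_floor)
  g <- gaussian_kernel(Z, eps)
  K <- anisotropic_kernel(g, config$alpha)
  M <- row_normalize(K)
  M_sym <- symmetrize_kernel(K)
  sp <- markov_spectrum(M_sym)
  structure(list(K = K, M = M, M_sym = M_sym,
                 values = sp$values, vectors = sp$vectors,
                 sigma = spectral_gap(sp$values, k_states),
                 k_states = as.integer(k_states),
                 timescales = implied_timescales(sp$values),
                 config = config),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> m =", nrow(x$M), "samples, k =", x$k_states, "\n")
  cat("  spectral gap sigma =", format(x$sigma, digits = 4), "\n")
  cat("  leading eigenvalues:",
      paste(format(utils::head(x$values, 5), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

as_cv_matrix <- function(Z) {
  if (is.null(dim(Z))) Z <- matrix(as.numeric(Z), ncol = 1)
  Z <- unclass(Z)
  attr(Z, "dt") <- NULL
  storage.mode(Z) <- "double"
  if (any(!is.finite(Z))) stop("non-finite values in samples")
  Z
}
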