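#' Linear target mapping from features to collective variables
#'
#' The target mapping \eqn{z = \xi(x)} carries high-dimensional features into
#' a d-dimensional reduced space. The default architecture is linear,
#' \eqn{z_k = \sum_j w_{kj} x_j}, applied to per-feature standardized inputs
#' (z-scores frozen at fit time). After training the output is rescaled to
#' \[0, 1\] over the training set — a monotone affine change with no effect on
#' the spectral gap.
#'
#' @param weights n x d numeric matrix of mapping parameters.
#' @param center,scale per-feature input normalization statistics (length n).
#' @param out_shift,out_scale per-CV output affine rescaling (length d).
#' @param feature_names optional feature identifiers (length n).
#' @return Object of class `target_mapping`.
#' @export
target_mapping <- function(weights, center = NULL, scale = NULL,
                           out_shift = NULL, out_scale = NULL,
                           feature_names = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  d <- ncol(weights)
  structure(list(
    weights = weights,
    center = center %||% rep(0, n),
    scale = scale %||% rep(1, n),
    out_shift = out_shift %||% rep(0, d),
    out_scale = out_scale %||% rep(1, d),
    feature_names = feature_names
  ), class = "target_mapping")
}

#' @export
print.target_mapping <- function(x, ...) {
  cat("<target_mapping> linear,", nrow(x$weights), "features ->",
      ncol(x$weights), "CV(s)\n")
  invisible(x)
}

#' Apply a target mapping to feature samples
#'
#' @param mapping a [target_mapping()].
#' @param X feature matrix (T x n) or [feature_matrix()].
#' @return T x d matrix of CV values, time order preserved.
#' @export
map_samples <- function(mapping, X) {
  X <- feature_values(X)
  if (ncol(X) != nrow(mapping$weights))
    stop("dimension mismatch: mapping expects ", nrow(mapping$weights),
         " features, got ", ncol(X))
  Xn <- sweep(sweep(X, 2, mapping$center), 2, mapping$scale, "/")
  Z <- Xn %*% mapping$weights
  sweep(sweep(Z, 2, mapping$out_shift), 2, mapping$out_scale, "/")
}

#' Training configuration for spectral-gap maximization
#'
#' Defaults follow the published protocol: Adam with learning rate 1e-3,
#' 100 epochs, batches of 2000 samples, linear target mapping.
#'
#' @param d CV dimension.
#' @param k_states target metastable-state count (gap \eqn{\sigma_k}).
#' @param epochs training epochs.
#' @param batch_size samples per batch.
#' @param learning_rate Adam step size.
#' @param r neighborhood fraction for the adaptive scales; `NULL` selects it
#'   by a short grid search ([select_r()]) before training.
#' @param alpha anisotropic diffusion constant.
#' @param seed RNG seed for permutations and initialization.
#' @return List of class `train_config`.
#' @export
train_config <- function(d = 1, k_states = 2, epochs = 100, batch_size = 2000,
                         learning_rate = 1e-3, r = NULL, alpha = 0.5,
                         seed = 1) {
  stopifnot(d >= 1, k_states >= 1, epochs >= 1, batch_size >= k_states + 1,
            learning_rate > 0)
  structure(list(d = as.integer(d), k_states = as.integer(k_states),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, r = r, alpha = alpha,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Spectral-gap objective and its gradient on a batch
#'
#' Composes the kernel pipeline (adaptive scales, Gaussian kernel,
#' anisotropic normalization, symmetrization, symmetric eigendecomposition)
#' and returns \eqn{\sigma_k = \lambda_{k-1} - \lambda_k} together with its
#' gradient with respect to the batch CV coordinates, computed analytically
#' by backpropagating the eigenvalue perturbation identity
#' \eqn{\partial \lambda / \partial \hat M = \psi \psi^\top} through the
#' kernel chain. The adaptive scales are treated as constants of the batch
#' (no gradient flows through the neighbor radii); see the methods vignette.
#'
#' @param Z_batch m x d batch of CV samples.
#' @param k_states metastable-state count.
#' @param config a [kernel_config()].
#' @param gradient if `FALSE`, skip the backward pass.
#' @return List with `sigma`, `grad` (m x d, `NULL` unless requested), and
#'   `degenerate` (`TRUE` when the gap pair is numerically degenerate and the
#'   gradient is unreliable — callers should skip the batch).
#' @export
spectral_gap_objective <- function(Z_batch, k_states = 2,
                                   config = kernel_config(),
                                   gradient = TRUE) {
  Z <- as_cv_matrix(Z_batch)
  m <- nrow(Z)
  if (m < k_states + 1) stop("batch smaller than k_states + 1")
  eps <- scale_matrix(Z, config$r, config$eps_floor)
  obj <- sg_forward_backward(Z, eps, k_states, config$alpha, gradient)
  obj
}

# Forward + analytic backward pass at fixed scale matrix eps.
# Chain: S -> g = exp(-S/eps) -> K = g/(rho_i rho_j)^alpha
#          -> Msym = K/sqrt(d_i d_j) -> eigenvalues -> sigma.
sg_forward_backward <- function(Z, eps, k_states, alpha, gradient) {
  m <- nrow(Z)
  S <- as.matrix(stats::dist(Z))^2
  dimnames(S) <- NULL
  g <- exp(-S / eps)
  rho <- rowSums(g)
  P <- outer(rho, rho)^alpha
  K <- g / P
  dK <- rowSums(K)
  Msym <- K / sqrt(outer(dK, dK))
  e <- eigen(Msym, symmetric = TRUE)
  lam <- e$values
  sigma <- lam[k_states] - lam[k_states + 1]
  degenerate <- abs(sigma) < 1e-6
  grad <- NULL
  if (gradient && !degenerate) {
    psi_a <- e$vectors[, k_states]
    psi_b <- e$vectors[, k_states + 1]
    A <- tcrossprod(psi_a) - tcrossprod(psi_b)  # d sigma / d Msym
    # Msym = K / sqrt(d_i d_j), d_i = sum_j K_ij
    b <- rowSums(A * Msym) / dK
    C <- A / sqrt(outer(dK, dK)) - 0.5 * outer(b, rep(1, m)) -
      0.5 * outer(rep(1, m), b)
    # K = g / (rho_i rho_j)^alpha, rho_i = sum_j g_ij
    cc <- rowSums(C * K) / rho
    G <- C / P - alpha * outer(cc, rep(1, m)) - alpha * outer(rep(1, m), cc)
    E <- -G * g / eps                            # d sigma / d S
    grad <- 4 * (rowSums(E) * Z - E %*% Z)       # d sigma / d Z
  }
  list(sigma = sigma, grad = grad, degenerate = degenerate,
       values = lam)
}

#' Train a target mapping by stochastic spectral-gap maximization
#'
#' Each epoch permutes the sample order, splits it into batches, maps every
#' batch through the current linear mapping, evaluates the spectral gap of
#' the batch's Markov transition matrix and takes an Adam ascent step on the
#' mapping weights. The returned mapping is the checkpoint with the best
#' epoch-averaged gap, with its output rescaled to \[0, 1\] over the training
#' set.
#'
#' @param X feature data: a [feature_matrix()] or plain T x n matrix.
#' @param cfg a [train_config()].
#' @param config_kernel kernel constants; its `r` is overridden by `cfg$r`
#'   (or by [select_r()] when `cfg$r` is `NULL`).
#' @param verbose print per-epoch progress.
#' @return List of class `spectral_map_fit`: `mapping` (best checkpoint),
#'   `history` (data frame: epoch, batch, sigma), `sigma_best`, `r`,
#'   `cfg`, and `converged` (`FALSE` when no epoch improved on the first).
#' @examples
#' \donttest{
#' z <- simulate_langevin(double_well(5), n_steps = 2e5, seed = 1)
#' X <- lift_trajectory(z, n = 10, seed = 2)
#' fit <- train_spectral_map(X, train_config(epochs = 10, batch_size = 500))
#' fit$sigma_best
#' }
#' @export
train_spectral_map <- function(X, cfg = train_config(),
                               config_kernel = kernel_config(),
                               verbose = FALSE) {
  Xv <- feature_values(X)
  T_ <- nrow(Xv)
  n <- ncol(Xv)
  if (T_ < cfg$batch_size)
    stop("batch_size exceeds the number of samples")
  set.seed(cfg$seed)
  center <- colMeans(Xv)
  scale <- apply(Xv, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xn <- sweep(sweep(Xv, 2, center), 2, scale, "/")

  r <- cfg$r
  if (is.null(r)) {
    sel <- select_r(X, cfg)
    r <- sel$r
    if (verbose) message("select_r: r = ", r)
  }
  kcfg <- kernel_config(alpha = cfg$alpha, r = r,
                        eps_floor = config_kernel$eps_floor)

  set.seed(cfg$seed) # restart the stream after any select_r scan
  W <- matrix(stats::rnorm(n * cfg$d, sd = 1 / sqrt(n)), n, cfg$d)
  adam <- adam_state(dim(W))
  n_batch <- T_ %/% cfg$batch_size
  hist <- vector("list", cfg$epochs)
  best <- list(sigma = -Inf, W = W)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(T_)
    sig_ep <- rep(NA_real_, n_batch)
    for (b in seq_len(n_batch)) {
      idx <- perm[((b - 1) * cfg$batch_size + 1):(b * cfg$batch_size)]
      Xb <- Xn[idx, , drop = FALSE]
      Zb <- Xb %*% W
      obj <- tryCatch(
        spectral_gap_objective(Zb, cfg$k_states, kcfg, gradient = TRUE),
        error = function(e) NULL)
      if (is.null(obj)) next # degenerate batch: skip, not fatal
      sig_ep[b] <- obj$sigma
      if (obj$degenerate || is.null(obj$grad)) next
      gW <- crossprod(Xb, obj$grad)
      if (any(!is.finite(gW)))
        stop("non-finite gradient at epoch ", ep, ", batch ", b)
      upd <- adam_step(adam, gW, cfg$learning_rate)
      adam <- upd$state
      W <- W + upd$delta # ascent
    }
    m_ep <- mean(sig_ep, na.rm = TRUE)
    if (is.finite(m_ep) && m_ep > best$sigma)
      best <- list(sigma = m_ep, W = W)
    hist[[ep]] <- data.frame(epoch = ep, batch = seq_len(n_batch),
                             sigma = sig_ep)
    if (verbose) message(sprintf("epoch %3d  mean sigma %.4f", ep, m_ep))
  }
  history <- do.call(rbind, hist)
  ep_mean <- tapply(history$sigma, history$epoch, mean, na.rm = TRUE)
  converged <- length(ep_mean) < 2 || any(ep_mean[-1] > ep_mean[1])
  if (!converged)
    warning("spectral gap did not improve over the first epoch")

  Z_all <- Xn %*% best$W
  out_shift <- apply(Z_all, 2, min)
  out_scale <- apply(Z_all, 2, max) - out_shift
  out_scale[out_scale < 1e-12] <- 1
  mapping <- target_mapping(best$W, center, scale, out_shift, out_scale,
                            feature_names = feature_names(X))
  structure(list(mapping = mapping, history = history,
                 sigma_best = best$sigma, r = r, cfg = cfg,
                 converged = converged),
            class = "spectral_map_fit")
}

#' @export
print.spectral_map_fit <- function(x, ...) {
  cat("<spectral_map_fit> d =", x$cfg$d, " k =", x$cfg$k_states,
      " r =", x$r, "\n  best epoch-mean sigma =",
      format(x$sigma_best, digits = 4), "\n")
  invisible(x)
}

#' Select the neighborhood fraction r by short training runs
#'
#' Trains a short-budget spectral map per candidate `r` and returns the value
#' with the largest attained epoch-mean spectral gap (ties go to the smaller
#' `r`). This mirrors the published protocol in which r is set by scanning a
#' grid for the largest converged gap.
#'
#' @param X feature data.
#' @param cfg a [train_config()]; its `epochs` are capped at `budget` for the
#'   scan.
#' @param r_grid candidate fractions in \[0, 1\].
#' @param budget epochs per scan run.
#' @return List with `r` (selected), `sigma` (per-grid-point gaps), `r_grid`.
#' @export
select_r <- function(X, cfg = train_config(),
                     r_grid = c(0.1, 0.3, 0.5, 0.65, 0.9), budget = 5) {
  stopifnot(length(r_grid) >= 1, all(r_grid >= 0), all(r_grid <= 1))
  if (length(r_grid) == 1)
    return(list(r = r_grid, sigma = NA_real_, r_grid = r_grid))
  sig <- vapply(r_grid, function(r) {
    cfg_r <- cfg
    cfg_r$r <- r
    cfg_r$epochs <- min(cfg$epochs, as.integer(budget))
    fit <- suppressWarnings(train_spectral_map(X, cfg_r))
    fit$sigma_best
  }, numeric(1))
  ord <- order(-sig, r_grid) # ties -> smaller r
  list(r = r_grid[ord[1]], sigma = sig, r_grid = r_grid)
}

adam_state <- function(dims, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = array(0, dims), v = array(0, dims), t = 0L,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

# Ascent step: returns the (positive) update for gradient g of the objective.
adam_step <- function(state, g, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * g
  state$v <- state$beta2 * state$v + (1 - state$beta2) * g^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(state = state, delta = lr * mhat / (sqrt(vhat) + state$eps))
}
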