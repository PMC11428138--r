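#' Toy potentials for overdamped Langevin benchmarks
#'
#' `double_well()` builds the symmetric quartic double well
#' \eqn{U(z) = h (z^2 - 1)^2} with minima at \eqn{z = \pm 1}, \eqn{U(\pm 1) = 0}
#' and barrier height \eqn{U(0) = h}. `harmonic_well()` builds
#' \eqn{U(z) = \kappa z^2 / 2}. `double_well_harmonic_2d()` is the separable
#' 2-D potential with a double well along the first (slow) coordinate and a
#' harmonic well along the second (fast) coordinate. `mueller_like_2d()` is a
#' smooth 2-D surface made of Gaussian wells/barriers, loosely shaped like the
#' classic Mueller–Brown test surface.
#'
#' A potential object carries analytic `value(z)` and `grad(z)` functions plus
#' an internal id that routes simulation to the compiled integrator.
#'
#' @param h barrier height in units of the energy scale (k_BT when beta = 1).
#' @param kappa harmonic spring constant.
#' @param A,centers,widths Gaussian amplitudes (negative = well), a `ng x 2`
#'   matrix of centers, and per-Gaussian isotropic widths.
#' @return An object of class `smap_potential` with elements `value`, `grad`,
#'   `dim`, and a suggested starting point `z0`.
#' @examples
#' pot <- double_well(5)
#' pot$value(0)   # barrier top: 5
#' pot$grad(1)    # minimum: 0
#' @export
double_well <- function(h = 5) {
  stopifnot(h > 0)
  new_potential(
    value = function(z) h * (z^2 - 1)^2,
    grad = function(z) 4 * h * z * (z^2 - 1),
    dim = 1L, z0 = -1, cpp_id = 1L, cpp_params = h,
    label = sprintf("double_well(h=%g)", h)
  )
}

#' @rdname double_well
#' @export
harmonic_well <- function(kappa = 1) {
  stopifnot(kappa > 0)
  new_potential(
    value = function(z) 0.5 * kappa * z^2,
    grad = function(z) kappa * z,
    dim = 1L, z0 = 0, cpp_id = 2L, cpp_params = kappa,
    label = sprintf("harmonic(kappa=%g)", kappa)
  )
}

#' @rdname double_well
#' @export
double_well_harmonic_2d <- function(h = 5, kappa = 100) {
  stopifnot(h > 0, kappa > 0)
  new_potential(
    value = function(z) h * (z[1]^2 - 1)^2 + 0.5 * kappa * z[2]^2,
    grad = function(z) c(4 * h * z[1] * (z[1]^2 - 1), kappa * z[2]),
    dim = 2L, z0 = c(-1, 0), cpp_id = 3L, cpp_params = c(h, kappa),
    label = sprintf("double_well+harmonic(h=%g,kappa=%g)", h, kappa)
  )
}

#' @rdname double_well
#' @export
mueller_like_2d <- function(A = c(-8, -8, -6, 3),
                            centers = rbind(c(-1, 0), c(1, 0), c(0, 1.2), c(0, 0.4)),
                            widths = c(0.6, 0.6, 0.6, 0.4)) {
  centers <- as.matrix(centers)
  ng <- length(A)
  stopifnot(nrow(centers) == ng, ncol(centers) == 2, length(widths) == ng,
            all(widths > 0))
  value <- function(z) {
    sum(A * exp(-((z[1] - centers[, 1])^2 + (z[2] - centers[, 2])^2) /
                  (2 * widths^2)))
  }
  grad <- function(z) {
    e <- A * exp(-((z[1] - centers[, 1])^2 + (z[2] - centers[, 2])^2) /
                   (2 * widths^2))
    c(-sum(e * (z[1] - centers[, 1]) / widths^2),
      -sum(e * (z[2] - centers[, 2]) / widths^2))
  }
  new_potential(
    value = value, grad = grad, dim = 2L, z0 = centers[which.min(A), ],
    cpp_id = 4L, cpp_params = c(ng, A, centers[, 1], centers[, 2], widths),
    label = "mueller_like_2d"
  )
}

new_potential <- function(value, grad, dim, z0, cpp_id = NA_integer_,
                          cpp_params = numeric(), label = "potential") {
  structure(list(value = value, grad = grad, dim = as.integer(dim), z0 = z0,
                 cpp_id = cpp_id, cpp_params = cpp_params, label = label),
            class = "smap_potential")
}

#' @export
print.smap_potential <- function(x, ...) {
  cat("<smap_potential> ", x$label, " (dim ", x$dim, ")\n", sep = "")
  invisible(x)
}

#' Simulate overdamped Langevin dynamics
#'
#' Integrates the overdamped Langevin equation
#' \deqn{z_{t+1} = z_t - D \nabla U(z_t)\, dt + \sqrt{2 D\, dt / \beta}\ \xi_t,
#'   \quad \xi_t \sim N(0, 1)}
#' with the Euler--Maruyama scheme. The stationary distribution is the
#' Boltzmann density \eqn{\propto e^{-\beta U(z)}}. The diffusion coefficient
#' defaults to unity, matching the reduced-dynamics convention in which all
#' position dependence of the diffusion is neglected during learning.
#'
#' @param potential an `smap_potential` (see [double_well()]), or any list with
#'   `grad`, `dim`, `z0` fields.
#' @param beta inverse temperature 1/(k_B T); `Inf` gives noiseless gradient
#'   descent.
#' @param dt integration time step (natural units).
#' @param n_steps number of integration steps.
#' @param z0 starting point; defaults to the potential's suggested start.
#' @param thin keep every `thin`-th frame (output sampling interval is
#'   `dt * thin`).
#' @param D diffusion coefficient (constant).
#' @param seed optional RNG seed set before integration.
#' @param bound divergence guard: an error is raised if |z| exceeds it.
#' @return A numeric matrix (frames x dim) of class `smap_trajectory` with
#'   attribute `dt` equal to the output sampling interval `dt * thin`.
#' @examples
#' z <- simulate_langevin(double_well(5), beta = 1, dt = 1e-3,
#'                        n_steps = 1e5, seed = 1)
#' range(z)
#' @export
simulate_langevin <- function(potential, beta = 1, dt = 1e-3, n_steps,
                              z0 = NULL, thin = 10L, D = 1, seed = NULL,
                              bound = 1e6) {
  stopifnot(inherits(potential, "smap_potential") || is.list(potential),
            dt > 0, n_steps >= 1, D > 0, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- potential$dim
  if (is.null(z0)) z0 <- potential$z0
  stopifnot(length(z0) == d)
  thin <- as.integer(thin)
  if (!is.na(potential$cpp_id)) {
    out <- .sim_langevin_cpp(potential$cpp_id, potential$cpp_params,
                             as.numeric(z0), beta, dt, as.numeric(n_steps),
                             thin, D, bound)
  } else {
    out <- sim_langevin_r(potential, as.numeric(z0), beta, dt,
                          as.integer(n_steps), thin, D, bound)
  }
  structure(out, dt = dt * thin, class = c("smap_trajectory", class(out)))
}

# Interpreted fallback for user-supplied potentials; fine for small n_steps.
sim_langevin_r <- function(potential, z0, beta, dt, n_steps, thin, D, bound) {
  d <- length(z0)
  noise <- if (is.finite(beta)) sqrt(2 * D * dt / beta) else 0
  n_out <- n_steps %/% thin
  out <- matrix(NA_real_, n_out, d)
  z <- z0
  row <- 0L
  for (t in seq_len(n_steps)) {
    z <- z - D * potential$grad(z) * dt +
      if (noise > 0) noise * stats::rnorm(d) else 0
    if (any(!is.finite(z)) || any(abs(z) > bound))
      stop("trajectory diverged; reduce the time step dt")
    if (t %% thin == 0L) {
      row <- row + 1L
      out[row, ] <- z
    }
  }
  out
}

#' Lift a low-dimensional trajectory into a high-dimensional feature space
#'
#' Emulates the premise that molecular features are driven by a few slow
#' coordinates plus fast, adiabatically equilibrating noise: the observed
#' feature matrix is
#' \deqn{X = z A_{slow}^\top + \sum_f u_f A_{f}^\top + \eta,}
#' where `z` is the supplied slow trajectory, the `u_f` are
#' Ornstein--Uhlenbeck processes with relaxation time `tau_fast` (much shorter
#' than the slow relaxation time), the columns of `A = [A_slow, A_fast]` are
#' random orthonormal directions, and `eta` is small i.i.d. Gaussian noise.
#' The ground-truth slow coordinate and mixing directions are attached for
#' parameter-recovery tests.
#'
#' @param z slow trajectory (vector or frames x d matrix), e.g. from
#'   [simulate_langevin()].
#' @param n ambient feature dimension (must exceed `d + n_fast`).
#' @param n_fast number of fast Ornstein--Uhlenbeck modes.
#' @param tau_fast relaxation time of the fast modes, in the same time units
#'   as the trajectory sampling interval `dt`; must satisfy
#'   `tau_fast < tau_slow / 100` (explicit time-scale separation).
#' @param tau_slow nominal slow relaxation time used to validate separation.
#'   The default (150) corresponds to the Kramers time of the h = 5 double
#'   well in natural units.
#' @param sd_fast stationary standard deviation of each fast mode.
#' @param sd_noise standard deviation of the i.i.d. measurement noise.
#' @param dt sampling interval of `z`; defaults to its `dt` attribute.
#' @param seed optional RNG seed.
#' @return A [feature_matrix()] (frames x n) with attributes `ground_truth`
#'   (list with `z`, `A_slow`) for recovery tests.
#' @export
lift_trajectory <- function(z, n = 10, n_fast = 3, tau_fast = 0.5,
                            tau_slow = 150, sd_fast = 0.3, sd_noise = 0.01,
                            dt = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (is.null(dt)) dt <- attr(z, "dt") %||% 1
  d <- ncol(z)
  T_ <- nrow(z)
  if (n < d + n_fast)
    stop("ambient dimension n must be at least d + n_fast")
  if (tau_fast >= tau_slow / 100)
    stop("time-scale separation violated: need tau_fast < tau_slow / 100")
  # random orthonormal mixing directions
  Q <- qr.Q(qr(matrix(stats::rnorm(n * (d + n_fast)), n)))
  A_slow <- Q[, seq_len(d), drop = FALSE]
  A_fast <- Q[, d + seq_len(n_fast), drop = FALSE]
  U <- vapply(seq_len(n_fast),
              function(i) ou_process(T_, tau_fast, sd_fast, dt),
              numeric(T_))
  X <- unclass(z) %*% t(A_slow)
  if (n_fast > 0) X <- X + U %*% t(A_fast)
  X <- X + matrix(stats::rnorm(T_ * n, sd = sd_noise), T_)
  fm <- feature_matrix(X, dt = dt,
                       names = sprintf("f%03d", seq_len(n) - 1L))
  attr(fm, "ground_truth") <- list(z = unclass(z), A_slow = A_slow)
  fm
}

# Exact stationary discretization of an OU process via a recursive filter.
ou_process <- function(n, tau, sd, dt) {
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1, sd = sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

#' Two-state telegraph signal and toy Markov chains
#'
#' `telegraph_signal()` samples a discrete-time two-state process with
#' per-step switching probabilities `k1 * dt` (state 1 to 2) and `k2 * dt`
#' (state 2 to 1), i.e. exponential dwell times with rates `k1`, `k2` in the
#' continuous limit. `sample_chain()` samples a finite Markov chain from a
#' row-stochastic transition matrix. Both serve as exact oracles for
#' first-passage and coarse-graining routines.
#'
#' @param k1,k2 exit rates of states 1 and 2 (1/time).
#' @param n number of time steps.
#' @param dt time step; `k1 * dt` and `k2 * dt` must lie in (0, 1).
#' @param seed optional RNG seed.
#' @return For `telegraph_signal()`, an integer vector of labels in {1, 2}
#'   with attribute `dt`. For `sample_chain()`, an integer vector of states.
#' @export
telegraph_signal <- function(k1, k2, n, dt = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(k1 * dt, k2 * dt)
  stopifnot(all(p > 0), all(p < 1))
  # draw alternating geometric dwell lengths until n steps are covered
  labels <- integer(0)
  state <- sample(1:2, 1, prob = c(k2, k1) / (k1 + k2)) # stationary start
  while (length(labels) < n) {
    m <- 1000L + 2L * ceiling(n * max(p))
    states <- rep_len(c(state, 3L - state), m)
    dwells <- 1L + stats::rgeom(m, p[states])
    labels <- c(labels, rep.int(states, dwells))
    state <- 3L - states[m]
  }
  structure(labels[seq_len(n)], dt = dt)
}

#' @rdname telegraph_signal
#' @param P row-stochastic transition matrix.
#' @param init initial state (default: sampled from the uniform distribution).
#' @export
sample_chain <- function(P, n, init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- as.matrix(P)
  k <- nrow(P)
  stopifnot(ncol(P) == k, all(P >= 0),
            max(abs(rowSums(P) - 1)) < 1e-8)
  out <- integer(n)
  s <- if (is.null(init)) sample.int(k, 1) else as.integer(init)
  # vectorized inverse-CDF sampling, one uniform per step
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(n)
  for (t in seq_len(n)) {
    s <- findInterval(u[t], cum[s, ], left.open = TRUE) + 1L
    out[t] <- s
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
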