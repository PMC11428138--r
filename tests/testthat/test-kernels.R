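test_that("scale_matrix implements the adaptive kNN-radius rule", {
  # collinear points 0, 1, 3: eta = (1, 1, 2) at r = 0
  Z <- matrix(c(0, 1, 3), 3, 1)
  eps <- scale_matrix(Z, r = 0)
  expect_equal(eps[1, 2], 1^2 + 1^2)
  expect_equal(eps[1, 3], 1^2 + 2^2)
  expect_equal(eps, t(eps))

  # r = 0 -> nearest neighbor, r = 1 -> farthest neighbor
  set.seed(4)
  Z <- matrix(rnorm(30), 15, 2)
  expect_equal(scale_matrix(Z, 0), pmax(outer(oracle_eta(Z, 0)^2,
                                              oracle_eta(Z, 0)^2, "+"),
                                        1e-12))
  expect_equal(scale_matrix(Z, 1), pmax(outer(oracle_eta(Z, 1)^2,
                                              oracle_eta(Z, 1)^2, "+"),
                                        1e-12))

  # mostly-duplicated batch is degenerate
  Zdup <- matrix(c(1, 1, 1, 1, 2), 5, 1)
  expect_error(scale_matrix(Zdup, 0.5), "degenerate")
})

test_that("gaussian and anisotropic kernels match hand evaluation", {
  # identical samples -> g = 1
  Zs <- matrix(0, 3, 2)
  expect_equal(gaussian_kernel(Zs, matrix(1, 3, 3)),
               matrix(1, 3, 3))
  # ||dz||^2 = eps -> exp(-1)
  Z2 <- matrix(c(0, 1), 2, 1)
  g <- gaussian_kernel(Z2, matrix(1, 2, 2))
  expect_equal(g[1, 2], exp(-1))
  expect_equal(diag(g), c(1, 1))

  # two-sample anisotropic case, alpha = 1/2, evaluated by the oracle
  K <- anisotropic_kernel(g, 0.5)
  expect_equal(K, oracle_kernel(Z2, matrix(1, 2, 2), 0.5))
  expect_equal(K[1, 1], 1 / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(K[1, 2], exp(-1) / (1 + exp(-1)), tolerance = 1e-10)

  # alpha = 0 leaves the kernel unchanged; alpha = 1 matches oracle
  set.seed(9)
  Z <- matrix(rnorm(24), 12, 2)
  eps <- scale_matrix(Z, 0.4)
  g <- gaussian_kernel(Z, eps)
  expect_identical(anisotropic_kernel(g, 0), g)
  expect_equal(anisotropic_kernel(g, 1), oracle_kernel(Z, eps, 1))

  # permutation equivariance
  p <- sample(12)
  expect_equal(anisotropic_kernel(g, 0.5)[p, p],
               anisotropic_kernel(g[p, p], 0.5))
})

test_that("row and symmetric normalizations share the Markov spectrum", {
  set.seed(11)
  # 2x2 symmetric case: both normalizations coincide; eigenvalues by trace
  Z2 <- matrix(c(0, 1), 2, 1)
  K <- anisotropic_kernel(gaussian_kernel(Z2, matrix(1, 2, 2)), 0.5)
  M <- row_normalize(K)
  expect_equal(M, symmetrize_kernel(K))
  expect_equal(M, matrix(c(0.7311, 0.2689, 0.2689, 0.7311), 2,
                         byrow = TRUE), tolerance = 1e-4)
  lam <- markov_spectrum(symmetrize_kernel(K))$values
  expect_equal(lam, c(1, 2 * K[1, 1] / sum(K[1, ]) - 1), tolerance = 1e-10)

  # random batches: eig(M) = eig(M_sym) within 1e-8, rows sum to 1,
  # top eigenvector of M_sym proportional to sqrt(degree)
  for (i in 1:20) {
    Z <- matrix(rnorm(30 * 2), 30)
    eps <- scale_matrix(Z, runif(1, 0.2, 0.8))
    K <- anisotropic_kernel(gaussian_kernel(Z, eps), 0.5)
    M <- row_normalize(K)
    Ms <- symmetrize_kernel(K)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
    expect_true(all(M >= 0))
    expect_lt(max(abs(Ms - t(Ms))), 1e-10)
    lam_M <- sort(Re(eigen(M)$values), decreasing = TRUE) # dense oracle
    lam_S <- markov_spectrum(Ms)$values
    expect_equal(lam_S, lam_M, tolerance = 1e-8)
    expect_equal(lam_S[1], 1, tolerance = 1e-8)
    v <- markov_spectrum(Ms)$vectors[, 1]
    d <- sqrt(rowSums(K))
    expect_lt(max(abs(v / (v[1] / d[1]) - d)), 1e-6)
  }

  expect_error(row_normalize(matrix(c(1, -1, 0, 1), 2)), "degenerate")
  expect_equal(row_normalize(matrix(5, 1, 1)), matrix(1, 1, 1))
})

test_that("spectral gap and implied time scales follow their definitions", {
  expect_equal(spectral_gap(c(1, 0.98, 0.10, 0.05), k = 2), 0.88)
  expect_equal(spectral_gap(c(1, 1, 0, 0), k = 2), 1)
  expect_equal(spectral_gap(c(1, 0.5), k = 1), 0.5)
  expect_error(spectral_gap(c(1, 0.5), k = 2), "out of range")

  expect_equal(implied_timescales(exp(-1)), 1)
  expect_equal(implied_timescales(0.5), 1 / log(2))
  expect_identical(implied_timescales(1), Inf)
  expect_identical(implied_timescales(-0.2), NA_real_)
  lam <- seq(0.5, 0.999, length.out = 20)
  expect_true(all(diff(implied_timescales(lam)) > 0))
})

test_that("markov_model satisfies its invariants and is motion-invariant", {
  set.seed(21)
  z <- two_cluster_batch(100, sd = 0.05, seed = 21)
  mm <- markov_model(z, kernel_config(r = 0.45), k_states = 2)
  expect_lt(max(abs(rowSums(mm$M) - 1)), 1e-10)
  expect_equal(mm$values[1], 1, tolerance = 1e-8)
  expect_equal(mm$sigma, mm$values[2] - mm$values[3])

  # rigid motion and sample permutation leave sigma unchanged
  Z <- cbind(z, 0.1 * rnorm(100))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  cfg <- kernel_config(r = 0.45)
  s0 <- markov_model(Z, cfg)$sigma
  expect_equal(markov_model(Z %*% R + 3, cfg)$sigma, s0, tolerance = 1e-10)
  p <- sample(100)
  expect_equal(markov_model(Z[p, ], cfg)$sigma, s0, tolerance = 1e-10)

  # two well-separated clusters: lambda_1 >= 0.9 and sigma(k=2) > sigma(k=3)
  expect_gte(mm$values[2], 0.9)
  expect_gt(mm$sigma, spectral_gap(mm$values, k = 3))
})
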