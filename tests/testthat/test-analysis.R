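test_that("free_energy_profile inverts known Boltzmann densities", {
  set.seed(71)
  # uniform samples: flat profile within sampling noise
  fu <- free_energy_profile(runif(2e5), bins = 20)
  expect_lt(max(fu$F, na.rm = TRUE), 0.1)

  # standard normal: F(z) = z^2/2 on well-populated bins
  z <- rnorm(5e5)
  fn <- free_energy_profile(z, bins = 50)
  ok <- !is.na(fn$F) & fn$count >= 100
  expect_lt(max(abs(fn$F[ok] - (fn$center[ok]^2 / 2 -
                                  min(fn$center[ok]^2 / 2)))), 0.5)

  # beta rescales F; monotone affine rescaling of z relabels bins only
  fb <- free_energy_profile(z, bins = 50, beta = 2)
  expect_equal(fb$F, fn$F / 2, tolerance = 1e-10)
  fa <- free_energy_profile(3 * z + 1, bins = 50)
  expect_equal(fa$F, fn$F, tolerance = 1e-10)

  expect_error(free_energy_profile(numeric(0)), "empty")
})

test_that("min_free_energy_path finds the saddle crossing", {
  # flat landscape: minimal-hop (Chebyshev) path
  flat <- structure(list(x = 1:6, y = 1:5, F = matrix(0, 6, 5),
                         count = matrix(10, 6, 5), beta = 1),
                    class = "fe_landscape")
  p <- min_free_energy_path(flat, c(1, 1), c(6, 3), as_bins = TRUE)
  expect_equal(nrow(p), 1 + max(abs(c(6, 3) - c(1, 1))))

  # two wells separated by a ridge with a low saddle: the path must cross
  # at the saddle; verified against an exhaustive path-enumeration oracle
  F <- matrix(0, 5, 5)
  F[3, ] <- c(8, 6, 1, 6, 8) # ridge along row 3, saddle at column 3
  land <- structure(list(x = 1:5, y = 1:5, F = F,
                         count = matrix(10, 5, 5), beta = 1),
                    class = "fe_landscape")
  p2 <- min_free_energy_path(land, c(1, 3), c(5, 3), as_bins = TRUE)
  expect_true(any(p2$i == 3 & p2$j == 3))
  oracle <- oracle_min_path(F, c(1, 3), c(5, 3))
  expect_equal(sum((p2$F[-1] + head(p2$F, -1)) / 2), oracle$cost,
               tolerance = 1e-6)

  # barrier property: the path maximum is at least both endpoint energies
  expect_gte(max(p2$F), p2$F[1])
  expect_gte(max(p2$F), p2$F[nrow(p2)])

  # masked bins disconnect regions
  F3 <- matrix(c(0, NA, 0), 3, 1)[, c(1, 1, 1)]
  land3 <- structure(list(x = 1:3, y = 1:3, F = F3,
                          count = (!is.na(F3)) * 10, beta = 1),
                     class = "fe_landscape")
  expect_error(min_free_energy_path(land3, c(1, 1), c(3, 3),
                                    as_bins = TRUE), "disconnected")
})

test_that("markovianity_profile handles degenerate transition regions", {
  set.seed(72)
  z <- rnorm(5000)
  # never entering ts: p* = 0 with a warning
  expect_warning(m0 <- markovianity_profile(z, ts = c(10, 11)), "never")
  expect_equal(attr(m0, "p_star"), 0)
  # entirely inside ts: degenerate, p = 1 everywhere
  expect_warning(m1 <- markovianity_profile(z, ts = c(-100, 100)),
                 "degenerate")
  expect_equal(attr(m1, "p_star"), 1)
  expect_true(attr(m1, "degenerate"))
  expect_true(all(m1$p_ts_given_z[m1$count > 0] == 1))
})

test_that("diffusion_profile recovers known diffusion coefficients", {
  # static trajectory: D = 0
  ds <- diffusion_profile(rep(c(0, 0, 0, 1e-9), 500), dt = 1, bins = 2,
                          lags = 1:3, min_count = 10)
  expect_lt(max(abs(ds$D), na.rm = TRUE), 1e-9)

  # OU processes: short-lag slope equals the noise D, independent of the
  # spring constant (closed-form MSD/2 ~ D tau for kappa tau << 1)
  set.seed(73)
  dt <- 1e-3
  for (kap in c(1, 4)) {
    n <- 4e5
    a <- exp(-kap * dt)
    sdst <- sqrt(1 / kap) # D = 1
    zou <- as.numeric(stats::filter(
      c(rnorm(1, sd = sdst), rnorm(n - 1, sd = sdst * sqrt(1 - a^2))),
      a, method = "recursive"))
    dp <- diffusion_profile(zou, dt = dt, bins = 8, lags = 1:5,
                            min_count = 2000)
    expect_equal(stats::median(dp$D, na.rm = TRUE), 1, tolerance = 0.1)
  }
})

test_that("diffusion_corrected reduces to F for constant D", {
  set.seed(74)
  z <- rnorm(1e5)
  fe <- free_energy_profile(z, bins = 30)
  dp <- structure(data.frame(center = fe$center, D = 2, count = fe$count),
                  dt = 1, lags = 1:5,
                  class = c("diffusion_profile", "data.frame"))
  fd <- diffusion_corrected(fe, dp)
  expect_equal(fd$F, fe$F, tolerance = 1e-12) # exact identity
  expect_equal(attr(fd, "discrepancy"), 0, tolerance = 1e-12)

  # D = D0 * e at a single bin shifts that bin by exactly 1 k_BT
  dp2 <- dp
  ref_bin <- which.min(fe$F) # D0 is taken at the F minimum
  target <- which(!is.na(fe$F) & seq_along(fe$F) != ref_bin)[1]
  dp2$D[target] <- 2 * exp(1)
  fd2 <- diffusion_corrected(fe, dp2)
  expect_equal(fd2$F[target], fe$F[target] - 1, tolerance = 1e-10)
  delta <- abs(fd2$F - fe$F)
  expect_true(all(delta[-target] < 1e-10, na.rm = TRUE))

  # mild variation (factor < e): mean discrepancy below 1 k_BT
  dp3 <- dp
  ok <- !is.na(fe$F)
  dp3$D[ok] <- 2 * exp(runif(sum(ok), -0.9, 0.9))
  fd3 <- diffusion_corrected(fe, dp3)
  expect_lt(attr(fd3, "discrepancy"), 1)

  expect_error(diffusion_corrected(free_energy_profile(z, bins = 10), dp),
               "mismatch")
})

test_that("mfpt_estimate matches closed-form telegraph kinetics", {
  lab <- telegraph_signal(k1 = 8, k2 = 8, n = 4e5, dt = 1e-3, seed = 75)
  mf <- mfpt_estimate(lab, dt = 1e-3, lags = c(1, 2, 5), n_boot = 50)
  # symmetric rates: MFPT ratio ~ 1
  expect_equal(mf[["1->2"]]$plateau / mf[["2->1"]]$plateau, 1,
               tolerance = 0.15)
  # detailed balance: the MFPT ratio is the inverse of the equilibrium
  # population ratio (MFPT_1->2 / MFPT_2->1 = k2/k1 = pi_1/pi_2)
  lab2 <- telegraph_signal(k1 = 16, k2 = 4, n = 4e5, dt = 1e-3, seed = 76)
  mf2 <- mfpt_estimate(lab2, dt = 1e-3, lags = c(1, 2, 5), n_boot = 50)
  pop <- table(lab2) / length(lab2)
  expect_equal(mf2[["1->2"]]$plateau / mf2[["2->1"]]$plateau,
               as.numeric(pop[1] / pop[2]), tolerance = 0.15)
  # CI contains the point estimate
  expect_true(mf2[["1->2"]]$ci[1] <= mf2[["1->2"]]$plateau &&
                mf2[["1->2"]]$plateau <= mf2[["1->2"]]$ci[2])
  # one-way trajectory: the unobserved direction is flagged infinite
  mf3 <- mfpt_estimate(c(rep(1L, 200), rep(3L, 50)), dt = 1, lags = 1:2,
                       n_boot = 0)
  expect_true(is.finite(mf3[["1->3"]]$plateau))
  expect_identical(mf3[["3->1"]]$plateau, Inf)
  expect_identical(mf3[["3->1"]]$n_events, 0L)
})
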