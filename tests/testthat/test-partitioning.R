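block_chain <- function() {
  # two irreducible blocks: 2 states and 3 states
  M <- matrix(0, 5, 5)
  M[1:2, 1:2] <- 0.5
  M[3:5, 3:5] <- 1 / 3
  M
}

test_that("propagate_markov is exact matrix power", {
  M <- matrix(c(0.7311, 0.2689, 0.2689, 0.7311), 2, byrow = TRUE)
  expect_equal(propagate_markov(M, 1), M)
  expect_equal(propagate_markov(M, 2), M %*% M, tolerance = 1e-12)
  expect_equal(propagate_markov(M, 7), M %*% M %*% M %*% M %*% M %*% M %*% M,
               tolerance = 1e-12)
  # block-diagonal chain converges to per-block stationary rows
  Mt <- propagate_markov(block_chain(), 2^20)
  expect_equal(Mt[1, ], c(0.5, 0.5, 0, 0, 0), tolerance = 1e-10)
  expect_equal(Mt[5, ], c(0, 0, 1 / 3, 1 / 3, 1 / 3), tolerance = 1e-10)
  expect_lt(max(abs(rowSums(Mt) - 1)), 1e-10)
})

test_that("coarse_grain recovers blocks, flags ambiguity, finds TS", {
  # exactly block-diagonal: two pure states, empty TS
  p <- coarse_grain(block_chain(), 2)
  expect_equal(length(unique(p$labels)), 2)
  expect_true(all(p$labels > 0))
  expect_equal(p$labels[1], p$labels[2])
  expect_equal(p$labels[3], p$labels[5])
  expect_lt(max(abs(rowSums(p$sink_probs) - 1)), 1e-8)

  # all-identical rows: fully mixed, everything is transition state
  expect_warning(pu <- coarse_grain(matrix(0.25, 4, 4), 2), "distinct")
  expect_true(all(pu$labels == 0))

  # 3-block nearest-neighbor chain with a weak middle state at k = 2:
  # the middle has committor ~ 1/2 (exact oracle) and must be labeled TS
  P <- matrix(0, 5, 5)
  P[1, ] <- c(0.9, 0.1, 0, 0, 0)
  P[2, ] <- c(0.1, 0.8, 0.1, 0, 0)
  P[3, ] <- c(0, 0.5, 0, 0.5, 0)
  P[4, ] <- c(0, 0, 0.1, 0.8, 0.1)
  P[5, ] <- c(0, 0, 0, 0.1, 0.9)
  q <- oracle_committor(P, A = 1:2, B = 4:5)
  expect_equal(q[3], 0.5, tolerance = 1e-10)
  pc <- coarse_grain(P, 2, delta = 0.1)
  expect_equal(pc$labels[3], 0L)
  expect_true(all(pc$labels[c(1, 2)] > 0))
  expect_equal(pc$sink_probs[3, 1], 0.5, tolerance = 0.1)

  # TS fraction decreases monotonically as delta -> 0
  fr <- vapply(c(0.3, 0.1, 0.02), function(d) {
    mean(coarse_grain(P, 2, delta = d)$labels == 0)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))

  # permutation equivariance: PMP^-1 gives identically permuted labels
  pr <- c(4, 1, 5, 2, 3)
  Pp <- P[pr, pr]
  pc2 <- coarse_grain(Pp, 2, delta = 0.1)
  agree <- mean(outer(pc$labels[pr], pc$labels[pr], "==") ==
                  outer(pc2$labels, pc2$labels, "=="))
  expect_equal(agree, 1)
})

test_that("merge_batches reconciles batch labelings through Ward", {
  part <- function(lab, k) {
    sink <- outer(pmax(lab, 1), seq_len(k), function(a, b)
      as.numeric(a == b))
    structure(list(labels = lab, sink_probs = sink, k_states = k,
                   delta = 0.1, t = 1), class = "cv_partition")
  }
  # identical clusterings merge to identity
  p1 <- part(c(1L, 1L, 2L, 2L), 2)
  cent1 <- rbind(c(0), c(1))
  m <- merge_batches(list(p1, p1), list(cent1, cent1), 2)
  expect_identical(m$labels[[1]], m$labels[[2]])

  # label-permuted copy of the same clustering gets consistent labels
  p2 <- part(c(2L, 2L, 1L, 1L), 2)
  cent2 <- rbind(c(1), c(0))
  m2 <- merge_batches(list(p1, p2), list(cent1, cent2), 2)
  expect_identical(m2$labels[[1]], m2$labels[[2]])

  # TS labels pass through unchanged
  p3 <- part(c(1L, 0L, 2L, 2L), 2)
  m3 <- merge_batches(list(p3), list(cent1), 2)
  expect_equal(m3$labels[[1]][2], 0L)

  # 4 centroids on a line at k = 2: {0, 0.1} vs {0.9, 1.0}, matching the
  # exhaustive Ward oracle
  cents <- list(rbind(0, 0.9), rbind(0.1, 1.0))
  m4 <- merge_batches(list(p1, p1), cents, 2)
  ward <- oracle_ward_1d(c(0, 0.9, 0.1, 1.0), 2)
  expect_equal(m4$assignment$global == m4$assignment$global[1],
               ward == ward[1])

  expect_error(merge_batches(list(p1), list(rbind(0)), 2), "fewer")
})

test_that("fit_boundary separates states with a nonlinear boundary", {
  set.seed(61)
  # linearly separable blobs: perfect training separation
  Z <- rbind(matrix(rnorm(100, -1, 0.2), 50, 2),
             matrix(rnorm(100, 1, 0.2), 50, 2))
  lab <- rep(1:2, each = 50)
  bd <- fit_boundary(Z, lab)
  expect_equal(bd$predict(Z), lab)

  # XOR arrangement requires the nonlinear kernel
  n <- 40
  Zx <- rbind(matrix(rnorm(2 * n, sd = 0.15), n, 2) +
                matrix(c(1, 1), n, 2, byrow = TRUE),
              matrix(rnorm(2 * n, sd = 0.15), n, 2) +
                matrix(c(-1, -1), n, 2, byrow = TRUE),
              matrix(rnorm(2 * n, sd = 0.15), n, 2) +
                matrix(c(1, -1), n, 2, byrow = TRUE),
              matrix(rnorm(2 * n, sd = 0.15), n, 2) +
                matrix(c(-1, 1), n, 2, byrow = TRUE))
  labx <- rep(c(1L, 1L, 2L, 2L), each = n)
  bdx <- fit_boundary(Zx, labx)
  expect_gte(mean(bdx$predict(Zx) == labx), 0.95)

  # affine rescaling of the CV leaves predictions unchanged (standardized)
  Zr <- sweep(Zx, 2, c(3, 0.2), "*") + 5
  bdr <- fit_boundary(Zr, labx)
  expect_equal(bdr$predict(Zr), bdx$predict(Zx))

  expect_error(fit_boundary(Z, rep(1L, 100)), "at least 2")
  # TS samples (label 0) are excluded from the fit
  lab0 <- lab
  lab0[1:5] <- 0L
  expect_silent(fit_boundary(Z, lab0))
})

test_that("partition_cv places the TS over the free-energy barrier", {
  # long run so both wells are properly populated; moderate r keeps the
  # adaptive scales within one well even under occupancy fluctuations
  z <- simulate_langevin(double_well(5), n_steps = 1e7, seed = 62)
  set.seed(63)
  zs <- z[sample(nrow(z), 3000), 1]
  pc <- partition_cv(zs, k_states = 2, kernel_config(r = 0.35),
                     batch_size = 1000, delta = 0.1, seed = 1)
  expect_setequal(sort(unique(pc$labels)), 0:2)
  # states ordered along the CV; wells on either side of the barrier
  expect_lt(mean(zs[pc$labels == 1]), -0.5)
  expect_gt(mean(zs[pc$labels == 2]), 0.5)
  # the TS span contains the barrier top (z = 0)
  expect_lt(pc$ts_span[1], 0)
  expect_gt(pc$ts_span[2], 0)
  # sink rows sum to one in every batch
  for (b in pc$batches)
    expect_lt(max(abs(rowSums(b$sink_probs) - 1)), 1e-8)
})
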