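#' Free-energy profile along a collective variable
#'
#' Boltzmann inversion of the sampled density,
#' \eqn{F(z) = -\beta^{-1} \ln p(z)}, on a uniform histogram. The profile is
#' shifted so its minimum is zero; empty bins are masked as `NA`, never
#' interpolated.
#'
#' @param z CV samples (vector).
#' @param bins number of bins, or a vector of break points.
#' @param beta inverse temperature (1/k_BT); F is in k_BT units when
#'   `beta = 1`.
#' @param range optional c(min, max) histogram support.
#' @return Object of class `fe_profile`: data frame with `center`, `F`,
#'   `count`; attributes `beta`, `breaks`.
#' @export
free_energy_profile <- function(z, bins = 50, beta = 1, range = NULL) {
  z <- as.numeric(z)
  z <- z[is.finite(z)]
  if (length(z) == 0) stop("empty trajectory")
  breaks <- make_breaks(z, bins, range)
  counts <- bin_counts(z, breaks)
  width <- diff(breaks)
  dens <- counts / (sum(counts) * width)
  F <- rep(NA_real_, length(counts))
  F[counts > 0] <- -log(dens[counts > 0]) / beta
  F <- F - min(F, na.rm = TRUE)
  out <- data.frame(center = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    F = F, count = counts)
  structure(out, beta = beta, breaks = breaks,
            class = c("fe_profile", "data.frame"))
}

#' Two-dimensional free-energy landscape
#'
#' @param Z T x 2 matrix of CV samples.
#' @param bins bins per axis (scalar or length 2).
#' @param beta inverse temperature.
#' @return Object of class `fe_landscape`: list with `x`, `y` (bin centers),
#'   `F` (matrix, `NA` on empty bins, min-shifted to 0), `count`.
#' @export
free_energy_landscape <- function(Z, bins = 50, beta = 1) {
  Z <- as_cv_matrix(Z)
  stopifnot(ncol(Z) == 2)
  bins <- rep(bins, length.out = 2)
  bx <- make_breaks(Z[, 1], bins[1], NULL)
  by <- make_breaks(Z[, 2], bins[2], NULL)
  ix <- bin_index(Z[, 1], bx)
  iy <- bin_index(Z[, 2], by)
  counts <- matrix(0, length(bx) - 1, length(by) - 1)
  tab <- table(factor(ix, levels = seq_len(nrow(counts))),
               factor(iy, levels = seq_len(ncol(counts))))
  counts[] <- as.numeric(tab)
  dens <- counts / (sum(counts) * outer(diff(bx), diff(by)))
  F <- matrix(NA_real_, nrow(counts), ncol(counts))
  F[counts > 0] <- -log(dens[counts > 0]) / beta
  F <- F - min(F, na.rm = TRUE)
  structure(list(x = (bx[-1] + bx[-length(bx)]) / 2,
                 y = (by[-1] + by[-length(by)]) / 2,
                 F = F, count = counts, beta = beta),
            class = "fe_landscape")
}

#' Minimum free-energy path on a 2-D landscape
#'
#' Least-cost path between two landscape bins through populated bins only,
#' on the 8-connected bin graph with edge cost equal to the mean free energy
#' of the two endpoint bins (Dijkstra). A vanishing hop penalty breaks ties
#' in favor of shorter paths, so a flat landscape yields a minimal-hop
#' (Chebyshev-straight) path.
#'
#' @param F2d an `fe_landscape` from [free_energy_landscape()].
#' @param from,to endpoints: CV coordinates `c(x, y)` (mapped to the nearest
#'   populated bin) or integer bin indices `c(i, j)` when `as_bins = TRUE`.
#' @param as_bins interpret `from`/`to` as bin indices.
#' @return Data frame with the path: `i`, `j` (bin indices), `x`, `y` (bin
#'   centers), `F` along the path.
#' @export
min_free_energy_path <- function(F2d, from, to, as_bins = FALSE) {
  stopifnot(inherits(F2d, "fe_landscape"))
  F <- F2d$F
  pop <- which(!is.na(F), arr.ind = TRUE)
  if (nrow(pop) < 2) stop("landscape has fewer than 2 populated bins")
  id <- matrix(NA_integer_, nrow(F), ncol(F))
  id[pop] <- seq_len(nrow(pop))
  locate <- function(p) {
    if (as_bins) {
      v <- id[p[1], p[2]]
      if (is.na(v)) stop("endpoint bin is unpopulated")
      return(v)
    }
    d2 <- (F2d$x[pop[, 1]] - p[1])^2 + (F2d$y[pop[, 2]] - p[2])^2
    which.min(d2)
  }
  a <- locate(from)
  b <- locate(to)
  # 8-connected edges among populated bins
  shifts <- cbind(di = c(1, 1, 0, -1), dj = c(0, 1, 1, 1))
  ed <- NULL
  w <- NULL
  hop <- max(F, na.rm = TRUE) * 1e-9 + 1e-12
  for (s in seq_len(nrow(shifts))) {
    ni <- pop[, 1] + shifts[s, 1]
    nj <- pop[, 2] + shifts[s, 2]
    ok <- ni >= 1 & ni <= nrow(F) & nj >= 1 & nj <= ncol(F)
    nb <- rep(NA_integer_, nrow(pop))
    nb[ok] <- id[cbind(ni[ok], nj[ok])]
    keep <- !is.na(nb)
    ed <- rbind(ed, cbind(seq_len(nrow(pop))[keep], nb[keep]))
    w <- c(w, (F[pop][keep] + F[pop[nb[keep], , drop = FALSE]]) / 2 + hop)
  }
  gr <- igraph::graph_from_edgelist(ed, directed = FALSE)
  path <- suppressWarnings(
    igraph::shortest_paths(gr, a, b, weights = w)$vpath[[1]])
  if (length(path) == 0) stop("endpoints are disconnected through populated bins")
  v <- as.integer(path)
  data.frame(i = pop[v, 1], j = pop[v, 2],
             x = F2d$x[pop[v, 1]], y = F2d$y[pop[v, 2]],
             F = F[pop[v, , drop = FALSE]])
}

#' Bayesian Markovianity test along a one-dimensional coordinate
#'
#' For a transition region `ts = [a, b]`, a frame is on a transition path if
#' it lies inside (a, b) during an excursion that enters through one boundary
#' and leaves through the other. The profile
#' \eqn{p(ts|z) = p(z|ts)\,p(ts)/p(z)} is estimated per histogram bin by
#' counting crossing frames in one direction; by detailed balance the two
#' directions have identical probability, so the estimator averages the
#' a-to-b and b-to-a counts to halve its variance. The maximum \eqn{p^*} is
#' reported: for Markovian dynamics in the overdamped regime
#' \eqn{p^* = 1/4}; memory pushes \eqn{p^*} below 1/4.
#'
#' @param z CV trajectory (vector, uniform time spacing).
#' @param ts transition region `c(a, b)`, e.g. the transition-state span from
#'   [partition_cv()].
#' @param bins histogram bins (count or breaks).
#' @param min_count bins with fewer frames are masked when taking the
#'   maximum.
#' @return Object of class `markovianity_profile`: data frame with `center`,
#'   `p_ts_given_z`, `count`; attributes `p_star`, `ts`, `degenerate` (no
#'   boundary crossings observable), `n_paths` (transition-path count).
#' @export
markovianity_profile <- function(z, ts, bins = 50, min_count = 100) {
  z <- as.numeric(z)
  stopifnot(length(ts) == 2, ts[1] < ts[2])
  a <- ts[1]
  b <- ts[2]
  region <- ifelse(z <= a, -1L, ifelse(z >= b, 1L, 0L))
  degenerate <- all(region == 0L)
  on_ab <- rep(FALSE, length(z))
  on_ba <- rep(FALSE, length(z))
  n_paths <- 0L
  if (degenerate) {
    warning("trajectory never leaves the transition region; ",
            "p(ts|z) = 1 everywhere is degenerate")
    on_ab[] <- TRUE
    on_ba[] <- TRUE
  } else if (all(region != 0L)) {
    warning("trajectory never enters the transition region; p* = 0")
  } else {
    r <- rle(region)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    inside <- which(r$values == 0L)
    for (k in inside) {
      if (k == 1L || k == length(r$values)) next # truncated excursion
      if (r$values[k - 1L] == -1L && r$values[k + 1L] == 1L) {
        on_ab[starts[k]:ends[k]] <- TRUE
        n_paths <- n_paths + 1L
      } else if (r$values[k - 1L] == 1L && r$values[k + 1L] == -1L) {
        on_ba[starts[k]:ends[k]] <- TRUE
        n_paths <- n_paths + 1L
      }
    }
  }
  breaks <- make_breaks(z, bins, NULL)
  idx <- bin_index(z, breaks)
  nb <- length(breaks) - 1
  count <- tabulate(idx, nb)
  tp_count <- (tabulate(idx[on_ab], nb) + tabulate(idx[on_ba], nb)) / 2
  p <- ifelse(count > 0, tp_count / count, NA_real_)
  eligible <- count >= min_count & !is.na(p)
  p_star <- if (degenerate) 1 else if (any(eligible)) max(p[eligible]) else 0
  out <- data.frame(center = (breaks[-1] + breaks[-nb - 1]) / 2,
                    p_ts_given_z = p, count = count)
  structure(out, p_star = p_star, ts = c(a, b), degenerate = degenerate,
            n_paths = n_paths,
            class = c("markovianity_profile", "data.frame"))
}

#' Coordinate-dependent diffusion coefficients
#'
#' In each bin b of the coordinate, D(b) is the slope of the conditional
#' half mean-squared displacement
#' \eqn{\langle (z(t+\tau) - z(t))^2 \rangle / 2} against lag \eqn{\tau}
#' (linear regression over the lag window, conditioning on \eqn{z(t) \in b}).
#' In the short-time limit this recovers the local diffusion coefficient of
#' overdamped dynamics regardless of the local drift.
#'
#' @param z CV trajectory (vector, uniform spacing `dt`).
#' @param dt sampling interval of `z`.
#' @param bins histogram bins (count or breaks).
#' @param lags integer lag window in frames (>= 2 lags).
#' @param min_count bins with fewer conditioning frames are masked.
#' @return Object of class `diffusion_profile`: data frame with `center`,
#'   `D`, `count`; attributes `dt`, `lags`.
#' @export
diffusion_profile <- function(z, dt, bins = 50, lags = 1:5,
                              min_count = 50) {
  z <- as.numeric(z)
  lags <- sort(unique(as.integer(lags)))
  stopifnot(length(lags) >= 2, all(lags >= 1), dt > 0)
  breaks <- make_breaks(z, bins, NULL)
  nb <- length(breaks) - 1
  n <- length(z)
  maxlag <- max(lags)
  base <- seq_len(n - maxlag)
  idx <- bin_index(z[base], breaks)
  count <- tabulate(idx, nb)
  msd2 <- matrix(NA_real_, nb, length(lags)) # half-MSD per bin per lag
  for (li in seq_along(lags)) {
    tau <- lags[li]
    disp2 <- (z[base + tau] - z[base])^2 / 2
    sums <- rowsum(disp2, idx, reorder = FALSE)
    rows <- as.integer(rownames(sums))
    msd2[rows, li] <- sums[, 1] / count[rows]
  }
  D <- rep(NA_real_, nb)
  tau_t <- lags * dt
  for (bn in which(count >= min_count)) {
    fit <- stats::lm.fit(cbind(1, tau_t), msd2[bn, ])
    D[bn] <- fit$coefficients[2]
  }
  out <- data.frame(center = (breaks[-1] + breaks[-nb - 1]) / 2,
                    D = D, count = count)
  structure(out, dt = dt, lags = lags,
            class = c("diffusion_profile", "data.frame"))
}

#' Diffusion-corrected free-energy profile
#'
#' Folds coordinate-dependent diffusion into the free energy:
#' \deqn{F_D(z) = F(z) - \beta^{-1} \ln [D(z) / D_0],}
#' where \eqn{D_0} is the diffusion coefficient at the reference (first
#' metastable, typically folded) state. Constant D leaves F unchanged;
#' locally faster diffusion lowers the effective barrier. The mean absolute
#' discrepancy from F quantifies how much position-dependent friction
#' distorts the landscape.
#'
#' @param F_prof an `fe_profile` from [free_energy_profile()].
#' @param D_prof a `diffusion_profile` on the same bins.
#' @param beta inverse temperature.
#' @param D0 reference diffusion coefficient; default: D at the populated
#'   bin where F attains its minimum (the deepest, reference state).
#' @return Object of class `fe_profile` with extra columns `D` and
#'   `F_uncorrected`; attribute `discrepancy` = mean |F_D - F| over shared
#'   bins.
#' @export
diffusion_corrected <- function(F_prof, D_prof, beta = 1, D0 = NULL) {
  stopifnot(inherits(F_prof, "fe_profile"),
            inherits(D_prof, "diffusion_profile"))
  if (nrow(F_prof) != nrow(D_prof) ||
      max(abs(F_prof$center - D_prof$center)) > 1e-8)
    stop("bin mismatch between free-energy and diffusion profiles")
  D <- D_prof$D
  ok <- !is.na(F_prof$F) & !is.na(D) & D > 0
  if (is.null(D0)) {
    cand <- which(ok)
    D0 <- D[cand[which.min(F_prof$F[cand])]]
  }
  FD <- rep(NA_real_, nrow(F_prof))
  FD[ok] <- F_prof$F[ok] - log(D[ok] / D0) / beta
  shift <- min(FD, na.rm = TRUE)
  FD <- FD - shift
  disc <- mean(abs(FD[ok] - (F_prof$F[ok] - shift)))
  out <- data.frame(center = F_prof$center, F = FD, count = F_prof$count,
                    D = D, F_uncorrected = F_prof$F)
  structure(out, beta = beta, D0 = D0, discrepancy = disc,
            breaks = attr(F_prof, "breaks"),
            class = c("fe_profile", "data.frame"))
}

#' Mean first-passage times between metastable states
#'
#' Counts transitions between state core sets directly from a per-frame
#' label sequence: for each ordered pair of (non-transition-state) states,
#' the MFPT is the average time from a frame in the source core to the first
#' subsequent entry into the target core, evaluated on the trajectory
#' subsampled at each lag. The estimate is reported across the lag grid with
#' a plateau value (first lag where successive estimates agree within 5%)
#' and a 0.95 block-bootstrap confidence interval at the plateau lag. Blocks
#' span 50 mean passages (or 10 lags, whichever is larger), so resampling
#' preserves the dwell-time correlation structure.
#'
#' @param labels integer per-frame state labels (0 = transition state;
#'   transition-state frames belong to no core).
#' @param dt frame interval (time units).
#' @param lags integer lag grid in frames.
#' @param n_boot bootstrap resamples (0 disables the CI).
#' @param level confidence level.
#' @return Object of class `mfpt_estimate`: list per direction `"i->j"` with
#'   `lags`, `mfpt` (per lag), `plateau`, `plateau_lag`, `ci`, `n_events`.
#'   Directions with no observed transition carry `plateau = Inf`.
#' @export
mfpt_estimate <- function(labels, dt = 1, lags = 1:10, n_boot = 1000,
                          level = 0.95) {
  labels <- as.integer(labels)
  lags <- sort(unique(as.integer(lags)))
  states <- sort(setdiff(unique(labels), 0L))
  stopifnot(length(states) >= 2, all(lags >= 1))
  out <- list()
  for (i in states) for (j in setdiff(states, i)) {
    key <- sprintf("%d->%d", i, j)
    est <- vapply(lags, function(l) {
      mfpt_at_lag(labels[seq(1, length(labels), by = l)], i, j) * l * dt
    }, numeric(1))
    if (all(!is.finite(est))) {
      out[[key]] <- list(lags = lags, mfpt = est, plateau = Inf,
                         plateau_lag = NA, ci = c(NA, NA), n_events = 0L)
      next
    }
    pl_idx <- length(est)
    for (l in seq_along(est)[-1]) {
      if (is.finite(est[l]) && is.finite(est[l - 1]) &&
          abs(est[l] - est[l - 1]) < 0.05 * est[l - 1]) {
        pl_idx <- l
        break
      }
    }
    plat_lag <- lags[pl_idx]
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0) {
      # blocks must span many dwell periods, not just the lag
      bl <- max(10L * plat_lag, ceiling(50 * est[pl_idx] / dt), 10L)
      boots <- vapply(seq_len(n_boot), function(bb) {
        lb <- block_resample(labels, bl)
        mfpt_at_lag(lb[seq(1, length(lb), by = plat_lag)], i, j) *
          plat_lag * dt
      }, numeric(1))
      boots <- boots[is.finite(boots)]
      if (length(boots) > 10)
        ci <- stats::quantile(boots, c((1 - level) / 2, (1 + level) / 2),
                              names = FALSE)
    }
    out[[key]] <- list(lags = lags, mfpt = est, plateau = est[pl_idx],
                       plateau_lag = plat_lag, ci = ci,
                       n_events = count_transitions(labels, i, j))
  }
  structure(out, dt = dt, class = "mfpt_estimate")
}

# Mean, over frames in core i, of the number of (subsampled) steps until the
# first subsequent visit to core j. Returns Inf when no passage is observed.
mfpt_at_lag <- function(lab, i, j) {
  pos <- which(lab == j)
  src <- which(lab == i)
  if (length(pos) == 0 || length(src) == 0) return(Inf)
  k <- findInterval(src, pos) + 1L # first j-visit after each source frame
  ok <- k <= length(pos)
  if (!any(ok)) return(Inf)
  mean(pos[k[ok]] - src[ok])
}

count_transitions <- function(lab, i, j) {
  core <- lab[lab != 0L]
  rl <- rle(core)$values
  sum(rl[-length(rl)] == i & rl[-1] == j)
}

block_resample <- function(x, block) {
  n <- length(x)
  nb <- ceiling(n / block)
  starts <- sample.int(max(n - block + 1L, 1L), nb, replace = TRUE)
  idx <- rep(starts, each = block) + rep(seq_len(block) - 1L, nb)
  x[idx[seq_len(n)]]
}

make_breaks <- function(z, bins, range) {
  if (length(bins) > 1) return(as.numeric(bins))
  rg <- if (is.null(range)) base::range(z) else range
  if (diff(rg) == 0) rg <- rg + c(-0.5, 0.5)
  seq(rg[1], rg[2], length.out = bins + 1)
}

bin_index <- function(z, breaks) {
  idx <- findInterval(z, breaks, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(breaks) - 1] <- NA_integer_
  idx
}

bin_counts <- function(z, breaks) {
  tabulate(bin_index(z, breaks), length(breaks) - 1)
}
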