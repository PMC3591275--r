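#' Triangular lattice specification
#'
#' A periodic triangular lattice of `n1 x n2` primitive cells with spacing
#' `a`, the geometry on which the velocity dynamics become exactly solvable
#' when positions are frozen: the linear part diagonalizes in Fourier modes
#' over the discrete Brillouin zone.
#'
#' @param a lattice spacing (um).
#' @param n1,n2 primitive cell counts (even numbers give a clean Brillouin
#'   sampling and a rectangular-periodic particle arrangement).
#' @return A `lattice_spec`: `a`, `n1`, `n2`, `prim` (2 x 2 primitive
#'   vectors by row), `neighbors` (6 x 2 nearest-neighbor displacements),
#'   `recip` (reciprocal basis).
#' @export
lattice_spec <- function(a = 16, n1 = 48, n2 = 48) {
  stopifnot(a > 0, n1 >= 2, n2 >= 2)
  if (n1 %% 2L || n2 %% 2L)
    warning("odd lattice dimensions; even n1, n2 recommended")
  prim <- rbind(c(a, 0), c(a / 2, a * sqrt(3) / 2))
  nb <- rbind(prim[1, ], prim[2, ], prim[2, ] - prim[1, ])
  nb <- rbind(nb, -nb)
  recip <- 2 * pi * t(solve(prim))
  structure(list(a = a, n1 = as.integer(n1), n2 = as.integer(n2),
                 prim = prim, neighbors = nb, recip = recip),
            class = "lattice_spec")
}

# particle positions of the lattice folded into a rectangular box for
# display; the dynamical adjacency is built by lattice_graph(), not from
# these folded coordinates
lattice_positions <- function(spec) {
  i <- rep(seq_len(spec$n1) - 1L, times = spec$n2)
  j <- rep(seq_len(spec$n2) - 1L, each = spec$n1)
  Lx <- spec$n1 * spec$a
  Ly <- spec$n2 * spec$a * sqrt(3) / 2
  x <- (i * spec$a + j * spec$a / 2) %% Lx
  y <- j * spec$a * sqrt(3) / 2
  list(pos = cbind(x, y), box = box_spec(Lx, Ly), i = i, j = j)
}

# exact 6-neighbor adjacency of the triangular lattice on the
# {n1 a1, n2 a2} torus, in lattice index coordinates (m1, m2); sector s of
# each bond follows the +x-anchored sector rule of the infinite lattice:
# +a1 -> 1, +a2 -> 2, a2-a1 -> 3, -a1 -> 4, -a2 -> 5, a1-a2 -> 6
lattice_graph <- function(spec) {
  n1 <- spec$n1; n2 <- spec$n2
  n <- n1 * n2
  m1 <- rep(seq_len(n1) - 1L, times = n2)
  m2 <- rep(seq_len(n2) - 1L, each = n1)
  idx <- function(a, b) 1L + (a %% n1) + n1 * (b %% n2)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(-1L, 1L),
                 c(-1L, 0L), c(0L, -1L), c(1L, -1L))
  nbr <- matrix(NA_integer_, n, 6)
  for (s in seq_along(shifts))
    nbr[, s] <- idx(m1 + shifts[[s]][1], m2 + shifts[[s]][2])
  valid <- !is.na(nbr)
  from <- rep.int(seq_len(n), 6)
  g <- list(nbr = nbr, dist = matrix(spec$a, n, 6),
            rbar = rep(spec$a, n), degree = rep(6L, n),
            edges = data.frame(from = from, to = as.vector(nbr)),
            cutoff = 1.1 * spec$a,
            box = box_spec(n1 * spec$a, n2 * spec$a * sqrt(3) / 2),
            symmetrized = TRUE)
  class(g) <- "neighbor_graph"
  g
}

#' Relaxation rates of the lattice velocity modes
#'
#' With positions frozen on the lattice, the damping-plus-alignment dynamics
#' decouple into Fourier modes with relaxation rate
#' `lambda_q = alpha + beta * sum_e (1 - cos(q . e))` over the 6
#' nearest-neighbor displacements `e`. The uniform mode q = 0 relaxes at
#' exactly `alpha`; all rates satisfy `lambda_q >= alpha`.
#'
#' @param spec a [lattice_spec()].
#' @param alpha damping rate (1/h).
#' @param beta alignment coupling (1/h).
#' @return A `mode_spectrum`: `q` (M x 2 wavevectors), `lambda` (rates),
#'   `alpha`, `beta`, `spec`.
#' @export
mode_rates <- function(spec, alpha, beta) {
  m1 <- rep(seq_len(spec$n1) - 1L, times = spec$n2)
  m2 <- rep(seq_len(spec$n2) - 1L, each = spec$n1)
  q <- cbind(m1 / spec$n1, m2 / spec$n2) %*% spec$recip
  lambda <- alpha + beta * rowSums(1 - cos(q %*% t(spec$neighbors)))
  structure(list(q = q, lambda = lambda, alpha = alpha, beta = beta,
                 spec = spec), class = "mode_spectrum")
}

# per-mode stationary autocovariance of dv/dt = -lambda v + sigma eta with
# OU noise of correlation time tau (unit stationary variance), evaluated at
# lag t (sigma = 1); closed form
#   C(t) = [exp(-t/tau) - exp(-lambda t)/(lambda tau)] / (lambda^2 - 1/tau^2)
# with the analytic limit at lambda*tau = 1
mode_autocov <- function(lambda, tau, t) {
  mu <- 1 / tau
  degen <- abs(lambda - mu) < 1e-10 * mu
  out <- numeric(length(lambda))
  l <- lambda[!degen]
  out[!degen] <- (exp(-mu * t) - (mu / l) * exp(-l * t)) / (l^2 - mu^2)
  if (any(degen))
    out[degen] <- exp(-mu * t) * (1 + mu * t) / (2 * mu^2)
  out
}

#' Closed-form temporal velocity autocorrelation (frozen lattice)
#'
#' Mode-averaged stationary autocovariance of the OU-driven linear velocity
#' dynamics, normalized to 1 at lag 0. Each mode contributes a
#' two-exponential term mixing its relaxation rate `lambda_q` and the noise
#' time `1/tau`.
#'
#' @param spectrum a [mode_rates()] result.
#' @param tau OU correlation time (h).
#' @param t lag grid (h), >= 0.
#' @param drop_uniform drop the q = 0 (uniform translation) mode, default
#'   `TRUE`: empirical correlation estimators subtract the instantaneous
#'   mean velocity, which removes exactly this mode, so comparisons against
#'   mean-removed curves must drop it here too.
#' @return A [correlation_curve()].
#' @export
analytic_temporal_autocorr <- function(spectrum, tau, t, drop_uniform = TRUE) {
  stopifnot(all(t >= 0), tau > 0)
  lam <- spectrum$lambda
  if (drop_uniform) lam <- lam[-which.min(lam)]
  c0 <- sum(mode_autocov(lam, tau, 0))
  vals <- vapply(t, function(tt) sum(mode_autocov(lam, tau, tt)),
                 numeric(1)) / c0
  correlation_curve(t, vals * c0, vals, rep(length(lam), length(t)))
}

#' Closed-form equal-time spatial velocity correlation (frozen lattice)
#'
#' Inverse discrete Fourier sum of the per-mode stationary variances
#' `1 / (lambda_q (lambda_q + 1/tau))`, normalized at r = 0. With no
#' coupling (beta = 0) the correlation is a delta at r = 0.
#'
#' @param spectrum a [mode_rates()] result.
#' @param tau OU correlation time (h).
#' @param r_vectors M x 2 matrix of displacement vectors (um), ideally
#'   lattice vectors.
#' @inheritParams analytic_temporal_autocorr
#' @return A [correlation_curve()] with `lag` the displacement moduli.
#' @export
analytic_spatial_corr <- function(spectrum, tau, r_vectors,
                                  drop_uniform = TRUE) {
  r_vectors <- matrix(r_vectors, ncol = 2)
  mu <- 1 / tau
  lam <- spectrum$lambda
  q <- spectrum$q
  if (drop_uniform) {
    k0 <- which.min(lam)
    lam <- lam[-k0]
    q <- q[-k0, , drop = FALSE]
  }
  w <- 1 / (lam * (lam + mu))
  w0 <- sum(w)
  vals <- vapply(seq_len(nrow(r_vectors)), function(k) {
    sum(w * cos(q %*% r_vectors[k, ])) / w0
  }, numeric(1))
  correlation_curve(sqrt(rowSums(r_vectors^2)), vals * w0, vals,
                    rep(length(w), nrow(r_vectors)))
}

# convenience: analytic curves along the first lattice direction and a time
# grid, as used by the lattice fitting objective
lattice_curves <- function(alpha, beta, tau, spec = lattice_spec(),
                           t_grid = seq(0, 4, by = 0.1),
                           kmax = floor(spec$n1 / 2)) {
  spectrum <- mode_rates(spec, alpha, beta)
  rv <- outer(0:kmax, spec$prim[1, ])
  list(spatial = analytic_spatial_corr(spectrum, tau, rv),
       temporal = analytic_temporal_autocorr(spectrum, tau, t_grid))
}

#' Frozen-position lattice simulation
#'
#' Integrates the velocity dynamics (damping, alignment, OU noise) with the
#' particle positions pinned to the triangular lattice, and returns the
#' empirical spatial correlation along the first lattice direction and the
#' Lagrangian temporal autocorrelation — the stochastic counterpart of the
#' closed forms, used to validate them.
#'
#' @param spec a [lattice_spec()].
#' @param config a [sim_config()] (`alpha`, `beta`, `tau`, `sigma0`, `dt`,
#'   `seed` are used).
#' @param t_end simulated duration (h); the first `t_burn` hours are
#'   discarded as transient.
#' @param t_burn transient (h), default 5.
#' @param snapshot_every snapshot cadence (h).
#' @param kmax maximal neighbor-shell index for the spatial curve.
#' @return List `spatial`, `temporal` ([correlation_curve()]s), `vel`
#'   (final velocities), `box`.
#' @export
frozen_sim <- function(spec, config, t_end, t_burn = 5,
                       snapshot_every = 0.1, kmax = 8) {
  set.seed(config$seed)
  lat <- lattice_positions(spec)
  n <- nrow(lat$pos)
  graph <- lattice_graph(spec)   # exact torus adjacency, 6 bonds per site
  state <- particle_state(lat$pos, eta = matrix(rnorm(2 * n), n, 2))
  cfg <- config
  cfg$A_rep <- 0; cfg$A_att <- 0  # positions frozen: no interaction forces
  nsteps <- round(t_end / config$dt)
  every <- max(1L, round(snapshot_every / config$dt))
  snaps <- list()
  times <- numeric(0)
  for (step in seq_len(nsteps)) {
    state$eta <- ou_step(state$eta, config$dt, config$tau)
    state <- velocity_step(state, graph, cfg, config$dt)
    if (step %% every == 0L && step * config$dt > t_burn) {
      times <- c(times, step * config$dt)
      snaps[[length(snaps) + 1L]] <- state$vel
    }
  }
  # spatial correlation on exact lattice displacements (shifts along the
  # first lattice direction), averaged over snapshots and both components;
  # the per-snapshot mean is removed, matching the particle estimators
  i <- lat$i; j <- lat$j
  idx <- matrix(seq_len(n)[order(j, i)], spec$n1, spec$n2)
  corr_k <- function(V, k) {
    sh <- idx[c((k + 1):spec$n1, seq_len(k)), , drop = FALSE]
    num <- den <- 0
    for (ci in 1:2) {
      u <- V[, ci] - mean(V[, ci])
      num <- num + mean(u[idx] * u[sh])
      den <- den + mean(u[idx]^2)
    }
    num / den
  }
  ks <- 0:kmax
  sp_vals <- rowMeans(sapply(snaps, function(V)
    vapply(ks, function(k) if (k == 0) 1 else corr_k(V, k), numeric(1))))
  spatial <- correlation_curve(ks * spec$a, sp_vals, sp_vals / sp_vals[1],
                               rep(n * length(snaps), length(ks)))
  traj <- list(times = times, vel = snaps, config = config)
  temporal_x <- temporal_autocorrelation(traj, "x", "lagrangian")
  temporal_y <- temporal_autocorrelation(traj, "y", "lagrangian")
  temporal <- average_curves(list(temporal_x, temporal_y))
  list(spatial = spatial, temporal = temporal, vel = state$vel,
       box = lat$box)
}

#' Leader-driven border progression estimate
#'
#' Mean border position under the entrainment picture: each leader appearing
#' at rate `rate` (per mm of border per hour) entrains a border portion of
#' lateral extent `ell_corr` (the velocity correlation length) at speed
#' `V_L` instead of the baseline `v0`, so the mean border speed grows
#' linearly and the position quadratically:
#' `x(t) = v0 t + 0.5 (rate/1000) ell_corr (V_L - v0) t^2`. After
#' `switch_time` the rate changes and the trajectory continues with matched
#' value and slope.
#'
#' @param rate,rate_late leader creation rates (1/(mm h)).
#' @param V_L leader speed (um/h).
#' @param v0 baseline border speed (um/h).
#' @param ell_corr velocity correlation length (um).
#' @param t times (h).
#' @param switch_time rate switch time (h), default 20.
#' @return Mean border positions (um) at `t`.
#' @export
border_estimate <- function(rate, V_L, v0, ell_corr, t,
                            rate_late = rate, switch_time = 20) {
  stopifnot(all(t >= 0), rate >= 0, rate_late >= 0, ell_corr >= 0)
  c_early <- 0.5 * (rate / 1000) * ell_corr * (V_L - v0)
  c_late <- 0.5 * (rate_late / 1000) * ell_corr * (V_L - v0)
  ts <- switch_time
  x_s <- v0 * ts + c_early * ts^2
  v_s <- v0 + 2 * c_early * ts
  ifelse(t < ts,
         v0 * t + c_early * t^2,
         x_s + v_s * (t - ts) + c_late * (t - ts)^2)
}
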