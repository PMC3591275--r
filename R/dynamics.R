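#' Particle state container
#'
#' Per-cell state of a simulation: position, velocity, OU noise state, kind
#' (bulk follower or leader), the stored leader target velocity, and an
#' alive flag. Leaders additionally carry a per-leader speed cap. The vector
#' `leader_y_created` records the y-coordinate of every leader creation event
#' (used by the spatial exclusion rule).
#'
#' @param pos,vel,eta N x 2 matrices (um, um/h, dimensionless).
#' @param kind integer vector, 0 = bulk, 1 = leader.
#' @param ids integer particle ids.
#' @return A `particle_state` list.
#' @export
particle_state <- function(pos, vel = NULL, eta = NULL, kind = NULL,
                           ids = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 2, all(is.finite(pos)))
  if (is.null(vel)) vel <- matrix(0, n, 2)
  if (is.null(eta)) eta <- matrix(0, n, 2)
  if (is.null(kind)) kind <- integer(n)
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(nrow(as.matrix(vel)) == n, nrow(as.matrix(eta)) == n,
            length(kind) == n, length(ids) == n)
  s <- list(pos = pos, vel = as.matrix(vel), eta = as.matrix(eta),
            kind = as.integer(kind),
            leader_v = matrix(NA_real_, n, 2),
            leader_vcap = rep(NA_real_, n),
            alive = rep(TRUE, n),
            ids = as.integer(ids),
            leader_y_created = numeric(0))
  class(s) <- "particle_state"
  s
}

#' @export
print.particle_state <- function(x, ...) {
  cat("<particle_state>", nrow(x$pos), "particles (",
      sum(x$kind == 1L), "leaders )\n")
  invisible(x)
}

#' Exact Ornstein-Uhlenbeck noise update
#'
#' Advances the dimensionless OU noise state by `dt` with the exact
#' stationarity-preserving update `eta' = eta * exp(-dt/tau) +
#' sqrt(1 - exp(-2 dt/tau)) * zeta`, `zeta` standard gaussian per component.
#' The stationary per-component variance is 1 and the autocorrelation decays
#' as `exp(-t/tau)` for any `dt`.
#'
#' @param eta N x 2 matrix of noise states.
#' @param dt time step (h), > 0.
#' @param tau correlation time (h), > 0.
#' @return Updated N x 2 matrix.
#' @export
ou_step <- function(eta, dt, tau) {
  stopifnot(dt > 0, tau > 0)
  eta <- as.matrix(eta)
  ef <- exp(-dt / tau)
  eta * ef + sqrt(1 - ef^2) * matrix(rnorm(length(eta)), nrow(eta), ncol(eta))
}

#' Noise amplitude as a function of local density
#'
#' Constant mode returns `sigma0`. Density mode implements a noise amplitude
#' that increases as the local density drops below the reference density:
#' `sigma = sigma0 * (1 + kappa * max(0, 1 - d/d0))`, equal to `sigma0`
#' wherever `d >= d0` and at most `sigma0 * (1 + kappa)`.
#'
#' @param d local densities (1/um^2), > 0.
#' @param config a [sim_config()] (fields `sigma0`, `density_noise`, `kappa`,
#'   `d0`).
#' @return Noise amplitudes (um/h^2), same length as `d`.
#' @export
noise_amplitude <- function(d, config) {
  stopifnot(all(d > 0))
  if (!config$density_noise) return(rep(config$sigma0, length(d)))
  config$sigma0 * (1 + config$kappa * pmax(0, 1 - d / config$d0))
}

# accumulate per-particle sums over directed edges
edge_rowsum <- function(contrib, from, n) {
  out <- matrix(0, n, 2)
  if (length(from)) {
    s <- rowsum(contrib, from)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

#' One explicit-Euler velocity update
#'
#' Advances all bulk-cell velocities by `dt` under damping, neighbor velocity
#' alignment (plain sum over sector neighbors, or the mean if `align_mean`),
#' pairwise central forces, the OU noise drive, and an optional external
#' force. Leader velocities are left untouched (they are prescribed by
#' [update_leader()]).
#'
#' @param state a [particle_state()].
#' @param graph the current [find_neighbors()] graph.
#' @param config a [sim_config()].
#' @param dt time step (h).
#' @param sigma per-particle noise amplitudes; default `sigma0` everywhere.
#' @param f_ext optional N x 2 external force matrix (um/h^2), e.g. the
#'   free-surface repulsion.
#' @return The state with updated `vel`.
#' @export
velocity_step <- function(state, graph, config, dt, sigma = NULL,
                          f_ext = NULL) {
  n <- nrow(state$pos)
  v <- state$vel
  from <- graph$edges$from
  to <- graph$edges$to
  if (is.null(sigma)) sigma <- rep(config$sigma0, n)

  align <- edge_rowsum(v[to, , drop = FALSE] - v[from, , drop = FALSE], from, n)
  if (config$align_mean) {
    deg <- tabulate(from, n)
    align <- align / pmax(deg, 1)
  }
  rvec <- edge_displacements(state$pos, from, to, graph$box)
  fsum <- edge_rowsum(pair_force(rvec, config), from, n)
  if (!is.null(f_ext)) fsum <- fsum + f_ext

  acc <- -config$alpha * v + config$beta * align + fsum + sigma * state$eta
  vnew <- v + dt * acc
  leaders <- state$kind == 1L
  vnew[leaders, ] <- v[leaders, , drop = FALSE]
  if (!all(is.finite(vnew)))
    stop("velocity_step: non-finite velocity; the integration step dt = ",
         dt, " h is too large for these parameters")
  state$vel <- vnew
  state
}

#' One kinematic position update
#'
#' Overdamped kinematics `x <- x + v dt` with periodic wrapping where the
#' box is periodic.
#'
#' @inheritParams velocity_step
#' @param box a [box_spec()]; default from `config`.
#' @return The state with updated `pos`.
#' @export
position_step <- function(state, config, dt, box = as_box(config)) {
  stopifnot(all(is.finite(state$vel)))
  p <- state$pos + state$vel * dt
  if (box$periodic_x) p[, 1] <- p[, 1] %% box$Lx
  if (box$periodic_y) p[, 2] <- p[, 2] %% box$Ly
  state$pos <- p
  state
}

# hexagonal packing of approximately n points at density n/(Lx*Ly);
# returns the nearest complete nx x ny grid (within ~1% of n)
hex_packing <- function(n, Lx, Ly, jitter = 0) {
  a <- sqrt(2 * Lx * Ly / (sqrt(3) * n))
  nx <- max(1L, round(Lx / a))
  ny <- max(1L, round(n / nx))
  ax <- Lx / nx
  dy <- Ly / ny
  j <- rep(seq_len(ny) - 1L, each = nx)
  i <- rep(seq_len(nx) - 1L, times = ny)
  pos <- cbind((i + 0.25 + 0.5 * (j %% 2)) * ax, (j + 0.5) * dy)
  if (jitter > 0) pos <- pos + matrix(rnorm(2 * nrow(pos), sd = jitter),
                                      ncol = 2)
  pos[, 1] <- pos[, 1] %% Lx
  pos[, 2] <- pos[, 2] %% Ly
  pos
}

#' Simulate the epithelium bulk
#'
#' Runs the full bulk update loop (neighbor graph refresh, local density,
#' OU noise, velocity, position) in a periodic box starting from a jittered
#' hexagonal packing at density `n_particles / (Lx * Ly)` with zero initial
#' velocities and stationary noise states. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()] with `boundary = "periodic"`.
#' @param n_particles requested particle count; the realized count is the
#'   nearest complete hexagonal grid (within about 1 percent).
#' @param t_end simulated duration (h).
#' @param snapshot_every snapshot cadence (h); must be a multiple of `dt`.
#' @param init_state optional [particle_state()] to start from (warm start
#'   from an equilibrated configuration) instead of the hexagonal packing;
#'   `n_particles` is ignored then.
#' @return A `trajectory`: list with `times`, `pos` and `vel` (lists of
#'   N x 2 matrices per snapshot), `kind`, `ids`, `config`, `seed`.
#' @examples
#' cfg <- sim_config(Lx = 200, Ly = 200, seed = 3)
#' tr <- simulate_bulk(cfg, n_particles = 160, t_end = 0.1)
#' length(tr$times)
#' @export
simulate_bulk <- function(config, n_particles, t_end,
                          snapshot_every = 0.1, init_state = NULL) {
  stopifnot(inherits(config, "sim_config"), config$boundary == "periodic",
            t_end > 0)
  every <- max(1L, round(snapshot_every / config$dt))
  set.seed(config$seed)
  box <- as_box(config)
  if (is.null(init_state)) {
    pos <- hex_packing(n_particles, config$Lx, config$Ly, config$init_jitter)
    n <- nrow(pos)
    state <- particle_state(pos,
                            eta = matrix(rnorm(2 * n), n, 2))
  } else {
    stopifnot(inherits(init_state, "particle_state"))
    state <- init_state
    n <- nrow(state$pos)
  }
  nblocks <- ceiling(round(t_end / config$dt) / every)
  times <- 0
  snap_pos <- list(state$pos)
  snap_vel <- list(state$vel)
  sigma <- rep(config$sigma0, n)
  for (blk in seq_len(nblocks)) {
    if (config$density_noise) {
      graph <- find_neighbors(state$pos, config$neighbor_cutoff, box)
      sigma <- noise_amplitude(local_density(graph), config)
    }
    state <- advance_state(state, config, box, every, sigma = sigma)
    times <- c(times, blk * every * config$dt)
    snap_pos[[length(snap_pos) + 1L]] <- state$pos
    snap_vel[[length(snap_vel) + 1L]] <- state$vel
  }
  tr <- list(times = times, pos = snap_pos, vel = snap_vel,
             kind = state$kind, ids = state$ids,
             state = state, config = config, seed = config$seed)
  class(tr) <- "trajectory"
  tr
}

# advance a particle_state by nsteps fine steps through the compiled loop;
# semantics identical to the composition ou_step -> velocity_step ->
# position_step with a per-step graph refresh
advance_state <- function(state, config, box, nsteps, sigma = NULL,
                          f_ext = NULL) {
  n <- nrow(state$pos)
  stopifnot(nrow(state$vel) == n, nrow(state$eta) == n,
            length(state$kind) == n)
  if (is.null(sigma)) sigma <- rep(config$sigma0, n)
  stopifnot(length(sigma) == n)
  res <- cpp_advance(state$pos, state$vel, state$eta,
                     sigma, state$kind == 1L, f_ext,
                     config[c("alpha", "beta", "tau", "A_rep", "r_rep",
                              "A_att", "r_att", "r_cut")],
                     as.integer(nsteps), config$dt,
                     box$Lx, box$Ly, box$periodic_x, box$periodic_y,
                     config$neighbor_cutoff,
                     as.integer(config$graph_refresh_every),
                     config$align_mean, config$symmetrize_graph)
  state$pos <- res$pos
  state$vel <- res$vel
  state$eta <- res$eta
  state
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$times), "snapshots,",
      nrow(x$pos[[1]]), "particles, t in [", min(x$times), ",",
      max(x$times), "] h\n")
  invisible(x)
}
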