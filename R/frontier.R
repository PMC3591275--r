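#' Free-surface particle field
#'
#' The unexplored surface (x > 0 in the band geometry) is covered by a
#' regular grid of static surface particles. Each carries a scalar damage
#' variable `w` that accumulates the force magnitudes exerted by nearby
#' cells (leaky integration with relaxation time `tau_w`); a particle whose
#' damage reaches `w_threshold` is removed permanently. Alive surface
#' particles repel non-leader cells.
#'
#' @param free_depth extent of the field along +x (um).
#' @param Ly band length (um).
#' @param params a [frontier_params()].
#' @param left_depth optional extent (um) of a second surface block behind
#'   the band (the stencil band is bounded by free surface on both sides;
#'   the rear block keeps cells from leaking around the open back edge).
#' @param left_at x-coordinate (um) of the rear block's inner face.
#' @return A `surface_field`: `pos` (M x 2), `w`, `alive`, `params`.
#' @export
surface_field <- function(free_depth, Ly, params = frontier_params(),
                          left_depth = 0, left_at = 0) {
  gs <- params$grid_spacing
  nx <- round(free_depth / gs)
  ny <- round(Ly / gs)
  pos <- cbind(rep((seq_len(nx) - 0.5) * gs, times = ny),
               rep((seq_len(ny) - 0.5) * gs, each = nx))
  if (left_depth > 0) {
    nxl <- round(left_depth / gs)
    left <- cbind(rep(left_at - (seq_len(nxl) - 0.5) * gs, times = ny),
                  rep((seq_len(ny) - 0.5) * gs, each = nxl))
    pos <- rbind(pos, left)
  }
  s <- list(pos = pos, w = numeric(nrow(pos)),
            alive = rep(TRUE, nrow(pos)), params = params)
  class(s) <- "surface_field"
  s
}

#' @export
print.surface_field <- function(x, ...) {
  cat("<surface_field>", nrow(x$pos), "particles,", sum(x$alive),
      "alive\n")
  invisible(x)
}

#' Detect the epithelium border
#'
#' The border is the particle with the largest x-coordinate in successive
#' y-bands covering the box. Empty bands are filled by linear interpolation
#' from flanking bands (with periodic wrap in y).
#'
#' @param positions N x 2 positions of alive cells.
#' @param Ly band length (um).
#' @param band_width y-band width (um), default 20.
#' @return A list: `y_mid` (band centers), `x_border` (per-band border x),
#'   `mean_x` (mean border position), `band_width`.
#' @export
detect_border <- function(positions, Ly, band_width = 20) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) stop("detect_border: no particles")
  nb <- max(1L, floor(Ly / band_width))
  bw <- Ly / nb
  band <- pmin(floor((positions[, 2] %% Ly) / bw), nb - 1L) + 1L
  xb <- rep(NA_real_, nb)
  agg <- tapply(positions[, 1], band, max)
  xb[as.integer(names(agg))] <- agg
  if (all(is.na(xb))) stop("detect_border: all bands empty")
  if (anyNA(xb)) {
    # periodic linear interpolation across empty bands
    idx <- seq_len(nb)
    known <- which(!is.na(xb))
    ext_i <- c(known - nb, known, known + nb)
    ext_x <- rep(xb[known], 3)
    xb[-known] <- approx(ext_i, ext_x, xout = idx[-known])$y
  }
  list(y_mid = (seq_len(nb) - 0.5) * bw, x_border = xb,
       mean_x = mean(xb), band_width = bw)
}

# border x at given y values (nearest band lookup)
border_x_at <- function(border, y, Ly) {
  nb <- length(border$x_border)
  band <- pmin(floor((y %% Ly) / border$band_width), nb - 1L) + 1L
  border$x_border[band]
}

#' Initialize the band geometry
#'
#' Cells tile `x` in `[-band_width_x, 0]` as a jittered hexagonal packing at
#' density `d0`; surface particles tile `x > 0` on a regular grid. The box
#' is periodic in y only; the border starts straight at x = 0.
#'
#' @param config a [sim_config()] with `boundary = "band"`.
#' @param n_particles number of cells.
#' @param band_width_x band depth (um); `NULL` derives it from `n_particles`
#'   and `config$d0`.
#' @param free_depth extent of the surface field (um).
#' @param params a [frontier_params()].
#' @param rear_wall_depth extent (um) of the surface block behind the band
#'   (both long sides of a stencil band face free surface; without it,
#'   cells leak around the open rear edge and, once isolated, race away
#'   under undamped noise). 0 disables it.
#' @return List with `state` ([particle_state()]), `surface`
#'   ([surface_field()]), `band_width_x`.
#' @export
init_band <- function(config, n_particles, band_width_x = NULL,
                      free_depth = 600, params = frontier_params(),
                      rear_wall_depth = 60) {
  stopifnot(inherits(config, "sim_config"), config$boundary == "band")
  if (is.null(band_width_x))
    band_width_x <- n_particles / (config$d0 * config$Ly)
  pos <- hex_packing(n_particles, band_width_x, config$Ly,
                     config$init_jitter)
  pos[, 1] <- pos[, 1] - band_width_x
  n <- nrow(pos)
  state <- particle_state(pos, eta = matrix(rnorm(2 * n), n, 2))
  list(state = state,
       surface = surface_field(free_depth, config$Ly, params,
                               left_depth = rear_wall_depth,
                               left_at = -band_width_x),
       band_width_x = band_width_x)
}

#' Create leader cells along the border
#'
#' Candidate creation events are Poisson with mean `rate(t) * border_length
#' * dt` (`rate_early` before `switch_time`, `rate_late` after). Each event
#' transforms a uniformly chosen non-leader cell lying within
#' `creation_depth` of the border into a leader, provided its y-coordinate
#' is at least `exclusion_dy` (periodic distance) from every previously
#' created leader; otherwise the event is skipped. A new leader moves along
#' +x with a speed drawn from a gaussian of mean `v_mean` and s.d. `v_sd`
#' truncated at zero.
#'
#' @param state a [particle_state()].
#' @param border a [detect_border()] result.
#' @param t current time (h).
#' @param dt time step (h).
#' @param params a [frontier_params()].
#' @param Ly band length (um).
#' @return List with the updated `state` and `events`, a data.frame
#'   `t, id, x, y, speed` of accepted creations.
#' @export
spawn_leaders <- function(state, border, t, dt, params, Ly) {
  rate <- if (t < params$switch_time) params$rate_early else params$rate_late
  lambda <- rate * (Ly / 1000) * dt
  k <- if (lambda > 0) rpois(1, lambda) else 0L
  events <- list()
  if (k > 0) {
    for (ev in seq_len(k)) {
      # reference is the band's border, floored at the median border level:
      # transient low-density dents in single bands would otherwise let
      # leaders appear deep inside the sheet
      ref_x <- pmax(border_x_at(border, state$pos[, 2], Ly),
                    median(border$x_border))
      depth <- ref_x - state$pos[, 1]
      eligible <- which(state$alive & state$kind == 0L &
                          depth <= params$creation_depth)
      if (length(state$leader_y_created) && length(eligible)) {
        dy <- outer(state$pos[eligible, 2], state$leader_y_created, "-")
        dy <- abs(min_image(dy, Ly, TRUE))
        eligible <- eligible[apply(dy >= params$exclusion_dy, 1, all)]
      }
      if (!length(eligible)) next
      i <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      speed <- rnorm(1, params$v_mean, params$v_sd)
      while (speed <= 0) speed <- rnorm(1, params$v_mean, params$v_sd)
      state$kind[i] <- 1L
      state$leader_v[i, ] <- c(speed, 0)
      state$vel[i, ] <- c(speed, 0)
      state$leader_vcap[i] <- if (is.na(params$v_cap)) speed else params$v_cap
      state$leader_y_created <- c(state$leader_y_created, state$pos[i, 2])
      events[[length(events) + 1L]] <-
        data.frame(t = t, id = state$ids[i], x = state$pos[i, 1],
                   y = state$pos[i, 2], speed = speed)
    }
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(t = numeric(0), id = integer(0), x = numeric(0),
                            y = numeric(0), speed = numeric(0))
  list(state = state, events = events)
}

#' Leader velocity rule
#'
#' A leader keeps its stored velocity while it has at least `min_followers`
#' neighbors. With 1 to `min_followers - 1` neighbors it takes the mean
#' velocity of its neighbors, capped in modulus at its speed cap. A
#' neighborless leader keeps its previous direction at the cap modulus. The
#' stored velocity is restored as soon as the neighbor count recovers.
#'
#' @param state a [particle_state()].
#' @param graph the current neighbor graph.
#' @param params a [frontier_params()].
#' @return The state with leader velocities updated.
#' @export
update_leader <- function(state, graph, params) {
  leaders <- which(state$kind == 1L & state$alive)
  for (i in leaders) {
    nb <- graph$nbr[i, ]
    nb <- nb[!is.na(nb)]
    cap <- state$leader_vcap[i]
    if (length(nb) >= params$min_followers) {
      state$vel[i, ] <- state$leader_v[i, ]
    } else if (length(nb) >= 1L) {
      m <- colMeans(state$vel[nb, , drop = FALSE])
      sp <- sqrt(sum(m^2))
      if (is.finite(cap) && sp > cap) m <- m * cap / sp
      state$vel[i, ] <- m
    } else {
      dirv <- state$vel[i, ]
      sp <- sqrt(sum(dirv^2))
      u <- if (sp > 0) dirv / sp else c(1, 0)
      state$vel[i, ] <- u * cap
    }
  }
  state
}

#' Free-surface repulsion on cells
#'
#' Alive surface particles within `3 * r_surf` repel non-leader cells with a
#' gaussian kernel `A_surf_normal * exp(-r^2 / (2 r_surf^2))` directed away
#' from the surface particle. Leaders feel no surface force (their dynamics
#' are prescribed).
#'
#' @param state a [particle_state()].
#' @param surface a [surface_field()].
#' @param box a [box_spec()] (band geometry: periodic in y).
#' @return N x 2 force matrix (um/h^2); zero rows for leaders.
#' @export
surface_force <- function(state, surface, box) {
  n <- nrow(state$pos)
  out <- matrix(0, n, 2)
  sp <- surface$params
  alive_s <- which(surface$alive)
  if (!length(alive_s)) return(out)
  pr <- cpp_radius_pairs(state$pos, surface$pos[alive_s, , drop = FALSE],
                         3 * sp$r_surf, box$Lx, box$Ly,
                         box$periodic_x, box$periodic_y)
  if (!length(pr$i)) return(out)
  keep <- state$kind[pr$i] == 0L & state$alive[pr$i] & pr$d > 0
  if (!any(keep)) return(out)
  i <- pr$i[keep]; d <- pr$d[keep]
  amp <- sp$A_surf_normal * exp(-d^2 / (2 * sp$r_surf^2)) / d
  fx <- -amp * pr$dx[keep]
  fy <- -amp * pr$dy[keep]
  acc <- rowsum(cbind(fx, fy), i)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' Surface damage dynamics
#'
#' Each alive surface particle integrates the force magnitudes exerted on it
#' by cells within `interaction_radius`, leaking with relaxation time
#' `tau_w`: `w <- w + dt * (-w/tau_w + sum |f|)`. Bulk cells act through the
#' normal gaussian kernel (`A_surf_normal`, `r_surf`), leaders through the
#' much stronger leader kernel (`A_surf_leader`, `r_surf_leader`) so that
#' they clear surface quickly. Particles whose damage reaches `w_threshold`
#' are removed permanently.
#'
#' @inheritParams surface_force
#' @param dt time step (h).
#' @return The updated `surface_field`.
#' @export
damage_step <- function(surface, state, dt, box) {
  sp <- surface$params
  alive_s <- which(surface$alive)
  if (!length(alive_s)) return(surface)
  live_c <- which(state$alive)
  inflow <- numeric(length(alive_s))
  if (length(live_c)) {
    pr <- cpp_radius_pairs(surface$pos[alive_s, , drop = FALSE],
                           state$pos[live_c, , drop = FALSE],
                           sp$interaction_radius, box$Lx, box$Ly,
                           box$periodic_x, box$periodic_y)
    if (length(pr$i)) {
      kind <- state$kind[live_c[pr$j]]
      A <- ifelse(kind == 1L, sp$A_surf_leader, sp$A_surf_normal)
      r0 <- ifelse(kind == 1L, sp$r_surf_leader, sp$r_surf)
      fmag <- A * exp(-pr$d^2 / (2 * r0^2))
      acc <- rowsum(fmag, pr$i)
      inflow[as.integer(rownames(acc))] <- acc
    }
  }
  w <- surface$w[alive_s]
  leak <- if (is.finite(sp$tau_w)) w / sp$tau_w else 0
  w <- w + dt * (-leak + inflow)
  surface$w[alive_s] <- w
  surface$alive[alive_s[w >= sp$w_threshold]] <- FALSE
  surface
}

#' Density-capped cell division
#'
#' Every bulk cell divides with probability `dt * ln(2) / T_div` per step.
#' A daughter is placed at `daughter_offset` in a uniformly random direction
#' with the parent's velocity and noise state; the division is rolled back
#' if it would raise the parent's local density above the density cap.
#' Leaders never divide.
#'
#' @param state a [particle_state()].
#' @param dt time step (h).
#' @param params a [frontier_params()].
#' @param config a [sim_config()] (for `d0` and the neighbor cutoff).
#' @param box a [box_spec()].
#' @return The updated state (possibly with appended daughters).
#' @export
divide_cells <- function(state, dt, params, config, box = as_box(config)) {
  p <- dt * log(2) / params$T_div
  stopifnot(p < 1)
  cap <- if (is.na(params$density_cap)) config$d0 else params$density_cap
  n <- nrow(state$pos)
  dividing <- which(state$alive & state$kind == 0L & runif(n) < p)
  accepted_parents <- integer(0)
  if (!length(dividing)) {
    attr(state, "division_parents") <- accepted_parents
    return(state)
  }
  for (i in dividing) {
    theta <- runif(1, 0, 2 * pi)
    dpos <- state$pos[i, ] + params$daughter_offset * c(cos(theta), sin(theta))
    if (box$periodic_x) dpos[1] <- dpos[1] %% box$Lx
    if (box$periodic_y) dpos[2] <- dpos[2] %% box$Ly
    trial <- rbind(state$pos[state$alive, , drop = FALSE], dpos)
    dens <- sector_density_at(state$pos[i, ], trial,
                              config$neighbor_cutoff, box)
    if (dens > cap) next
    state$pos <- rbind(state$pos, dpos)
    state$vel <- rbind(state$vel, state$vel[i, ])
    state$eta <- rbind(state$eta, state$eta[i, ])
    state$kind <- c(state$kind, 0L)
    state$leader_v <- rbind(state$leader_v, c(NA_real_, NA_real_))
    state$leader_vcap <- c(state$leader_vcap, NA_real_)
    state$alive <- c(state$alive, TRUE)
    state$ids <- c(state$ids, max(state$ids) + 1L)
    accepted_parents <- c(accepted_parents, i)
  }
  attr(state, "division_parents") <- accepted_parents
  state
}

#' Simulate the band with free surface
#'
#' Full driver for the wound-healing geometry: per step it refreshes the
#' neighbor graph, evaluates local densities, advances the OU noise, detects
#' the border, spawns leaders, applies the leader velocity rule, updates
#' bulk velocities (including free-surface repulsion), damages the surface,
#' attempts divisions, and moves all particles (periodic in y). Reproducible
#' from `config$seed`.
#'
#' @param config a [sim_config()] with `boundary = "band"`.
#' @param n_particles initial cell count.
#' @param t_end simulated duration (h).
#' @param params a [frontier_params()].
#' @param free_depth surface-field extent (um).
#' @param snapshot_every snapshot cadence (h).
#' @param leaders,surface,division logical switches for the three frontier
#'   mechanisms (controls for comparison runs).
#' @param band_width_x band depth (um); `NULL` derives it from `d0`.
#' @param frontier_every number of fine dynamics steps per frontier update
#'   (border detection, leader events, surface damage, division); the
#'   frontier cadence is `frontier_every * dt` (default 10 x 0.002 = 0.02 h),
#'   well below the fastest frontier timescale (`tau_w` = 1 h).
#' @return A `band_run`: list with `times`, `pos`, `vel`, `kind`, `ids`
#'   (per-snapshot lists), `border` (data.frame `t, mean_x`), `border_final`
#'   (last polyline), `leader_log`, `surface` (final field), `state` (final),
#'   `config`, `params`.
#' @export
simulate_band <- function(config, n_particles, t_end,
                          params = frontier_params(),
                          free_depth = 600, snapshot_every = 0.2,
                          leaders = TRUE, surface = TRUE, division = TRUE,
                          band_width_x = NULL, frontier_every = 10L) {
  stopifnot(inherits(config, "sim_config"), config$boundary == "band",
            t_end > 0)
  dt_c <- frontier_every * config$dt  # frontier (coarse) step
  every <- max(1L, round(snapshot_every / dt_c))
  set.seed(config$seed)
  box <- as_box(config)
  ini <- init_band(config, n_particles, band_width_x, free_depth, params)
  state <- ini$state
  surf <- ini$surface
  ncoarse <- round(t_end / dt_c)
  bd0 <- detect_border(state$pos[state$alive, , drop = FALSE], config$Ly,
                       params$border_band_width)
  times <- 0
  snap_pos <- list(state$pos); snap_vel <- list(state$vel)
  snap_kind <- list(state$kind); snap_ids <- list(state$ids)
  border_t <- 0; border_x <- bd0$mean_x
  leader_log <- list()
  border <- bd0
  for (step in seq_len(ncoarse)) {
    t <- (step - 1L) * dt_c
    graph <- find_neighbors(state$pos, config$neighbor_cutoff, box,
                            symmetrize = config$symmetrize_graph)
    sigma <- if (config$density_noise)
      noise_amplitude(local_density(graph), config)
    else rep(config$sigma0, nrow(state$pos))
    border <- detect_border(state$pos[state$alive, , drop = FALSE],
                            config$Ly, params$border_band_width)
    if (leaders) {
      sp <- spawn_leaders(state, border, t, dt_c, params, config$Ly)
      state <- sp$state
      if (nrow(sp$events)) leader_log[[length(leader_log) + 1L]] <- sp$events
      state <- update_leader(state, graph, params)
    }
    fext <- if (surface) surface_force(state, surf, box) else NULL
    state <- advance_state(state, config, box, frontier_every,
                           sigma = sigma, f_ext = fext)
    if (surface) surf <- damage_step(surf, state, dt_c, box)
    if (division) state <- divide_cells(state, dt_c, params, config, box)
    if (step %% every == 0L) {
      times <- c(times, step * dt_c)
      snap_pos[[length(snap_pos) + 1L]] <- state$pos
      snap_vel[[length(snap_vel) + 1L]] <- state$vel
      snap_kind[[length(snap_kind) + 1L]] <- state$kind
      snap_ids[[length(snap_ids) + 1L]] <- state$ids
      bd <- detect_border(state$pos[state$alive, , drop = FALSE],
                          config$Ly, params$border_band_width)
      border_t <- c(border_t, step * dt_c)
      border_x <- c(border_x, bd$mean_x)
      border <- bd
    }
  }
  leader_log <- if (length(leader_log)) do.call(rbind, leader_log)
                else data.frame(t = numeric(0), id = integer(0),
                                x = numeric(0), y = numeric(0),
                                speed = numeric(0))
  out <- list(times = times, pos = snap_pos, vel = snap_vel,
              kind = snap_kind, ids = snap_ids,
              border = data.frame(t = border_t, mean_x = border_x),
              border_final = border, leader_log = leader_log,
              surface = surf, state = state,
              config = config, params = params)
  class(out) <- "band_run"
  out
}

#' @export
print.band_run <- function(x, ...) {
  cat("<band_run>", length(x$times), "snapshots,",
      nrow(x$state$pos), "cells (", sum(x$state$kind == 1L), "leaders ),",
      nrow(x$leader_log), "leader events; border advance",
      round(x$border$mean_x[nrow(x$border)] - x$border$mean_x[1], 1),
      "um\n")
  invisible(x)
}
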