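#' Simulation configuration
#'
#' Builds and validates the full parameter set of the particle model: the
#' Langevin velocity dynamics (damping `alpha`, per-neighbor alignment
#' coupling `beta`, Ornstein-Uhlenbeck noise correlation time `tau`, base
#' noise amplitude `sigma0`), the optional density-dependent noise amplitude,
#' the pairwise interaction potential, the sector-neighbor cutoff, the
#' simulation box and the integration settings.
#'
#' Units are micrometres and hours throughout: `alpha`, `beta` in 1/h, `tau`
#' in h, `sigma0` and the force amplitudes in um/h^2, lengths in um, `dt` in
#' h, densities in 1/um^2.
#'
#' The default dynamical triple (alpha, beta, tau) = (1.42, 38, 1.40) is the
#' reference bulk fit used throughout the package; `sigma0 = 450` calibrates
#' the bulk mean cell speed to about 15 um/h at those parameters (see
#' [calibrate_sigma()]). The potential defaults give a relaxed nearest
#' neighbour spacing of roughly 16-17 um, i.e. about 4e-3 cells/um^2, the
#' density of a confluent MDCK monolayer of 15-25 um cells.
#'
#' The default `dt = 0.002` h is set by the stiffest velocity modes: with up
#' to 6 neighbors the alignment sum relaxes at rates up to about
#' `alpha + 12 beta` (~460/h at the defaults), and the explicit Euler update
#' requires `dt < 2` divided by that rate; 0.002 h keeps a factor ~2 margin.
#'
#' @param alpha damping rate (1/h), > 0.
#' @param beta velocity-alignment coupling per neighbor (1/h), >= 0.
#' @param tau OU noise correlation time (h), > 0.
#' @param sigma0 base noise amplitude (um/h^2), >= 0.
#' @param density_noise logical; if `TRUE` the noise amplitude increases
#'   linearly as the local density falls below `d0` (see [noise_amplitude()]).
#' @param kappa dimensionless shape parameter of the density-dependent noise.
#' @param d0 reference (initial) cell density (1/um^2).
#' @param A_rep,r_rep amplitude (um/h^2) and range (um) of the repulsive
#'   gaussian core of the pair potential.
#' @param A_att,r_att,r_cut amplitude (um/h^2), onset (um) and cutoff (um) of
#'   the Heaviside-gated linear attractive branch; `r_rep < r_att <= r_cut <=
#'   neighbor_cutoff` is enforced.
#' @param neighbor_cutoff sector-neighbor search cutoff (um), default 100.
#' @param Lx,Ly box dimensions (um).
#' @param boundary `"periodic"` (both directions) or `"band"` (periodic in y
#'   only, free surface along +x).
#' @param dt integration step (h).
#' @param seed integer RNG seed recorded with every run.
#' @param graph_refresh_every rebuild the neighbor graph every this many
#'   steps (default 5, i.e. every 0.01 h at the default `dt`; per-step
#'   displacements are below 0.05 um, far under the cell spacing).
#' @param symmetrize_graph logical; symmetrize the (generally asymmetric)
#'   sector neighbor relation. Used for momentum-conservation checks.
#' @param align_mean logical; if `TRUE` the alignment term is the mean over
#'   neighbors instead of the plain sum (sensitivity variant).
#' @param init_jitter s.d. (um) of the gaussian jitter applied to the initial
#'   hexagonal packing.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$alpha
#' @export
sim_config <- function(alpha = 1.42, beta = 38, tau = 1.40, sigma0 = 450,
                       density_noise = FALSE, kappa = 2, d0 = 4e-3,
                       A_rep = 150, r_rep = 5, A_att = 2, r_att = 25,
                       r_cut = 50, neighbor_cutoff = 100,
                       Lx = 1000, Ly = 1000,
                       boundary = c("periodic", "band"),
                       dt = 0.002, seed = 1L, graph_refresh_every = 5L,
                       symmetrize_graph = FALSE, align_mean = FALSE,
                       init_jitter = 1) {
  cfg <- list(
    schema = 1L,
    alpha = alpha, beta = beta, tau = tau, sigma0 = sigma0,
    density_noise = isTRUE(density_noise), kappa = kappa, d0 = d0,
    A_rep = A_rep, r_rep = r_rep, A_att = A_att, r_att = r_att,
    r_cut = r_cut, neighbor_cutoff = neighbor_cutoff,
    Lx = Lx, Ly = Ly, boundary = match.arg(boundary),
    dt = dt, seed = as.integer(seed),
    graph_refresh_every = as.integer(graph_refresh_every),
    symmetrize_graph = isTRUE(symmetrize_graph),
    align_mean = isTRUE(align_mean),
    init_jitter = init_jitter
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> (alpha, beta, tau) = (", x$alpha, ",", x$beta, ",",
      x$tau, "), sigma0 =", x$sigma0,
      if (x$density_noise) sprintf("(density-dependent, kappa = %g)", x$kappa)
      else "(constant)", "\n")
  cat("  box", x$Lx, "x", x$Ly, "um,", x$boundary,
      "; dt =", x$dt, "h; seed =", x$seed, "\n")
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  num <- c("alpha", "beta", "tau", "sigma0", "kappa", "d0", "A_rep", "r_rep",
           "A_att", "r_att", "r_cut", "neighbor_cutoff", "Lx", "Ly", "dt",
           "init_jitter")
  for (f in num) chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
                       is.finite(cfg[[f]]), paste(f, "must be a finite number"))
  chk(cfg$alpha > 0, "alpha must be > 0")
  chk(cfg$tau > 0, "tau must be > 0")
  chk(cfg$beta >= 0, "beta must be >= 0")
  chk(cfg$sigma0 >= 0, "sigma0 must be >= 0")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$d0 > 0, "d0 must be > 0")
  chk(cfg$neighbor_cutoff > 0, "neighbor_cutoff must be > 0")
  chk(cfg$r_rep < cfg$r_att, "r_rep must be < r_att")
  chk(cfg$r_att <= cfg$r_cut, "r_att must be <= r_cut")
  chk(cfg$r_cut <= cfg$neighbor_cutoff, "r_cut must be <= neighbor_cutoff")
  chk(cfg$Lx > 0 && cfg$Ly > 0, "box dimensions must be > 0")
  chk(cfg$graph_refresh_every >= 1L, "graph_refresh_every must be >= 1")
  cfg
}

#' Frontier (free-surface, leader, division) parameters
#'
#' Parameters of the band geometry: leader-cell creation and feedback,
#' surface particles with damage dynamics, and density-capped cell division.
#' The creation rates are per mm of border per hour; the rate drops from
#' `rate_early` to `rate_late` at `switch_time` (20 h), mirroring the
#' measured slowdown of leader appearance. New leaders move along +x with a
#' speed drawn from a gaussian of mean `v_mean` (18 um/h) truncated at zero,
#' keep that velocity while they have at least `min_followers` (4) neighbors,
#' and otherwise take the mean velocity of their neighbors capped at `v_cap`
#' (by default each leader's own initial speed).
#'
#' @param rate_early,rate_late leader creation rates (1/(mm h)).
#' @param switch_time time (h) of the rate drop.
#' @param creation_depth max distance (um) behind the border at which a cell
#'   can turn into a leader.
#' @param exclusion_dy minimal y-distance (um) to any previously created
#'   leader.
#' @param v_mean,v_sd mean and s.d. (um/h) of the initial leader speed.
#' @param min_followers neighbor count below which a leader follows its
#'   neighbors instead of its stored velocity.
#' @param v_cap speed cap (um/h) for follower-driven leader motion; `NA`
#'   means each leader uses its own initial speed.
#' @param tau_w damage relaxation time (h) of surface particles; `Inf` gives
#'   pure accumulation.
#' @param A_surf_normal,r_surf amplitude (um/h^2) and gaussian range (um) of
#'   the surface-particle repulsion felt by non-leader cells (and of the
#'   damage they inflict). The amplitude must be of the order of the noise
#'   drive `sigma` (which reaches `sigma0 (1 + kappa)` at the depleted
#'   border) or cells punch through the surface on noise excursions; the
#'   default 300 restrains the border at the default noise settings while
#'   barely compressing the sheet.
#' @param A_surf_leader,r_surf_leader the (much larger) damage kernel of
#'   leader cells.
#' @param w_threshold damage threshold at which a surface particle is
#'   removed; default `9 * tau_w * A_surf_normal`. The default sits well above
#'   the steady-state damage inflow of ordinary border cells pressed
#'   against the surface (a few cells at their force-balance distance
#'   inject roughly `tau_w * A_surf_normal`), so the border without leaders
#'   is restrained, while the 50-fold leader kernel still clears surface in
#'   a few minutes.
#' @param interaction_radius distance (um) within which cells damage a
#'   surface particle.
#' @param grid_spacing surface particle grid spacing (um).
#' @param T_div cell doubling time (h).
#' @param daughter_offset distance (um) at which a daughter is placed.
#' @param density_cap local density above which a division is rolled back;
#'   `NA` means the configuration's `d0`.
#' @param border_band_width y-band width (um) for border detection.
#'
#' @return An object of class `frontier_params`.
#' @export
frontier_params <- function(rate_early = 0.3, rate_late = 0.1,
                            switch_time = 20, creation_depth = 30,
                            exclusion_dy = 150, v_mean = 18, v_sd = 4,
                            min_followers = 4L, v_cap = NA_real_,
                            tau_w = 1, A_surf_normal = 3000, r_surf = 10,
                            A_surf_leader = 1e6, r_surf_leader = 35,
                            w_threshold = NA_real_, interaction_radius = 30,
                            grid_spacing = 10,
                            T_div = 20, daughter_offset = 2,
                            density_cap = NA_real_,
                            border_band_width = 20) {
  if (is.na(w_threshold)) {
    w_threshold <- if (is.finite(tau_w)) 9 * tau_w * A_surf_normal
                   else 9 * A_surf_normal
  }
  p <- list(rate_early = rate_early, rate_late = rate_late,
            switch_time = switch_time, creation_depth = creation_depth,
            exclusion_dy = exclusion_dy, v_mean = v_mean, v_sd = v_sd,
            min_followers = as.integer(min_followers), v_cap = v_cap,
            tau_w = tau_w, A_surf_normal = A_surf_normal, r_surf = r_surf,
            A_surf_leader = A_surf_leader, r_surf_leader = r_surf_leader,
            w_threshold = w_threshold, interaction_radius = interaction_radius,
            grid_spacing = grid_spacing, T_div = T_div,
            daughter_offset = daughter_offset, density_cap = density_cap,
            border_band_width = border_band_width)
  stopifnot(p$rate_early >= 0, p$rate_late >= 0, p$v_mean > 0,
            p$min_followers >= 1L, p$T_div > 0, p$tau_w > 0,
            p$grid_spacing > 0, p$w_threshold > 0)
  class(p) <- "frontier_params"
  p
}

#' Named simulation presets
#'
#' Two ready-made geometries: `"bulk"` — N = 4000 cells in a 1000 x 1000 um
#' fully periodic box at the reference parameter triple, used for the bulk
#' statistics and for parameter fitting; `"band"` — an epithelial band
#' (default 2000 cells) with its border at x = 0, a free surface covered by
#' surface particles for x > 0, periodic in y over a 1.5 mm border, leaders,
#' division and density-dependent noise enabled.
#'
#' @param name `"bulk"` or `"band"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return For `"bulk"`, a `sim_config`; for `"band"`, a list with elements
#'   `config`, `frontier` ([frontier_params()]), `n_particles`, and
#'   `free_depth` (extent of the surface-particle field, um).
#' @export
preset_config <- function(name = c("bulk", "band"), seed = 1L, ...) {
  name <- match.arg(name)
  if (name == "bulk") {
    cfg <- sim_config(Lx = 1000, Ly = 1000, boundary = "periodic",
                      seed = seed, ...)
    attr(cfg, "n_particles") <- 4000L
    return(cfg)
  }
  # the attractive branch is inert in the confluent bulk (spacing ~17 um)
  # but essential in the band: it binds cells at 25-50 um separations so
  # finger cells and border stragglers stay cohesive instead of detaching
  # and racing off under undamped, density-boosted noise
  cfg <- sim_config(Lx = 1000, Ly = 1500, boundary = "band",
                    density_noise = TRUE, A_att = 50, seed = seed, ...)
  list(config = cfg, frontier = frontier_params(),
       n_particles = 2000L, free_depth = 800)
}

#' Read a configuration file
#'
#' Reads a YAML key-value configuration (`schema: 1`). Top-level keys are the
#' [sim_config()] arguments; an optional nested `frontier:` map holds
#' [frontier_params()] arguments. Unknown keys are rejected; all values are
#' validated.
#'
#' @param path file path.
#' @return A list with elements `config` (`sim_config`) and `frontier`
#'   (`frontier_params` or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration must be a key-value document")
  if (!is.null(raw$schema) && raw$schema != 1L)
    stop("unsupported configuration schema: ", raw$schema)
  raw$schema <- NULL
  fr_raw <- raw$frontier
  raw$frontier <- NULL
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(sim_config, raw)
  fr <- NULL
  if (!is.null(fr_raw)) {
    fknown <- names(formals(frontier_params))
    funknown <- setdiff(names(fr_raw), fknown)
    if (length(funknown))
      stop("unknown frontier key(s): ", paste(funknown, collapse = ", "))
    fr <- do.call(frontier_params, fr_raw)
  }
  list(config = cfg, frontier = fr)
}

#' Write a configuration file
#'
#' Serializes a [sim_config()] (and optionally [frontier_params()]) to the
#' YAML schema read by [load_config()]; `load_config(write_config(...))` is
#' the identity.
#'
#' @param config a `sim_config`.
#' @param path output path.
#' @param frontier optional `frontier_params`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, frontier = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  if (!is.null(frontier)) {
    stopifnot(inherits(frontier, "frontier_params"))
    out$frontier <- unclass(frontier)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
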