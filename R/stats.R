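#' Histogram container
#'
#' @param x sample values.
#' @param breaks bin edges (strictly increasing) or a bin width.
#' @param mode `"density"` (integrates to 1) or `"count"`.
#' @return A `velocity_histogram`: `edges`, `counts`, `density`, `mode`.
#' @export
make_histogram <- function(x, breaks, mode = c("density", "count")) {
  mode <- match.arg(mode)
  if (length(x) == 0) {
    return(structure(list(edges = numeric(0), counts = numeric(0),
                          density = numeric(0), mode = mode),
                     class = "velocity_histogram"))
  }
  if (length(breaks) == 1) {
    lo <- floor(min(x) / breaks) * breaks
    hi <- ceiling(max(x) / breaks) * breaks
    if (hi <= lo) hi <- lo + breaks
    breaks <- seq(lo, hi, by = breaks)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(edges = h$breaks, counts = h$counts, density = h$density,
                 mode = mode), class = "velocity_histogram")
}

#' Velocity histograms and gaussian moments
#'
#' Density-normalized histograms of the two velocity components and of the
#' modulus, with the gaussian moment fit (mean, s.d.) of each component. In
#' the bulk model the components are gaussian and the modulus follows the
#' corresponding 2-D modulus density `(r/s^2) exp(-r^2/(2 s^2))`.
#'
#' @param velocities N x 2 matrix (um/h), N >= 2.
#' @param bin bin width (um/h), default 1.
#' @return List `vx`, `vy`, `speed` ([make_histogram()] objects) and
#'   `moments` (data.frame with `component`, `mean`, `sd`).
#' @export
velocity_histograms <- function(velocities, bin = 1) {
  velocities <- as.matrix(velocities)
  if (nrow(velocities) < 2) stop("need at least 2 velocity samples")
  sp <- sqrt(rowSums(velocities^2))
  list(vx = make_histogram(velocities[, 1], bin),
       vy = make_histogram(velocities[, 2], bin),
       speed = make_histogram(sp, bin),
       moments = data.frame(component = c("vx", "vy"),
                            mean = colMeans(velocities),
                            sd = apply(velocities, 2, sd)))
}

#' Correlation curve container
#'
#' @param lag lag grid (um or h).
#' @param value raw correlation values.
#' @param normalized values normalized so the lag-0 entry is 1.
#' @param n per-bin sample counts.
#' @return A `correlation_curve` data.frame.
#' @export
correlation_curve <- function(lag, value, normalized, n) {
  df <- data.frame(lag = lag, value = value, normalized = normalized, n = n)
  class(df) <- c("correlation_curve", "data.frame")
  df
}

#' Pair correlation of cell centers
#'
#' Radial distribution function g(r): the pair count per annulus normalized
#' by the ideal-gas expectation `N * rho * 2 pi r dr`, so a structureless
#' (Poisson) configuration gives 1 at all r and the curve tends to 1 at
#' large r.
#'
#' @param positions N x 2 matrix (um).
#' @param box a periodic [box_spec()].
#' @param dr annulus width (um), default 2.
#' @param rmax maximal distance (um), default `min(Lx, Ly)/4`.
#' @return A [correlation_curve()] with `lag` the annulus midpoints and
#'   `value = normalized = g(r)`.
#' @export
pair_correlation_centers <- function(positions, box, dr = 2, rmax = NULL) {
  if (dr <= 0) stop("dr must be > 0")
  box <- as_box(box)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(rmax)) rmax <- min(box$Lx, box$Ly) / 4
  bins <- cpp_pair_bins(positions, numeric(0), numeric(0), rmax, dr,
                        box$Lx, box$Ly, box$periodic_x, box$periodic_y)
  nb <- length(bins$counts)
  r_lo <- (seq_len(nb) - 1) * dr
  r_hi <- r_lo + dr
  rho <- n / (box$Lx * box$Ly)
  expected <- n * rho * pi * (r_hi^2 - r_lo^2) / 2
  g <- bins$counts / expected
  correlation_curve((r_lo + r_hi) / 2, g, g, bins$counts)
}

#' Distribution of neighbor distances
#'
#' Histogram over all (cell, sector-neighbor) distances of a neighbor graph.
#'
#' @param graph a [find_neighbors()] result.
#' @param bin bin width (um), default 1.
#' @return A [make_histogram()] object.
#' @export
neighbor_distance_distribution <- function(graph, bin = 1) {
  d <- graph$dist[!is.na(graph$dist)]
  make_histogram(d, bin)
}

#' Equal-time spatial velocity correlation
#'
#' `C_u(r) = <u_i u_j>` over particle pairs binned by distance, after
#' removing the sample mean of the component `u`, normalized by the
#' u-variance; the r = 0 bin is the self term (1 after normalization).
#'
#' @param positions,velocities N x 2 matrices.
#' @param component `"x"` or `"y"`.
#' @param dr bin width (um), default 10.
#' @param box a [box_spec()].
#' @param rmax maximal distance (um), default `min(Lx, Ly)/2.5`.
#' @return A [correlation_curve()]; `lag` starts at 0 (self term).
#' @export
spatial_velocity_correlation <- function(positions, velocities,
                                         component = c("x", "y"),
                                         dr = 10, box, rmax = NULL) {
  component <- match.arg(component)
  box <- as_box(box)
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 particles")
  u <- velocities[, if (component == "x") 1 else 2]
  u <- u - mean(u)
  v0 <- mean(u^2)
  if (v0 == 0) stop("degenerate velocity sample: zero variance")
  if (is.null(rmax)) rmax <- min(box$Lx, box$Ly) / 2.5
  ux <- if (component == "x") u else numeric(n)
  uy <- if (component == "y") u else numeric(n)
  bins <- cpp_pair_bins(positions, ux, uy, rmax, dr,
                        box$Lx, box$Ly, box$periodic_x, box$periodic_y)
  s <- if (component == "x") bins$sum_ux else bins$sum_uy
  cnt <- bins$counts
  val <- ifelse(cnt > 0, s / cnt, NA_real_)
  mids <- (seq_along(cnt) - 0.5) * dr
  correlation_curve(c(0, mids), c(v0, val), c(1, val / v0), c(n, cnt))
}

# average several correlation curves on a common lag grid
average_curves <- function(curves) {
  lag <- curves[[1]]$lag
  vals <- sapply(curves, function(cv) cv$normalized)
  m <- rowMeans(vals, na.rm = TRUE)
  correlation_curve(lag, m, m / m[1],
                    rowSums(sapply(curves, function(cv) cv$n)))
}

#' Temporal velocity autocorrelation
#'
#' Lagrangian mode follows particle identities:
#' `A_u(t) = <u_i(s) u_i(s+t)>` over particles and stationary start times,
#' per-snapshot mean removed, normalized by the lag-0 value. Eulerian mode
#' first bins each snapshot to a [grid_velocity_field()] and correlates per
#' grid cell (only cells occupied at both times contribute).
#'
#' @param trajectory a [simulate_bulk()] result (or any list with `times`,
#'   `vel`, and for eulerian mode `pos`).
#' @param component `"x"` or `"y"`.
#' @param mode `"lagrangian"` or `"eulerian"`.
#' @param grid_step grid step (um) for eulerian mode, default 30.
#' @param t_start only snapshots at `t >= t_start` are used (transient
#'   removal).
#' @return A [correlation_curve()] with `lag` in hours.
#' @export
temporal_autocorrelation <- function(trajectory, component = c("x", "y"),
                                     mode = c("lagrangian", "eulerian"),
                                     grid_step = 30, t_start = 0) {
  component <- match.arg(component)
  mode <- match.arg(mode)
  keep <- which(trajectory$times >= t_start)
  if (length(keep) < 2) stop("need at least 2 snapshots")
  times <- trajectory$times[keep]
  ci <- if (component == "x") 1 else 2
  if (mode == "lagrangian") {
    if (!is.null(trajectory$ids) && is.list(trajectory$ids)) {
      ids <- trajectory$ids[keep]
      if (!all(vapply(ids, identical, logical(1), ids[[1]])))
        stop("lagrangian autocorrelation requires constant particle ids")
    }
    U <- sapply(keep, function(k) trajectory$vel[[k]][, ci])  # N x T
  } else {
    fields <- lapply(keep, function(k)
      grid_velocity_field(trajectory$pos[[k]], trajectory$vel[[k]],
                          grid_step, as_box(trajectory$config)))
    key <- paste(fields[[1]]$cx, fields[[1]]$cy)
    U <- sapply(fields, function(f) {
      v <- rep(NA_real_, length(key))
      idx <- match(paste(f$cx, f$cy), key)
      ok <- !is.na(idx)
      v[idx[ok]] <- if (component == "x") f$vx[ok] else f$vy[ok]
      v
    })
  }
  U <- sweep(U, 2, colMeans(U, na.rm = TRUE))
  nt <- ncol(U)
  dt_snap <- mean(diff(times))
  lags <- 0:(nt - 1)
  acf_vals <- vapply(lags, function(L) {
    a <- U[, seq_len(nt - L), drop = FALSE]
    b <- U[, seq_len(nt - L) + L, drop = FALSE]
    mean(a * b, na.rm = TRUE)
  }, numeric(1))
  cnt <- vapply(lags, function(L) {
    sum(!is.na(U[, seq_len(nt - L), drop = FALSE] +
                 U[, seq_len(nt - L) + L, drop = FALSE]))
  }, numeric(1))
  correlation_curve(lags * dt_snap, acf_vals, acf_vals / acf_vals[1], cnt)
}

#' Correlation length or time (1/e crossing)
#'
#' First crossing of 1/e of the normalized curve, linearly interpolated
#' between bins.
#'
#' @param curve a [correlation_curve()].
#' @return The crossing lag (same units as `curve$lag`).
#' @export
correlation_length <- function(curve) {
  y <- curve$normalized
  x <- curve$lag
  ok <- !is.na(y)
  y <- y[ok]; x <- x[ok]
  thr <- exp(-1)
  below <- which(y < thr)
  if (!length(below))
    stop("no 1/e crossing within lag range [", min(x), ", ", max(x), "]")
  i <- below[1]
  if (i == 1) return(x[1])
  x[i - 1] + (thr - y[i - 1]) * (x[i] - x[i - 1]) / (y[i] - y[i - 1])
}

#' Gridded velocity field
#'
#' Bins particles to a square grid and assigns to each cell the arithmetic
#' mean velocity of the particles it contains (the gridded form produced by
#' PIV-style analyses). Empty cells are absent from the output.
#'
#' @param positions,velocities N x 2 matrices.
#' @param grid_step grid step (um).
#' @param box a [box_spec()].
#' @return A `velocity_field` data.frame: `cx, cy, vx, vy, count`.
#' @export
grid_velocity_field <- function(positions, velocities, grid_step, box) {
  stopifnot(grid_step > 0)
  box <- as_box(box)
  positions <- as.matrix(positions)
  px <- if (box$periodic_x) positions[, 1] %% box$Lx else positions[, 1]
  py <- if (box$periodic_y) positions[, 2] %% box$Ly else positions[, 2]
  ix <- floor(px / grid_step)
  iy <- floor(py / grid_step)
  key <- paste(ix, iy)
  agg <- rowsum(cbind(velocities, 1), key)
  ids <- strsplit(rownames(agg), " ", fixed = TRUE)
  ixs <- as.numeric(vapply(ids, `[`, "", 1))
  iys <- as.numeric(vapply(ids, `[`, "", 2))
  cnt <- agg[, 3]
  out <- data.frame(cx = (ixs + 0.5) * grid_step, cy = (iys + 0.5) * grid_step,
                    vx = agg[, 1] / cnt, vy = agg[, 2] / cnt, count = cnt)
  out <- out[order(out$cx, out$cy), ]
  rownames(out) <- NULL
  class(out) <- c("velocity_field", "data.frame")
  out
}

#' Border progression kinetics
#'
#' Fits the mean border position with a quadratic anchored at the initial
#' position for `t < t_crossover` and a straight line for `t >=
#' t_crossover`, and estimates a log-log slope for each regime. The log-log
#' slope of a regime is computed on the advance since that regime's onset
#' (`x(t) - x(t_on)` against `t - t_on`), so a purely quadratic early phase
#' reports 2 and a constant-speed late phase reports 1.
#'
#' @param times time grid (h).
#' @param xbar mean border positions (um).
#' @param t_crossover regime boundary (h).
#' @return List: `quad_coef` (um/h^2), `late_slope` (um/h), `late_intercept`,
#'   `loglog_early`, `loglog_late`, `x0`.
#' @export
border_kinetics <- function(times, xbar, t_crossover) {
  stopifnot(length(times) == length(xbar))
  early <- times < t_crossover
  late <- !early
  if (sum(early) < 5 || sum(late) < 5)
    stop("need at least 5 time points per regime")
  x0 <- xbar[which.min(times)]
  te <- times[early]; xe <- xbar[early] - x0
  quad <- coef(lm(xe ~ 0 + I(te^2)))[[1]]
  tl <- times[late]; xl <- xbar[late]
  lf <- coef(lm(xl ~ tl))
  ll_slope <- function(t, x) {
    ok <- t > 0 & x > 0
    if (sum(ok) < 3) return(NA_real_)
    coef(lm(log(x[ok]) ~ log(t[ok])))[[2]]
  }
  t_on <- min(tl)
  x_on <- xl[which.min(tl)]
  list(quad_coef = quad,
       late_slope = lf[[2]], late_intercept = lf[[1]],
       loglog_early = ll_slope(te, xe),
       loglog_late = ll_slope(tl - t_on, xl - x_on),
       x0 = x0)
}

#' Border-aligned velocity profiles
#'
#' For each requested time, translates positions so the mean border position
#' maps to 0 and averages the velocity component normal to the border (v_x)
#' in bins of the distance to the border.
#'
#' @param run a [simulate_band()] result.
#' @param times times (h) to profile; the nearest snapshot within 0.5 h is
#'   used (error if none).
#' @param bin bin width (um), default 50.
#' @return A data.frame `time, x_rel, vx, n`.
#' @export
velocity_profile <- function(run, times = c(0, 10, 20), bin = 50) {
  out <- list()
  for (tq in times) {
    k <- which.min(abs(run$times - tq))
    if (abs(run$times[k] - tq) > 0.5)
      stop("no snapshot within 0.5 h of t = ", tq)
    pos <- run$pos[[k]]; vel <- run$vel[[k]]
    bd <- detect_border(pos, run$config$Ly, run$params$border_band_width)
    xr <- pos[, 1] - bd$mean_x
    bins <- floor(xr / bin)
    agg <- rowsum(cbind(vel[, 1], 1), bins)
    b <- as.numeric(rownames(agg))
    out[[length(out) + 1L]] <- data.frame(
      time = run$times[k], x_rel = (b + 0.5) * bin,
      vx = agg[, 1] / agg[, 2], n = agg[, 2])
  }
  do.call(rbind, out)
}

#' Cell density along a finger
#'
#' Identifies digitated protrusions (fingers) as y-clusters of cells ahead
#' of the base border level — the median of the per-band border positions,
#' which is robust to the fingers themselves — takes the most advanced
#' cluster (preferring clusters containing a leader), and averages local
#' cell density in bins of the distance from the finger base toward the
#' tip.
#'
#' @param state a [particle_state()] (final band state).
#' @param config the band [sim_config()].
#' @param params the [frontier_params()].
#' @param bin arclength bin (um), default 25.
#' @param min_cells minimal cluster size to count as a finger.
#' @return A data.frame `s_mid, density, n` (possibly empty when no finger
#'   exists).
#' @export
finger_density <- function(state, config, params = frontier_params(),
                           bin = 25, min_cells = 5) {
  box <- as_box(config)
  alive <- state$alive
  pos <- state$pos[alive, , drop = FALSE]
  kind <- state$kind[alive]
  bd <- detect_border(pos, config$Ly, params$border_band_width)
  base_x <- median(bd$x_border)
  beyond <- which(pos[, 1] > base_x + 2 * params$grid_spacing)
  empty <- data.frame(s_mid = numeric(0), density = numeric(0),
                      n = numeric(0))
  if (length(beyond) < min_cells) return(empty)
  ys <- sort(pos[beyond, 2])
  gaps <- diff(ys)
  brk <- which(gaps > 3 * params$grid_spacing)
  cl_id <- cumsum(c(1, gaps > 3 * params$grid_spacing))
  cl_of <- cl_id[match(pos[beyond, 2], ys)]
  clusters <- split(beyond, cl_of)
  clusters <- clusters[vapply(clusters, length, 1L) >= min_cells]
  if (!length(clusters)) return(empty)
  has_leader <- vapply(clusters, function(ix) any(kind[ix] == 1L), logical(1))
  cand <- if (any(has_leader)) clusters[has_leader] else clusters
  finger <- cand[[which.max(vapply(cand, function(ix) max(pos[ix, 1]), 1))]]
  graph <- find_neighbors(pos, config$neighbor_cutoff, box)
  dens <- local_density(graph, finger)
  s <- pos[finger, 1] - base_x
  bins <- floor(s / bin)
  agg <- rowsum(cbind(dens, 1), bins)
  b <- as.numeric(rownames(agg))
  data.frame(s_mid = (b + 0.5) * bin, density = agg[, 1] / agg[, 2],
             n = agg[, 2])
}
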