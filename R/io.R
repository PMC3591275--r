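#' Write / read a trajectory as columnar text
#'
#' One row per (time, particle): `t,id,x,y,vx,vy,kind`. A `.gz` suffix
#' writes through a gzip connection.
#'
#' @param trajectory a [simulate_bulk()] or [simulate_band()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  rows <- lapply(seq_along(trajectory$times), function(k) {
    n <- nrow(trajectory$pos[[k]])
    kind <- if (is.list(trajectory$kind)) trajectory$kind[[k]]
            else trajectory$kind
    ids <- if (is.list(trajectory$ids)) trajectory$ids[[k]]
           else trajectory$ids
    data.frame(t = rep(trajectory$times[k], n), id = ids,
               x = trajectory$pos[[k]][, 1], y = trajectory$pos[[k]][, 2],
               vx = trajectory$vel[[k]][, 1], vy = trajectory$vel[[k]][, 2],
               kind = kind)
  })
  df <- do.call(rbind, rows)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  times <- sort(unique(df$t))
  sp <- split(df, df$t)
  sp <- sp[order(as.numeric(names(sp)))]
  list(times = times,
       pos = lapply(sp, function(d) cbind(d$x, d$y)),
       vel = lapply(sp, function(d) cbind(d$vx, d$vy)),
       kind = lapply(sp, function(d) d$kind),
       ids = lapply(sp, function(d) d$id))
}

#' Write a correlation curve or histogram with a metadata header
#'
#' Columnar text preceded by `#`-prefixed metadata lines (estimator name,
#' sample size, seed).
#'
#' @param x a [correlation_curve()] or [make_histogram()] object, or any
#'   data.frame.
#' @param path output path.
#' @param meta named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  if (inherits(x, "velocity_histogram")) {
    x <- data.frame(edge_lo = head(x$edges, -1), edge_hi = x$edges[-1],
                    count = x$counts, density = x$density)
  }
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Inventory of the output files of a run: configuration echo, seed, and an
#' md5 content hash per file (reproducible for a fixed seed).
#'
#' @param files character vector of output paths.
#' @param config the run's [sim_config()].
#' @param path manifest output path.
#' @return The manifest data.frame, invisibly; written as columnar text.
#' @export
run_manifest <- function(files, config, path) {
  df <- data.frame(file = files,
                   md5 = unname(tools::md5sum(files)),
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", config$seed), con)
  writeLines(sprintf("# alpha: %g beta: %g tau: %g sigma0: %g",
                     config$alpha, config$beta, config$tau, config$sigma0),
             con)
  writeLines(sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             con)
  write.csv(df, con, row.names = FALSE)
  invisible(df)
}

#' Synthetic PIV-style velocity-field series
#'
#' Emulates the gridded velocity output of a PIV analysis of a monolayer
#' movie: runs a bulk simulation, bins each snapshot to a square grid
#' (30 or 60 um steps are typical), and adds isotropic gaussian measurement
#' noise. The generating parameters are returned as a truth record — these
#' fields are the standard synthetic fit target for [fit_parameters()].
#'
#' @param config a [sim_config()].
#' @param n_particles particle count.
#' @param t_end duration (h).
#' @param grid_step grid step (um), default 30.
#' @param measurement_noise s.d. (um/h) of the added gaussian noise per
#'   velocity component, default 0.
#' @param snapshot_every cadence (h).
#' @return List `fields` (list of [grid_velocity_field()] frames), `times`,
#'   `truth` (list `alpha, beta, tau, sigma0, seed`), `trajectory`.
#' @export
make_synthetic_piv <- function(config, n_particles = 1000, t_end = 8,
                               grid_step = 30, measurement_noise = 0,
                               snapshot_every = 0.1) {
  tr <- simulate_bulk(config, n_particles, t_end, snapshot_every)
  box <- as_box(config)
  fields <- lapply(seq_along(tr$times), function(k) {
    f <- grid_velocity_field(tr$pos[[k]], tr$vel[[k]], grid_step, box)
    if (measurement_noise > 0) {
      f$vx <- f$vx + rnorm(nrow(f), sd = measurement_noise)
      f$vy <- f$vy + rnorm(nrow(f), sd = measurement_noise)
    }
    f
  })
  list(fields = fields, times = tr$times,
       truth = list(alpha = config$alpha, beta = config$beta,
                    tau = config$tau, sigma0 = config$sigma0,
                    seed = config$seed),
       trajectory = tr)
}
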