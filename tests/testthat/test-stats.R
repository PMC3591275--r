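test_that("velocity histograms are density-normalized with sound moments", {
  set.seed(51)
  v <- cbind(rnorm(5000, sd = 8), rnorm(5000, sd = 8))
  h <- velocity_histograms(v, bin = 1)
  w <- diff(h$vx$edges)
  expect_equal(sum(h$vx$density * w), 1, tolerance = 1e-9)
  expect_equal(h$moments$sd, c(8, 8), tolerance = 0.05)

  # modulus follows the 2-D gaussian-component modulus density
  sp <- sqrt(rowSums(v^2))
  ks <- suppressWarnings(
    ks.test(sp, function(q) 1 - exp(-q^2 / (2 * 64))))
  expect_gt(ks$p.value, 0.01)

  # all-zero velocities: single occupied bin at 0
  h0 <- velocity_histograms(matrix(0, 10, 2), bin = 1)
  expect_equal(sum(h0$speed$counts > 0), 1)
  expect_error(velocity_histograms(matrix(0, 1, 2)), "2")
})

test_that("pair correlation of centers matches structure and brute force", {
  # uniform Poisson points: g(r) ~ 1
  set.seed(52)
  L <- 400; n <- 2000
  pos <- cbind(runif(n, 0, L), runif(n, 0, L))
  box <- box_spec(L, L)
  g <- pair_correlation_centers(pos, box, dr = 5, rmax = 80)
  keep <- g$lag > 10
  expect_lt(max(abs(g$value[keep] - 1)), 0.15)
  expect_equal(mean(g$value[keep]), 1, tolerance = 0.02)

  # hexagonal lattice: empty below the spacing, peaks at a and a*sqrt(3)
  fx <- hex_fixture(16, 16, a = 16)
  gh <- pair_correlation_centers(fx$pos, fx$box, dr = 1, rmax = 40)
  expect_true(all(gh$value[gh$lag < 15] == 0))
  expect_gt(gh$value[which.min(abs(gh$lag - 16))], 3)
  expect_gt(gh$value[which.min(abs(gh$lag - 16 * sqrt(3)))], 1.5)

  # estimator equals brute-force annulus counting
  set.seed(53)
  pos2 <- cbind(runif(100, 0, 200), runif(100, 0, 200))
  box2 <- box_spec(200, 200)
  g2 <- pair_correlation_centers(pos2, box2, dr = 4, rmax = 60)
  expect_equal(g2$n, oracle_pair_counts(pos2, box2, 4, 60))
  expect_error(pair_correlation_centers(pos2, box2, dr = 0), "dr")
})

test_that("spatial velocity correlation matches brute force and independence", {
  set.seed(54)
  L <- 300
  pos <- cbind(runif(50, 0, L), runif(50, 0, L))
  vel <- cbind(rnorm(50), rnorm(50))
  box <- box_spec(L, L)
  cur <- spatial_velocity_correlation(pos, vel, "x", dr = 20, box = box,
                                      rmax = 100)
  or <- oracle_spatial_corr(pos, vel[, 1], box, 20, 100)
  expect_equal(cur$normalized, or$normalized, tolerance = 1e-12)
  expect_equal(cur$n, or$counts)
  expect_equal(cur$normalized[1], 1)

  # independent velocities: C(r > 0) ~ 0 within 3 SE
  set.seed(55)
  n <- 3000
  posb <- cbind(runif(n, 0, L), runif(n, 0, L))
  velb <- cbind(rnorm(n), rnorm(n))
  curb <- spatial_velocity_correlation(posb, velb, "x", dr = 20, box = box)
  se <- 1 / sqrt(curb$n[-1])
  expect_true(all(abs(curb$normalized[-1]) < 3.5 * se))

  # identical velocities: zero variance is flagged
  expect_error(
    spatial_velocity_correlation(pos, matrix(3, 50, 2), "x", box = box),
    "variance")
})

test_that("temporal autocorrelation is exact at lag 0 and tracks closed form", {
  # uncoupled damped particles driven by OU noise: matches the
  # single-mode two-exponential closed form within 3 SE
  cfg <- sim_config(alpha = 1.42, beta = 0, tau = 1.4, sigma0 = 100,
                    Lx = 200, Ly = 200, A_rep = 0, A_att = 0, seed = 56)
  spec <- lattice_spec(a = 16, n1 = 4, n2 = 4)
  fs <- frozen_sim(spec, cfg, t_end = 60, t_burn = 10, kmax = 2)
  expect_equal(fs$temporal$normalized[1], 1)
  spectrum <- mode_rates(spec, cfg$alpha, 0)
  ana <- analytic_temporal_autocorr(spectrum, cfg$tau, fs$temporal$lag)
  lags_check <- fs$temporal$lag <= 3 & fs$temporal$lag > 0
  # SE of the autocorrelation estimate from the effective sample count
  n_eff <- 16 * 50 / (2 * 1.4 / 0.1)
  expect_lt(max(abs(fs$temporal$normalized[lags_check] -
                      ana$normalized[lags_check])), 3 / sqrt(n_eff))

  # eulerian and lagrangian agree on a bulk run at 30 and 60 um grids
  cfgb <- sim_config(Lx = 400, Ly = 400, seed = 57)
  tr <- simulate_bulk(cfgb, 640, 6, snapshot_every = 0.2)
  lagr <- temporal_autocorrelation(tr, "x", "lagrangian", t_start = 2)
  for (gs in c(30, 60)) {
    eul <- temporal_autocorrelation(tr, "x", "eulerian", grid_step = gs,
                                    t_start = 2)
    keep <- lagr$lag <= 2
    expect_lt(max(abs(lagr$normalized[keep] - eul$normalized[keep])), 0.12)
  }
})

test_that("correlation length finds the 1/e crossing by interpolation", {
  lam <- 45
  r <- seq(0, 300, by = 10)
  cur <- correlation_curve(r, exp(-r / lam), exp(-r / lam), rep(100, length(r)))
  expect_equal(correlation_length(cur), lam, tolerance = 5 / lam)

  flat <- correlation_curve(r, rep(0.9, length(r)), rep(0.9, length(r)),
                            rep(100, length(r)))
  expect_error(correlation_length(flat), "crossing")

  # noisy exponential, SNR 10: recovered within 10%
  set.seed(58)
  noisy <- exp(-r / lam) * (1 + rnorm(length(r), sd = 0.03))
  curn <- correlation_curve(r, noisy, noisy, rep(100, length(r)))
  expect_equal(correlation_length(curn), lam, tolerance = 0.1)
})

test_that("grid velocity field averages per cell and matches brute force", {
  box <- box_spec(100, 100)
  f1 <- grid_velocity_field(matrix(c(12, 37), 1, 2),
                            matrix(c(3, -2), 1, 2), 25, box)
  expect_equal(nrow(f1), 1)
  expect_equal(c(f1$vx, f1$vy), c(3, -2))
  expect_equal(c(f1$cx, f1$cy), c(12.5, 37.5))

  set.seed(59)
  pos <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  vel <- cbind(rnorm(200), rnorm(200))
  f <- grid_velocity_field(pos, vel, 20, box)
  expect_equal(sum(f$count), 200)
  # brute force per cell
  for (k in sample(nrow(f), 5)) {
    inside <- pos[, 1] >= f$cx[k] - 10 & pos[, 1] < f$cx[k] + 10 &
      pos[, 2] >= f$cy[k] - 10 & pos[, 2] < f$cy[k] + 10
    expect_equal(f$vx[k], mean(vel[inside, 1]), tolerance = 1e-12)
  }

  # uniform velocities: constant field
  fu <- grid_velocity_field(pos, matrix(c(5, 1), 200, 2, byrow = TRUE), 20,
                            box)
  expect_true(all(abs(fu$vx - 5) < 1e-12))
})

test_that("border kinetics separates quadratic and linear regimes", {
  t <- seq(0, 40, by = 0.5)
  # pure quadratic early phase
  bk <- border_kinetics(t, 7 + 3 * t^2, t_crossover = 41 - 3)
  expect_equal(bk$quad_coef, 3, tolerance = 1e-9)
  expect_equal(bk$loglog_early, 2, tolerance = 0.02)

  # pure linear series
  bk2 <- border_kinetics(t, 5 + 12 * t, t_crossover = 10)
  expect_equal(bk2$late_slope, 12, tolerance = 1e-9)

  # piecewise: quadratic then linear with matched value and slope
  tc <- 20
  x <- ifelse(t < tc, 0.5 * t^2, 0.5 * tc^2 + tc * (t - tc))
  bk3 <- border_kinetics(t, x, t_crossover = tc)
  expect_equal(bk3$loglog_early, 2, tolerance = 0.05)
  expect_equal(bk3$loglog_late, 1, tolerance = 0.05)
  expect_error(border_kinetics(t[1:6], x[1:6], t_crossover = 2), "5")
})

test_that("velocity profile translates to the border and averages per bin", {
  # synthetic band run object: all cells move +x at 10 um/h
  pos <- cbind(runif(300, -400, 0), runif(300, 0, 500))
  run <- list(times = c(0, 10),
              pos = list(pos, pos), vel = list(matrix(c(10, 0), 300, 2,
                                                      byrow = TRUE),
                                               matrix(c(10, 0), 300, 2,
                                                      byrow = TRUE)),
              config = sim_config(Lx = 500, Ly = 500, boundary = "band",
                                  seed = 1),
              params = frontier_params())
  vp <- velocity_profile(run, times = c(0, 10), bin = 50)
  expect_true(all(abs(vp$vx - 10) < 1e-9))
  expect_true(all(vp$x_rel <= 0 + 50))
  expect_error(velocity_profile(run, times = 5), "0.5")
})
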