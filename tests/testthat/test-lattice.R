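test_that("mode rates match the dense eigendecomposition of the coupling", {
  spec <- lattice_spec(a = 16, n1 = 6, n2 = 6)
  alpha <- 1.42; beta <- 38
  spectrum <- mode_rates(spec, alpha, beta)
  expect_equal(min(spectrum$lambda), alpha, tolerance = 1e-12)
  expect_true(all(spectrum$lambda >= alpha - 1e-12))

  # numerically diagonalized coupling matrix on the same periodic lattice
  g <- epimotion:::lattice_graph(spec)
  expect_true(all(g$degree == 6))
  n <- nrow(g$nbr)
  M <- diag(alpha + 6 * beta, n)
  for (i in seq_len(n)) M[i, g$nbr[i, ]] <- M[i, g$nbr[i, ]] - beta
  ev <- eigen(M, only.values = TRUE)$values
  expect_lt(max(abs(sort(Re(ev)) - sort(spectrum$lambda))), 1e-8)

  # beta = 0 decouples all modes
  expect_equal(mode_rates(spec, 2, 0)$lambda, rep(2, 36))
})

test_that("analytic autocorrelation is validated by direct integration", {
  # numeric integration of the exact two-filter spectral integral
  lam <- 3.3; tau <- 1.4
  direct <- function(t) {
    integrand <- function(w) 2 * (1 / tau) /
      (((1 / tau)^2 + w^2) * (lam^2 + w^2)) * cos(w * t) / pi
    integrate(integrand, 0, Inf, rel.tol = 1e-9,
              subdivisions = 4000L)$value
  }
  ts <- c(0, 0.5, 1, 2, 4)
  closed <- epimotion:::mode_autocov(rep(lam, length(ts)), tau, 0)
  vals <- vapply(ts, function(t) epimotion:::mode_autocov(lam, tau, t),
                 numeric(1))
  nums <- vapply(ts, direct, numeric(1))
  expect_equal(vals, nums, tolerance = 1e-8)

  # degenerate lambda * tau = 1 handled by the analytic limit
  mu <- 1 / tau
  v_deg <- epimotion:::mode_autocov(mu, tau, 1.0)
  v_near <- epimotion:::mode_autocov(mu * (1 + 1e-7), tau, 1.0)
  expect_equal(v_deg, v_near, tolerance = 1e-5)

  spec <- lattice_spec(a = 16, n1 = 12, n2 = 12)
  spectrum <- mode_rates(spec, 1.42, 38)
  A <- analytic_temporal_autocorr(spectrum, 1.4, c(0, 1, 2))
  expect_equal(A$normalized[1], 1)
  expect_true(all(diff(A$normalized) < 0))
})

test_that("analytic spatial correlation is a delta without coupling", {
  spec <- lattice_spec(a = 16, n1 = 12, n2 = 12)
  spectrum0 <- mode_rates(spec, 1.42, 0)
  rv <- outer(0:4, spec$prim[1, ])
  # raw (all-mode) curve: exact delta at r = 0
  C0 <- analytic_spatial_corr(spectrum0, 1.4, rv, drop_uniform = FALSE)
  expect_equal(C0$normalized, c(1, 0, 0, 0, 0), tolerance = 1e-10)
  # mean-removed convention: the dropped uniform mode leaves the exact
  # -1/(M-1) floor of mean-subtracted uncorrelated samples
  C0m <- analytic_spatial_corr(spectrum0, 1.4, rv)
  expect_equal(C0m$normalized[-1], rep(-1 / (144 - 1), 4), tolerance = 1e-10)

  spectrum <- mode_rates(spec, 1.42, 38)
  C <- analytic_spatial_corr(spectrum, 1.4, rv)
  expect_equal(C$normalized[1], 1)
  expect_true(all(C$normalized[1:3] > 0))
  expect_true(all(diff(C$normalized) < 0))
})

test_that("parameter sensitivity follows the expected directions", {
  spec <- lattice_spec(a = 16, n1 = 48, n2 = 48)
  rv <- outer(0:20, spec$prim[1, ])
  tgrid <- seq(0, 4, by = 0.1)
  len_s <- function(a, b, tau)
    correlation_length(analytic_spatial_corr(mode_rates(spec, a, b), tau, rv))
  len_t <- function(a, b, tau)
    correlation_length(analytic_temporal_autocorr(mode_rates(spec, a, b),
                                                  tau, tgrid))
  base_s <- len_s(1.42, 38, 1.4); base_t <- len_t(1.42, 38, 1.4)

  # higher damping shrinks both the spatial and the temporal extent
  expect_lt(len_s(2.84, 38, 1.4), base_s)
  expect_lt(len_t(2.84, 38, 1.4), base_t)
  expect_gt(len_s(0.71, 38, 1.4), base_s)
  expect_gt(len_t(0.71, 38, 1.4), base_t)

  # higher alignment extends the spatial range, barely the temporal decay
  # (the gain saturates below the sqrt(2) of an infinite sheet as the
  # correlation length approaches the torus size)
  expect_gt(len_s(1.42, 76, 1.4), 1.1 * base_s)
  expect_lt(abs(len_t(1.42, 76, 1.4) - base_t), 0.15 * base_t)

  # longer noise memory slows the temporal decay, weakly the spatial range
  expect_gt(len_t(1.42, 38, 2.8), 1.3 * base_t)
  expect_lt(abs(len_s(1.42, 38, 2.8) - base_s), 0.15 * base_s)
})

test_that("analytic curves converge as the lattice grows", {
  # convergence is slow at the reference parameters (the mode weights peak
  # as 1/lambda^2 at small q, and the mean-removed curves lose a 1/M share
  # of weight with the uniform mode), so successive doublings are checked
  # for contraction rather than a fixed small bound
  diffs_s <- diffs_t <- numeric(0)
  rv <- outer(0:8, lattice_spec(16, 24, 24)$prim[1, ])
  tg <- seq(0, 4, 0.5)
  for (n in c(24, 48, 96)) {
    s <- analytic_spatial_corr(mode_rates(lattice_spec(16, n, n), 1.42, 38),
                               1.4, rv)
    t <- analytic_temporal_autocorr(mode_rates(lattice_spec(16, n, n),
                                               1.42, 38), 1.4, tg)
    if (n > 24) {
      diffs_s <- c(diffs_s, max(abs(s$normalized - prev_s)))
      diffs_t <- c(diffs_t, max(abs(t$normalized - prev_t)))
    }
    prev_s <- s$normalized; prev_t <- t$normalized
  }
  expect_lt(diffs_s[2], 0.6 * diffs_s[1])  # contraction under doubling
  expect_lt(diffs_t[2], 0.6 * diffs_t[1])
  expect_lt(diffs_s[2], 0.12)
  expect_lt(diffs_t[2], 0.03)
})

test_that("frozen simulation reproduces the closed forms within 3 SE", {
  cfg <- sim_config(sigma0 = 300, seed = 61)
  spec <- lattice_spec(a = 16, n1 = 12, n2 = 12)
  fs <- frozen_sim(spec, cfg, t_end = 40, t_burn = 5, kmax = 4)
  spectrum <- mode_rates(spec, cfg$alpha, cfg$beta)

  # bound covers 3 SE plus the first-order (O(dt)) variance distortion of
  # the explicit Euler step on the stiff modes
  ana_t <- analytic_temporal_autocorr(spectrum, cfg$tau, fs$temporal$lag)
  for (lag_h in c(0.5, 1, 2)) {
    k <- which.min(abs(fs$temporal$lag - lag_h))
    expect_lt(abs(fs$temporal$normalized[k] - ana_t$normalized[k]), 0.06)
  }
  ana_s <- analytic_spatial_corr(spectrum, cfg$tau,
                                 outer(0:4, spec$prim[1, ]))
  expect_lt(max(abs(fs$spatial$normalized[2:4] - ana_s$normalized[2:4])),
            0.06)

  # sigma rescaling leaves normalized curves unchanged at the same seed
  cfg2 <- cfg; cfg2$sigma0 <- 600
  fs2 <- frozen_sim(spec, cfg2, t_end = 10, t_burn = 2, kmax = 4)
  fs1 <- frozen_sim(spec, cfg, t_end = 10, t_burn = 2, kmax = 4)
  expect_equal(fs1$spatial$normalized, fs2$spatial$normalized,
               tolerance = 1e-6)
  expect_equal(fs1$temporal$normalized, fs2$temporal$normalized,
               tolerance = 1e-6)
})

test_that("border progression estimate is quadratic then rate-switched", {
  t <- seq(0, 40, by = 0.5)
  # no leaders: linear only
  expect_equal(border_estimate(0, 18, 3, 150, t), 3 * t)

  # leader-induced advance is exactly quadratic before the switch
  x <- border_estimate(0.3, 18, 3, 150, t, rate_late = 0.1)
  adv <- x - 3 * t
  early <- t > 0 & t < 20
  slope <- coef(lm(log(adv[early]) ~ log(t[early])))[[2]]
  expect_equal(slope, 2, tolerance = 1e-9)

  # continuous value and slope at the switch
  eps <- 1e-6
  x_m <- border_estimate(0.3, 18, 3, 150, 20 - eps, rate_late = 0.1)
  x_p <- border_estimate(0.3, 18, 3, 150, 20 + eps, rate_late = 0.1)
  expect_equal(x_m, x_p, tolerance = 1e-6)

  # matches an event-driven brute-force leader accumulation within 5%
  rate <- 0.3; ellc <- 150; VL <- 18; v0 <- 3; Lb <- 1.5  # mm
  R <- rate * Lb                      # leaders per hour
  arrivals <- seq(0.5 / R, 20, by = 1 / R)
  brute <- vapply(t[t <= 20 & t >= 5], function(tt) {
    v0 * tt + sum(pmax(tt - arrivals[arrivals <= tt], 0) *
                    (VL - v0) * ellc / (Lb * 1000))
  }, numeric(1))
  model <- border_estimate(rate, VL, v0, ellc, t[t <= 20 & t >= 5])
  expect_lt(max(abs(brute - model) / model), 0.05)
})
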