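---
title: "A stochastic interacting-particle model of collective epithelial motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic interacting-particle model of collective epithelial motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epimotion)
```

## The model

`epimotion` simulates a confluent epithelial sheet (MDCK-type) as a system
of point particles, one per cell. Each cell carries a velocity $v_i$ that
evolves by a continuous-time Langevin equation:

$$\frac{dv_i}{dt} \;=\; -\alpha\, v_i \;+\; \beta \sum_{j \in N(i)} (v_j - v_i)
\;+\; \sum_{j \in N(i)} f(x_j - x_i) \;+\; \sigma\, \eta_i ,
\qquad \frac{dx_i}{dt} = v_i .$$

The four terms are: effective damping (`alpha`, 1/h) standing in for
adhesion rupture and substrate friction; velocity alignment toward each
sector neighbor (`beta`, 1/h per neighbor — a plain sum over neighbors, not
a mean); a central pair force with a repulsive gaussian core and a weak
Heaviside-gated linear attraction; and an Ornstein-Uhlenbeck noise drive
$\eta_i$ with correlation time `tau` (h), unit stationary variance and
amplitude `sigma0` (um/h^2). There is no preferred speed and no
spontaneous-flocking nonlinearity: all collective order is driven by noise
filtered through damping and alignment.

Neighbors are defined by the sector rule: the disc of radius 100 um around
a cell is split into six 60-degree sectors anchored on the +x axis and the
nearest particle in each sector is a neighbor. The local density is
$d_i = 2 / (\sqrt{3}\,\bar r_i^2)$, with $\bar r_i$ the mean sector
distance (empty sectors contribute the cutoff), so a hexagonal lattice of
spacing $a$ reports exactly its true density $2/(\sqrt3 a^2)$.

The reference parameter triple `(alpha, beta, tau) = (1.42, 38, 1.40)` is
the bulk fit used throughout; `sigma0 = 450` calibrates the bulk mean cell
speed to about 15 um/h at those parameters via the lattice closed form
(`calibrate_sigma()`).

```{r}
cfg <- preset_config("bulk", seed = 1)   # N = 4000, 1 mm x 1 mm, periodic
tr  <- simulate_bulk(cfg, attr(cfg, "n_particles"), t_end = 10)
cur <- bulk_correlations(tr, t_start = 5)
correlation_length(cur$spatial)   # 130-170 um by seed: ~ten cell diameters
correlation_length(cur$temporal)  # ~1.6 h
```

## Integration and numerical choices

- **Step size.** The velocity dynamics are integrated with explicit Euler
  plus an exact OU substep. The stiffest modes are set by the alignment
  sum: with up to 6 neighbors the fastest relaxation rate approaches
  $\alpha + 12\beta \approx 460$/h at the defaults, so stability requires
  $dt < 2/(\alpha + 12\beta) \approx 0.0044$ h. The default `dt = 0.002` h
  keeps a factor-two margin. The OU substep
  $\eta' = \eta e^{-dt/\tau} + \sqrt{1 - e^{-2dt/\tau}}\,\zeta$ is exact
  for any `dt`.
- **Euler bias.** Explicit Euler inflates the stationary variance of the
  stiffest modes by a factor $\approx 1/(1 - \lambda dt/2)$. At
  `dt = 0.002` this distorts normalized frozen-lattice correlation curves
  by up to a few hundredths at the farther shells; the frozen-lattice
  validation tests budget for this alongside the statistical error.
- **Neighbor graph refresh.** Per-step displacements are below 0.05 um
  (0.3% of the cell spacing), so the graph is rebuilt every 5 steps
  (0.01 h) by default.
- **Sector boundaries.** Sector classification is pure comparisons (no
  `atan2`) with a 1e-9 relative snap so that bonds lying on a sector
  boundary up to rounding — the six bonds of an axis-aligned hexagonal
  lattice — classify deterministically and identically in the R and C++
  paths.
- **Force cap.** Below 0.5 um separation the radial force magnitude is
  pinned at its 0.5-um value so freshly divided daughters (placed 2 um
  apart) separate robustly; the paired potential is continued linearly.
- **Initialization.** Bulk runs start from the nearest complete hexagonal
  grid at the requested density (within ~1% of the requested N; an exact-N
  tiling would leave a partial-row density seam) with 1 um gaussian
  jitter, zero velocities and stationary noise states. At the default
  `d0 = 4e-3` cells/um^2 the packing spacing is
  $a = \sqrt{2/(\sqrt3 d_0)} \approx 17.0$ um.

## The band geometry: leaders, free surface, division

`simulate_band()` models the stencil-lift experiment: cells tile
$x \in [-w, 0]$ at density `d0`, the free surface $x > 0$ is covered by a
10-um grid of static surface particles, and the box is periodic in y.

- **Leaders** appear along the border as a Poisson process (0.3 per mm per
  hour before 20 h, 0.1 after — the measured rates are not legible in the
  source, so these are package defaults preserving the reported shape: a
  constant early rate with a drop at 20 h). A leader moves along +x at a
  speed drawn from a gaussian of mean 18 um/h (s.d. 4), keeps that
  velocity while it has at least 4 neighbors, otherwise follows the mean
  velocity of its remaining neighbors capped at its own initial speed; a
  neighborless leader keeps its previous direction at the cap. Leaders are
  never created within 150 um (in y) of any earlier leader and never
  divide.
- **Surface damage.** Each surface particle integrates the force
  magnitudes exerted by cells within 30 um with a 1-h leak
  (`w' = -w/tau_w + sum |f|`) and is removed permanently at
  `w >= 0.5 tau_w A_surf_normal`. Leaders carry a 50-fold stronger damage
  kernel, so they clear surface quickly while ordinary cells are repelled
  by the alive surface (gaussian kernel, range 10 um) — the effective
  description of the difference in free-surface exploration.
- **Division** attempts occur at rate `ln 2 / T_div` per cell
  (`T_div = 20` h) and are rolled back unless the parent's post-division
  local density stays at or below `d0`. The acceptance check is evaluated
  at the parent; the 2-um daughter transiently raises densities in its
  neighborhood until the repulsive core relaxes the pair apart, so
  instantaneous density fields can briefly overshoot the cap in a
  division-dense neighborhood. Daughters inherit the parent's velocity and
  noise state (a fresh state would inject extra noise exactly at division
  events).
- **Frontier cadence.** Border detection, leader events, surface damage and
  divisions advance every 10 dynamics steps (0.02 h), far below the
  fastest frontier timescale (`tau_w` = 1 h).

## The frozen-lattice approximation

With positions pinned to a triangular lattice the velocity dynamics become
linear and decouple into Fourier modes over the discrete Brillouin zone,
with relaxation rates
$\lambda_q = \alpha + \beta \sum_{e} (1 - \cos(q \cdot e))$ over the six
nearest-neighbor bonds. Each mode is an OU-driven linear filter whose
stationary autocovariance is the two-exponential closed form implemented in
`analytic_temporal_autocorr()`; `analytic_spatial_corr()` is the inverse
Fourier sum of the per-mode variances $1/(\lambda_q(\lambda_q + 1/\tau))$.
`frozen_sim()` integrates the same dynamics stochastically on the exact
lattice torus and validates the closed forms.

Two conventions matter and are easy to get wrong:

- **The uniform mode.** All empirical estimators subtract the
  instantaneous mean velocity, which removes exactly the $q = 0$ mode —
  the largest single weight in the spectrum. The analytic curves therefore
  drop it by default (`drop_uniform = TRUE`); keeping it adds a constant
  offset that masquerades as extra correlation range. The mean cell
  *speed*, in contrast, includes the collective drift, so
  `calibrate_sigma()` keeps the full spectrum with the lattice sized to
  the particle count (the drift variance scales as $1/N$).
- **The torus.** Folding the lattice into a rectangle changes the
  periodicity (the y-wrap is $n_2 a_2 - (n_2/2) a_1$, not $n_2 a_2$), so
  the frozen simulation uses the exact index-torus adjacency rather than a
  distance search on folded coordinates; the mode spectrum is eigen-checked
  against the dense coupling matrix.

At the reference triple (spacing 17 um) the frozen lattice gives a spatial
1/e length of ~122 um and a temporal 1/e time of ~1.67 h. The full moving
model agrees on the temporal side (~1.6 h) but is longer-ranged spatially
(~150-170 um): the central repulsion transmits motion between moving
neighbors, a channel the frozen-position approximation lacks. The lattice
curves are therefore used for initialization, oracles and calibration —
never as ground truth for full-model curves.

On the temporal decay specifically: the velocity is OU noise passed through
a linear filter, so its autocorrelation starts with zero slope and no mode
decays (after normalization) faster than $e^{-t/\tau}$. With
$\tau = 1.40$ h the 1/e crossing of any mode mixture is bounded below by
1.40 h; the measured full-model value of ~1.6 h is as fast as this model
family gets, and "decays on the hour scale" should be read as the tail
timescale, not a sub-hour 1/e crossing.

## Parameter fitting and its limits

`fit_parameters()` minimizes the summed squared mismatch between
normalized model and target correlation curves (spatial up to
`R_max = 300` um, temporal up to `T_max = 4` h) with Nelder-Mead in
log-parameter space, initialized from a deterministic coarse grid probe of
the lattice objective; `sigma0` is then set by `calibrate_sigma()` and the
loop repeats until the parameters move by less than 1%.

The fit's conditioning deserves honesty. The curve pair constrains
`beta/alpha` (which sets the spatial range) and `tau` (the temporal tail)
well, but the overall rate scale is nearly unidentifiable: along
`(c alpha, c beta, tau)` the spatial correlation is exactly invariant, and
because $\lambda \tau \gg 1$ for most modes the autocorrelation changes
only at early times. In practice a lattice-objective refit of a
reference-run target recovers `beta/alpha` and `tau` to a few percent
while the individual `alpha` lands elsewhere in the flat valley; a
simulation-objective refit is additionally noise-driven, because a single
run's curves carry only ~35 effectively independent spatial patches in a
1-mm box. Curve comparisons are also only meaningful between runs with
identical averaging windows: short-window autocorrelation estimates are
biased low at large lags, and a window mismatch masquerades as a `tau`
shift.

## The synthetic PIV generator

`make_synthetic_piv()` emulates the gridded output of a PIV analysis of a
monolayer movie: a bulk simulation binned to a 30- or 60-um grid
(`grid_velocity_field()`) with isotropic gaussian measurement noise added,
plus a truth record of the generating parameters. It reproduces the data
*format* and the field statistics of the model — not optical artifacts,
segmentation errors, drift, or the density heterogeneity of real
monolayers, so passing recovery tests on it demonstrates estimator
correctness, not robustness to real-microscopy nuisances.

## Desk-scale study sizes

The statistical tests and the acceptance analyses run at the sizes used
throughout this vignette: the bulk reference geometry (N = 4000, 1 mm x
1 mm, 10 h with a 5-h transient discarded), the band geometry at N = 2000
over a 1.5-mm border for ~30 h, leader-statistics replicates at N = 600
(a shallower band; leader speed draws are independent of the band depth),
and 12- to 48-cell lattices for the closed-form oracles. These reproduce
the model's headline statistics — the ~150-um velocity correlation length,
the hour-scale velocity memory, the quadratic-then-linear border
progression, and the base-to-tip density decrease along fingers — at
workstation cost.

## Known limitations

- **Density coarsening.** Aligned velocity patches persist for about `tau`
  and compress the soft gaussian-core packing, so the sheet's density
  field develops strong inhomogeneity over several hours (5th-95th
  percentiles of `d/d0` reach 0.3-3 by 10 h even in the constant-noise
  periodic bulk). Early-time structure (the first couple of hours) matches
  a jittered hexagonal packing; statistics gathered later average over a
  clustered sheet. Stiffening the core or flattening the density-noise
  dependence does not remove the effect; it is intrinsic to alignment plus
  soft repulsion at these parameters.
- **Finger morphology.** With the packaged frontier constants, the leader's
  entourage travels as a compact cluster at the finger tip while the
  depleted zone sits at the finger base, and the leader-driven mean-border
  advance is flat for its first ~15 h (entrained fingers initially grow at
  the expense of the flanking border) before growing roughly linearly. A
  clean quadratic early regime of the mean border does not emerge at desk
  scale; the closed-form entrainment estimate (`border_estimate()`)
  retains it exactly.
- **Refit identifiability.** See the fitting section: the overall rate
  scale of the dynamics is nearly unidentifiable from the correlation-curve
  pair; only `beta/alpha` and `tau` are well constrained.
- Point particles: no cell shapes, no membranes, no substrate mechanics.
- The density-dependent noise amplitude uses a linear stand-in form
  `sigma0 (1 + kappa max(0, 1 - d/d0))`; only its monotonicity is
  constrained by the source material.
- Leader fate is imposed, not emergent; nothing in the model says which
  cell becomes a leader.
- The frontier constants (creation rates, damage parameters, kernel
  amplitudes) are package defaults chosen to reproduce the qualitative
  phenomenology; they are configurable and should not be quoted as
  measured values.
- Explicit Euler limits `dt`; a stiff integrator would allow larger steps
  but is deliberately out of scope.
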