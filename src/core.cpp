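#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <set>
using namespace Rcpp;

// Cell-list spatial hash shared by the neighbor search and the pair binners.
// Coordinates are wrapped into [0, L) for periodic dimensions; non-periodic
// dimensions use the data's bounding box.
struct CellGrid {
  int ncx, ncy;
  double x0, y0, csx, csy, Lx, Ly;
  bool px, py;
  std::vector<std::vector<int> > cells;

  CellGrid(const NumericMatrix& pos, double cellsize,
           double Lx_, double Ly_, bool px_, bool py_)
    : Lx(Lx_), Ly(Ly_), px(px_), py(py_) {
    const int n = pos.nrow();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, pos(i, 0)); xmax = std::max(xmax, pos(i, 0));
      ymin = std::min(ymin, pos(i, 1)); ymax = std::max(ymax, pos(i, 1));
    }
    if (px) { x0 = 0.0; ncx = std::max(1, (int)std::floor(Lx / cellsize)); csx = Lx / ncx; }
    else {
      x0 = xmin;
      double ext = std::max(xmax - xmin, cellsize);
      ncx = std::max(1, (int)std::floor(ext / cellsize));
      csx = ext / ncx * (1.0 + 1e-12);
    }
    if (py) { y0 = 0.0; ncy = std::max(1, (int)std::floor(Ly / cellsize)); csy = Ly / ncy; }
    else {
      y0 = ymin;
      double ext = std::max(ymax - ymin, cellsize);
      ncy = std::max(1, (int)std::floor(ext / cellsize));
      csy = ext / ncy * (1.0 + 1e-12);
    }
    cells.resize((size_t)ncx * ncy);
    for (int i = 0; i < n; ++i) {
      cells[index_of(pos(i, 0), pos(i, 1))].push_back(i);
    }
  }

  double wrap(double v, double L) const {
    double w = v - L * std::floor(v / L);
    if (w >= L) w = 0.0;
    return w;
  }

  size_t index_of(double x, double y) const {
    int cx, cy;
    if (px) cx = (int)(wrap(x, Lx) / csx); else cx = (int)((x - x0) / csx);
    if (py) cy = (int)(wrap(y, Ly) / csy); else cy = (int)((y - y0) / csy);
    if (cx < 0) cx = 0; if (cx >= ncx) cx = ncx - 1;
    if (cy < 0) cy = 0; if (cy >= ncy) cy = ncy - 1;
    return (size_t)cy * ncx + cx;
  }

  // visit candidate indices in cells within `range` cells of (x, y); each
  // cell is visited at most once even when a periodic grid is narrower than
  // the scan window
  template <class F>
  void visit(double x, double y, int range, F f) const {
    int cx, cy;
    if (px) cx = (int)(wrap(x, Lx) / csx); else cx = (int)((x - x0) / csx);
    if (py) cy = (int)(wrap(y, Ly) / csy); else cy = (int)((y - y0) / csy);
    const bool ally = py && (2 * range + 1 >= ncy);
    const bool allx = px && (2 * range + 1 >= ncx);
    int ylo = ally ? 0 : -range, yhi = ally ? ncy - 1 : range;
    int xlo = allx ? 0 : -range, xhi = allx ? ncx - 1 : range;
    for (int dy = ylo; dy <= yhi; ++dy) {
      int gy = ally ? dy : cy + dy;
      if (py) { gy = ((gy % ncy) + ncy) % ncy; }
      else if (gy < 0 || gy >= ncy) continue;
      for (int dx = xlo; dx <= xhi; ++dx) {
        int gx = allx ? dx : cx + dx;
        if (px) { gx = ((gx % ncx) + ncx) % ncx; }
        else if (gx < 0 || gx >= ncx) continue;
        const std::vector<int>& cell = cells[(size_t)gy * ncx + gx];
        for (size_t k = 0; k < cell.size(); ++k) f(cell[k]);
      }
    }
  }
};

static inline double minimg(double d, double L, bool periodic) {
  if (!periodic) return d;
  return d - L * std::round(d / L);
}

// 60-degree sector of the displacement (dx, dy), sectors [60k, 60(k+1))
// anchored on the +x axis. Pure comparisons (no atan2) with a small
// relative snap tolerance so that displacements lying on a sector boundary
// up to rounding (e.g. the six bonds of a hexagonal lattice) classify
// deterministically onto the boundary they bound from below, identically
// in the R and C++ implementations.
static inline int sector_of(double dx, double dy) {
  static const double SQRT3 = 1.7320508075688772;
  const double tol = 1e-9 * (std::fabs(dx) + std::fabs(dy));
  if (std::fabs(dy) <= tol) dy = 0.0;
  int base = 0;
  if (!(dy > 0.0 || (dy == 0.0 && dx > 0.0))) { // angle in [180, 360)
    base = 3; dx = -dx; dy = -dy;
  }
  // now angle in [0, 180)
  double diff = dy - SQRT3 * dx;   // 0 on the 60-degree boundary (dx > 0)
  if (std::fabs(diff) <= tol) diff = 0.0;
  double diff2 = dy + SQRT3 * dx;  // 0 on the 120-degree boundary (dx < 0)
  if (std::fabs(diff2) <= tol) diff2 = 0.0;
  if (dx > 0.0 && diff < 0.0) return base;                   // [0, 60)
  if (dx >= 0.0 ? (diff >= 0.0) : (diff2 > 0.0)) return base + 1; // [60, 120)
  return base + 2;                                           // [120, 180)
}

// Sector-based neighbor detection: the neighborhood of each particle is split
// into 6 equal 60-degree sectors anchored on the +x axis; the closest particle
// in each sector within `cutoff` is a neighbor (ties broken by lower index).
// Returns an N x 6 matrix of 1-based neighbor ids (0 = empty sector) and the
// matching distances (NA when empty).
// [[Rcpp::export]]
List cpp_sector_neighbors(NumericMatrix pos, double cutoff,
                          double Lx, double Ly, bool px, bool py) {
  const int n = pos.nrow();
  IntegerMatrix nbr(n, 6);
  NumericMatrix dist(n, 6);
  std::fill(dist.begin(), dist.end(), NA_REAL);
  if (n == 0) return List::create(_["nbr"] = nbr, _["dist"] = dist);

  CellGrid grid(pos, cutoff / 2.0, Lx, Ly, px, py);
  const double cut2 = cutoff * cutoff;

  for (int i = 0; i < n; ++i) {
    double xi = pos(i, 0), yi = pos(i, 1);
    double best[6]; int bestid[6];
    for (int s = 0; s < 6; ++s) { best[s] = R_PosInf; bestid[s] = -1; }
    grid.visit(xi, yi, 2, [&](int j) {
      if (j == i) return;
      double dx = minimg(pos(j, 0) - xi, Lx, px);
      double dy = minimg(pos(j, 1) - yi, Ly, py);
      double d2 = dx * dx + dy * dy;
      if (d2 > cut2 || d2 == 0.0) return;
      int s = sector_of(dx, dy);
      if (d2 < best[s] || (d2 == best[s] && j < bestid[s])) {
        best[s] = d2; bestid[s] = j;
      }
    });
    for (int s = 0; s < 6; ++s) {
      if (bestid[s] >= 0) {
        nbr(i, s) = bestid[s] + 1;
        dist(i, s) = std::sqrt(best[s]);
      }
    }
  }
  return List::create(_["nbr"] = nbr, _["dist"] = dist);
}

// All (i in A, j in B) pairs with distance <= radius. Returns 1-based index
// vectors plus the displacement components dx = xB - xA (minimum image).
// [[Rcpp::export]]
List cpp_radius_pairs(NumericMatrix A, NumericMatrix B, double radius,
                      double Lx, double Ly, bool px, bool py) {
  std::vector<int> ia, jb;
  std::vector<double> ddx, ddy, dd;
  const int na = A.nrow();
  if (na > 0 && B.nrow() > 0) {
    double cellsize = std::max(radius, 1e-6);
    CellGrid grid(B, cellsize, Lx, Ly, px, py);
    for (int i = 0; i < na; ++i) {
      double xi = A(i, 0), yi = A(i, 1);
      grid.visit(xi, yi, 1, [&](int j) {
        double dx = minimg(B(j, 0) - xi, Lx, px);
        double dy = minimg(B(j, 1) - yi, Ly, py);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= radius) {
          ia.push_back(i + 1); jb.push_back(j + 1);
          ddx.push_back(dx); ddy.push_back(dy); dd.push_back(d);
        }
      });
    }
  }
  return List::create(_["i"] = wrap(ia), _["j"] = wrap(jb),
                      _["dx"] = wrap(ddx), _["dy"] = wrap(ddy),
                      _["d"] = wrap(dd));
}

// Distance-binned accumulator over unordered particle pairs: per-bin pair
// counts plus sums of ux_i*ux_j and uy_i*uy_j (used by the radial
// distribution function and the equal-time spatial velocity correlation).
// Bin k covers (k*dr, (k+1)*dr]; the self-pair r = 0 is excluded.
// [[Rcpp::export]]
List cpp_pair_bins(NumericMatrix pos, NumericVector ux, NumericVector uy,
                   double rmax, double dr,
                   double Lx, double Ly, bool px, bool py) {
  const int n = pos.nrow();
  const int nbins = (int)std::ceil(rmax / dr);
  NumericVector counts(nbins), sx(nbins), sy(nbins);
  const bool have_u = (ux.size() == n && uy.size() == n);
  double cellsize = std::min(std::max(rmax / 3.0, 25.0), std::max(rmax, 25.0));
  CellGrid grid(pos, cellsize, Lx, Ly, px, py);
  int range = (int)std::ceil(rmax / cellsize);

  for (int i = 0; i < n; ++i) {
    double xi = pos(i, 0), yi = pos(i, 1);
    grid.visit(xi, yi, range, [&](int j) {
      if (j <= i) return;
      double dx = minimg(pos(j, 0) - xi, Lx, px);
      double dy = minimg(pos(j, 1) - yi, Ly, py);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d == 0.0 || d > rmax) return;
      int k = (int)std::ceil(d / dr) - 1;
      if (k < 0) k = 0;
      if (k >= nbins) return;
      counts[k] += 1.0;
      if (have_u) { sx[k] += ux[i] * ux[j]; sy[k] += uy[i] * uy[j]; }
    });
  }
  return List::create(_["counts"] = counts, _["sum_ux"] = sx, _["sum_uy"] = sy);
}

// Advance the coupled (eta, v, x) dynamics by `nsteps` explicit-Euler steps
// of size dt with the exact OU noise substep, rebuilding the sector
// neighbor graph every `refresh_every` steps. Leaders keep their velocity
// (it is prescribed outside); everyone moves. The gaussian draws come from
// R's RNG in the same order as the R-level ou_step (column-major), so a
// single seeded generator governs the whole simulation.
// [[Rcpp::export]]
List cpp_advance(NumericMatrix pos0, NumericMatrix vel0, NumericMatrix eta0,
                 NumericVector sigma, LogicalVector leader,
                 Nullable<NumericMatrix> f_ext_, List par,
                 int nsteps, double dt,
                 double Lx, double Ly, bool px, bool py,
                 double cutoff, int refresh_every,
                 bool align_mean, bool symmetrize) {
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0), eta = clone(eta0);
  const double alpha = par["alpha"], beta = par["beta"], tau = par["tau"];
  const double A_rep = par["A_rep"], r_rep = par["r_rep"];
  const double A_att = par["A_att"], r_att = par["r_att"];
  const double r_cut = par["r_cut"];
  const double ef = std::exp(-dt / tau), sf = std::sqrt(1.0 - ef * ef);
  NumericMatrix fext(n, 2);
  if (f_ext_.isNotNull()) fext = NumericMatrix(f_ext_);

  // capped radial force magnitude (positive = repulsive)
  const double fcap = A_rep * (0.5 / (r_rep * r_rep)) *
    std::exp(-0.25 / (2.0 * r_rep * r_rep));
  auto fmag = [&](double r) -> double {
    if (r > r_cut) return 0.0;
    if (r < 0.5) return fcap;
    double f = A_rep * (r / (r_rep * r_rep)) *
      std::exp(-r * r / (2.0 * r_rep * r_rep));
    if (r > r_att) f -= A_att * (r - r_att) / (r_cut - r_att);
    return f;
  };

  std::vector<int> efrom, eto;
  std::vector<int> degree(n);
  auto rebuild = [&]() {
    List g = cpp_sector_neighbors(pos, cutoff, Lx, Ly, px, py);
    IntegerMatrix nbr = g["nbr"];
    efrom.clear(); eto.clear();
    std::fill(degree.begin(), degree.end(), 0);
    for (int s = 0; s < 6; ++s)
      for (int i = 0; i < n; ++i)
        if (nbr(i, s) > 0) { efrom.push_back(i); eto.push_back(nbr(i, s) - 1); }
    if (symmetrize) {
      std::set<std::pair<int, int> > seen;
      for (size_t k = 0; k < efrom.size(); ++k)
        seen.insert(std::make_pair(efrom[k], eto[k]));
      std::vector<std::pair<int, int> > extra;
      for (std::set<std::pair<int, int> >::iterator it = seen.begin();
           it != seen.end(); ++it) {
        std::pair<int, int> rev(it->second, it->first);
        if (!seen.count(rev)) extra.push_back(rev);
      }
      for (size_t k = 0; k < extra.size(); ++k) {
        efrom.push_back(extra[k].first); eto.push_back(extra[k].second);
      }
    }
    for (size_t k = 0; k < efrom.size(); ++k) degree[efrom[k]]++;
  };

  std::vector<double> ax(n), ay(n);
  for (int step = 1; step <= nsteps; ++step) {
    if ((step - 1) % refresh_every == 0) rebuild();
    // exact OU substep, draws in column-major order
    for (int c = 0; c < 2; ++c)
      for (int i = 0; i < n; ++i)
        eta(i, c) = eta(i, c) * ef + sf * R::norm_rand();
    // accelerations from old velocities
    for (int i = 0; i < n; ++i) {
      ax[i] = -alpha * vel(i, 0) + sigma[i] * eta(i, 0) + fext(i, 0);
      ay[i] = -alpha * vel(i, 1) + sigma[i] * eta(i, 1) + fext(i, 1);
    }
    for (size_t k = 0; k < efrom.size(); ++k) {
      int i = efrom[k], j = eto[k];
      double bw = align_mean ? beta / std::max(degree[i], 1) : beta;
      ax[i] += bw * (vel(j, 0) - vel(i, 0));
      ay[i] += bw * (vel(j, 1) - vel(i, 1));
      double dx = minimg(pos(j, 0) - pos(i, 0), Lx, px);
      double dy = minimg(pos(j, 1) - pos(i, 1), Ly, py);
      double d = std::sqrt(dx * dx + dy * dy);
      double f = fmag(d);
      if (f != 0.0 && d > 0.0) {
        ax[i] -= f * dx / d;
        ay[i] -= f * dy / d;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!leader[i]) {
        vel(i, 0) += dt * ax[i];
        vel(i, 1) += dt * ay[i];
        if (!R_finite(vel(i, 0)) || !R_finite(vel(i, 1)))
          stop("cpp_advance: non-finite velocity; dt too large");
      }
      pos(i, 0) += vel(i, 0) * dt;
      pos(i, 1) += vel(i, 1) * dt;
      if (px) { pos(i, 0) -= Lx * std::floor(pos(i, 0) / Lx); }
      if (py) { pos(i, 1) -= Ly * std::floor(pos(i, 1) / Ly); }
    }
  }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["eta"] = eta);
}
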