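// Langevin-dynamics core for the toy solvent-slab / monolayer system.
//
// Reduced units throughout (epsilon = sigma = m = kB = 1).  Pair
// interactions are Lennard-Jones 12-6, truncated and force-shifted at a
// per-pair cutoff so the logged virial is self-consistent with the forces
// (no impulsive truncation terms).  Integration is BAOAB Langevin
// splitting; with friction = 0 the O-step is the identity and the scheme
// reduces to velocity Verlet.  The RNG is a self-contained xoshiro256++
// so that runs are bitwise reproducible for a given seed, independent of
// R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s[4];
  bool have_cached;
  double cached;

  explicit RNG(uint64_t seed) : have_cached(false), cached(0.0) {
    // splitmix64 expansion of the user seed into the xoshiro state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (have_cached) {
      have_cached = false;
      return cached;
    }
    double u1;
    do {
      u1 = unif();
    } while (u1 <= 0.0);
    const double u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586476925287 * u2;
    cached = r * std::sin(a);
    have_cached = true;
    return r * std::cos(a);
  }
};

inline double wrap(double x, double L) {
  // into [-L/2, L/2)
  x -= L * std::floor(x / L + 0.5);
  return x;
}

struct PairTable {
  int ns;
  std::vector<double> c12, c6, rc, rc2, fshift, ushift;
  double rcmax;

  PairTable(const NumericMatrix& eps, const NumericMatrix& sig,
            const NumericMatrix& rcut) {
    ns = eps.nrow();
    c12.resize(ns * ns);
    c6.resize(ns * ns);
    rc.resize(ns * ns);
    rc2.resize(ns * ns);
    fshift.resize(ns * ns);
    ushift.resize(ns * ns);
    rcmax = 0.0;
    for (int a = 0; a < ns; ++a) {
      for (int b = 0; b < ns; ++b) {
        const int k = a * ns + b;
        const double e = eps(a, b), s = sig(a, b), r = rcut(a, b);
        c12[k] = 4.0 * e * std::pow(s, 12.0);
        c6[k] = 4.0 * e * std::pow(s, 6.0);
        rc[k] = r;
        rc2[k] = r * r;
        if (e > 0.0 && r > 0.0) {
          const double ir = 1.0 / r;
          const double ir6 = std::pow(ir, 6.0);
          // FLJ(rc) = 24 eps (2 (s/r)^12 - (s/r)^6) / r
          fshift[k] = (12.0 * c12[k] * ir6 * ir6 - 6.0 * c6[k] * ir6) * ir;
          ushift[k] = c12[k] * ir6 * ir6 - c6[k] * ir6;  // ULJ(rc)
          if (r > rcmax) rcmax = r;
        } else {
          fshift[k] = 0.0;
          ushift[k] = 0.0;
        }
      }
    }
    if (rcmax <= 0.0) rcmax = 1.0;  // ideal-gas case: any cell size works
  }
};

struct Sim {
  int n, ns;
  std::vector<double> x, y, z;    // positions, box-centred
  std::vector<double> vx, vy, vz;
  std::vector<double> fx, fy, fz;
  std::vector<int> sp;
  double Lx, Ly, Lz;
  PairTable pt;
  // bonds
  std::vector<int> b1, b2;
  double bond_k, bond_r0;
  // wall
  bool has_wall;
  double x_wall, wall_k;
  int wall_pow;
  std::vector<int> restrained;  // per species 0/1
  // accumulators from the last force evaluation
  double Wxx, Wyy, Wzz;   // virial
  double pot;             // potential energy
  bool want_pot;          // skip PE bookkeeping on non-sampled steps
  double wall_total;      // instantaneous sum of |F_wall| magnitudes
  std::vector<double> wall_by_species;
  // cell list scratch
  int ncx, ncy, ncz;
  std::vector<int> head, nxt;
  // Verlet neighbour list (pairs within rcmax + skin, rebuilt when any
  // particle has moved more than skin/2 since the last build)
  double skin;
  std::vector<int> nl_i, nl_j;
  std::vector<double> x0, y0, z0;  // positions at last rebuild

  Sim(const NumericMatrix& coords, const IntegerVector& species,
      const NumericVector& box, const NumericMatrix& eps,
      const NumericMatrix& sig, const NumericMatrix& rcut)
      : pt(eps, sig, rcut) {
    n = coords.nrow();
    ns = eps.nrow();
    x.resize(n); y.resize(n); z.resize(n);
    vx.assign(n, 0.0); vy.assign(n, 0.0); vz.assign(n, 0.0);
    fx.resize(n); fy.resize(n); fz.resize(n);
    sp.resize(n);
    Lx = box[0]; Ly = box[1]; Lz = box[2];
    for (int i = 0; i < n; ++i) {
      x[i] = wrap(coords(i, 0), Lx);
      y[i] = wrap(coords(i, 1), Ly);
      z[i] = wrap(coords(i, 2), Lz);
      sp[i] = species[i];
      if (sp[i] < 0 || sp[i] >= ns) stop("species index out of range");
    }
    wall_by_species.assign(ns, 0.0);
    skin = 0.4;
    const double rlist = pt.rcmax + skin;
    ncx = std::max(1, (int)std::floor(Lx / rlist));
    ncy = std::max(1, (int)std::floor(Ly / rlist));
    ncz = std::max(1, (int)std::floor(Lz / rlist));
    // the 13-offset half-stencil requires >= 3 cells per dimension;
    // otherwise collapse that dimension to a single cell (the stencil
    // then covers it exactly once via the self/neighbour dedup below)
    if (ncx < 3) ncx = 1;
    if (ncy < 3) ncy = 1;
    if (ncz < 3) ncz = 1;
    head.resize(ncx * ncy * ncz);
    nxt.resize(n);
  }

  inline int cell_of(int i) const {
    int ix = (int)std::floor((x[i] / Lx + 0.5) * ncx);
    int iy = (int)std::floor((y[i] / Ly + 0.5) * ncy);
    int iz = (int)std::floor((z[i] / Lz + 0.5) * ncz);
    if (ix < 0) ix = 0; if (ix >= ncx) ix = ncx - 1;
    if (iy < 0) iy = 0; if (iy >= ncy) iy = ncy - 1;
    if (iz < 0) iz = 0; if (iz >= ncz) iz = ncz - 1;
    return (iz * ncy + iy) * ncx + ix;
  }

  inline void pair_force(int i, int j) {
    // positions are kept wrapped in [-L/2, L/2), so |dx| < L and a
    // single conditional image shift is the full minimum image
    double dx = x[i] - x[j];
    double dy = y[i] - y[j];
    double dz = z[i] - z[j];
    if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx;
    if (dy > 0.5 * Ly) dy -= Ly; else if (dy < -0.5 * Ly) dy += Ly;
    if (dz > 0.5 * Lz) dz -= Lz; else if (dz < -0.5 * Lz) dz += Lz;
    const int k = sp[i] * ns + sp[j];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= pt.rc2[k] || pt.c12[k] == 0.0) return;
    const double r = std::sqrt(r2);
    const double ir = 1.0 / r;
    const double ir2 = ir * ir;
    const double ir6 = ir2 * ir2 * ir2;
    const double flj = (12.0 * pt.c12[k] * ir6 * ir6 - 6.0 * pt.c6[k] * ir6) * ir;
    const double fmag = flj - pt.fshift[k];       // force-shifted magnitude
    const double fr = fmag * ir;                  // F / r
    const double fxx = fr * dx, fyy = fr * dy, fzz = fr * dz;
    fx[i] += fxx; fy[i] += fyy; fz[i] += fzz;
    fx[j] -= fxx; fy[j] -= fyy; fz[j] -= fzz;
    Wxx += fxx * dx; Wyy += fyy * dy; Wzz += fzz * dz;
    if (want_pot)
      pot += pt.c12[k] * ir6 * ir6 - pt.c6[k] * ir6 - pt.ushift[k]
             + (r - pt.rc[k]) * pt.fshift[k];
  }

  inline void maybe_pair(int i, int j, double rl2) {
    double dx = x[i] - x[j];
    double dy = y[i] - y[j];
    double dz = z[i] - z[j];
    if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx;
    if (dy > 0.5 * Ly) dy -= Ly; else if (dy < -0.5 * Ly) dy += Ly;
    if (dz > 0.5 * Lz) dz -= Lz; else if (dz < -0.5 * Lz) dz += Lz;
    if (dx * dx + dy * dy + dz * dz < rl2) {
      nl_i.push_back(i);
      nl_j.push_back(j);
    }
  }

  bool need_rebuild() const {
    if (x0.empty()) return true;
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - x0[i];
      double dy = y[i] - y0[i];
      double dz = z[i] - z0[i];
      if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx;
      if (dy > 0.5 * Ly) dy -= Ly; else if (dy < -0.5 * Ly) dy += Ly;
      if (dz > 0.5 * Lz) dz -= Lz; else if (dz < -0.5 * Lz) dz += Lz;
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void rebuild_list() {
    nl_i.clear();
    nl_j.clear();
    const double rl = pt.rcmax + skin;
    const double rl2 = rl * rl;
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      const int c = cell_of(i);
      nxt[i] = head[c];
      head[c] = i;
    }
    static const int off[13][3] = {
        {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
        {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
        {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};
    for (int cz = 0; cz < ncz; ++cz) {
      for (int cy = 0; cy < ncy; ++cy) {
        for (int cx = 0; cx < ncx; ++cx) {
          const int c = (cz * ncy + cy) * ncx + cx;
          for (int i = head[c]; i != -1; i = nxt[i])
            for (int j = nxt[i]; j != -1; j = nxt[j]) maybe_pair(i, j, rl2);
          for (int o = 0; o < 13; ++o) {
            int ox = off[o][0], oy = off[o][1], oz = off[o][2];
            if (ncx == 1 && ox != 0) continue;
            if (ncy == 1 && oy != 0) continue;
            if (ncz == 1 && oz != 0) continue;
            if (ox == 0 && oy == 0 && oz == 0) continue;
            const int jx = (cx + ox + ncx) % ncx;
            const int jy = (cy + oy + ncy) % ncy;
            const int jz = (cz + oz + ncz) % ncz;
            const int c2 = (jz * ncy + jy) * ncx + jx;
            for (int i = head[c]; i != -1; i = nxt[i])
              for (int j = head[c2]; j != -1; j = nxt[j])
                maybe_pair(i, j, rl2);
          }
        }
      }
    }
    x0.assign(x.begin(), x.end());
    y0.assign(y.begin(), y.end());
    z0.assign(z.begin(), z.end());
  }

  void forces(bool compute_pot = true) {
    want_pot = compute_pot;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    Wxx = Wyy = Wzz = 0.0;
    pot = 0.0;
    wall_total = 0.0;
    std::fill(wall_by_species.begin(), wall_by_species.end(), 0.0);

    // --- non-bonded pairs via the Verlet list ---
    if (need_rebuild()) rebuild_list();
    const size_t np = nl_i.size();
    for (size_t p = 0; p < np; ++p) pair_force(nl_i[p], nl_j[p]);

    // --- harmonic bonds (not minimum-imaged across z: molecules are
    //     small compared to the box, but image anyway for safety) ---
    const int nb = (int)b1.size();
    for (int b = 0; b < nb; ++b) {
      const int i = b1[b], j = b2[b];
      double dx = x[i] - x[j];
      double dy = y[i] - y[j];
      double dz = z[i] - z[j];
      dx -= Lx * std::floor(dx / Lx + 0.5);
      dy -= Ly * std::floor(dy / Ly + 0.5);
      dz -= Lz * std::floor(dz / Lz + 0.5);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      const double fmag = -bond_k * (r - bond_r0);  // along +d for r < r0
      const double fr = fmag / r;
      const double fxx = fr * dx, fyy = fr * dy, fzz = fr * dz;
      fx[i] += fxx; fy[i] += fyy; fz[i] += fzz;
      fx[j] -= fxx; fy[j] -= fyy; fz[j] -= fzz;
      Wxx += fxx * dx; Wyy += fyy * dy; Wzz += fzz * dz;
      if (want_pot) pot += 0.5 * bond_k * (r - bond_r0) * (r - bond_r0);
    }

    // --- semipermeable virtual walls at x = +-x_wall ---
    if (has_wall) {
      for (int i = 0; i < n; ++i) {
        if (!restrained[sp[i]]) continue;
        const double ax = std::fabs(x[i]);
        if (ax <= x_wall) continue;
        const double d = ax - x_wall;
        const double fmagn = (wall_pow == 2) ? wall_k * d * d : wall_k * d;
        const double fxx = (x[i] > 0.0) ? -fmagn : fmagn;  // push inward
        fx[i] += fxx;
        Wxx += fxx * x[i];
        wall_total += fmagn;
        wall_by_species[sp[i]] += fmagn;
        if (want_pot)
          pot += (wall_pow == 2) ? wall_k * d * d * d / 3.0
                                 : 0.5 * wall_k * d * d;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(NumericMatrix coords, IntegerVector species, NumericVector box,
                 Nullable<NumericMatrix> velocities, NumericMatrix eps,
                 NumericMatrix sigma, NumericMatrix rcut, IntegerMatrix bonds,
                 double bond_k, double bond_r0, bool has_wall, double x_wall,
                 double wall_k, int wall_pow, LogicalVector restrained,
                 double temperature, double friction, double dt, int n_steps,
                 int sample_every, double t0, double seed, int relax_steps) {
  Sim sim(coords, species, box, eps, sigma, rcut);
  sim.bond_k = bond_k;
  sim.bond_r0 = bond_r0;
  sim.has_wall = has_wall;
  sim.x_wall = x_wall;
  sim.wall_k = wall_k;
  sim.wall_pow = wall_pow;
  sim.restrained.resize(sim.ns);
  for (int a = 0; a < sim.ns; ++a)
    sim.restrained[a] = (a < restrained.size() && restrained[a]) ? 1 : 0;
  const int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    sim.b1.push_back(bonds(b, 0) - 1);  // 1-based from R
    sim.b2.push_back(bonds(b, 1) - 1);
  }

  RNG rng((uint64_t)seed);
  const int n = sim.n;

  if (velocities.isNotNull()) {
    NumericMatrix v(velocities);
    for (int i = 0; i < n; ++i) {
      sim.vx[i] = v(i, 0);
      sim.vy[i] = v(i, 1);
      sim.vz[i] = v(i, 2);
    }
  } else {
    // Maxwell-Boltzmann draw at the target temperature, zero net momentum
    const double sd = std::sqrt(temperature);
    double mx = 0, my = 0, mz = 0;
    for (int i = 0; i < n; ++i) {
      sim.vx[i] = sd * rng.norm();
      sim.vy[i] = sd * rng.norm();
      sim.vz[i] = sd * rng.norm();
      mx += sim.vx[i]; my += sim.vy[i]; mz += sim.vz[i];
    }
    for (int i = 0; i < n; ++i) {
      sim.vx[i] -= mx / n;
      sim.vy[i] -= my / n;
      sim.vz[i] -= mz / n;
    }
  }

  // displacement-capped steepest-descent relaxation: defuses overlaps in
  // freshly packed configurations without affecting equilibrated states
  if (relax_steps > 0) {
    const double cap = 0.05;
    for (int it = 0; it < relax_steps; ++it) {
      sim.forces(false);
      for (int i = 0; i < n; ++i) {
        double fmag = std::sqrt(sim.fx[i] * sim.fx[i] +
                                sim.fy[i] * sim.fy[i] +
                                sim.fz[i] * sim.fz[i]);
        if (fmag < 1e-12) continue;
        const double sc = std::min(cap, 0.005 * fmag) / fmag;
        sim.x[i] = wrap(sim.x[i] + sc * sim.fx[i], sim.Lx);
        sim.y[i] = wrap(sim.y[i] + sc * sim.fy[i], sim.Ly);
        sim.z[i] = wrap(sim.z[i] + sc * sim.fz[i], sim.Lz);
      }
    }
  }

  const double c1 = (friction > 0.0) ? std::exp(-friction * dt) : 1.0;
  const double c2 =
      (friction > 0.0) ? std::sqrt((1.0 - c1 * c1) * temperature) : 0.0;
  const double half = 0.5 * dt;
  const double V = sim.Lx * sim.Ly * sim.Lz;
  const double bound = 10.0 * std::max(sim.Lx, std::max(sim.Ly, sim.Lz));

  const int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector times(n_samples), pxx(n_samples), pyy(n_samples),
      pzz(n_samples), wtot(n_samples), temp_s(n_samples), pot_s(n_samples);
  NumericMatrix wsp(n_samples, sim.ns);
  NumericVector traj(Dimension(n, 3, std::max(n_samples, 1)));

  sim.forces();
  int isamp = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      sim.vx[i] += half * sim.fx[i];
      sim.vy[i] += half * sim.fy[i];
      sim.vz[i] += half * sim.fz[i];
    }
    // A
    for (int i = 0; i < n; ++i) {
      sim.x[i] += half * sim.vx[i];
      sim.y[i] += half * sim.vy[i];
      sim.z[i] += half * sim.vz[i];
    }
    // O
    if (friction > 0.0) {
      for (int i = 0; i < n; ++i) {
        sim.vx[i] = c1 * sim.vx[i] + c2 * rng.norm();
        sim.vy[i] = c1 * sim.vy[i] + c2 * rng.norm();
        sim.vz[i] = c1 * sim.vz[i] + c2 * rng.norm();
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      sim.x[i] += half * sim.vx[i];
      sim.y[i] += half * sim.vy[i];
      sim.z[i] += half * sim.vz[i];
      sim.x[i] = wrap(sim.x[i], sim.Lx);
      sim.y[i] = wrap(sim.y[i], sim.Ly);
      sim.z[i] = wrap(sim.z[i], sim.Lz);
    }
    sim.forces(sample_every > 0 && step % sample_every == 0);
    // B
    for (int i = 0; i < n; ++i) {
      sim.vx[i] += half * sim.fx[i];
      sim.vy[i] += half * sim.fy[i];
      sim.vz[i] += half * sim.fz[i];
    }

    if (sample_every > 0 && step % sample_every == 0) {
      double Kxx = 0, Kyy = 0, Kzz = 0;
      for (int i = 0; i < n; ++i) {
        Kxx += sim.vx[i] * sim.vx[i];
        Kyy += sim.vy[i] * sim.vy[i];
        Kzz += sim.vz[i] * sim.vz[i];
        // positions are kept wrapped, so runaway dynamics shows up as
        // non-finite coordinates or step displacements beyond the box
        if (!std::isfinite(sim.x[i]) || std::fabs(sim.x[i]) > bound ||
            !std::isfinite(sim.z[i]) || std::fabs(sim.z[i]) > bound ||
            !std::isfinite(sim.vx[i] + sim.vy[i] + sim.vz[i]) ||
            std::fabs(sim.vx[i]) * dt > bound ||
            std::fabs(sim.vz[i]) * dt > bound)
          stop("integration diverged at step %d (particle %d)", step, i + 1);
      }
      times[isamp] = t0 + step * dt;
      pxx[isamp] = (Kxx + sim.Wxx) / V;
      pyy[isamp] = (Kyy + sim.Wyy) / V;
      pzz[isamp] = (Kzz + sim.Wzz) / V;
      wtot[isamp] = sim.wall_total;
      for (int a = 0; a < sim.ns; ++a) wsp(isamp, a) = sim.wall_by_species[a];
      temp_s[isamp] = (Kxx + Kyy + Kzz) / (3.0 * n);
      pot_s[isamp] = sim.pot;
      for (int i = 0; i < n; ++i) {
        traj[(size_t)isamp * 3 * n + 0 * n + i] = sim.x[i];
        traj[(size_t)isamp * 3 * n + 1 * n + i] = sim.y[i];
        traj[(size_t)isamp * 3 * n + 2 * n + i] = sim.z[i];
      }
      ++isamp;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xyz_final(n, 3), vel_final(n, 3);
  for (int i = 0; i < n; ++i) {
    xyz_final(i, 0) = sim.x[i];
    xyz_final(i, 1) = sim.y[i];
    xyz_final(i, 2) = sim.z[i];
    vel_final(i, 0) = sim.vx[i];
    vel_final(i, 1) = sim.vy[i];
    vel_final(i, 2) = sim.vz[i];
  }

  return List::create(
      _["times"] = times, _["traj"] = traj, _["pxx"] = pxx, _["pyy"] = pyy,
      _["pzz"] = pzz, _["wall_total"] = wtot, _["wall_by_species"] = wsp,
      _["temperature"] = temp_s, _["potential"] = pot_s,
      _["coords_final"] = xyz_final, _["velocities_final"] = vel_final);
}
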