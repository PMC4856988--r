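// Langevin-dynamics engine for the bead-spring chromatin + binder model.
//
// Reduced units: sigma (diameter of a chromatin bead) = 1, kBT = 1,
// friction gamma = 1 for a diameter-1 particle (so D = 1 and the time unit
// is the Brownian time sigma^2/D).  Integration is the BAOAB splitting of
// underdamped Langevin dynamics with unit mass; gamma scales with particle
// diameter (Stokes).  Positions are integrated unwrapped; the periodic box
// enters through minimum-image non-bonded forces.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>
#include <sstream>
#include <map>
#include <functional>
#include <algorithm>

using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding; fast uniform doubles for the
// thermostat noise.  Gaussians via Marsaglia polar with a cached spare.
struct FastRng {
  std::uint64_t s[4];
  bool have_spare = false;
  double spare = 0;

  explicit FastRng(std::uint64_t seed) {
    std::uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      std::uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (-1, 1)
    return (double)(std::int64_t)next() * (1.0 / 9223372036854775808.0);
  }
  inline double gauss() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, q;
    do {
      u = unif();
      v = unif();
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

struct CellGrid {
  int nc;            // cells per edge
  double box, cell;
  std::vector<int> head;   // nc^3, -1 = empty
  std::vector<int> nxt;    // per particle
  std::vector<int> dirty;  // cells touched since last reset
  std::vector<int> pcx, pcy, pcz;  // per-particle cell coordinates
  std::vector<int> wtab;   // wrap table for coord +/- 1

  // cell >= cutoff whenever nc > 3; at nc == 3 the 27-cell scan covers the
  // whole box, so no pair is missed either way.  nc capped to bound memory.
  void init(double box_, double cutoff, int n) {
    box = box_;
    nc = std::min(64, std::max(3, (int)std::floor(box / cutoff)));
    cell = box / nc;
    head.assign((size_t)nc * nc * nc, -1);
    nxt.assign(n, -1);
    dirty.clear();
    dirty.reserve(n);
    pcx.assign(n, 0);
    pcy.assign(n, 0);
    pcz.assign(n, 0);
    wtab.resize(nc + 2);
    for (int i = 0; i < nc + 2; ++i) wtab[i] = (i - 1 + nc) % nc;
  }
  inline int wrap_idx(double x) const {
    double w = x - box * std::floor(x / box);
    int c = (int)(w / cell);
    if (c >= nc) c = nc - 1;
    if (c < 0) c = 0;
    return c;
  }
  inline int cell_of(const double* p) const {
    return (wrap_idx(p[0]) * nc + wrap_idx(p[1])) * nc + wrap_idx(p[2]);
  }
  void build(const std::vector<double>& pos, int n) {
    for (int c : dirty) head[c] = -1;
    dirty.clear();
    for (int i = 0; i < n; ++i) {
      int cx = wrap_idx(pos[3 * i]);
      int cy = wrap_idx(pos[3 * i + 1]);
      int cz = wrap_idx(pos[3 * i + 2]);
      pcx[i] = cx;
      pcy[i] = cy;
      pcz[i] = cz;
      int c = (cx * nc + cy) * nc + cz;
      if (head[c] == -1) dirty.push_back(c);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  inline int shifted(int c, int dx, int dy, int dz) const {
    int cx = c / (nc * nc), cy = (c / nc) % nc, cz = c % nc;
    cx = (cx + dx + nc) % nc;
    cy = (cy + dy + nc) % nc;
    cz = (cz + dz + nc) % nc;
    return (cx * nc + cy) * nc + cz;
  }
  // neighbor cell of particle i without divisions
  inline int neighbor_of(int i, int dx, int dy, int dz) const {
    return (wtab[pcx[i] + dx + 1] * nc + wtab[pcy[i] + dy + 1]) * nc +
           wtab[pcz[i] + dz + 1];
  }
};

struct Sim {
  int n = 0, n_species = 0, n_colors = 0;
  double box = 0;
  std::vector<double> pos, posw, vel, frc, diam, gamma_;
  std::vector<int> species;     // 0 = chromatin bead, 1..S = factor species
  std::vector<int> colorbits;   // bead color bitmask over palette
  std::vector<int> bonds;       // 2*m
  std::vector<int> angles;      // 3*a
  std::vector<double> angle_kb;
  std::vector<double> eps;      // S x C, row-major: eps[s*C + c]
  std::vector<char> active;     // per species
  std::vector<char> monovalent; // per species
  std::vector<int> partner;     // per particle; -1 none (monovalent cap)
  double fene_k = 30, fene_r0 = 1.6, rc_mult = 1.8, eps_steric = 1, kT = 1;
  double max_cut = 0;
  CellGrid grid;
  bool has_attraction = false, any_monovalent = false;
  // Verlet pair list with skin; rebuilt when any particle has moved by
  // skin/2 since the last build, so no pair inside max_cut is ever missed
  double skin = 0.4;
  std::vector<int> vi, vj;
  std::vector<double> ref;
  bool list_valid = false;
  // phantom mode: only bonded pairs interact sterically (stiffness
  // validation against the ideal discrete worm-like chain)
  bool phantom = false;
  std::vector<std::uint64_t> bonded_keys;  // sorted i*n+j keys, i<j

  inline void minimg(double& dx, double& dy, double& dz) const {
    dx -= box * std::nearbyint(dx / box);
    dy -= box * std::nearbyint(dy / box);
    dz -= box * std::nearbyint(dz / box);
  }

  // strongest affinity of species s (1-based) for a bead color mask
  inline double affinity(int s, int mask) const {
    if (!active[s]) return 0.0;
    const double* row = &eps[(size_t)(s - 1) * n_colors];
    double best = 0.0;
    while (mask) {
      int c = __builtin_ctz(mask);
      if (row[c] > best) best = row[c];
      mask &= mask - 1;
    }
    return best;
  }

  // cognate attraction strength for particle pair, 0 if steric-only
  inline double pair_eps(int i, int j) const {
    int si = species[i], sj = species[j];
    if (si == 0 && sj > 0) return affinity(sj, colorbits[i]);
    if (sj == 0 && si > 0) return affinity(si, colorbits[j]);
    return 0.0;
  }

  // LJ force/energy pieces (sig = contact diameter)
  static inline void lj(double r2, double sig, double e, double rc,
                        double& fmag_over_r, double& u) {
    // truncated-shifted LJ; fmag_over_r = -(dU/dr)/r
    double s2 = sig * sig / r2;
    double s6 = s2 * s2 * s2;
    double s12 = s6 * s6;
    double src6 = std::pow(sig / rc, 6);
    double shift = 4.0 * e * (src6 * src6 - src6);
    u = 4.0 * e * (s12 - s6) - shift;
    fmag_over_r = 24.0 * e * (2.0 * s12 - s6) / r2;
  }
  static inline void wca(double r2, double sig, double e,
                         double& fmag_over_r, double& u) {
    double s2 = sig * sig / r2;
    double s6 = s2 * s2 * s2;
    double s12 = s6 * s6;
    u = 4.0 * e * (s12 - s6) + e;
    fmag_over_r = 24.0 * e * (2.0 * s12 - s6) / r2;
  }

  // monovalent species: partner = nearest cognate bead within range, else -1
  void update_partners() {
    std::vector<double> bestr2(n, 1e300);
    std::fill(partner.begin(), partner.end(), -1);
    const double hbox = 0.5 * box;
    for (size_t k = 0; k < vi.size(); ++k) {
      int a = vi[k], b = vj[k];
      int f, bead;
      if (species[a] > 0 && species[b] == 0) { f = a; bead = b; }
      else if (species[b] > 0 && species[a] == 0) { f = b; bead = a; }
      else continue;
      int s = species[f];
      if (!monovalent[s] || !active[s]) continue;
      if (affinity(s, colorbits[bead]) <= 0) continue;
      double ddx = posw[3 * f] - posw[3 * bead];
      double ddy = posw[3 * f + 1] - posw[3 * bead + 1];
      double ddz = posw[3 * f + 2] - posw[3 * bead + 2];
      if (ddx > hbox) ddx -= box; else if (ddx < -hbox) ddx += box;
      if (ddy > hbox) ddy -= box; else if (ddy < -hbox) ddy += box;
      if (ddz > hbox) ddz -= box; else if (ddz < -hbox) ddz += box;
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      double sig = 0.5 * (diam[f] + diam[bead]);
      double rc = rc_mult * sig;
      if (r2 < rc * rc && r2 < bestr2[f]) { bestr2[f] = r2; partner[f] = bead; }
    }
  }

  void build_list() {
    for (int i = 0; i < 3 * n; ++i)
      posw[i] = pos[i] - box * std::floor(pos[i] / box);
    grid.build(posw, n);
    vi.clear();
    vj.clear();
    const double hbox = 0.5 * box;
    const double rl = max_cut + skin, rl2 = rl * rl;
    for (int i = 0; i < n; ++i) {
      const double xi = posw[3 * i], yi = posw[3 * i + 1],
                   zi = posw[3 * i + 2];
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int c = grid.neighbor_of(i, dx, dy, dz);
            for (int j = grid.head[c]; j != -1; j = grid.nxt[j]) {
              if (j <= i) continue;
              double ddx = xi - posw[3 * j];
              double ddy = yi - posw[3 * j + 1];
              double ddz = zi - posw[3 * j + 2];
              if (ddx > hbox) ddx -= box; else if (ddx < -hbox) ddx += box;
              if (ddy > hbox) ddy -= box; else if (ddy < -hbox) ddy += box;
              if (ddz > hbox) ddz -= box; else if (ddz < -hbox) ddz += box;
              if (ddx * ddx + ddy * ddy + ddz * ddz < rl2) {
                vi.push_back(i);
                vj.push_back(j);
              }
            }
          }
    }
    ref = pos;
    list_valid = true;
  }

  bool need_rebuild() const {
    if (!list_valid) return true;
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = pos[3 * i] - ref[3 * i];
      double dy = pos[3 * i + 1] - ref[3 * i + 1];
      double dz = pos[3 * i + 2] - ref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  // full force + potential-energy evaluation
  double forces(long step) {
    std::fill(frc.begin(), frc.end(), 0.0);
    double U = 0.0;
    if (need_rebuild()) build_list();
    // wrapped copy: all pair separations then need at most one box shift
    for (int i = 0; i < 3 * n; ++i)
      posw[i] = pos[i] - box * std::floor(pos[i] / box);
    if (any_monovalent) update_partners();

    const double hbox = 0.5 * box;
    const double irc6 = std::pow(1.0 / rc_mult, 6);   // (sig/rc)^6, rc-shift
    const double shift_per_eps = 4.0 * (irc6 * irc6 - irc6);
    const double wca2_unit = std::pow(2.0, 1.0 / 3.0);  // (2^(1/6))^2
    const size_t npair = vi.size();
    for (size_t k = 0; k < npair; ++k) {
      const int i = vi[k], j = vj[k];
      double ddx = posw[3 * i] - posw[3 * j];
      double ddy = posw[3 * i + 1] - posw[3 * j + 1];
      double ddz = posw[3 * i + 2] - posw[3 * j + 2];
      if (ddx > hbox) ddx -= box; else if (ddx < -hbox) ddx += box;
      if (ddy > hbox) ddy -= box; else if (ddy < -hbox) ddy += box;
      if (ddz > hbox) ddz -= box; else if (ddz < -hbox) ddz += box;
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      double sig = 0.5 * (diam[i] + diam[j]);
      double sig2 = sig * sig;
      double rc2 = rc_mult * rc_mult * sig2;
      if (r2 >= rc2) continue;
      if (phantom) {
        std::uint64_t key = (std::uint64_t)i * (std::uint64_t)n + j;
        if (!std::binary_search(bonded_keys.begin(), bonded_keys.end(), key))
          continue;
      }
      double e = pair_eps(i, j);
      if (e > 0 && any_monovalent) {
        // monovalent cap: attraction only toward chosen partner
        int f = species[i] > 0 ? i : j;  // the factor of the pair
        int b = species[i] > 0 ? j : i;
        if (monovalent[species[f]] && partner[f] != b) e = 0;
      }
      double fr, u;
      double s2 = sig2 / r2;
      double s6 = s2 * s2 * s2;
      double s12 = s6 * s6;
      if (e > 0) {
        u = 4.0 * e * (s12 - s6) - e * shift_per_eps;
        fr = 24.0 * e * (2.0 * s12 - s6) / r2;
      } else {
        if (r2 >= wca2_unit * sig2) continue;
        u = 4.0 * eps_steric * (s12 - s6) + eps_steric;
        fr = 24.0 * eps_steric * (2.0 * s12 - s6) / r2;
      }
      U += u;
      frc[3 * i] += fr * ddx;
      frc[3 * i + 1] += fr * ddy;
      frc[3 * i + 2] += fr * ddz;
      frc[3 * j] -= fr * ddx;
      frc[3 * j + 1] -= fr * ddy;
      frc[3 * j + 2] -= fr * ddz;
    }

    // FENE bonds (unwrapped coordinates: bonded beads stay close)
    const double r02 = fene_r0 * fene_r0;
    for (size_t b = 0; b < bonds.size() / 2; ++b) {
      int i = bonds[2 * b], j = bonds[2 * b + 1];
      double ddx = pos[3 * i] - pos[3 * j];
      double ddy = pos[3 * i + 1] - pos[3 * j + 1];
      double ddz = pos[3 * i + 2] - pos[3 * j + 2];
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (r2 >= r02) {
        std::ostringstream msg;
        msg << "exploded bond " << b + 1 << " (beads " << i + 1 << "-"
            << j + 1 << "): length " << std::sqrt(r2)
            << " sigma >= max extension " << fene_r0 << " at step " << step;
        throw std::runtime_error(msg.str());
      }
      double rr = r2 / r02;
      U += -0.5 * fene_k * r02 * std::log(1.0 - rr);
      double fr = -fene_k / (1.0 - rr);  // (dU/dr)/r with sign for f = fr*dr
      frc[3 * i] += fr * ddx;
      frc[3 * i + 1] += fr * ddy;
      frc[3 * i + 2] += fr * ddz;
      frc[3 * j] -= fr * ddx;
      frc[3 * j + 1] -= fr * ddy;
      frc[3 * j + 2] -= fr * ddz;
    }

    // Kratky-Porod bending: U = kb (1 - cos theta), theta between bonds
    for (size_t a = 0; a < angles.size() / 3; ++a) {
      int ia = angles[3 * a], ib = angles[3 * a + 1], ic = angles[3 * a + 2];
      double kb = angle_kb[a];
      // u = b - a, v = c - b
      double ux = pos[3 * ib] - pos[3 * ia];
      double uy = pos[3 * ib + 1] - pos[3 * ia + 1];
      double uz = pos[3 * ib + 2] - pos[3 * ia + 2];
      double vx = pos[3 * ic] - pos[3 * ib];
      double vy = pos[3 * ic + 1] - pos[3 * ib + 1];
      double vz = pos[3 * ic + 2] - pos[3 * ib + 2];
      double cu = std::sqrt(ux * ux + uy * uy + uz * uz);
      double cv = std::sqrt(vx * vx + vy * vy + vz * vz);
      double dot = ux * vx + uy * vy + uz * vz;
      double cth = dot / (cu * cv);
      if (cth > 1) cth = 1;
      if (cth < -1) cth = -1;
      U += kb * (1.0 - cth);
      // dc/du and dc/dv ; F = kb * dc/dx
      double icucv = 1.0 / (cu * cv);
      double gux = vx * icucv - cth * ux / (cu * cu);
      double guy = vy * icucv - cth * uy / (cu * cu);
      double guz = vz * icucv - cth * uz / (cu * cu);
      double gvx = ux * icucv - cth * vx / (cv * cv);
      double gvy = uy * icucv - cth * vy / (cv * cv);
      double gvz = uz * icucv - cth * vz / (cv * cv);
      // F = -dU/dx = kb * dcth/dx with dcth/da = -gu, dcth/db = gu - gv,
      // dcth/dc = gv (from du/da = -I, du/db = I, dv/db = -I, dv/dc = I)
      frc[3 * ia + 0] += -kb * gux;
      frc[3 * ia + 1] += -kb * guy;
      frc[3 * ia + 2] += -kb * guz;
      frc[3 * ib + 0] += kb * (gux - gvx);
      frc[3 * ib + 1] += kb * (guy - gvy);
      frc[3 * ib + 2] += kb * (guz - gvz);
      frc[3 * ic + 0] += kb * gvx;
      frc[3 * ic + 1] += kb * gvy;
      frc[3 * ic + 2] += kb * gvz;
    }
    return U;
  }
};

Sim make_sim(List cfg) {
  Sim s;
  NumericMatrix pos = cfg["pos"];
  s.n = pos.nrow();
  s.box = as<double>(cfg["box"]);
  s.pos.resize(3 * s.n);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) s.pos[3 * i + k] = pos(i, k);
  s.posw.assign(3 * s.n, 0.0);
  s.vel.assign(3 * s.n, 0.0);
  if (cfg.containsElementNamed("vel") && !Rf_isNull(cfg["vel"])) {
    NumericMatrix vel = cfg["vel"];
    for (int i = 0; i < s.n; ++i)
      for (int k = 0; k < 3; ++k) s.vel[3 * i + k] = vel(i, k);
  }
  s.frc.assign(3 * s.n, 0.0);
  s.diam = as<std::vector<double>>(cfg["diam"]);
  s.gamma_.resize(s.n);
  for (int i = 0; i < s.n; ++i) s.gamma_[i] = s.diam[i];  // Stokes
  s.species = as<std::vector<int>>(cfg["species"]);
  s.colorbits = as<std::vector<int>>(cfg["colorbits"]);
  IntegerMatrix bonds = cfg["bonds"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    s.bonds.push_back(bonds(b, 0));
    s.bonds.push_back(bonds(b, 1));
  }
  IntegerMatrix angles = cfg["angles"];
  for (int a = 0; a < angles.nrow(); ++a) {
    s.angles.push_back(angles(a, 0));
    s.angles.push_back(angles(a, 1));
    s.angles.push_back(angles(a, 2));
  }
  s.angle_kb = as<std::vector<double>>(cfg["angle_kb"]);
  NumericMatrix eps = cfg["eps"];
  s.n_species = eps.nrow();
  s.n_colors = eps.ncol();
  s.eps.resize((size_t)s.n_species * s.n_colors);
  for (int i = 0; i < s.n_species; ++i)
    for (int j = 0; j < s.n_colors; ++j)
      s.eps[(size_t)i * s.n_colors + j] = eps(i, j);
  s.active.assign(s.n_species + 1, 1);
  if (cfg.containsElementNamed("activation_step")) {
    IntegerVector act = cfg["activation_step"];
    for (int i = 0; i < s.n_species && i < act.size(); ++i)
      s.active[i + 1] = (act[i] <= 0);
  }
  s.monovalent.assign(s.n_species + 1, 0);
  LogicalVector mono = cfg["monovalent"];
  for (int i = 0; i < s.n_species; ++i) s.monovalent[i + 1] = mono[i];
  s.any_monovalent = false;
  for (int i = 1; i <= s.n_species; ++i)
    if (s.monovalent[i]) s.any_monovalent = true;
  s.partner.assign(s.n, -1);
  s.fene_k = as<double>(cfg["fene_k"]);
  s.fene_r0 = as<double>(cfg["fene_r0"]);
  s.rc_mult = as<double>(cfg["rc_mult"]);
  s.eps_steric = as<double>(cfg["eps_steric"]);
  s.kT = as<double>(cfg["kT"]);
  if (cfg.containsElementNamed("phantom"))
    s.phantom = as<bool>(cfg["phantom"]);
  if (s.phantom) {
    for (size_t b = 0; b < s.bonds.size() / 2; ++b) {
      int i = s.bonds[2 * b], j = s.bonds[2 * b + 1];
      if (i > j) std::swap(i, j);
      s.bonded_keys.push_back((std::uint64_t)i * (std::uint64_t)s.n + j);
    }
    std::sort(s.bonded_keys.begin(), s.bonded_keys.end());
  }
  double max_d = 0;
  for (double d : s.diam) max_d = std::max(max_d, d);
  s.max_cut = s.rc_mult * max_d;
  if (s.box < 3.0 * s.max_cut)
    stop("box edge (%f sigma) must be at least 3x the interaction cutoff (%f sigma)",
         s.box, s.max_cut);
  s.grid.init(s.box, s.max_cut, s.n);
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(List cfg) {
  Sim s = make_sim(cfg);
  const double dt = as<double>(cfg["dt"]);
  const long n_steps = (long)as<double>(cfg["n_steps"]);
  const long sample_every = (long)as<double>(cfg["sample_every_steps"]);
  const std::uint64_t seed = (std::uint64_t)as<double>(cfg["seed"]);
  IntegerVector act = cfg["activation_step"];  // per species
  IntegerVector sch_step = cfg["sched_step"];
  IntegerVector sch_sp = cfg["sched_species"];
  IntegerVector sch_col = cfg["sched_color"];
  NumericVector sch_eps = cfg["sched_eps"];

  FastRng rng(seed);

  // velocities: Maxwell-Boltzmann unless supplied
  bool have_vel = cfg.containsElementNamed("vel") && !Rf_isNull(cfg["vel"]);
  if (!have_vel && s.kT > 0) {
    for (int i = 0; i < 3 * s.n; ++i) s.vel[i] = std::sqrt(s.kT) * rng.gauss();
  }

  // OU coefficients per particle (m = 1)
  std::vector<double> c1(s.n), c2(s.n);
  for (int i = 0; i < s.n; ++i) {
    c1[i] = std::exp(-s.gamma_[i] * dt);
    c2[i] = std::sqrt(s.kT * (1.0 - c1[i] * c1[i]));
  }

  long n_snap = n_steps / sample_every + 1;
  NumericVector traj((R_xlen_t)3 * s.n * n_snap);
  NumericVector times(n_snap);
  long isnap = 0;
  auto snapshot = [&](long step) {
    for (int i = 0; i < 3 * s.n; ++i)
      traj[(R_xlen_t)isnap * 3 * s.n + i] = s.pos[i];
    times[isnap] = step * dt;
    ++isnap;
  };

  // species activation at step 0
  for (int sp = 1; sp <= s.n_species; ++sp) s.active[sp] = (act[sp - 1] <= 0);
  s.forces(0);
  snapshot(0);

  long next_sched = 0;
  const double half = 0.5 * dt;
  for (long step = 1; step <= n_steps; ++step) {
    // activation & scheduled affinity changes take effect at this step
    for (int sp = 1; sp <= s.n_species; ++sp)
      if (!s.active[sp] && act[sp - 1] <= step) s.active[sp] = 1;
    while (next_sched < sch_step.size() && sch_step[next_sched] <= step) {
      int sp = sch_sp[next_sched] - 1, col = sch_col[next_sched];
      s.eps[(size_t)sp * s.n_colors + col] = sch_eps[next_sched];
      ++next_sched;
    }
    // BAOAB
    for (int i = 0; i < 3 * s.n; ++i) s.vel[i] += half * s.frc[i];
    for (int i = 0; i < 3 * s.n; ++i) s.pos[i] += half * s.vel[i];
    for (int i = 0; i < s.n; ++i) {
      s.vel[3 * i] = c1[i] * s.vel[3 * i] + c2[i] * rng.gauss();
      s.vel[3 * i + 1] = c1[i] * s.vel[3 * i + 1] + c2[i] * rng.gauss();
      s.vel[3 * i + 2] = c1[i] * s.vel[3 * i + 2] + c2[i] * rng.gauss();
    }
    for (int i = 0; i < 3 * s.n; ++i) s.pos[i] += half * s.vel[i];
    s.forces(step);
    for (int i = 0; i < 3 * s.n; ++i) s.vel[i] += half * s.frc[i];

    if (step % sample_every == 0) {
      if (!std::isfinite(s.pos[0]))
        stop("non-finite coordinates at step %ld", step);
      snapshot(step);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix fpos(s.n, 3), fvel(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) {
      fpos(i, k) = s.pos[3 * i + k];
      fvel(i, k) = s.vel[3 * i + k];
    }
  traj.attr("dim") = IntegerVector::create(3 * s.n, n_snap);
  return List::create(_["times"] = times, _["traj"] = traj,
                      _["pos"] = fpos, _["vel"] = fvel);
}

// [[Rcpp::export]]
List cpp_forces(List cfg) {
  Sim s = make_sim(cfg);
  double U = s.forces(0);
  NumericMatrix f(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) f(i, k) = s.frc[3 * i + k];
  return List::create(_["forces"] = f, _["energy"] = U);
}

// Deterministic relaxation: displacement-capped steepest descent.
// Used to remove residual overlaps after initial placement and for
// zero-temperature relaxation checks.
// [[Rcpp::export]]
List cpp_relax(List cfg, int n_steps, double step_size, double max_move) {
  Sim s = make_sim(cfg);
  double U = 0;
  for (int it = 0; it < n_steps; ++it) {
    U = s.forces(it);
    for (int i = 0; i < s.n; ++i) {
      for (int k = 0; k < 3; ++k) {
        double d = step_size * s.frc[3 * i + k];
        if (d > max_move) d = max_move;
        if (d < -max_move) d = -max_move;
        s.pos[3 * i + k] += d;
      }
    }
  }
  U = s.forces(n_steps);
  NumericMatrix p(s.n, 3), f(s.n, 3);
  for (int i = 0; i < s.n; ++i)
    for (int k = 0; k < 3; ++k) {
      p(i, k) = s.pos[3 * i + k];
      f(i, k) = s.frc[3 * i + k];
    }
  return List::create(_["pos"] = p, _["forces"] = f, _["energy"] = U);
}

// All pairs with minimum-image distance <= cutoff (strict optionally).
// Returns 1-based index pairs ordered (i < j, lexicographic).
// [[Rcpp::export]]
List cpp_pairs(NumericMatrix pos, double box, double cutoff, bool strict) {
  int n = pos.nrow();
  if (cutoff > box / 2)
    stop("cutoff (%f) exceeds half the box edge (%f)", cutoff, box / 2);
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  CellGrid grid;
  grid.init(box, cutoff, n);
  grid.build(p, n);
  std::vector<int> ii, jj;
  std::vector<double> dd;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    int c0 = grid.cell_of(&p[3 * i]);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int c = grid.shifted(c0, dx, dy, dz);
          for (int j = grid.head[c]; j != -1; j = grid.nxt[j]) {
            if (j <= i) continue;
            double ddx = p[3 * i] - p[3 * j];
            double ddy = p[3 * i + 1] - p[3 * j + 1];
            double ddz = p[3 * i + 2] - p[3 * j + 2];
            ddx -= box * std::nearbyint(ddx / box);
            ddy -= box * std::nearbyint(ddy / box);
            ddz -= box * std::nearbyint(ddz / box);
            double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
            bool in = strict ? (r2 < c2) : (r2 <= c2);
            if (in) {
              ii.push_back(i + 1);
              jj.push_back(j + 1);
              dd.push_back(std::sqrt(r2));
            }
          }
        }
  }
  // deterministic ordering
  std::vector<size_t> ord(ii.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return ii[a] != ii[b] ? ii[a] < ii[b] : jj[a] < jj[b];
  });
  IntegerMatrix out(ii.size(), 2);
  NumericVector dist(ii.size());
  for (size_t k = 0; k < ord.size(); ++k) {
    out(k, 0) = ii[ord[k]];
    out(k, 1) = jj[ord[k]];
    dist[k] = dd[ord[k]];
  }
  return List::create(_["pairs"] = out, _["dist"] = dist);
}

// Union-find connected components from a pair list (1-based), n nodes.
// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerMatrix pairs) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  for (int k = 0; k < pairs.nrow(); ++k) {
    int a = find(pairs(k, 0) - 1), b = find(pairs(k, 1) - 1);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
  IntegerVector comp(n);
  std::map<int, int> relabel;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) {
      int id = (int)relabel.size() + 1;
      relabel[r] = id;
      comp[i] = id;
    } else {
      comp[i] = it->second;
    }
  }
  return comp;
}

// Grow self-avoiding random walks (one per fiber) in a periodic box.
// Beads are placed at unit bond length; a candidate is rejected when any
// existing bead lies within min_dist (minimum image).  Returns unwrapped
// coordinates; fibers start at random positions.
// [[Rcpp::export]]
NumericMatrix cpp_grow_saw(IntegerVector fiber_len, double box,
                           double min_dist, int max_try, double seed) {
  std::mt19937_64 rng((std::uint64_t)seed ^ 0xA5A5A5A5DEADBEEFULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int ntot = 0;
  for (int l : fiber_len) ntot += l;
  std::vector<double> p;
  p.reserve(3 * ntot);
  CellGrid grid;
  grid.init(box, std::max(min_dist, 1.0), ntot);
  int placed = 0;
  auto clash = [&](double x, double y, double z) {
    double q[3] = {x, y, z};
    int c0 = grid.cell_of(q);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int c = grid.shifted(c0, dx, dy, dz);
          for (int j = grid.head[c]; j != -1; j = grid.nxt[j]) {
            double ddx = x - p[3 * j], ddy = y - p[3 * j + 1],
                   ddz = z - p[3 * j + 2];
            ddx -= box * std::nearbyint(ddx / box);
            ddy -= box * std::nearbyint(ddy / box);
            ddz -= box * std::nearbyint(ddz / box);
            if (ddx * ddx + ddy * ddy + ddz * ddz < min_dist * min_dist)
              return true;
          }
        }
    return false;
  };
  auto add = [&](double x, double y, double z) {
    p.push_back(x);
    p.push_back(y);
    p.push_back(z);
    int c = grid.cell_of(&p[3 * placed]);
    if (grid.head[c] == -1) grid.dirty.push_back(c);
    grid.nxt[placed] = grid.head[c];
    grid.head[c] = placed;
    ++placed;
  };
  for (int f = 0; f < fiber_len.size(); ++f) {
    int L = fiber_len[f];
    // first bead
    int tries = 0;
    for (;;) {
      double x = unif(rng) * box, y = unif(rng) * box, z = unif(rng) * box;
      if (!clash(x, y, z)) {
        add(x, y, z);
        break;
      }
      if (++tries > max_try) stop("could not place fiber %d: box too dense", f + 1);
    }
    for (int b = 1; b < L; ++b) {
      int t = 0;
      bool ok = false;
      while (t++ < max_try) {
        // random unit step
        double u = 2.0 * unif(rng) - 1.0, phi = 2.0 * M_PI * unif(rng);
        double st = std::sqrt(1.0 - u * u);
        double x = p[3 * (placed - 1)] + st * std::cos(phi);
        double y = p[3 * (placed - 1) + 1] + st * std::sin(phi);
        double z = p[3 * (placed - 1) + 2] + u;
        if (!clash(x, y, z)) {
          add(x, y, z);
          ok = true;
          break;
        }
      }
      if (!ok) {
        // back off: remove last few beads and retry growth from there
        stop("self-avoiding walk stuck at bead %d of fiber %d", b + 1, f + 1);
      }
    }
  }
  NumericMatrix out(ntot, 3);
  for (int i = 0; i < ntot; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = p[3 * i + k];
  return out;
}

// Place n spheres uniformly, avoiding existing particles within min_dist.
// [[Rcpp::export]]
NumericMatrix cpp_place_spheres(int n, NumericMatrix existing, double box,
                                double min_dist, int max_try, double seed) {
  std::mt19937_64 rng((std::uint64_t)seed ^ 0xC0FFEE123456789ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int n0 = existing.nrow();
  std::vector<double> p(3 * (n0 + n));
  for (int i = 0; i < n0; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = existing(i, k);
  CellGrid grid;
  grid.init(box, std::max(min_dist, 1.0), n0 + n);
  grid.build(p, n0);
  int placed = n0;
  for (int i = 0; i < n; ++i) {
    int tries = 0;
    for (;;) {
      double x = unif(rng) * box, y = unif(rng) * box, z = unif(rng) * box;
      bool bad = false;
      double q[3] = {x, y, z};
      int c0 = grid.cell_of(q);
      for (int dx = -1; dx <= 1 && !bad; ++dx)
        for (int dy = -1; dy <= 1 && !bad; ++dy)
          for (int dz = -1; dz <= 1 && !bad; ++dz) {
            int c = grid.shifted(c0, dx, dy, dz);
            for (int j = grid.head[c]; j != -1; j = grid.nxt[j]) {
              double ddx = x - p[3 * j], ddy = y - p[3 * j + 1],
                     ddz = z - p[3 * j + 2];
              ddx -= box * std::nearbyint(ddx / box);
              ddy -= box * std::nearbyint(ddy / box);
              ddz -= box * std::nearbyint(ddz / box);
              if (ddx * ddx + ddy * ddy + ddz * ddz < min_dist * min_dist) {
                bad = true;
                break;
              }
            }
          }
      if (!bad) {
        p[3 * placed] = x;
        p[3 * placed + 1] = y;
        p[3 * placed + 2] = z;
        int c = grid.cell_of(&p[3 * placed]);
        if (grid.head[c] == -1) grid.dirty.push_back(c);
        grid.nxt[placed] = grid.head[c];
        grid.head[c] = placed;
        ++placed;
        break;
      }
      if (++tries > max_try)
        stop("could not place sphere %d of %d: configuration too dense", i + 1, n);
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = p[3 * (n0 + i) + k];
  return out;
}

// Accumulate a binned contact map over snapshots.
// traj: (3*nbead_total) x nsnap matrix of positions for the SELECTED beads
// already extracted in fiber order; bin = beads per bin.
// [[Rcpp::export]]
NumericMatrix cpp_contact_map(NumericMatrix traj, int n_beads, double box,
                              double threshold, int bin) {
  int nsnap = traj.ncol();
  int nbin = (n_beads + bin - 1) / bin;
  NumericMatrix map(nbin, nbin);
  std::vector<double> p(3 * n_beads);
  CellGrid grid;
  grid.init(box, threshold, n_beads);
  for (int t = 0; t < nsnap; ++t) {
    for (int i = 0; i < 3 * n_beads; ++i) p[i] = traj(i, t);
    grid.build(p, n_beads);
    double c2 = threshold * threshold;
    for (int i = 0; i < n_beads; ++i) {
      int c0 = grid.cell_of(&p[3 * i]);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int c = grid.shifted(c0, dx, dy, dz);
            for (int j = grid.head[c]; j != -1; j = grid.nxt[j]) {
              if (j <= i) continue;
              double ddx = p[3 * i] - p[3 * j];
              double ddy = p[3 * i + 1] - p[3 * j + 1];
              double ddz = p[3 * i + 2] - p[3 * j + 2];
              ddx -= box * std::nearbyint(ddx / box);
              ddy -= box * std::nearbyint(ddy / box);
              ddz -= box * std::nearbyint(ddz / box);
              if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) {
                // each unordered pair counts once in each triangle, so
                // binning conserves the total
                int bi = i / bin, bj = j / bin;
                map(bi, bj) += 1;
                map(bj, bi) += 1;
              }
            }
          }
      // diagonal self-contact convention: each bead contacts itself
      map(i / bin, i / bin) += 1;
    }
  }
  return map;
}

// Contact counts by 1D separation for P(s): same-fiber pairs only.
// fiber_id: per-bead fiber index (1-based); idx_in_fiber: position (0-based).
// [[Rcpp::export]]
List cpp_contact_by_sep(NumericMatrix traj, int n_beads, double box,
                        double threshold, IntegerVector fiber_id,
                        IntegerVector idx_in_fiber, int max_sep) {
  int nsnap = traj.ncol();
  NumericVector counts(max_sep + 1);
  std::vector<double> p(3 * n_beads);
  CellGrid grid;
  grid.init(box, threshold, n_beads);
  for (int t = 0; t < nsnap; ++t) {
    for (int i = 0; i < 3 * n_beads; ++i) p[i] = traj(i, t);
    grid.build(p, n_beads);
    double c2 = threshold * threshold;
    for (int i = 0; i < n_beads; ++i) {
      int c0 = grid.cell_of(&p[3 * i]);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int c = grid.shifted(c0, dx, dy, dz);
            for (int j = grid.head[c]; j != -1; j = grid.nxt[j]) {
              if (j <= i) continue;
              if (fiber_id[i] != fiber_id[j]) continue;
              int sep = std::abs(idx_in_fiber[i] - idx_in_fiber[j]);
              if (sep > max_sep) continue;
              double ddx = p[3 * i] - p[3 * j];
              double ddy = p[3 * i + 1] - p[3 * j + 1];
              double ddz = p[3 * i + 2] - p[3 * j + 2];
              ddx -= box * std::nearbyint(ddx / box);
              ddy -= box * std::nearbyint(ddy / box);
              ddz -= box * std::nearbyint(ddz / box);
              if (ddx * ddx + ddy * ddy + ddz * ddz <= c2) counts[sep] += 1;
            }
          }
    }
  }
  return List::create(_["counts"] = counts, _["n_snapshots"] = nsnap);
}
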