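// Overdamped Brownian-dynamics core for the coarse-grained vWF bead-spring
// chain in simple shear flow.  Everything here works in reduced units:
// length = pair sigma, energy = kBT, time = zeta*sigma^2/kBT (zeta the Stokes
// drag of one bead), so the free-draining bead mobility and diffusivity are 1.
// The R layer owns the mapping to nm / pN / s.
//
// Chain topology (N beads, N even): monomer i = beads (2i, 2i+1) joined by a
// FENE spring (the A2 domain); consecutive monomers joined by a stiff
// harmonic bond (the disulfide link) between beads 2i+1 and 2i+2.
//
// The free-draining production path uses a Verlet neighbour list (skin 0.4
// sigma, rebuilt on the half-skin displacement criterion) and a
// structure-of-arrays layout; the pairwise-mobility (RPY) path is a dense
// O(N^2)/O(N^3) reference intended for small systems.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64, polar Box-Muller normals.
// Self-contained so trajectories are bit-reproducible for a given seed
// independent of R's RNG state.
// ---------------------------------------------------------------------------

static inline std::uint64_t splitmix64(std::uint64_t &x) {
  std::uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  std::uint64_t s[4];
  double cached;
  bool has_cached;

  explicit Rng(std::uint64_t seed) : has_cached(false) {
    std::uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
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

  // uniform in (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double normal() {
    if (has_cached) { has_cached = false; return cached; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    cached = v * f;
    has_cached = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// Model parameters (reduced units)
// ---------------------------------------------------------------------------

struct Par {
  int n;            // beads
  double fene_k;    // kBT / sigma^2
  double fene_R0;   // sigma
  double harm_k;
  double harm_r0;
  double eps;       // pair well depth, kBT
  double rc2;       // pair cutoff^2
  double shear;     // gamma_dot * tau
  double dt;        // tau
  bool hi;          // pairwise RPY mobility instead of free draining
  double a;         // hydrodynamic bead radius, sigma (RPY only)
  bool noise;       // thermal noise on (off = deterministic drift only)
};

static Par par_from_list(const List &p) {
  Par q;
  q.n       = as<int>(p["n"]);
  q.fene_k  = as<double>(p["fene_k"]);
  q.fene_R0 = as<double>(p["fene_R0"]);
  q.harm_k  = as<double>(p["harm_k"]);
  q.harm_r0 = as<double>(p["harm_r0"]);
  q.eps     = as<double>(p["eps"]);
  double rc = as<double>(p["cutoff"]);
  q.rc2     = rc * rc;
  q.shear   = as<double>(p["shear"]);
  q.dt      = as<double>(p["dt"]);
  q.hi      = as<bool>(p["hi"]);
  q.a       = as<double>(p["a"]);
  q.noise   = p.containsElementNamed("noise") ? as<bool>(p["noise"]) : true;
  if (q.n < 2 || q.n % 2 != 0) stop("n must be even and >= 2");
  return q;
}

// Lennard-Jones force factor (force = fac * separation vector, repulsive
// positive); r clamped below 0.8 sigma so a rare deep overlap cannot
// destabilise the explicit update.
static inline double lj_fac(double r2, double eps) {
  const double r2e = (r2 < 0.64) ? 0.64 : r2;
  const double ir2 = 1.0 / r2e;
  const double ir6 = ir2 * ir2 * ir2;
  return 24.0 * eps * ir6 * (2.0 * ir6 - 1.0) * ir2;
}

// bonded forces + FENE tensions on a structure-of-arrays state; adds to f*.
// A zero FENE constant disables the springs (ideal-bead runs) including the
// finite-extensibility check.
static void bonded_forces(const Par &p, const std::vector<double> &x,
                          const std::vector<double> &y,
                          const std::vector<double> &z,
                          std::vector<double> &fx, std::vector<double> &fy,
                          std::vector<double> &fz, double *tension) {
  const double R02 = p.fene_R0 * p.fene_R0;
  for (int i = 0; p.fene_k > 0.0 && i < p.n / 2; ++i) {
    const int b0 = 2 * i, b1 = 2 * i + 1;
    const double dx = x[b1] - x[b0], dy = y[b1] - y[b0], dz = z[b1] - z[b0];
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= R02)
      stop("FENE spring %d over-extended (r = %.3f >= R0 = %.3f): "
           "reduce the timestep or the shear rate", i + 1, std::sqrt(r2),
           p.fene_R0);
    const double fac = p.fene_k / (1.0 - r2 / R02);
    tension[i] = fac * std::sqrt(r2);
    fx[b0] += fac * dx; fx[b1] -= fac * dx;
    fy[b0] += fac * dy; fy[b1] -= fac * dy;
    fz[b0] += fac * dz; fz[b1] -= fac * dz;
  }
  for (int i = 0; p.harm_k > 0.0 && i < p.n / 2 - 1; ++i) {
    const int b0 = 2 * i + 1, b1 = 2 * i + 2;
    const double dx = x[b1] - x[b0], dy = y[b1] - y[b0], dz = z[b1] - z[b0];
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > 1e-12) {
      const double fac = p.harm_k * (r - p.harm_r0) / r;
      fx[b0] += fac * dx; fx[b1] -= fac * dx;
      fy[b0] += fac * dy; fy[b1] -= fac * dy;
      fz[b0] += fac * dz; fz[b1] -= fac * dz;
    }
  }
}

// free-draining simulation state with a Verlet neighbour list
struct Sim {
  Par p;
  int n;
  std::vector<double> x, y, z, fx, fy, fz;
  std::vector<double> xr, yr, zr;        // positions at last list build
  std::vector<int> nbr, nbr_off;         // CSR neighbour list (i < j)
  double rl2, half_skin2;

  Sim(const Par &par, const arma::mat &pos0) : p(par), n(par.n) {
    x.resize(n); y.resize(n); z.resize(n);
    fx.resize(n); fy.resize(n); fz.resize(n);
    xr.resize(n); yr.resize(n); zr.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    }
    const double skin = 0.4;
    const double rl = std::sqrt(p.rc2) + skin;
    rl2 = rl * rl;
    half_skin2 = (skin / 2) * (skin / 2);
    nbr_off.resize(n + 1);
    build_list();
  }

  void build_list() {
    nbr.clear();
    for (int i = 0; i < n; ++i) {
      nbr_off[i] = (int)nbr.size();
      const double xi = x[i], yi = y[i], zi = z[i];
      for (int j = i + 1; j < n; ++j) {
        const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
        if (dx * dx + dy * dy + dz * dz < rl2) nbr.push_back(j);
      }
      xr[i] = x[i]; yr[i] = y[i]; zr[i] = z[i];
    }
    nbr_off[n] = (int)nbr.size();
  }

  bool list_stale() const {
    for (int i = 0; i < n; ++i) {
      const double dx = x[i] - xr[i], dy = y[i] - yr[i], dz = z[i] - zr[i];
      if (dx * dx + dy * dy + dz * dz > half_skin2) return true;
    }
    return false;
  }

  void forces(double *tension) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    if (p.fene_k > 0.0)
      std::fill(tension, tension + n / 2, 0.0);
    if (p.eps > 0.0) {
      if (list_stale()) build_list();
      for (int i = 0; i < n; ++i) {
        const double xi = x[i], yi = y[i], zi = z[i];
        double fxi = 0.0, fyi = 0.0, fzi = 0.0;
        for (int k = nbr_off[i]; k < nbr_off[i + 1]; ++k) {
          const int j = nbr[k];
          const double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
          const double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 >= p.rc2) continue;
          const double fac = lj_fac(r2, p.eps);
          fxi += fac * dx; fx[j] -= fac * dx;
          fyi += fac * dy; fy[j] -= fac * dy;
          fzi += fac * dz; fz[j] -= fac * dz;
        }
        fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
      }
    }
    bonded_forces(p, x, y, z, fx, fy, fz, tension);
  }

  void step(Rng &rng) {
    const double sd = p.noise ? std::sqrt(2.0 * p.dt) : 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += fx[i] * p.dt + p.shear * z[i] * p.dt + sd * rng.normal();
      y[i] += fy[i] * p.dt + sd * rng.normal();
      z[i] += fz[i] * p.dt + sd * rng.normal();
    }
  }
};

// ---------------------------------------------------------------------------
// Dense reference forces (used by the exported force evaluator and the RPY
// path); writes the full force matrix.
// ---------------------------------------------------------------------------

static void forces_dense(const arma::mat &pos, const Par &p, arma::mat &frc,
                         arma::vec &tension) {
  const int n = p.n;
  frc.zeros();
  tension.zeros();

  if (p.eps > 0.0) {
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double dx = pos(i, 0) - pos(j, 0);
        const double dy = pos(i, 1) - pos(j, 1);
        const double dz = pos(i, 2) - pos(j, 2);
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= p.rc2) continue;
        const double fac = lj_fac(r2, p.eps);
        frc(i, 0) += fac * dx; frc(j, 0) -= fac * dx;
        frc(i, 1) += fac * dy; frc(j, 1) -= fac * dy;
        frc(i, 2) += fac * dz; frc(j, 2) -= fac * dz;
      }
    }
  }

  const double R02 = p.fene_R0 * p.fene_R0;
  for (int i = 0; p.fene_k > 0.0 && i < n / 2; ++i) {
    const int b0 = 2 * i, b1 = 2 * i + 1;
    const double dx = pos(b1, 0) - pos(b0, 0);
    const double dy = pos(b1, 1) - pos(b0, 1);
    const double dz = pos(b1, 2) - pos(b0, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= R02)
      stop("FENE spring %d over-extended (r = %.3f >= R0 = %.3f): "
           "reduce the timestep or the shear rate", i + 1, std::sqrt(r2),
           p.fene_R0);
    const double fac = p.fene_k / (1.0 - r2 / R02);
    tension(i) = fac * std::sqrt(r2);
    frc(b0, 0) += fac * dx; frc(b1, 0) -= fac * dx;
    frc(b0, 1) += fac * dy; frc(b1, 1) -= fac * dy;
    frc(b0, 2) += fac * dz; frc(b1, 2) -= fac * dz;
  }

  for (int i = 0; p.harm_k > 0.0 && i < n / 2 - 1; ++i) {
    const int b0 = 2 * i + 1, b1 = 2 * i + 2;
    const double dx = pos(b1, 0) - pos(b0, 0);
    const double dy = pos(b1, 1) - pos(b0, 1);
    const double dz = pos(b1, 2) - pos(b0, 2);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r > 1e-12) {
      const double fac = p.harm_k * (r - p.harm_r0) / r;
      frc(b0, 0) += fac * dx; frc(b1, 0) -= fac * dx;
      frc(b0, 1) += fac * dy; frc(b1, 1) -= fac * dy;
      frc(b0, 2) += fac * dz; frc(b1, 2) -= fac * dz;
    }
  }
}

// Rotne-Prager-Yamakawa mobility (units of the free-bead mobility).
static arma::mat rpy_mobility(const arma::mat &pos, const Par &p) {
  const int n = p.n;
  const double a = p.a;
  arma::mat M(3 * n, 3 * n, arma::fill::eye);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      arma::vec3 d = { pos(j, 0) - pos(i, 0), pos(j, 1) - pos(i, 1),
                       pos(j, 2) - pos(i, 2) };
      const double r = arma::norm(d);
      arma::mat33 blk;
      if (r >= 2.0 * a) {
        arma::vec3 e = d / r;
        const double c1 = (3.0 * a) / (4.0 * r);
        const double a2r2 = (a * a) / (r * r);
        blk = c1 * ((1.0 + 2.0 * a2r2 / 3.0) * arma::eye(3, 3) +
                    (1.0 - 2.0 * a2r2) * (e * e.t()));
      } else if (r > 1e-12) {
        arma::vec3 e = d / r;
        blk = (1.0 - 9.0 * r / (32.0 * a)) * arma::eye(3, 3) +
              (3.0 * r / (32.0 * a)) * (e * e.t());
      } else {
        blk = arma::eye(3, 3);
      }
      M.submat(3 * i, 3 * j, 3 * i + 2, 3 * j + 2) = blk;
      M.submat(3 * j, 3 * i, 3 * j + 2, 3 * i + 2) = blk.t();
    }
  }
  return M;
}

static void step_rpy(arma::mat &pos, const Par &p, Rng &rng,
                     const arma::mat &frc) {
  const int n = p.n;
  arma::mat M = rpy_mobility(pos, p);
  arma::vec f(3 * n), xi(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) f(3 * i + k) = frc(i, k);
  for (int i = 0; i < 3 * n; ++i) xi(i) = rng.normal();
  arma::mat L = arma::chol(M, "lower");
  arma::vec drift = M * f * p.dt;
  arma::vec noise = (p.noise ? std::sqrt(2.0 * p.dt) : 0.0) * (L * xi);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) += drift(3 * i) + p.shear * pos(i, 2) * p.dt + noise(3 * i);
    pos(i, 1) += drift(3 * i + 1) + noise(3 * i + 1);
    pos(i, 2) += drift(3 * i + 2) + noise(3 * i + 2);
  }
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// Conservative forces and FENE tensions for one configuration.
// [[Rcpp::export(name = ".bd_forces")]]
List bd_forces_cpp(const arma::mat &pos, const List &params) {
  Par p = par_from_list(params);
  if ((int)pos.n_rows != p.n || pos.n_cols != 3)
    stop("pos must be an n x 3 matrix");
  arma::mat frc(p.n, 3);
  arma::vec tension(p.n / 2, arma::fill::zeros);
  forces_dense(pos, p, frc, tension);
  return List::create(_["forces"] = frc, _["tensions"] = tension);
}

// Integrate n_steps of overdamped dynamics.  If sample_every > 0, positions
// and tensions are recorded after steps sample_every, 2*sample_every, ...
// [[Rcpp::export(name = ".bd_run")]]
List bd_run_cpp(const arma::mat &pos0, const List &params, double n_steps,
                int sample_every, double seed) {
  Par p = par_from_list(params);
  if ((int)pos0.n_rows != p.n || pos0.n_cols != 3)
    stop("pos0 must be an n x 3 matrix");
  const long long ns = (long long)n_steps;
  if (ns < 0) stop("n_steps must be >= 0");

  Rng rng((std::uint64_t)seed);
  const int nspring = p.n / 2;
  arma::vec tension(nspring, arma::fill::zeros);

  const int nsamp = (sample_every > 0) ? (int)(ns / sample_every) : 0;
  arma::cube samp_pos;
  arma::mat samp_ten;
  if (nsamp > 0) {
    samp_pos.set_size(nsamp, p.n, 3);
    samp_ten.set_size(nsamp, nspring);
  }

  arma::mat pos = pos0;

  if (!p.hi) {
    Sim sim(p, pos0);
    int isamp = 0;
    for (long long step = 1; step <= ns; ++step) {
      sim.forces(tension.memptr());
      sim.step(rng);
      if (sample_every > 0 && step % sample_every == 0 && isamp < nsamp) {
        sim.forces(tension.memptr());  // tensions at the sampled state
        for (int b = 0; b < p.n; ++b) {
          samp_pos(isamp, b, 0) = sim.x[b];
          samp_pos(isamp, b, 1) = sim.y[b];
          samp_pos(isamp, b, 2) = sim.z[b];
        }
        for (int s = 0; s < nspring; ++s) samp_ten(isamp, s) = tension(s);
        ++isamp;
      }
      if (step % 200000 == 0) Rcpp::checkUserInterrupt();
    }
    sim.forces(tension.memptr());
    for (int b = 0; b < p.n; ++b) {
      pos(b, 0) = sim.x[b]; pos(b, 1) = sim.y[b]; pos(b, 2) = sim.z[b];
    }
  } else {
    arma::mat frc(p.n, 3);
    int isamp = 0;
    for (long long step = 1; step <= ns; ++step) {
      forces_dense(pos, p, frc, tension);
      step_rpy(pos, p, rng, frc);
      if (sample_every > 0 && step % sample_every == 0 && isamp < nsamp) {
        forces_dense(pos, p, frc, tension);
        for (int b = 0; b < p.n; ++b)
          for (int k = 0; k < 3; ++k) samp_pos(isamp, b, k) = pos(b, k);
        for (int s = 0; s < nspring; ++s) samp_ten(isamp, s) = tension(s);
        ++isamp;
      }
      if (step % 1000 == 0) Rcpp::checkUserInterrupt();
    }
    forces_dense(pos, p, frc, tension);
  }

  List out = List::create(_["final"] = pos, _["tensions"] = tension,
                          _["n_steps"] = (double)ns);
  if (nsamp > 0) {
    out["sampled_positions"] = samp_pos;
    out["sampled_tensions"] = samp_ten;
  }
  return out;
}
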