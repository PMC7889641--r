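// Core numerics for the coarse-grained condensate model:
//  - HPS-style pair force field (Ashbaugh-Hatch + Debye-Hueckel + cation-pi)
//    with shifted-truncation cutoffs and minimum-image periodic boundaries
//  - O(N^2)-rebuild Verlet pair lists with displacement-triggered refresh
//  - BAOAB-discretized Langevin integrator (deterministic under fixed seed)
//  - Berendsen isotropic barostat stage
// Units: nm, ps, K, kJ/mol, g/mol, elementary charges.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static const double KB = 8.31446261815324e-3; // kJ/mol/K
static const double KE = 138.935458;          // e^2/(4 pi eps0), kJ nm/mol

struct FF {
  int n;
  std::vector<double> x, y, z;      // positions
  double bx, by, bz;                // box edges
  std::vector<double> sigma, lam, q, mass;
  std::vector<int> cat, aro, chain;
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> br0, bk;
  // scalars
  double chi, eps_ah, eps_cp, eps_r, kappa; // kappa = 1/debye (0 if Inf)
  double rc_h, rc_e;
  // restraints (k <= 0 means none)
  std::vector<double> res_k, res_x, res_y, res_z;
  bool any_restraint;
  bool any_charge;
};

struct PairLists {
  std::vector<int> hi, hj;   // pairs within rc_h + skin
  std::vector<int> ei, ej;   // charged pairs within rc_e + skin
  std::vector<double> ref_x, ref_y, ref_z; // positions at build time
  double skin;
};

static inline double wrap1(double d, double L) {
  // minimum image displacement; valid for |d| < 1.5 L (positions are
  // kept wrapped into [0, L))
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

static const double RMIN2_FACT = 1.2599210498948732; // 2^(1/3)

static void build_lists(const FF& ff, PairLists& pl) {
  pl.hi.clear(); pl.hj.clear(); pl.ei.clear(); pl.ej.clear();
  const double rh2 = (ff.rc_h + pl.skin) * (ff.rc_h + pl.skin);
  const double re2 = (ff.rc_e + pl.skin) * (ff.rc_e + pl.skin);
  for (int i = 0; i < ff.n; ++i) {
    const double xi = ff.x[i], yi = ff.y[i], zi = ff.z[i];
    const bool qi = ff.any_charge && ff.q[i] != 0.0;
    for (int j = i + 1; j < ff.n; ++j) {
      // exclude directly bonded consecutive residues of the same chain
      if (ff.chain[i] == ff.chain[j] && (j - i) == 1) continue;
      double dx = wrap1(xi - ff.x[j], ff.bx);
      double dy = wrap1(yi - ff.y[j], ff.by);
      double dz = wrap1(zi - ff.z[j], ff.bz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rh2) { pl.hi.push_back(i); pl.hj.push_back(j); }
      if (qi && ff.q[j] != 0.0 && r2 < re2) {
        pl.ei.push_back(i); pl.ej.push_back(j);
      }
    }
  }
  pl.ref_x = ff.x; pl.ref_y = ff.y; pl.ref_z = ff.z;
}

static bool need_rebuild(const FF& ff, const PairLists& pl) {
  const double lim2 = 0.25 * pl.skin * pl.skin;
  for (int i = 0; i < ff.n; ++i) {
    double dx = wrap1(ff.x[i] - pl.ref_x[i], ff.bx);
    double dy = wrap1(ff.y[i] - pl.ref_y[i], ff.by);
    double dz = wrap1(ff.z[i] - pl.ref_z[i], ff.bz);
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

struct EnergyParts {
  double bonded, hydrophobic, electrostatic, cation_pi, restraint, virial;
  double total() const {
    return bonded + hydrophobic + electrostatic + cation_pi + restraint;
  }
};

// Forces are accumulated into fx/fy/fz (zeroed here).
static EnergyParts compute_forces(const FF& ff, const PairLists& pl,
                                  std::vector<double>& fx,
                                  std::vector<double>& fy,
                                  std::vector<double>& fz) {
  EnergyParts ep = {0, 0, 0, 0, 0, 0};
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);

  const double rc_h2 = ff.rc_h * ff.rc_h;
  const double rc_e2 = ff.rc_e * ff.rc_e;

  // hydrophobic (+ cation-pi) pairs; formulated sqrt-free in r^2
  const size_t nh = pl.hi.size();
  const double hbx = 0.5 * ff.bx, hby = 0.5 * ff.by, hbz = 0.5 * ff.bz;
  for (size_t p = 0; p < nh; ++p) {
    const int i = pl.hi[p], j = pl.hj[p];
    double dx = ff.x[i] - ff.x[j];
    if (dx > hbx) dx -= ff.bx; else if (dx < -hbx) dx += ff.bx;
    double dy = ff.y[i] - ff.y[j];
    if (dy > hby) dy -= ff.by; else if (dy < -hby) dy += ff.by;
    double dz = ff.z[i] - ff.z[j];
    if (dz > hbz) dz -= ff.bz; else if (dz < -hbz) dz += ff.bz;
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc_h2) continue;
    double inv_r2 = 1.0 / r2;
    double sij = 0.5 * (ff.sigma[i] + ff.sigma[j]);
    double lij = 0.5 * (ff.lam[i] + ff.lam[j]);
    double s2 = sij * sij;
    double sr2 = s2 * inv_r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    double lj = 4.0 * ff.eps_ah * (sr12 - sr6);
    // dU/dr * r (virial form; also gives fmag = -dU/dr / r = -w/r^2)
    double w = -24.0 * ff.eps_ah * (2.0 * sr12 - sr6);
    // shift so the AH term vanishes at rc_h
    double xc6 = s2 / rc_h2; xc6 = xc6 * xc6 * xc6;
    double ljc = 4.0 * ff.eps_ah * (xc6 * xc6 - xc6);
    double u, du_r; // du_r = dU/dr * r
    if (r2 <= RMIN2_FACT * s2) {
      u = lj + (1.0 - lij) * ff.eps_ah - lij * ljc;
      du_r = w;
    } else {
      u = lij * (lj - ljc);
      du_r = lij * w;
    }
    // cation-pi extra well (same cutoff)
    if (ff.eps_cp > 0.0 &&
        ((ff.cat[i] && ff.aro[j]) || (ff.cat[j] && ff.aro[i]))) {
      double s = ff.eps_cp / ff.eps_ah;
      ep.cation_pi += s * (lj - ljc);
      du_r += s * w;
    }
    ep.hydrophobic += u;
    double fmag = -du_r * inv_r2; // force along +r on i, per unit dx
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    ep.virial += -du_r;
  }

  // electrostatic pairs
  const size_t ne = pl.ei.size();
  for (size_t p = 0; p < ne; ++p) {
    const int i = pl.ei[p], j = pl.ej[p];
    double dx = wrap1(ff.x[i] - ff.x[j], ff.bx);
    double dy = wrap1(ff.y[i] - ff.y[j], ff.by);
    double dz = wrap1(ff.z[i] - ff.z[j], ff.bz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc_e2) continue;
    double r = std::sqrt(r2);
    double pref = ff.chi * ff.q[i] * ff.q[j] * KE / ff.eps_r;
    double ex = std::exp(-ff.kappa * r);
    double u = pref * ex / r;
    double exc = std::exp(-ff.kappa * ff.rc_e);
    double uc = pref * exc / ff.rc_e;
    double du = -pref * ex * (1.0 / r2 + ff.kappa / r);
    ep.electrostatic += u - uc;
    double fmag = -du / r;
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    ep.virial += -du * r;
  }

  // bonds
  const size_t nb = ff.bi.size();
  for (size_t b = 0; b < nb; ++b) {
    const int i = ff.bi[b], j = ff.bj[b];
    double dx = wrap1(ff.x[i] - ff.x[j], ff.bx);
    double dy = wrap1(ff.y[i] - ff.y[j], ff.by);
    double dz = wrap1(ff.z[i] - ff.z[j], ff.bz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - ff.br0[b];
    ep.bonded += 0.5 * ff.bk[b] * dr * dr;
    double du = ff.bk[b] * dr;
    double fmag = (r > 1e-12) ? -du / r : 0.0;
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    ep.virial += -du * r;
  }

  // harmonic position restraints (not wrapped: act in unwrapped frame of
  // the current image, used for single-bead validation and tethers)
  if (ff.any_restraint) {
    for (int i = 0; i < ff.n; ++i) {
      if (ff.res_k[i] <= 0.0) continue;
      double dx = ff.x[i] - ff.res_x[i];
      double dy = ff.y[i] - ff.res_y[i];
      double dz = ff.z[i] - ff.res_z[i];
      ep.restraint += 0.5 * ff.res_k[i] * (dx * dx + dy * dy + dz * dz);
      fx[i] -= ff.res_k[i] * dx;
      fy[i] -= ff.res_k[i] * dy;
      fz[i] -= ff.res_k[i] * dz;
    }
  }
  return ep;
}

static FF make_ff(NumericMatrix pos, NumericVector box, List beads,
                  List bonds, List scal, Nullable<List> restraints) {
  FF ff;
  ff.n = pos.nrow();
  ff.x.resize(ff.n); ff.y.resize(ff.n); ff.z.resize(ff.n);
  for (int i = 0; i < ff.n; ++i) {
    ff.x[i] = pos(i, 0); ff.y[i] = pos(i, 1); ff.z[i] = pos(i, 2);
  }
  ff.bx = box[0]; ff.by = box[1]; ff.bz = box[2];
  ff.sigma = as<std::vector<double>>(beads["sigma"]);
  ff.lam = as<std::vector<double>>(beads["lambda"]);
  ff.q = as<std::vector<double>>(beads["charge"]);
  ff.mass = as<std::vector<double>>(beads["mass"]);
  ff.cat = as<std::vector<int>>(beads["cation"]);
  ff.aro = as<std::vector<int>>(beads["aromatic"]);
  ff.chain = as<std::vector<int>>(beads["chain"]);
  ff.bi = as<std::vector<int>>(bonds["i"]);
  ff.bj = as<std::vector<int>>(bonds["j"]);
  ff.br0 = as<std::vector<double>>(bonds["r0"]);
  ff.bk = as<std::vector<double>>(bonds["k"]);
  ff.chi = as<double>(scal["chi"]);
  ff.eps_ah = as<double>(scal["eps_ah"]);
  ff.eps_cp = as<double>(scal["cation_pi_eps"]);
  ff.eps_r = as<double>(scal["rel_permittivity"]);
  double ld = as<double>(scal["debye_length"]);
  ff.kappa = std::isfinite(ld) ? 1.0 / ld : 0.0;
  ff.rc_h = as<double>(scal["cutoff_hydro"]);
  ff.rc_e = as<double>(scal["cutoff_elec"]);
  ff.any_restraint = false;
  ff.res_k.assign(ff.n, 0.0);
  ff.res_x.assign(ff.n, 0.0);
  ff.res_y.assign(ff.n, 0.0);
  ff.res_z.assign(ff.n, 0.0);
  if (restraints.isNotNull()) {
    List rl(restraints);
    ff.res_k = as<std::vector<double>>(rl["k"]);
    NumericMatrix rc = rl["center"];
    for (int i = 0; i < ff.n; ++i) {
      ff.res_x[i] = rc(i, 0); ff.res_y[i] = rc(i, 1); ff.res_z[i] = rc(i, 2);
    }
    for (int i = 0; i < ff.n; ++i)
      if (ff.res_k[i] > 0) { ff.any_restraint = true; break; }
  }
  ff.any_charge = false;
  if (ff.chi > 0.0) {
    for (int i = 0; i < ff.n; ++i)
      if (ff.q[i] != 0.0) { ff.any_charge = true; break; }
  }
  return ff;
}

// [[Rcpp::export]]
List cg_energy_forces(NumericMatrix pos, NumericVector box, List beads,
                      List bonds, List scal,
                      Nullable<List> restraints = R_NilValue) {
  FF ff = make_ff(pos, box, beads, bonds, scal, restraints);
  PairLists pl; pl.skin = 0.0;
  build_lists(ff, pl);
  const double floor_r = 1e-3;
  for (size_t p = 0; p < pl.hi.size(); ++p) {
    int i = pl.hi[p], j = pl.hj[p];
    double dx = wrap1(ff.x[i] - ff.x[j], ff.bx);
    double dy = wrap1(ff.y[i] - ff.y[j], ff.by);
    double dz = wrap1(ff.z[i] - ff.z[j], ff.bz);
    if (dx * dx + dy * dy + dz * dz < floor_r * floor_r)
      stop("beads %d and %d overlap below hard floor", i + 1, j + 1);
  }
  std::vector<double> fx(ff.n), fy(ff.n), fz(ff.n);
  EnergyParts ep = compute_forces(ff, pl, fx, fy, fz);
  NumericMatrix F(ff.n, 3);
  for (int i = 0; i < ff.n; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  return List::create(
    _["energy"] = ep.total(),
    _["bonded"] = ep.bonded,
    _["hydrophobic"] = ep.hydrophobic,
    _["electrostatic"] = ep.electrostatic,
    _["cation_pi"] = ep.cation_pi,
    _["restraint"] = ep.restraint,
    _["virial"] = ep.virial,
    _["forces"] = F);
}

static double kinetic_energy(const FF& ff, const std::vector<double>& vx,
                             const std::vector<double>& vy,
                             const std::vector<double>& vz) {
  double ke = 0;
  for (int i = 0; i < ff.n; ++i)
    ke += 0.5 * ff.mass[i] *
      (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
  return ke;
}

static void remove_com_momentum(const FF& ff, std::vector<double>& vx,
                                std::vector<double>& vy,
                                std::vector<double>& vz) {
  double px = 0, py = 0, pz = 0, M = 0;
  for (int i = 0; i < ff.n; ++i) {
    px += ff.mass[i] * vx[i]; py += ff.mass[i] * vy[i];
    pz += ff.mass[i] * vz[i]; M += ff.mass[i];
  }
  px /= M; py /= M; pz /= M;
  for (int i = 0; i < ff.n; ++i) { vx[i] -= px; vy[i] -= py; vz[i] -= pz; }
}

static inline void wrap_into_box(FF& ff) {
  for (int i = 0; i < ff.n; ++i) {
    ff.x[i] -= ff.bx * std::floor(ff.x[i] / ff.bx);
    ff.y[i] -= ff.by * std::floor(ff.y[i] / ff.by);
    ff.z[i] -= ff.bz * std::floor(ff.z[i] / ff.bz);
  }
}

// BAOAB Langevin integration.  Returns thinned frames, an energy log and
// the final phase-space state.  Deterministic for a fixed seed.
// [[Rcpp::export]]
List cg_langevin(NumericMatrix pos, NumericMatrix vel, NumericVector box,
                 List beads, List bonds, List scal, double temperature,
                 double dt_ps, double friction_time_ps, int n_steps,
                 int thin, int seed,
                 Nullable<List> restraints = R_NilValue,
                 double skin = 0.25, int com_every = 1000) {
  FF ff = make_ff(pos, box, beads, bonds, scal, restraints);
  std::vector<double> vx(ff.n), vy(ff.n), vz(ff.n);
  for (int i = 0; i < ff.n; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  const double kT = KB * temperature;
  const double gamma = 1.0 / friction_time_ps;
  const double c1 = std::exp(-gamma * dt_ps);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const double half_dt = 0.5 * dt_ps;

  double min_sigma = ff.sigma.empty() ? 0.4 : ff.sigma[0];
  for (int i = 0; i < ff.n; ++i) min_sigma = std::min(min_sigma, ff.sigma[i]);
  const double max_disp = 0.5 * min_sigma;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);

  PairLists pl; pl.skin = skin;
  wrap_into_box(ff);
  build_lists(ff, pl);
  std::vector<double> fx(ff.n), fy(ff.n), fz(ff.n);
  EnergyParts ep = compute_forces(ff, pl, fx, fy, fz);

  const int n_frames = n_steps / thin;
  NumericVector frames(static_cast<R_xlen_t>(n_frames) * ff.n * 3);
  NumericMatrix elog(n_frames, 5); // step, time, Epot, Ekin, Tinst
  NumericVector ftime(n_frames);
  int frame = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < ff.n; ++i) {
      double im = half_dt / ff.mass[i];
      vx[i] += fx[i] * im; vy[i] += fy[i] * im; vz[i] += fz[i] * im;
    }
    // A: half drift
    for (int i = 0; i < ff.n; ++i) {
      ff.x[i] += vx[i] * half_dt;
      ff.y[i] += vy[i] * half_dt;
      ff.z[i] += vz[i] * half_dt;
    }
    // O: Ornstein-Uhlenbeck
    for (int i = 0; i < ff.n; ++i) {
      double sig = c2 * std::sqrt(kT / ff.mass[i]);
      vx[i] = c1 * vx[i] + sig * nd(rng);
      vy[i] = c1 * vy[i] + sig * nd(rng);
      vz[i] = c1 * vz[i] + sig * nd(rng);
    }
    // A: half drift, with instability detection
    for (int i = 0; i < ff.n; ++i) {
      double ddx = vx[i] * half_dt, ddy = vy[i] * half_dt,
             ddz = vz[i] * half_dt;
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (!std::isfinite(d2) || d2 > max_disp * max_disp)
        stop("integration unstable at step %d (per-step displacement "
             "exceeds sigma/2); reduce dt", step);
      ff.x[i] += ddx; ff.y[i] += ddy; ff.z[i] += ddz;
    }
    wrap_into_box(ff);
    if (need_rebuild(ff, pl)) build_lists(ff, pl);
    ep = compute_forces(ff, pl, fx, fy, fz);
    if (!std::isfinite(ep.total()))
      stop("non-finite potential energy at step %d", step);
    // B: half kick
    for (int i = 0; i < ff.n; ++i) {
      double im = half_dt / ff.mass[i];
      vx[i] += fx[i] * im; vy[i] += fy[i] * im; vz[i] += fz[i] * im;
    }
    if (com_every > 0 && step % com_every == 0)
      remove_com_momentum(ff, vx, vy, vz);

    if (step % thin == 0) {
      for (int i = 0; i < ff.n; ++i) {
        R_xlen_t base = (static_cast<R_xlen_t>(frame) * ff.n + i) * 3;
        frames[base] = ff.x[i];
        frames[base + 1] = ff.y[i];
        frames[base + 2] = ff.z[i];
      }
      double ke = kinetic_energy(ff, vx, vy, vz);
      elog(frame, 0) = step;
      elog(frame, 1) = step * dt_ps;
      elog(frame, 2) = ep.total();
      elog(frame, 3) = ke;
      elog(frame, 4) = 2.0 * ke / (3.0 * ff.n * KB);
      ftime[frame] = step * dt_ps;
      ++frame;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix P(ff.n, 3), V(ff.n, 3);
  for (int i = 0; i < ff.n; ++i) {
    P(i, 0) = ff.x[i]; P(i, 1) = ff.y[i]; P(i, 2) = ff.z[i];
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  return List::create(
    _["frames"] = frames, _["n_frames"] = frame, _["frame_time_ps"] = ftime,
    _["energy_log"] = elog, _["positions"] = P, _["velocities"] = V);
}

// Berendsen weak-coupling isotropic barostat stage (NPT pre-equilibration).
// pressure in kJ/mol/nm^3; beta_T in (kJ/mol/nm^3)^-1.
// [[Rcpp::export]]
List cg_berendsen(NumericMatrix pos, NumericMatrix vel, NumericVector box,
                  List beads, List bonds, List scal, double temperature,
                  double dt_ps, double friction_time_ps, double pressure,
                  double tau_p_ps, double beta_T, int n_steps, int seed,
                  double skin = 0.4) {
  FF ff = make_ff(pos, box, beads, bonds, scal, R_NilValue);
  std::vector<double> vx(ff.n), vy(ff.n), vz(ff.n);
  for (int i = 0; i < ff.n; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  const double kT = KB * temperature;
  const double gamma = 1.0 / friction_time_ps;
  const double c1 = std::exp(-gamma * dt_ps);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const double half_dt = 0.5 * dt_ps;
  const double max_cut = std::max(ff.rc_h, ff.rc_e);
  std::mt19937_64 rng(static_cast<uint64_t>(seed) + 0x9e3779b97f4a7c15ULL);
  std::normal_distribution<double> nd(0.0, 1.0);
  PairLists pl; pl.skin = skin;
  wrap_into_box(ff);
  build_lists(ff, pl);
  std::vector<double> fx(ff.n), fy(ff.n), fz(ff.n);
  EnergyParts ep = compute_forces(ff, pl, fx, fy, fz);
  const bool couple = std::isfinite(tau_p_ps);

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < ff.n; ++i) {
      double im = half_dt / ff.mass[i];
      vx[i] += fx[i] * im; vy[i] += fy[i] * im; vz[i] += fz[i] * im;
    }
    for (int i = 0; i < ff.n; ++i) {
      ff.x[i] += vx[i] * half_dt; ff.y[i] += vy[i] * half_dt;
      ff.z[i] += vz[i] * half_dt;
    }
    for (int i = 0; i < ff.n; ++i) {
      double sig = c2 * std::sqrt(kT / ff.mass[i]);
      vx[i] = c1 * vx[i] + sig * nd(rng);
      vy[i] = c1 * vy[i] + sig * nd(rng);
      vz[i] = c1 * vz[i] + sig * nd(rng);
    }
    for (int i = 0; i < ff.n; ++i) {
      ff.x[i] += vx[i] * half_dt; ff.y[i] += vy[i] * half_dt;
      ff.z[i] += vz[i] * half_dt;
    }
    wrap_into_box(ff);
    if (need_rebuild(ff, pl)) build_lists(ff, pl);
    ep = compute_forces(ff, pl, fx, fy, fz);
    for (int i = 0; i < ff.n; ++i) {
      double im = half_dt / ff.mass[i];
      vx[i] += fx[i] * im; vy[i] += fy[i] * im; vz[i] += fz[i] * im;
    }
    if (couple) {
      double V = ff.bx * ff.by * ff.bz;
      double ke = kinetic_energy(ff, vx, vy, vz);
      double P = (2.0 * ke + ep.virial) / (3.0 * V);
      double mu3 = 1.0 - beta_T * dt_ps / tau_p_ps * (pressure - P);
      if (mu3 < 0.5) mu3 = 0.5;
      if (mu3 > 2.0) mu3 = 2.0;
      double mu = std::cbrt(mu3);
      ff.bx *= mu; ff.by *= mu; ff.bz *= mu;
      for (int i = 0; i < ff.n; ++i) {
        ff.x[i] *= mu; ff.y[i] *= mu; ff.z[i] *= mu;
      }
      if (std::min({ff.bx, ff.by, ff.bz}) < 2.0 * max_cut)
        stop("Berendsen barostat collapsed the box below twice the "
             "interaction cutoff at step %d", step);
      build_lists(ff, pl);
      ep = compute_forces(ff, pl, fx, fy, fz);
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix P(ff.n, 3), V(ff.n, 3);
  for (int i = 0; i < ff.n; ++i) {
    P(i, 0) = ff.x[i]; P(i, 1) = ff.y[i]; P(i, 2) = ff.z[i];
    V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i];
  }
  return List::create(_["positions"] = P, _["velocities"] = V,
                      _["box"] = NumericVector::create(ff.bx, ff.by, ff.bz));
}

// Per-frame inter-chain contact counting at a distance cutoff.
// Returns an n x n accumulated count matrix (upper+lower symmetric).
// [[Rcpp::export]]
NumericMatrix cg_contact_counts(NumericVector frames, int n_frames, int n,
                                NumericVector box, IntegerVector chain,
                                double cutoff) {
  NumericMatrix C(n, n);
  const double c2 = cutoff * cutoff;
  for (int f = 0; f < n_frames; ++f) {
    const R_xlen_t off = static_cast<R_xlen_t>(f) * n * 3;
    for (int i = 0; i < n; ++i) {
      double xi = frames[off + i * 3], yi = frames[off + i * 3 + 1],
             zi = frames[off + i * 3 + 2];
      for (int j = i + 1; j < n; ++j) {
        if (chain[i] == chain[j]) continue;
        double dx = wrap1(xi - frames[off + j * 3], box[0]);
        double dy = wrap1(yi - frames[off + j * 3 + 1], box[1]);
        double dz = wrap1(zi - frames[off + j * 3 + 2], box[2]);
        if (dx * dx + dy * dy + dz * dz <= c2) {
          C(i, j) += 1.0; C(j, i) += 1.0;
        }
      }
    }
  }
  return C;
}
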