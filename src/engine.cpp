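// Dual-basin structure-based potential: energies, analytic forces, and a
// BAOAB Langevin integrator in reduced units (k_B = 1, unit epsilon_0,
// lengths in Angstrom). Topologies are passed from R as plain lists of
// term matrices (1-based atom indices, converted here).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// wrap an angle difference into (-pi, pi]
inline double wrap_angle(double d) {
  while (d > M_PI) d -= 2.0 * M_PI;
  while (d <= -M_PI) d += 2.0 * M_PI;
  return d;
}

struct Topology {
  int n_atoms;
  std::vector<double> mass;
  // bonds: i j r0 eps
  std::vector<std::array<double, 4>> bonds;
  // angles: i j k theta0 eps
  std::vector<std::array<double, 5>> angles;
  // harmonic dihedrals (improper/planar): i j k l chi0 eps
  std::vector<std::array<double, 6>> harm_dihedrals;
  // proper dihedrals: i j k l phi0 eps  (eps[(1-cos d)+0.5(1-cos 3d)])
  std::vector<std::array<double, 6>> propers;
  // contacts: i j r_alpha r_beta weight  (NaN marks an absent basin)
  std::vector<std::array<double, 5>> contacts;
  double gauss_A;
  double gauss_sigma;
  double eps_nc;
  double sigma_nc;
  std::unordered_set<long long> excluded; // pairs excluded from excl. volume
};

inline long long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return static_cast<long long>(i) * n + j;
}

Topology parse_topology(const List &topo, int n_atoms) {
  Topology T;
  T.n_atoms = n_atoms;
  NumericVector m = topo["masses"];
  if (m.size() != n_atoms) stop("mass vector length does not match atom count");
  T.mass.assign(m.begin(), m.end());

  NumericMatrix B = topo["bonds"];
  for (int r = 0; r < B.nrow(); ++r)
    T.bonds.push_back({B(r, 0) - 1, B(r, 1) - 1, B(r, 2), B(r, 3)});
  NumericMatrix A = topo["angles"];
  for (int r = 0; r < A.nrow(); ++r)
    T.angles.push_back({A(r, 0) - 1, A(r, 1) - 1, A(r, 2) - 1, A(r, 3), A(r, 4)});
  NumericMatrix H = topo["harm_dihedrals"];
  for (int r = 0; r < H.nrow(); ++r)
    T.harm_dihedrals.push_back({H(r, 0) - 1, H(r, 1) - 1, H(r, 2) - 1,
                                H(r, 3) - 1, H(r, 4), H(r, 5)});
  NumericMatrix P = topo["propers"];
  for (int r = 0; r < P.nrow(); ++r)
    T.propers.push_back({P(r, 0) - 1, P(r, 1) - 1, P(r, 2) - 1, P(r, 3) - 1,
                         P(r, 4), P(r, 5)});
  NumericMatrix C = topo["contacts"];
  for (int r = 0; r < C.nrow(); ++r)
    T.contacts.push_back({C(r, 0) - 1, C(r, 1) - 1, C(r, 2), C(r, 3), C(r, 4)});

  T.gauss_A = as<double>(topo["gauss_A"]);
  T.gauss_sigma = as<double>(topo["gauss_sigma"]);
  T.eps_nc = as<double>(topo["eps_nc"]);
  T.sigma_nc = as<double>(topo["sigma_nc"]);

  // excluded-volume exclusions: all bonded pairs and contact pairs
  for (auto &b : T.bonds)
    T.excluded.insert(pair_key((int)b[0], (int)b[1], n_atoms));
  for (auto &a : T.angles) {
    int i = (int)a[0], j = (int)a[1], k = (int)a[2];
    T.excluded.insert(pair_key(i, j, n_atoms));
    T.excluded.insert(pair_key(j, k, n_atoms));
    T.excluded.insert(pair_key(i, k, n_atoms));
  }
  auto excl4 = [&](const std::array<double, 6> &d) {
    int idx[4] = {(int)d[0], (int)d[1], (int)d[2], (int)d[3]};
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b)
        T.excluded.insert(pair_key(idx[a], idx[b], n_atoms));
  };
  for (auto &d : T.harm_dihedrals) excl4(d);
  for (auto &d : T.propers) excl4(d);
  for (auto &c : T.contacts)
    T.excluded.insert(pair_key((int)c[0], (int)c[1], n_atoms));
  return T;
}

struct EnergyAcc {
  double bond = 0, angle = 0, dihedral = 0, contact = 0, excluded = 0;
  double total() const { return bond + angle + dihedral + contact + excluded; }
};

// Gaussian well factor g = -A exp(-(r-r0)^2/(2 sigma^2)) and its dV/dr
inline double gauss_g(double r, double r0, double A, double sigma) {
  double d = r - r0;
  return -A * std::exp(-d * d / (2.0 * sigma * sigma));
}
inline double gauss_dg(double r, double r0, double A, double sigma) {
  double d = r - r0;
  return -A * std::exp(-d * d / (2.0 * sigma * sigma)) *
         (-d / (sigma * sigma));
}

void eval_forces(const Topology &T, const std::vector<Vec3> &x,
                 std::vector<Vec3> &f, EnergyAcc &E,
                 const std::vector<std::pair<int, int>> &ev_pairs) {
  const int n = T.n_atoms;
  for (int i = 0; i < n; ++i) f[i] = Vec3{0, 0, 0};

  // bonds: eps (r - r0)^2
  for (auto &b : T.bonds) {
    int i = (int)b[0], j = (int)b[1];
    Vec3 d = sub(x[i], x[j]);
    double r = norm(d);
    double dr = r - b[2];
    E.bond += b[3] * dr * dr;
    double fac = -2.0 * b[3] * dr / r;
    f[i].x += fac * d.x; f[i].y += fac * d.y; f[i].z += fac * d.z;
    f[j].x -= fac * d.x; f[j].y -= fac * d.y; f[j].z -= fac * d.z;
  }

  // angles: eps (theta - theta0)^2
  for (auto &a : T.angles) {
    int i = (int)a[0], j = (int)a[1], k = (int)a[2];
    Vec3 rij = sub(x[i], x[j]);
    Vec3 rkj = sub(x[k], x[j]);
    double nij = norm(rij), nkj = norm(rkj);
    double cost = dot(rij, rkj) / (nij * nkj);
    cost = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, cost));
    double theta = std::acos(cost);
    double dth = theta - a[3];
    E.angle += a[4] * dth * dth;
    double dVdtheta = 2.0 * a[4] * dth;
    double sint = std::sqrt(1.0 - cost * cost);
    // force_i = -dV/dr_i = +(dV/dtheta / sin theta) * d(cos theta)/dr_i
    double coef = dVdtheta / sint;
    // d(cos theta)/dri etc.
    Vec3 di{(rkj.x / (nij * nkj)) - cost * rij.x / (nij * nij),
            (rkj.y / (nij * nkj)) - cost * rij.y / (nij * nij),
            (rkj.z / (nij * nkj)) - cost * rij.z / (nij * nij)};
    Vec3 dk{(rij.x / (nij * nkj)) - cost * rkj.x / (nkj * nkj),
            (rij.y / (nij * nkj)) - cost * rkj.y / (nkj * nkj),
            (rij.z / (nij * nkj)) - cost * rkj.z / (nkj * nkj)};
    f[i].x += coef * di.x; f[i].y += coef * di.y; f[i].z += coef * di.z;
    f[k].x += coef * dk.x; f[k].y += coef * dk.y; f[k].z += coef * dk.z;
    f[j].x -= coef * (di.x + dk.x);
    f[j].y -= coef * (di.y + dk.y);
    f[j].z -= coef * (di.z + dk.z);
  }

  // dihedrals (shared geometry helper)
  auto dihedral_force = [&](int i, int j, int k, int l, double dVdphi,
                            double &phi_out) {
    Vec3 b1 = sub(x[j], x[i]);
    Vec3 b2 = sub(x[k], x[j]);
    Vec3 b3 = sub(x[l], x[k]);
    Vec3 n1 = cross(b1, b2);
    Vec3 n2 = cross(b2, b3);
    double nb2 = norm(b2);
    double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
    if (n1sq < 1e-18 || n2sq < 1e-18) { phi_out = 0.0; return; }
    Vec3 m1 = cross(n1, b2);
    double xph = dot(n1, n2);
    double yph = dot(m1, n2) / nb2;
    phi_out = std::atan2(yph, xph);
    // phi = atan2((n1 x b2).n2 / |b2|, n1.n2): with this sign convention
    // dphi/dr_i = +|b2|/|n1|^2 n1 and dphi/dr_l = -|b2|/|n2|^2 n2
    Vec3 fi{nb2 / n1sq * n1.x, nb2 / n1sq * n1.y, nb2 / n1sq * n1.z};
    Vec3 fl{-nb2 / n2sq * n2.x, -nb2 / n2sq * n2.y, -nb2 / n2sq * n2.z};
    double p = dot(b1, b2) / (nb2 * nb2);
    double q = dot(b3, b2) / (nb2 * nb2);
    Vec3 fj{-fi.x - p * fi.x + q * fl.x, -fi.y - p * fi.y + q * fl.y,
            -fi.z - p * fi.z + q * fl.z};
    Vec3 fk{-fl.x + p * fi.x - q * fl.x, -fl.y + p * fi.y - q * fl.y,
            -fl.z + p * fi.z - q * fl.z};
    // force = -dV/dphi * dphi/dr
    f[i].x -= dVdphi * fi.x; f[i].y -= dVdphi * fi.y; f[i].z -= dVdphi * fi.z;
    f[j].x -= dVdphi * fj.x; f[j].y -= dVdphi * fj.y; f[j].z -= dVdphi * fj.z;
    f[k].x -= dVdphi * fk.x; f[k].y -= dVdphi * fk.y; f[k].z -= dVdphi * fk.z;
    f[l].x -= dVdphi * fl.x; f[l].y -= dVdphi * fl.y; f[l].z -= dVdphi * fl.z;
  };

  for (auto &d : T.harm_dihedrals) {
    double phi = 0.0;
    // two passes: need phi first to get dV/dphi; compute geometry twice is
    // wasteful, so compute phi with zero force then apply.
    dihedral_force((int)d[0], (int)d[1], (int)d[2], (int)d[3], 0.0, phi);
    double dchi = wrap_angle(phi - d[4]);
    E.dihedral += d[5] * dchi * dchi;
    dihedral_force((int)d[0], (int)d[1], (int)d[2], (int)d[3],
                   2.0 * d[5] * dchi, phi);
  }
  for (auto &d : T.propers) {
    double phi = 0.0;
    dihedral_force((int)d[0], (int)d[1], (int)d[2], (int)d[3], 0.0, phi);
    double dphi = wrap_angle(phi - d[4]);
    E.dihedral += d[5] * ((1.0 - std::cos(dphi)) +
                          0.5 * (1.0 - std::cos(3.0 * dphi)));
    double dVdphi = d[5] * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
    dihedral_force((int)d[0], (int)d[1], (int)d[2], (int)d[3], dVdphi, phi);
  }

  // contacts: weight * [ (1+(s/r)^12)(1+Ga)(1+Gb) - 1 ]
  const double A = T.gauss_A, sg = T.gauss_sigma, snc = T.sigma_nc;
  for (auto &c : T.contacts) {
    int i = (int)c[0], j = (int)c[1];
    double w = c[4];
    Vec3 d = sub(x[i], x[j]);
    double r = norm(d);
    double rep = std::pow(snc / r, 12);
    double drep = -12.0 * rep / r;
    double ga = 0.0, dga = 0.0, gb = 0.0, dgb = 0.0;
    bool has_a = !ISNAN(c[2]), has_b = !ISNAN(c[3]);
    // a degenerate dual well (identical native distances) is one well:
    // squaring the Gaussian factor would artificially deepen/steepen it
    if (has_a && has_b && c[2] == c[3]) has_b = false;
    if (has_a) { ga = gauss_g(r, c[2], A, sg); dga = gauss_dg(r, c[2], A, sg); }
    if (has_b) { gb = gauss_g(r, c[3], A, sg); dgb = gauss_dg(r, c[3], A, sg); }
    double fa = 1.0 + ga, fb = 1.0 + gb;
    double e, dedr;
    if (has_a && has_b) {
      e = (1.0 + rep) * fa * fb - 1.0;
      dedr = drep * fa * fb + (1.0 + rep) * (dga * fb + fa * dgb);
    } else if (has_a) {
      e = (1.0 + rep) * fa - 1.0;
      dedr = drep * fa + (1.0 + rep) * dga;
    } else {
      e = (1.0 + rep) * fb - 1.0;
      dedr = drep * fb + (1.0 + rep) * dgb;
    }
    E.contact += w * e;
    double fac = -w * dedr / r;
    f[i].x += fac * d.x; f[i].y += fac * d.y; f[i].z += fac * d.z;
    f[j].x -= fac * d.x; f[j].y -= fac * d.y; f[j].z -= fac * d.z;
  }

  // excluded volume: eps_nc (sigma_nc / r)^12 over listed non-bonded pairs
  for (auto &pr : ev_pairs) {
    int i = pr.first, j = pr.second;
    Vec3 d = sub(x[i], x[j]);
    double r = norm(d);
    double rep = std::pow(T.sigma_nc / r, 12);
    E.excluded += T.eps_nc * rep;
    double fac = 12.0 * T.eps_nc * rep / (r * r);
    f[i].x += fac * d.x; f[i].y += fac * d.y; f[i].z += fac * d.z;
    f[j].x -= fac * d.x; f[j].y -= fac * d.y; f[j].z -= fac * d.z;
  }
}

std::vector<std::pair<int, int>> build_ev_pairs(const Topology &T,
                                                const std::vector<Vec3> &x,
                                                double cutoff) {
  std::vector<std::pair<int, int>> out;
  const int n = T.n_atoms;
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      Vec3 d = sub(x[i], x[j]);
      double r2 = dot(d, d);
      if (r2 < c2 && !T.excluded.count(pair_key(i, j, n)))
        out.emplace_back(i, j);
    }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".sbm_energy_forces")]]
List sbm_energy_forces(NumericMatrix coords, List topo) {
  const int n = coords.nrow();
  Topology T = parse_topology(topo, n);
  std::vector<Vec3> x(n), f(n);
  for (int i = 0; i < n; ++i) x[i] = Vec3{coords(i, 0), coords(i, 1), coords(i, 2)};
  // full excluded-volume pair list (no cutoff) for exact energies
  auto ev = build_ev_pairs(T, x, 1e9);
  EnergyAcc E;
  eval_forces(T, x, f, E, ev);
  NumericMatrix fm(n, 3);
  for (int i = 0; i < n; ++i) {
    fm(i, 0) = f[i].x; fm(i, 1) = f[i].y; fm(i, 2) = f[i].z;
  }
  return List::create(
      _["bond"] = E.bond, _["angle"] = E.angle, _["dihedral"] = E.dihedral,
      _["contact"] = E.contact, _["excluded"] = E.excluded,
      _["total"] = E.total(), _["forces"] = fm);
}

// [[Rcpp::export(name = ".sbm_run_langevin")]]
List sbm_run_langevin(NumericMatrix coords, List topo, int n_steps,
                      double dt, double temperature, double friction,
                      int seed, int stride, double ev_cutoff,
                      int nlist_every) {
  const int n = coords.nrow();
  Topology T = parse_topology(topo, n);
  std::vector<Vec3> x(n), v(n), f(n);
  for (int i = 0; i < n; ++i) x[i] = Vec3{coords(i, 0), coords(i, 1), coords(i, 2)};

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  // Maxwell-Boltzmann initial velocities
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(temperature / T.mass[i]);
    v[i] = Vec3{s * gauss(rng), s * gauss(rng), s * gauss(rng)};
  }

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));

  auto ev = build_ev_pairs(T, x, ev_cutoff);
  EnergyAcc E;
  eval_forces(T, x, f, E, ev);

  const int n_frames = n_steps / stride;
  NumericVector step_idx(n_frames), e_tot(n_frames), e_kin(n_frames),
      e_bond(n_frames), e_angle(n_frames), e_dihedral(n_frames),
      e_contact(n_frames), e_excl(n_frames);
  // frames stored as (n_frames) x (3n) matrix to keep one allocation
  NumericMatrix frames(n_frames, 3 * n);

  int frame = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / T.mass[i];
      v[i].x += h * f[i].x; v[i].y += h * f[i].y; v[i].z += h * f[i].z;
    }
    // A
    for (int i = 0; i < n; ++i) {
      x[i].x += 0.5 * dt * v[i].x; x[i].y += 0.5 * dt * v[i].y;
      x[i].z += 0.5 * dt * v[i].z;
    }
    // O
    if (friction > 0) {
      for (int i = 0; i < n; ++i) {
        double s = std::sqrt(temperature / T.mass[i]);
        v[i].x = c1 * v[i].x + c2 * s * gauss(rng);
        v[i].y = c1 * v[i].y + c2 * s * gauss(rng);
        v[i].z = c1 * v[i].z + c2 * s * gauss(rng);
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      x[i].x += 0.5 * dt * v[i].x; x[i].y += 0.5 * dt * v[i].y;
      x[i].z += 0.5 * dt * v[i].z;
    }
    if (step % nlist_every == 0) ev = build_ev_pairs(T, x, ev_cutoff);
    E = EnergyAcc();
    eval_forces(T, x, f, E, ev);
    // B
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / T.mass[i];
      v[i].x += h * f[i].x; v[i].y += h * f[i].y; v[i].z += h * f[i].z;
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i].x) || !std::isfinite(x[i].y) ||
          !std::isfinite(x[i].z))
        stop("unstable integration at step %d, atom %d", step, i + 1);
    }

    if (step % stride == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * T.mass[i] *
              (v[i].x * v[i].x + v[i].y * v[i].y + v[i].z * v[i].z);
      step_idx[frame] = step;
      e_bond[frame] = E.bond; e_angle[frame] = E.angle;
      e_dihedral[frame] = E.dihedral; e_contact[frame] = E.contact;
      e_excl[frame] = E.excluded; e_tot[frame] = E.total();
      e_kin[frame] = ke;
      for (int i = 0; i < n; ++i) {
        frames(frame, 3 * i) = x[i].x;
        frames(frame, 3 * i + 1) = x[i].y;
        frames(frame, 3 * i + 2) = x[i].z;
      }
      ++frame;
    }
  }

  return List::create(
      _["frames"] = frames, _["step_index"] = step_idx,
      _["potential"] = e_tot, _["kinetic"] = e_kin, _["bond"] = e_bond,
      _["angle"] = e_angle, _["dihedral"] = e_dihedral,
      _["contact"] = e_contact, _["excluded"] = e_excl);
}
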