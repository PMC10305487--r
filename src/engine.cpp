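// Spatial-grid kernels: clash detection, neighbor distances, nonbonded
// energies (Coulomb + Lennard-Jones with a CHARMM-style C1 switch), and the
// steepest-descent gradient used by relax(). All coordinates in Angstrom,
// energies in kcal/mol.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Grid {
  double cell;
  std::unordered_map<int64_t, std::vector<int> > bins;
  const NumericMatrix* pts;

  static int64_t key(int ix, int iy, int iz) {
    // pack three 21-bit signed cell indices
    const int64_t off = 1 << 20;
    return (((int64_t)(ix + off)) << 42) | (((int64_t)(iy + off)) << 21) |
           ((int64_t)(iz + off));
  }

  void build(const NumericMatrix& p, double cell_size) {
    pts = &p;
    cell = cell_size > 1e-9 ? cell_size : 1.0;
    bins.clear();
    for (int i = 0; i < p.nrow(); ++i) {
      int ix = (int)std::floor(p(i, 0) / cell);
      int iy = (int)std::floor(p(i, 1) / cell);
      int iz = (int)std::floor(p(i, 2) / cell);
      bins[key(ix, iy, iz)].push_back(i);
    }
  }

  template <class F>
  void neighbours(double x, double y, double z, F fun) const {
    int ix = (int)std::floor(x / cell);
    int iy = (int)std::floor(y / cell);
    int iz = (int)std::floor(z / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = bins.find(key(ix + dx, iy + dy, iz + dz));
          if (it == bins.end()) continue;
          for (int j : it->second) fun(j);
        }
  }
};

inline double dist3(const NumericMatrix& a, int i, const NumericMatrix& b,
                    int j) {
  double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
         dz = a(i, 2) - b(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

}  // namespace

// Clashing atom pairs between two coordinate sets.
// Pair (i,j) clashes iff d < ra[i] + rb[j] - tol (use_radii) or d < hard.
// [[Rcpp::export(name = ".cpp_clash_pairs")]]
List cpp_clash_pairs(NumericMatrix a, NumericVector ra, NumericMatrix b,
                     NumericVector rb, double tol, double hard,
                     bool use_radii, bool first_only) {
  double ra_max = 0, rb_max = 0;
  for (int i = 0; i < ra.size(); ++i) ra_max = std::max(ra_max, ra[i]);
  for (int j = 0; j < rb.size(); ++j) rb_max = std::max(rb_max, rb[j]);
  double thr_max = use_radii ? std::max(0.0, ra_max + rb_max - tol) : hard;

  std::vector<int> ii, jj;
  std::vector<double> dd;
  if (a.nrow() == 0 || b.nrow() == 0 || thr_max <= 0) {
    return List::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
  }
  Grid g;
  g.build(b, thr_max);
  bool done = false;
  for (int i = 0; i < a.nrow() && !done; ++i) {
    g.neighbours(a(i, 0), a(i, 1), a(i, 2), [&](int j) {
      if (done) return;
      double d = dist3(a, i, b, j);
      double thr = use_radii ? (ra[i] + rb[j] - tol) : hard;
      if (d < thr) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(d);
        if (first_only) done = true;
      }
    });
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}

// For each row of a: distance to the nearest row of b (Inf if none within
// `cap`). Used for thioester-contact and Fab-tip contact tests.
// [[Rcpp::export(name = ".cpp_nearest_dist")]]
NumericVector cpp_nearest_dist(NumericMatrix a, NumericMatrix b, double cap) {
  NumericVector out(a.nrow(), R_PosInf);
  if (b.nrow() == 0) return out;
  Grid g;
  g.build(b, cap);
  for (int i = 0; i < a.nrow(); ++i) {
    double best = R_PosInf;
    g.neighbours(a(i, 0), a(i, 1), a(i, 2), [&](int j) {
      double d = dist3(a, i, b, j);
      if (d < best) best = d;
    });
    out[i] = best;
  }
  return out;
}

// Count rows of b within radius r of any row of a (union of spheres).
// [[Rcpp::export(name = ".cpp_count_within")]]
int cpp_count_within(NumericMatrix a, NumericMatrix b, double r) {
  if (a.nrow() == 0 || b.nrow() == 0) return 0;
  Grid g;
  g.build(a, r);
  int n = 0;
  for (int j = 0; j < b.nrow(); ++j) {
    bool hit = false;
    g.neighbours(b(j, 0), b(j, 1), b(j, 2), [&](int i) {
      if (hit) return;
      if (dist3(b, j, a, i) <= r) hit = true;
    });
    if (hit) ++n;
  }
  return n;
}

namespace {

// CHARMM-style C1 switching function and derivative.
inline void switch_fn(double r, double s, double c, double& S, double& dS) {
  if (r <= s) {
    S = 1.0;
    dS = 0.0;
  } else if (r >= c) {
    S = 0.0;
    dS = 0.0;
  } else {
    double c2 = c * c, s2 = s * s, r2 = r * r;
    double denom = (c2 - s2) * (c2 - s2) * (c2 - s2);
    S = (c2 - r2) * (c2 - r2) * (c2 + 2 * r2 - 3 * s2) / denom;
    dS = 12.0 * r * (c2 - r2) * (s2 - r2) / denom;
  }
}

inline void pair_energy(double r, double qi, double qj, double ei, double ej,
                        double ri, double rj, double kcoul, double dielectric,
                        double s, double c, double& elec, double& vdw,
                        double& delec, double& dvdw) {
  double S, dS;
  switch_fn(r, s, c, S, dS);
  double e_raw = kcoul * qi * qj / (dielectric * r);
  double eps = std::sqrt(ei * ej);
  double rmin = 0.5 * (ri + rj);
  double rr6 = std::pow(rmin / r, 6);
  double v_raw = eps * (rr6 * rr6 - 2.0 * rr6);
  elec = e_raw * S;
  vdw = v_raw * S;
  double de_raw = -e_raw / r;
  double dv_raw = -12.0 * eps / r * (rr6 * rr6 - rr6);
  delec = de_raw * S + e_raw * dS;
  dvdw = dv_raw * S + v_raw * dS;
}

}  // namespace

// Nonbonded interaction energy between two disjoint atom groups.
// Returns c(elec, vdw). Exclusions (bonded neighbours) do not apply across
// groups on different molecules; for generality pairs with the same chain
// code and |residue difference| <= excl are skipped.
// [[Rcpp::export(name = ".cpp_group_energy")]]
NumericVector cpp_group_energy(NumericMatrix xa, NumericVector qa,
                               NumericVector ea, NumericVector rma,
                               IntegerVector cha, IntegerVector resa,
                               NumericMatrix xb, NumericVector qb,
                               NumericVector eb, NumericVector rmb,
                               IntegerVector chb, IntegerVector resb,
                               double kcoul, double dielectric, double s,
                               double c, int excl) {
  double elec = 0, vdw = 0;
  if (xa.nrow() == 0 || xb.nrow() == 0)
    return NumericVector::create(elec, vdw);
  Grid g;
  g.build(xb, c);
  for (int i = 0; i < xa.nrow(); ++i) {
    g.neighbours(xa(i, 0), xa(i, 1), xa(i, 2), [&](int j) {
      double d = dist3(xa, i, xb, j);
      if (d >= c || d < 1e-12) return;
      if (cha[i] == chb[j] && std::abs(resa[i] - resb[j]) <= excl) return;
      double el, vd, de, dv;
      pair_energy(d, qa[i], qb[j], ea[i], eb[j], rma[i], rmb[j], kcoul,
                  dielectric, s, c, el, vd, de, dv);
      elec += el;
      vdw += vd;
    });
  }
  return NumericVector::create(elec, vdw);
}

// Residue-pair energy matrix between two groups. Rows/cols indexed by the
// position of each atom's residue in ures_a / ures_b (1-based mapping passed
// in as rowa/rowb). Returns list(elec, vdw) matrices.
// [[Rcpp::export(name = ".cpp_residue_matrix")]]
List cpp_residue_matrix(NumericMatrix xa, NumericVector qa, NumericVector ea,
                        NumericVector rma, IntegerVector rowa,
                        NumericMatrix xb, NumericVector qb, NumericVector eb,
                        NumericVector rmb, IntegerVector rowb, int nra,
                        int nrb, double kcoul, double dielectric, double s,
                        double c) {
  NumericMatrix elec(nra, nrb), vdw(nra, nrb);
  if (xa.nrow() == 0 || xb.nrow() == 0)
    return List::create(_["elec"] = elec, _["vdw"] = vdw);
  Grid g;
  g.build(xb, c);
  for (int i = 0; i < xa.nrow(); ++i) {
    g.neighbours(xa(i, 0), xa(i, 1), xa(i, 2), [&](int j) {
      double d = dist3(xa, i, xb, j);
      if (d >= c || d < 1e-12) return;
      double el, vd, de, dv;
      pair_energy(d, qa[i], qb[j], ea[i], eb[j], rma[i], rmb[j], kcoul,
                  dielectric, s, c, el, vd, de, dv);
      elec(rowa[i] - 1, rowb[j] - 1) += el;
      vdw(rowa[i] - 1, rowb[j] - 1) += vd;
    });
  }
  return List::create(_["elec"] = elec, _["vdw"] = vdw);
}

// Total nonbonded energy of one configuration plus its gradient.
// chain/res arrays give the 1..2 bond exclusion (same chain, |dres| <= excl).
// bonds: two-column matrix of 1-based atom indices with harmonic terms.
// Pairs where both atoms are fixed contribute a constant and zero mobile
// gradient, so they are excluded from the reported energy.
// [[Rcpp::export(name = ".cpp_system_energy_gradient")]]
List cpp_system_energy_gradient(NumericMatrix x, NumericVector q,
                                NumericVector e, NumericVector rm,
                                IntegerVector ch, IntegerVector res,
                                LogicalVector fixed, IntegerMatrix bonds,
                                double bond_k, double bond_r0, double kcoul,
                                double dielectric, double s, double c,
                                int excl, bool want_gradient) {
  int n = x.nrow();
  NumericMatrix grad(want_gradient ? n : 1, 3);
  double energy = 0;
  Grid g;
  g.build(x, c);
  for (int i = 0; i < n; ++i) {
    g.neighbours(x(i, 0), x(i, 1), x(i, 2), [&](int j) {
      if (j <= i) return;
      if (fixed[i] && fixed[j]) return;
      double d = dist3(x, i, x, j);
      if (d >= c || d < 1e-12) return;
      if (ch[i] == ch[j] && std::abs(res[i] - res[j]) <= excl) return;
      double el, vd, de, dv;
      pair_energy(d, q[i], q[j], e[i], e[j], rm[i], rm[j], kcoul, dielectric,
                  s, c, el, vd, de, dv);
      energy += el + vd;
      if (want_gradient) {
        double f = (de + dv) / d;
        for (int k = 0; k < 3; ++k) {
          double dxk = x(i, k) - x(j, k);
          grad(i, k) += f * dxk;
          grad(j, k) -= f * dxk;
        }
      }
    });
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double d = dist3(x, i, x, j);
    double dev = d - bond_r0;
    energy += bond_k * dev * dev;
    if (want_gradient && d > 1e-12) {
      double f = 2.0 * bond_k * dev / d;
      for (int k = 0; k < 3; ++k) {
        double dxk = x(i, k) - x(j, k);
        grad(i, k) += f * dxk;
        grad(j, k) -= f * dxk;
      }
    }
  }
  return List::create(_["energy"] = energy, _["gradient"] = grad);
}
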