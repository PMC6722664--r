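#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Square-well triad evaluation. Energies are in h-bond units. All
// intermolecular terms act between heavy atoms only; hydrogens enter the
// model upstream (donor detection) and are skipped here.

struct Params {
  double e_hb, hb_cutoff, e_el1, e_el2, w1, wc, hp_scale, clash_weight;
  bool mixed;
};

static Params read_params(const List& p) {
  Params q;
  q.e_hb = as<double>(p["e_hb"]);
  q.hb_cutoff = as<double>(p["hb_cutoff"]);
  q.e_el1 = as<double>(p["e_el1"]);
  q.e_el2 = as<double>(p["e_el2"]);
  q.w1 = as<double>(p["el_well1_scale"]);
  q.wc = as<double>(p["el_cutoff_scale"]);
  q.hp_scale = as<double>(p["hp_cutoff_scale"]);
  q.clash_weight = as<double>(p["clash_weight"]);
  q.mixed = as<bool>(p["mixed_hydropathy"]);
  return q;
}

struct Atoms {
  NumericMatrix xyz;     // heavy atoms only
  NumericVector vdw, hp;
  IntegerVector donor, acceptor, charge, hpclass; // hpclass 0/1/2
  int n;
};

static Atoms read_atoms(const List& a) {
  Atoms at;
  at.xyz = as<NumericMatrix>(a["xyz"]);
  at.vdw = as<NumericVector>(a["vdw"]);
  at.hp = as<NumericVector>(a["hp"]);
  at.donor = as<IntegerVector>(a["donor"]);
  at.acceptor = as<IntegerVector>(a["acceptor"]);
  at.charge = as<IntegerVector>(a["charge"]);
  at.hpclass = as<IntegerVector>(a["hpclass"]);
  at.n = at.xyz.nrow();
  return at;
}

struct PairOut {
  std::vector<int> i, j, kind; // kind: 1 hbond, 2 el, 3 hp, 4 clash
  std::vector<double> r, sigma, energy;
  void push(int a, int b, int k, double rr, double s, double e) {
    i.push_back(a); j.push_back(b); kind.push_back(k);
    r.push_back(rr); sigma.push_back(s); energy.push_back(e);
  }
};

// Evaluate one intermolecular heavy-atom pair; accumulates energy,
// contact and clash counts; optionally records PairInteraction rows.
static inline void eval_pair(const Atoms& A, int i, const Atoms& B, int j,
                             double dx, double dy, double dz,
                             const Params& p, double& U, int& ncont,
                             int& nclash, PairOut* out) {
  double sigma = A.vdw[i] + B.vdw[j];
  double r2 = dx * dx + dy * dy + dz * dz;
  double rmax = p.wc * sigma;
  if (p.hb_cutoff > rmax) rmax = p.hb_cutoff;
  double hpcut = p.hp_scale * sigma;
  if (hpcut > rmax) rmax = hpcut;
  if (r2 >= rmax * rmax) return;
  double r = std::sqrt(r2);
  if (r < sigma) {
    ++nclash;
    if (out) out->push(i, j, 4, r, sigma, 0.0);
    return;
  }
  bool contact = false;
  if ((A.donor[i] && B.acceptor[j]) || (B.donor[j] && A.acceptor[i])) {
    if (r < p.hb_cutoff) {
      U += p.e_hb;
      contact = true;
      if (out) out->push(i, j, 1, r, sigma, p.e_hb);
    }
  }
  if (A.charge[i] != 0 && B.charge[j] != 0) {
    int s = A.charge[i] * B.charge[j];
    double e = 0.0;
    if (r > sigma && r < p.w1 * sigma) e = s * p.e_el1;
    else if (r >= p.w1 * sigma && r < p.wc * sigma) e = s * p.e_el2;
    if (e != 0.0) {
      U += e;
      contact = true;
      if (out) out->push(i, j, 2, r, sigma, e);
    }
  }
  if (A.hpclass[i] != 0 && B.hpclass[j] != 0 &&
      (p.mixed || A.hpclass[i] == B.hpclass[j]) && r < hpcut) {
    double e = A.hp[i] + B.hp[j];
    U += e;
    contact = true;
    if (out) out->push(i, j, 3, r, sigma, e);
  }
  if (contact) ++ncont;
}

// ---- cell list over the fixed unit ----------------------------------

struct CellList {
  double cell, x0, y0, z0;
  int nx, ny, nz;
  std::unordered_map<long long, std::vector<int> > cells;
  long long key(int ix, int iy, int iz) const {
    // exact packed key (collision-free for |index| < 2^20)
    return ((long long)(ix + 1048576)) |
           ((long long)(iy + 1048576) << 21) |
           ((long long)(iz + 1048576) << 42);
  }
  void build(const NumericMatrix& xyz, double cell_size) {
    cell = cell_size;
    x0 = y0 = z0 = R_PosInf;
    for (int i = 0; i < xyz.nrow(); ++i) {
      if (xyz(i, 0) < x0) x0 = xyz(i, 0);
      if (xyz(i, 1) < y0) y0 = xyz(i, 1);
      if (xyz(i, 2) < z0) z0 = xyz(i, 2);
    }
    cells.clear();
    for (int i = 0; i < xyz.nrow(); ++i) {
      int ix = (int)std::floor((xyz(i, 0) - x0) / cell);
      int iy = (int)std::floor((xyz(i, 1) - y0) / cell);
      int iz = (int)std::floor((xyz(i, 2) - z0) / cell);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
};

static double max_cutoff(const Atoms& A, const Atoms& B, const Params& p) {
  double ra = 0, rb = 0;
  for (int i = 0; i < A.n; ++i) if (A.vdw[i] > ra) ra = A.vdw[i];
  for (int j = 0; j < B.n; ++j) if (B.vdw[j] > rb) rb = B.vdw[j];
  double smax = ra + rb;
  double m = p.hb_cutoff;
  if (p.wc * smax > m) m = p.wc * smax;
  if (p.hp_scale * smax > m) m = p.hp_scale * smax;
  return m;
}

static void eval_all(const Atoms& F, const CellList& cl, const Atoms& M,
                     const NumericMatrix& mxyz, const Params& p,
                     double& U, int& ncont, int& nclash, PairOut* out) {
  U = 0.0; ncont = 0; nclash = 0;
  for (int j = 0; j < M.n; ++j) {
    double mx = mxyz(j, 0), my = mxyz(j, 1), mz = mxyz(j, 2);
    int ix = (int)std::floor((mx - cl.x0) / cl.cell);
    int iy = (int)std::floor((my - cl.y0) / cl.cell);
    int iz = (int)std::floor((mz - cl.z0) / cl.cell);
    for (int a = ix - 1; a <= ix + 1; ++a)
      for (int b = iy - 1; b <= iy + 1; ++b)
        for (int c = iz - 1; c <= iz + 1; ++c) {
          std::unordered_map<long long, std::vector<int> >::const_iterator
            it = cl.cells.find(cl.key(a, b, c));
          if (it == cl.cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t k = 0; k < v.size(); ++k) {
            int i = v[k];
            eval_pair(F, i, M, j, F.xyz(i, 0) - mx, F.xyz(i, 1) - my,
                      F.xyz(i, 2) - mz, p, U, ncont, nclash, out);
          }
        }
  }
}

// [[Rcpp::export]]
List cpp_interface_energy(List fixed, List mobile, List params,
                          bool want_pairs, bool naive) {
  Atoms F = read_atoms(fixed), M = read_atoms(mobile);
  Params p = read_params(params);
  double U = 0.0;
  int ncont = 0, nclash = 0;
  PairOut out;
  PairOut* po = want_pairs ? &out : 0;
  if (naive) {
    for (int i = 0; i < F.n; ++i)
      for (int j = 0; j < M.n; ++j)
        eval_pair(F, i, M, j, F.xyz(i, 0) - M.xyz(j, 0),
                  F.xyz(i, 1) - M.xyz(j, 1), F.xyz(i, 2) - M.xyz(j, 2),
                  p, U, ncont, nclash, po);
  } else {
    CellList cl;
    cl.build(F.xyz, max_cutoff(F, M, p));
    eval_all(F, cl, M, M.xyz, p, U, ncont, nclash, po);
  }
  List res = List::create(_["U"] = U, _["n_contacts"] = ncont,
                          _["n_clashes"] = nclash);
  if (want_pairs)
    res["pairs"] = DataFrame::create(
      _["i"] = wrap(out.i), _["j"] = wrap(out.j),
      _["kind"] = wrap(out.kind), _["r"] = wrap(out.r),
      _["sigma"] = wrap(out.sigma), _["energy"] = wrap(out.energy));
  return res;
}

// Objective over a batch of translations of an already-rotated mobile
// unit (naive pair loop; used by the exhaustive grid-search oracle).
// [[Rcpp::export]]
NumericMatrix cpp_grid_objective(List fixed, List mobile,
                                 NumericMatrix rotated, NumericMatrix trans,
                                 List params) {
  Atoms F = read_atoms(fixed), M = read_atoms(mobile);
  Params p = read_params(params);
  NumericMatrix out(trans.nrow(), 4);
  for (int k = 0; k < trans.nrow(); ++k) {
    double U = 0.0;
    int nc = 0, nk = 0;
    for (int i = 0; i < F.n; ++i)
      for (int j = 0; j < rotated.nrow(); ++j)
        eval_pair(F, i, M, j,
                  F.xyz(i, 0) - (rotated(j, 0) + trans(k, 0)),
                  F.xyz(i, 1) - (rotated(j, 1) + trans(k, 1)),
                  F.xyz(i, 2) - (rotated(j, 2) + trans(k, 2)),
                  p, U, nc, nk, 0);
    out(k, 0) = U + p.clash_weight * nk;
    out(k, 1) = U;
    out(k, 2) = nc;
    out(k, 3) = nk;
  }
  return out;
}

// ---- rigid-body Metropolis annealing --------------------------------

static inline void quat_rotate(const double* q, double x, double y, double z,
                               double* out) {
  // rotate vector by unit quaternion (w, x, y, z)
  double w = q[0], qx = q[1], qy = q[2], qz = q[3];
  double tx = 2.0 * (qy * z - qz * y);
  double ty = 2.0 * (qz * x - qx * z);
  double tz = 2.0 * (qx * y - qy * x);
  out[0] = x + w * tx + (qy * tz - qz * ty);
  out[1] = y + w * ty + (qz * tx - qx * tz);
  out[2] = z + w * tz + (qx * ty - qy * tx);
}

static inline void quat_mult(const double* a, const double* b, double* c) {
  c[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  c[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  c[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  c[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

static void place_mobile(const NumericMatrix& mxyz0, const double* c0,
                         const double* q, const double* t,
                         NumericMatrix& out) {
  double v[3];
  for (int i = 0; i < mxyz0.nrow(); ++i) {
    quat_rotate(q, mxyz0(i, 0) - c0[0], mxyz0(i, 1) - c0[1],
                mxyz0(i, 2) - c0[2], v);
    out(i, 0) = v[0] + t[0];
    out(i, 1) = v[1] + t[1];
    out(i, 2) = v[2] + t[2];
  }
}

// [[Rcpp::export]]
List cpp_mc_dock(List fixed, List mobile, List params,
                 NumericVector q0, NumericVector t0, NumericVector c0,
                 int n_steps, double t_start, double t_end,
                 double rot_max, double trans_max, double min_separation,
                 double max_separation) {
  Atoms F = read_atoms(fixed), M = read_atoms(mobile);
  Params p = read_params(params);
  CellList cl;
  cl.build(F.xyz, max_cutoff(F, M, p));

  double q[4] = {q0[0], q0[1], q0[2], q0[3]};
  double t[3] = {t0[0], t0[1], t0[2]};
  double cm[3] = {c0[0], c0[1], c0[2]};
  NumericMatrix mx(M.n, 3);
  place_mobile(M.xyz, cm, q, t, mx);

  double U;
  int nc, nk;
  eval_all(F, cl, M, mx, p, U, nc, nk, 0);
  double Fcur = U + p.clash_weight * nk;
  double bq[4] = {q[0], q[1], q[2], q[3]};
  double bt[3] = {t[0], t[1], t[2]};
  double Fbest = Fcur;
  NumericVector trace(n_steps);
  int accepted = 0;
  double cool = (n_steps > 1) ? std::pow(t_end / t_start,
                                         1.0 / (n_steps - 1)) : 1.0;
  double temp = t_start;
  double rot_rad = rot_max * M_PI / 180.0;

  for (int step = 0; step < n_steps; ++step) {
    double nq[4] = {q[0], q[1], q[2], q[3]};
    double nt[3] = {t[0], t[1], t[2]};
    bool valid = true;
    double mv = unif_rand();
    if (mv < 0.5) {
      // rotation: random axis, angle <= rot_max. A spin reorients the
      // mobile unit about its own center; an orbit rotates it rigidly
      // about the origin, reorienting the instantaneous docking axis.
      bool orbit = unif_rand() < 0.5;
      double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
      double an = std::sqrt(ax * ax + ay * ay + az * az);
      if (an < 1e-12) { ax = 1; ay = 0; az = 0; an = 1; }
      double ang = rot_rad * unif_rand();
      double s = std::sin(ang / 2.0) / an;
      double dq[4] = {std::cos(ang / 2.0), ax * s, ay * s, az * s};
      quat_mult(dq, q, nq);
      double nn = std::sqrt(nq[0] * nq[0] + nq[1] * nq[1] +
                            nq[2] * nq[2] + nq[3] * nq[3]);
      for (int k = 0; k < 4; ++k) nq[k] /= nn;
      if (orbit) quat_rotate(dq, t[0], t[1], t[2], nt);
    } else {
      // translation along the docking axis (origin -> mobile center)
      double s = std::sqrt(t[0] * t[0] + t[1] * t[1] + t[2] * t[2]);
      double d = trans_max * unif_rand();
      if (unif_rand() < 0.5) d = -d;
      double s2 = s + d;
      if (s2 < min_separation || s2 > max_separation) valid = false;
      else {
        double f = s2 / s;
        nt[0] = t[0] * f; nt[1] = t[1] * f; nt[2] = t[2] * f;
      }
    }
    if (valid) {
      place_mobile(M.xyz, cm, nq, nt, mx);
      double U2;
      int nc2, nk2;
      eval_all(F, cl, M, mx, p, U2, nc2, nk2, 0);
      double F2 = U2 + p.clash_weight * nk2;
      bool acc = F2 <= Fcur || unif_rand() < std::exp(-(F2 - Fcur) / temp);
      if (acc) {
        for (int k = 0; k < 4; ++k) q[k] = nq[k];
        for (int k = 0; k < 3; ++k) t[k] = nt[k];
        Fcur = F2;
        ++accepted;
        if (F2 < Fbest) {
          Fbest = F2;
          for (int k = 0; k < 4; ++k) bq[k] = q[k];
          for (int k = 0; k < 3; ++k) bt[k] = t[k];
        }
      }
    }
    trace[step] = Fbest;
    temp *= cool;
  }
  return List::create(_["q"] = NumericVector::create(bq[0], bq[1], bq[2],
                                                     bq[3]),
                      _["t"] = NumericVector::create(bt[0], bt[1], bt[2]),
                      _["best_F"] = Fbest, _["trace"] = trace,
                      _["accepted"] = accepted);
}
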