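#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// kcal/(mol*A) -> pN
static const double FORCE_PN = 69.479;

namespace {

struct PairKey {
  static inline long long key(int i, int j, int n) {
    return (long long)i * (long long)n + (long long)j;
  }
};

struct System {
  int n;
  std::vector<double> x, y, z;
  std::vector<int> bi, bj;            // bonds (0-based, i<j)
  std::vector<double> br0;
  std::vector<int> ci, cj;            // native contacts (0-based, i<j)
  std::vector<double> cr0, ceps;
  std::vector<int> chain, seq;        // chain index, within-chain position
  std::unordered_set<long long> excl; // bonded or native pairs (i<j)
  double fene_k, fene_R0, eps_l, sigma, kBT, zeta;
  double rep_cutoff; // absolute, A
};

inline double dist3(const System& s, int i, int j, double& dx, double& dy, double& dz) {
  dx = s.x[i] - s.x[j];
  dy = s.y[i] - s.y[j];
  dz = s.z[i] - s.z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// accumulates forces (negative gradient) and the three energy terms;
// returns false (with info in *bad) on FENE overstretch
bool eval_forces(const System& s, std::vector<double>& fx, std::vector<double>& fy,
                 std::vector<double>& fz, double& v_fene, double& v_att, double& v_rep,
                 int* bad_bond) {
  const int n = s.n;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  v_fene = v_att = v_rep = 0.0;
  const double R02 = s.fene_R0 * s.fene_R0;

  // FENE bonds
  for (size_t b = 0; b < s.bi.size(); ++b) {
    int i = s.bi[b], j = s.bj[b];
    double dx, dy, dz;
    double r = dist3(s, i, j, dx, dy, dz);
    double d = r - s.br0[b];
    double w = 1.0 - d * d / R02;
    if (w <= 0.0) { *bad_bond = (int)b; return false; }
    v_fene += -0.5 * s.fene_k * R02 * std::log(w);
    // dV/dr = k*d/w ; force on i = -dV/dr * (ri-rj)/r
    double fmag = -s.fene_k * d / w / std::max(r, 1e-12);
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }

  // native attractive LJ (no cutoff: fixed list)
  for (size_t c = 0; c < s.ci.size(); ++c) {
    int i = s.ci[c], j = s.cj[c];
    double dx, dy, dz;
    double r = dist3(s, i, j, dx, dy, dz);
    double q6 = std::pow(s.cr0[c] / r, 6.0);
    v_att += s.ceps[c] * (q6 * q6 - 2.0 * q6);
    // dV/dr = -12 eps/r (q12 - q6); force on i = -dV/dr * unit = +12 eps/r^2 (q12-q6) * d
    double fmag = 12.0 * s.ceps[c] * (q6 * q6 - q6) / (r * r);
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
  }

  // repulsive LJ over non-native, non-bonded pairs; the |i-j|=2 intra-chain term
  // is always included, other pairs only within rep_cutoff
  const double rc2 = s.rep_cutoff * s.rep_cutoff;
  const double sig6 = std::pow(s.sigma, 6.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool same_chain = s.chain[i] == s.chain[j];
      int sep = same_chain ? std::abs(s.seq[i] - s.seq[j]) : -1;
      if (s.excl.count(PairKey::key(i, j, n))) continue;
      if (same_chain && sep == 1) continue; // backbone handled by FENE
      double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      bool always = same_chain && sep == 2;
      if (!always && r2 > rc2) continue;
      double r = std::sqrt(r2);
      double v = s.eps_l * sig6 / (r2 * r2 * r2);
      v_rep += v;
      double fmag = 6.0 * v / r2; // -dV/dr / r, dV/dr = -6 v / r
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
  }
  return true;
}

System make_system(NumericMatrix coords, List topo, List params) {
  System s;
  s.n = coords.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = coords(i, 0); s.y[i] = coords(i, 1); s.z[i] = coords(i, 2);
  }
  IntegerVector bi = topo["bond_i"], bj = topo["bond_j"];
  NumericVector br0 = topo["bond_r0"];
  IntegerVector ci = topo["con_i"], cj = topo["con_j"];
  NumericVector cr0 = topo["con_r0"], ceps = topo["con_eps"];
  IntegerVector chain = topo["chain"], seq = topo["seq"];
  s.bi.assign(bi.begin(), bi.end());
  s.bj.assign(bj.begin(), bj.end());
  s.br0.assign(br0.begin(), br0.end());
  s.ci.assign(ci.begin(), ci.end());
  s.cj.assign(cj.begin(), cj.end());
  s.cr0.assign(cr0.begin(), cr0.end());
  s.ceps.assign(ceps.begin(), ceps.end());
  s.chain.assign(chain.begin(), chain.end());
  s.seq.assign(seq.begin(), seq.end());
  for (size_t b = 0; b < s.bi.size(); ++b)
    s.excl.insert(PairKey::key(std::min(s.bi[b], s.bj[b]), std::max(s.bi[b], s.bj[b]), s.n));
  for (size_t c = 0; c < s.ci.size(); ++c)
    s.excl.insert(PairKey::key(std::min(s.ci[c], s.cj[c]), std::max(s.ci[c], s.cj[c]), s.n));
  s.fene_k = as<double>(params["fene_k"]);
  s.fene_R0 = as<double>(params["fene_R0"]);
  s.eps_l = as<double>(params["eps_l"]);
  s.sigma = as<double>(params["sigma"]);
  s.kBT = as<double>(params["kBT"]);
  s.zeta = as<double>(params["zeta_eff"]);
  s.rep_cutoff = as<double>(params["rep_cutoff"]);
  return s;
}

} // namespace

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, List topo, List params) {
  System s = make_system(coords, topo, params);
  std::vector<double> fx(s.n), fy(s.n), fz(s.n);
  double vf, va, vr;
  int bad = -1;
  if (!eval_forces(s, fx, fy, fz, vf, va, vr, &bad))
    stop("FENE bond %d-%d overstretched: |r - r0| >= R0", s.bi[bad] + 1, s.bj[bad] + 1);
  NumericMatrix forces(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    forces(i, 0) = fx[i]; forces(i, 1) = fy[i]; forces(i, 2) = fz[i];
  }
  return List::create(_["v_fene"] = vf, _["v_att"] = va, _["v_rep"] = vr,
                      _["v_total"] = vf + va + vr, _["forces"] = forces);
}

// Overdamped Brownian propagation with optional cantilever, constant external
// forces and harmonic restraints. Each nominal step dt is subdivided into
// n_sub Euler-Maruyama substeps for stability of the stiff FENE term.
// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix coords, List topo, List params,
                LogicalVector fixed, int n_steps, int output_every,
                Nullable<NumericMatrix> ext_force,
                Nullable<List> cantilever,
                Nullable<List> traps,
                int n_sub, double max_disp) {
  System s = make_system(coords, topo, params);
  const int n = s.n;
  const double dt = as<double>(params["dt"]);
  const double h = dt / (double)n_sub;
  const double mob = h / s.zeta;
  const double noise_sd = (s.kBT > 0.0) ? std::sqrt(2.0 * s.kBT * h / s.zeta) : 0.0;

  bool has_ext = ext_force.isNotNull();
  NumericMatrix ext;
  if (has_ext) ext = NumericMatrix(ext_force);

  bool has_cant = cantilever.isNotNull();
  int pulled = -1, n_av = 1;
  double k_trans = 0.0, dx_c = 0.0;
  std::vector<double> dir(3, 0.0), anchor(3, 0.0), pulled0(3, 0.0);
  if (has_cant) {
    List cl(cantilever);
    pulled = as<int>(cl["pulled_bead"]) - 1;
    NumericVector d = cl["direction"];
    for (int k = 0; k < 3; ++k) dir[k] = d[k];
    k_trans = as<double>(cl["k_trans"]);
    dx_c = as<double>(cl["dx"]);
    n_av = as<int>(cl["n_av"]);
    NumericVector a0 = cl["anchor0"];
    for (int k = 0; k < 3; ++k) anchor[k] = a0[k];
    pulled0[0] = s.x[pulled]; pulled0[1] = s.y[pulled]; pulled0[2] = s.z[pulled];
  }

  bool has_traps = traps.isNotNull();
  std::vector<int> trap_idx;
  NumericMatrix trap_ctr;
  double trap_k = 0.0;
  if (has_traps) {
    List tl(traps);
    IntegerVector ti = tl["idx"];
    for (int k = 0; k < ti.size(); ++k) trap_idx.push_back(ti[k] - 1);
    trap_ctr = as<NumericMatrix>(tl["centers"]);
    trap_k = as<double>(tl["k"]);
  }

  std::vector<double> fx(n), fy(n), fz(n);
  int n_rec = n_steps / output_every;
  std::vector<double> frames;
  frames.reserve((size_t)n_rec * n * 3);
  std::vector<double> tr_time, tr_ext, tr_force, tr_vf, tr_va, tr_vr;
  tr_time.reserve(n_rec); tr_ext.reserve(n_rec); tr_force.reserve(n_rec);
  tr_vf.reserve(n_rec); tr_va.reserve(n_rec); tr_vr.reserve(n_rec);

  double vf, va, vr;
  int bad = -1;
  for (int step = 1; step <= n_steps; ++step) {
    if (has_cant && (step % n_av == 0))
      for (int k = 0; k < 3; ++k) anchor[k] += dx_c * dir[k];
    for (int sub = 0; sub < n_sub; ++sub) {
      if (!eval_forces(s, fx, fy, fz, vf, va, vr, &bad))
        stop("FENE bond %d-%d overstretched at step %d", s.bi[bad] + 1, s.bj[bad] + 1, step);
      if (has_ext)
        for (int i = 0; i < n; ++i) {
          fx[i] += ext(i, 0); fy[i] += ext(i, 1); fz[i] += ext(i, 2);
        }
      if (has_cant) {
        fx[pulled] += k_trans * (anchor[0] - s.x[pulled]);
        fy[pulled] += k_trans * (anchor[1] - s.y[pulled]);
        fz[pulled] += k_trans * (anchor[2] - s.z[pulled]);
      }
      if (has_traps)
        for (size_t t = 0; t < trap_idx.size(); ++t) {
          int i = trap_idx[t];
          fx[i] += trap_k * (trap_ctr(t, 0) - s.x[i]);
          fy[i] += trap_k * (trap_ctr(t, 1) - s.y[i]);
          fz[i] += trap_k * (trap_ctr(t, 2) - s.z[i]);
        }
      for (int i = 0; i < n; ++i) {
        if (fixed[i]) continue;
        double ddx = mob * fx[i], ddy = mob * fy[i], ddz = mob * fz[i];
        double dd = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
        if (dd > max_disp) { // cap the drift: guards the FENE wall only
          double sc = max_disp / dd;
          ddx *= sc; ddy *= sc; ddz *= sc;
        }
        if (noise_sd > 0.0) {
          ddx += noise_sd * norm_rand();
          ddy += noise_sd * norm_rand();
          ddz += noise_sd * norm_rand();
        }
        s.x[i] += ddx; s.y[i] += ddy; s.z[i] += ddz;
      }
    }
    if (step % output_every == 0) {
      for (int i = 0; i < n; ++i) {
        frames.push_back(s.x[i]); frames.push_back(s.y[i]); frames.push_back(s.z[i]);
      }
      tr_time.push_back((double)step * dt);
      if (has_cant) {
        double e = (s.x[pulled] - pulled0[0]) * dir[0] + (s.y[pulled] - pulled0[1]) * dir[1] +
                   (s.z[pulled] - pulled0[2]) * dir[2];
        double f = k_trans * ((anchor[0] - s.x[pulled]) * dir[0] +
                              (anchor[1] - s.y[pulled]) * dir[1] +
                              (anchor[2] - s.z[pulled]) * dir[2]);
        tr_ext.push_back(e);
        tr_force.push_back(f * FORCE_PN);
      } else {
        tr_ext.push_back(NA_REAL);
        tr_force.push_back(NA_REAL);
      }
      tr_vf.push_back(vf); tr_va.push_back(va); tr_vr.push_back(vr);
    }
  }

  NumericMatrix final_coords(n, 3);
  for (int i = 0; i < n; ++i) {
    final_coords(i, 0) = s.x[i]; final_coords(i, 1) = s.y[i]; final_coords(i, 2) = s.z[i];
  }
  NumericVector fr(frames.begin(), frames.end());
  // stored bead-major within frame: dim = (3, n, n_rec) then aperm in R
  fr.attr("dim") = IntegerVector::create(3, n, (int)tr_time.size());
  NumericVector anchor_out(3);
  for (int k = 0; k < 3; ++k) anchor_out[k] = anchor[k];
  return List::create(
      _["frames"] = fr, _["coords"] = final_coords,
      _["time"] = NumericVector(tr_time.begin(), tr_time.end()),
      _["extension"] = NumericVector(tr_ext.begin(), tr_ext.end()),
      _["force_pN"] = NumericVector(tr_force.begin(), tr_force.end()),
      _["v_fene"] = NumericVector(tr_vf.begin(), tr_vf.end()),
      _["v_att"] = NumericVector(tr_va.begin(), tr_va.end()),
      _["v_rep"] = NumericVector(tr_vr.begin(), tr_vr.end()),
      _["anchor"] = anchor_out);
}
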