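#include <Rcpp.h>
using namespace Rcpp;

// Fast path for the MCM engine: apply a degree-of-freedom parameter vector
// to the base coordinates and evaluate the objective, entirely in C++.
// The parameter layout matches the R-side state layout:
//   [ligand trans(3), ligand rotvec(3)] [ligand torsions] [side-chain chis]
//   [per-rigid-group trans(3)+rotvec(3)] [per-Cartesian-atom xyz(3)]
// Restraint projection (planes: axial coordinate reset; axial: rigid radial
// translation of the restrained group) is applied after the transforms,
// exactly as in the R reference implementation.

struct Blob {
  bool has_pose;
  IntegerVector lig_idx, ltor_a1, ltor_a2, chi_a1, chi_a2, cart_idx;
  std::vector<IntegerVector> ltor_moving, chi_moving, rigid_groups,
      axial_group;
  NumericVector axis_point, axis_dir;
  IntegerVector plane_atom, axial_atom, pin_atom;
  NumericVector plane_z, axial_rho, pin_free, pin_k;
  NumericMatrix pin_template;
  IntegerVector pair_i, pair_j, spring_i, spring_j;
  NumericVector pair_rmin, pair_eps, pair_qfac, pair_scale, spring_r0,
      spring_k;
  LogicalVector pair_ion, pair_cross;
  double cutoff, static_energy, torsion_barrier;
  bool use_vdw, use_elec;
  IntegerVector tor_a1, tor_a2, tor_ref, tor_mv;
};

static void parse_blob(List b, Blob &B) {
  B.has_pose = as<bool>(b["has_pose"]);
  B.lig_idx = b["lig_idx"];
  B.ltor_a1 = b["ltor_a1"]; B.ltor_a2 = b["ltor_a2"];
  B.chi_a1 = b["chi_a1"]; B.chi_a2 = b["chi_a2"];
  B.cart_idx = b["cart_idx"];
  List lm = b["ltor_moving"], cm = b["chi_moving"], rg = b["rigid_groups"],
       ag = b["axial_group"];
  for (int i = 0; i < lm.size(); ++i) B.ltor_moving.push_back(lm[i]);
  for (int i = 0; i < cm.size(); ++i) B.chi_moving.push_back(cm[i]);
  for (int i = 0; i < rg.size(); ++i) B.rigid_groups.push_back(rg[i]);
  for (int i = 0; i < ag.size(); ++i) B.axial_group.push_back(ag[i]);
  B.axis_point = b["axis_point"]; B.axis_dir = b["axis_dir"];
  B.plane_atom = b["plane_atom"]; B.plane_z = b["plane_z"];
  B.axial_atom = b["axial_atom"]; B.axial_rho = b["axial_rho"];
  B.pin_atom = b["pin_atom"]; B.pin_template = as<NumericMatrix>(b["pin_template"]);
  B.pin_free = b["pin_free"]; B.pin_k = b["pin_k"];
  B.pair_i = b["pair_i"]; B.pair_j = b["pair_j"];
  B.pair_rmin = b["pair_rmin"]; B.pair_eps = b["pair_eps"];
  B.pair_qfac = b["pair_qfac"]; B.pair_scale = b["pair_scale"];
  B.pair_ion = b["pair_ion"]; B.pair_cross = b["pair_cross"];
  B.spring_i = b["spring_i"]; B.spring_j = b["spring_j"];
  B.spring_r0 = b["spring_r0"]; B.spring_k = b["spring_k"];
  B.cutoff = as<double>(b["cutoff"]);
  B.use_vdw = as<bool>(b["use_vdw"]); B.use_elec = as<bool>(b["use_elec"]);
  B.static_energy = as<double>(b["static_energy"]);
  B.torsion_barrier = as<double>(b["torsion_barrier"]);
  B.tor_a1 = b["tor_a1"]; B.tor_a2 = b["tor_a2"];
  B.tor_ref = b["tor_ref"]; B.tor_mv = b["tor_mv"];
}

static void rotvec_matrix(const double *w, double R[3][3]) {
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (th < 1e-12) {
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) R[a][b] = (a == b);
    return;
  }
  double k[3] = {w[0] / th, w[1] / th, w[2] / th};
  double c = std::cos(th), s = std::sin(th), v = 1.0 - c;
  R[0][0] = c + k[0] * k[0] * v;
  R[0][1] = k[0] * k[1] * v - k[2] * s;
  R[0][2] = k[0] * k[2] * v + k[1] * s;
  R[1][0] = k[1] * k[0] * v + k[2] * s;
  R[1][1] = c + k[1] * k[1] * v;
  R[1][2] = k[1] * k[2] * v - k[0] * s;
  R[2][0] = k[2] * k[0] * v - k[1] * s;
  R[2][1] = k[2] * k[1] * v + k[0] * s;
  R[2][2] = c + k[2] * k[2] * v;
}

static void rotate_set(std::vector<double> &xyz, const IntegerVector &idx,
                       const double R[3][3], const double *ctr) {
  for (int t = 0; t < idx.size(); ++t) {
    int i = (idx[t] - 1) * 3;
    double p[3] = {xyz[i] - ctr[0], xyz[i + 1] - ctr[1], xyz[i + 2] - ctr[2]};
    for (int a = 0; a < 3; ++a)
      xyz[i + a] = R[a][0] * p[0] + R[a][1] * p[1] + R[a][2] * p[2] + ctr[a];
  }
}

static void rotate_bond(std::vector<double> &xyz, int a1, int a2,
                        const IntegerVector &moving, double phi) {
  if (phi == 0.0) return;
  int i1 = (a1 - 1) * 3, i2 = (a2 - 1) * 3;
  double ax[3] = {xyz[i2] - xyz[i1], xyz[i2 + 1] - xyz[i1 + 1],
                  xyz[i2 + 2] - xyz[i1 + 2]};
  double n = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  if (n < 1e-12) return;
  double w[3] = {ax[0] / n * phi, ax[1] / n * phi, ax[2] / n * phi};
  double R[3][3];
  rotvec_matrix(w, R);
  double ctr[3] = {xyz[i2], xyz[i2 + 1], xyz[i2 + 2]};
  rotate_set(xyz, moving, R, ctr);
}

static double dihedral(const std::vector<double> &xyz, int i1, int i2,
                       int i3, int i4) {
  double b1[3], b2[3], b3[3];
  for (int a = 0; a < 3; ++a) {
    b1[a] = xyz[i2 * 3 + a] - xyz[i1 * 3 + a];
    b2[a] = xyz[i3 * 3 + a] - xyz[i2 * 3 + a];
    b3[a] = xyz[i4 * 3 + a] - xyz[i3 * 3 + a];
  }
  double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1],
                  b1[2] * b2[0] - b1[0] * b2[2],
                  b1[0] * b2[1] - b1[1] * b2[0]};
  double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1],
                  b2[2] * b3[0] - b2[0] * b3[2],
                  b2[0] * b3[1] - b2[1] * b3[0]};
  double nb2 = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
  double m1[3] = {(n1[1] * b2[2] - n1[2] * b2[1]) / nb2,
                  (n1[2] * b2[0] - n1[0] * b2[2]) / nb2,
                  (n1[0] * b2[1] - n1[1] * b2[0]) / nb2};
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double y = m1[0] * n2[0] + m1[1] * n2[1] + m1[2] * n2[2];
  return std::atan2(y, x);
}

// Transform base coordinates by the parameter vector, then project the
// plane/axial constraints.
static void transform(const double *par, const NumericMatrix &base,
                      const Blob &B, std::vector<double> &xyz) {
  int n = base.nrow();
  xyz.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) xyz[i * 3 + a] = base(i, a);
  int pose_off = B.has_pose ? 6 : 0;
  for (int k = 0; k < B.ltor_a1.size(); ++k)
    rotate_bond(xyz, B.ltor_a1[k], B.ltor_a2[k], B.ltor_moving[k],
                par[pose_off + k]);
  if (B.has_pose) {
    double ctr[3] = {0, 0, 0};
    for (int t = 0; t < B.lig_idx.size(); ++t)
      for (int a = 0; a < 3; ++a) ctr[a] += base(B.lig_idx[t] - 1, a);
    for (int a = 0; a < 3; ++a) ctr[a] /= B.lig_idx.size();
    double w[3] = {par[3], par[4], par[5]};
    if (w[0] != 0 || w[1] != 0 || w[2] != 0) {
      double R[3][3];
      rotvec_matrix(w, R);
      rotate_set(xyz, B.lig_idx, R, ctr);
    }
    for (int t = 0; t < B.lig_idx.size(); ++t)
      for (int a = 0; a < 3; ++a)
        xyz[(B.lig_idx[t] - 1) * 3 + a] += par[a];
  }
  int off = pose_off + B.ltor_a1.size();
  for (int k = 0; k < B.chi_a1.size(); ++k)
    rotate_bond(xyz, B.chi_a1[k], B.chi_a2[k], B.chi_moving[k], par[off + k]);
  off += B.chi_a1.size();
  for (size_t g = 0; g < B.rigid_groups.size(); ++g) {
    const IntegerVector &idx = B.rigid_groups[g];
    double w[3] = {par[off + 3], par[off + 4], par[off + 5]};
    if (w[0] != 0 || w[1] != 0 || w[2] != 0) {
      double ctr[3] = {0, 0, 0};
      for (int t = 0; t < idx.size(); ++t)
        for (int a = 0; a < 3; ++a) ctr[a] += base(idx[t] - 1, a);
      for (int a = 0; a < 3; ++a) ctr[a] /= idx.size();
      double R[3][3];
      rotvec_matrix(w, R);
      rotate_set(xyz, idx, R, ctr);
    }
    for (int t = 0; t < idx.size(); ++t)
      for (int a = 0; a < 3; ++a)
        xyz[(idx[t] - 1) * 3 + a] += par[off + a];
    off += 6;
  }
  for (int k = 0; k < B.cart_idx.size(); ++k)
    for (int a = 0; a < 3; ++a)
      xyz[(B.cart_idx[k] - 1) * 3 + a] += par[off + 3 * k + a];
  // plane projection
  const double *ap = B.axis_point.begin(), *ad = B.axis_dir.begin();
  for (int k = 0; k < B.plane_atom.size(); ++k) {
    int i = (B.plane_atom[k] - 1) * 3;
    double z = 0;
    for (int a = 0; a < 3; ++a) z += (xyz[i + a] - ap[a]) * ad[a];
    for (int a = 0; a < 3; ++a) xyz[i + a] += (B.plane_z[k] - z) * ad[a];
  }
  // axial projection (rigid radial shift of the restrained group)
  for (int k = 0; k < B.axial_atom.size(); ++k) {
    int i = (B.axial_atom[k] - 1) * 3;
    double rel[3], z = 0;
    for (int a = 0; a < 3; ++a) rel[a] = xyz[i + a] - ap[a];
    for (int a = 0; a < 3; ++a) z += rel[a] * ad[a];
    double rad[3];
    for (int a = 0; a < 3; ++a) rad[a] = rel[a] - z * ad[a];
    double rho = std::sqrt(rad[0] * rad[0] + rad[1] * rad[1] +
                           rad[2] * rad[2]);
    double dir[3];
    if (rho < 1e-9) {
      double ref[3] = {std::abs(ad[0]) < 0.9 ? 1.0 : 0.0,
                       std::abs(ad[0]) < 0.9 ? 0.0 : 1.0, 0.0};
      double dp = ref[0] * ad[0] + ref[1] * ad[1] + ref[2] * ad[2];
      double nn = 0;
      for (int a = 0; a < 3; ++a) {
        dir[a] = ref[a] - dp * ad[a];
        nn += dir[a] * dir[a];
      }
      nn = std::sqrt(nn);
      for (int a = 0; a < 3; ++a) dir[a] /= nn;
    } else {
      for (int a = 0; a < 3; ++a) dir[a] = rad[a] / rho;
    }
    const IntegerVector &grp = B.axial_group[k];
    double shift = B.axial_rho[k] - rho;
    for (int t = 0; t < grp.size(); ++t)
      for (int a = 0; a < 3; ++a)
        xyz[(grp[t] - 1) * 3 + a] += shift * dir[a];
  }
}

static double energy(const std::vector<double> &xyz, const Blob &B) {
  double c2 = B.cutoff * B.cutoff;
  double evdw = 0, eel = 0;
  int np = B.pair_i.size();
  for (int k = 0; k < np; ++k) {
    int i = (B.pair_i[k] - 1) * 3, j = (B.pair_j[k] - 1) * 3;
    double dx = xyz[i] - xyz[j];
    double dy = xyz[i + 1] - xyz[j + 1];
    double dz = xyz[i + 2] - xyz[j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    bool within = r2 < c2;
    double sw = 0;
    if (within) { double u = 1.0 - r2 / c2; sw = u * u; }
    if (B.use_vdw && within && B.pair_eps[k] != 0) {
      double s2 = B.pair_rmin[k] * B.pair_rmin[k] / r2;
      double s6 = s2 * s2 * s2;
      evdw += B.pair_eps[k] * (s6 * s6 - 2.0 * s6) * sw * B.pair_scale[k];
    }
    if (B.use_elec && B.pair_qfac[k] != 0) {
      if (B.pair_ion[k]) eel += B.pair_qfac[k] / r2 * B.pair_scale[k];
      else if (within) eel += B.pair_qfac[k] / r2 * sw * B.pair_scale[k];
    }
  }
  double e = evdw + eel + B.static_energy;
  for (int k = 0; k < B.spring_i.size(); ++k) {
    int i = (B.spring_i[k] - 1) * 3, j = (B.spring_j[k] - 1) * 3;
    double dx = xyz[i] - xyz[j], dy = xyz[i + 1] - xyz[j + 1],
           dz = xyz[i + 2] - xyz[j + 2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) - B.spring_r0[k];
    e += B.spring_k[k] * d * d;
  }
  for (int k = 0; k < B.tor_a1.size(); ++k) {
    double phi = dihedral(xyz, B.tor_ref[k] - 1, B.tor_a1[k] - 1,
                          B.tor_a2[k] - 1, B.tor_mv[k] - 1);
    e += B.torsion_barrier / 2.0 * (1.0 + std::cos(3.0 * phi));
  }
  for (int k = 0; k < B.pin_atom.size(); ++k) {
    int i = (B.pin_atom[k] - 1) * 3;
    double dx = xyz[i] - B.pin_template(k, 0);
    double dy = xyz[i + 1] - B.pin_template(k, 1);
    double dz = xyz[i + 2] - B.pin_template(k, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) - B.pin_free[k];
    if (d > 0) e += B.pin_k[k] * d * d;
  }
  return e;
}

// [[Rcpp::export]]
NumericMatrix mcm_transform(NumericVector par, NumericMatrix base,
                            List blob) {
  Blob B;
  parse_blob(blob, B);
  std::vector<double> xyz;
  transform(par.begin(), base, B, xyz);
  NumericMatrix out(base.nrow(), 3);
  for (int i = 0; i < base.nrow(); ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = xyz[i * 3 + a];
  return out;
}

// [[Rcpp::export]]
double mcm_objective(NumericVector par, NumericMatrix base, List blob) {
  Blob B;
  parse_blob(blob, B);
  std::vector<double> xyz;
  transform(par.begin(), base, B, xyz);
  return energy(xyz, B);
}

// Forward-difference gradient of the objective, computed entirely in C++
// (one blob parse and no R round trips).
// [[Rcpp::export]]
NumericVector mcm_gradient(NumericVector par, NumericMatrix base, List blob,
                           double h = 1e-5) {
  Blob B;
  parse_blob(blob, B);
  int n = par.size();
  NumericVector g(n);
  std::vector<double> xyz, p(par.begin(), par.end());
  transform(&p[0], base, B, xyz);
  double e0 = energy(xyz, B);
  for (int k = 0; k < n; ++k) {
    p[k] = par[k] + h;
    transform(&p[0], base, B, xyz);
    g[k] = (energy(xyz, B) - e0) / h;
    p[k] = par[k];
  }
  return g;
}

// Full minimization driver is on the R side (stats::optim L-BFGS-B with
// this objective/gradient pair).
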