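#include <Rcpp.h>
using namespace Rcpp;

// Nonbonded pair-energy kernel.
//
// Pair constants (rmin, eps, qfac, ionized flag, 1-4 scale, cross flag) are
// precomputed once per energy context in R; this kernel only walks the pair
// list for the current coordinates.
//
// vdW: 12-6 Lennard-Jones, eps*((rm/r)^12 - 2*(rm/r)^6), multiplied by the
// shifting function S(r) = (1 - (r/c)^2)^2 so energy and first derivative
// vanish exactly at the cutoff c.
// Electrostatics: qfac / r^2 (qfac = 332.06*qi*qj/eps0, i.e. a distance-
// dependent dielectric eps0*r).  Pairs involving an ionized group are exempt
// from the cutoff; all other pairs are shifted to zero at the cutoff.
// [[Rcpp::export]]
NumericVector nb_pair_energy(NumericMatrix xyz,
                             IntegerVector pi, IntegerVector pj,
                             NumericVector rmin, NumericVector eps,
                             NumericVector qfac, LogicalVector ion,
                             NumericVector scale, LogicalVector cross,
                             double cutoff, bool do_vdw, bool do_elec) {
  const int np = pi.size();
  const double c2 = cutoff * cutoff;
  double evdw = 0.0, eel = 0.0, xvdw = 0.0, xel = 0.0;
  for (int k = 0; k < np; ++k) {
    const int i = pi[k] - 1, j = pj[k] - 1;
    const double dx = xyz(i, 0) - xyz(j, 0);
    const double dy = xyz(i, 1) - xyz(j, 1);
    const double dz = xyz(i, 2) - xyz(j, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    const bool within = r2 < c2;
    double sw = 0.0;
    if (within) {
      const double u = 1.0 - r2 / c2;
      sw = u * u;
    }
    double ev = 0.0, ee = 0.0;
    if (do_vdw && within && eps[k] != 0.0) {
      const double s2 = rmin[k] * rmin[k] / r2;
      const double s6 = s2 * s2 * s2;
      ev = eps[k] * (s6 * s6 - 2.0 * s6) * sw * scale[k];
    }
    if (do_elec && qfac[k] != 0.0) {
      if (ion[k]) {
        ee = qfac[k] / r2 * scale[k];
      } else if (within) {
        ee = qfac[k] / r2 * sw * scale[k];
      }
    }
    evdw += ev;
    eel += ee;
    if (cross[k]) { xvdw += ev; xel += ee; }
  }
  return NumericVector::create(_["vdw"] = evdw, _["elec"] = eel,
                               _["cross_vdw"] = xvdw, _["cross_elec"] = xel);
}

// Minimum heavy-atom distance from each residue-group to any ligand atom.
// groups: 1-based start index of each group in ch_xyz plus end sentinel.
// [[Rcpp::export]]
NumericVector min_group_dist(NumericMatrix ch_xyz, NumericMatrix lig_xyz,
                             IntegerVector gstart, IntegerVector gend) {
  const int ng = gstart.size(), nl = lig_xyz.nrow();
  NumericVector out(ng);
  for (int g = 0; g < ng; ++g) {
    double best = R_PosInf;
    for (int i = gstart[g] - 1; i < gend[g]; ++i) {
      for (int j = 0; j < nl; ++j) {
        const double dx = ch_xyz(i, 0) - lig_xyz(j, 0);
        const double dy = ch_xyz(i, 1) - lig_xyz(j, 1);
        const double dz = ch_xyz(i, 2) - lig_xyz(j, 2);
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
    }
    out[g] = std::sqrt(best);
  }
  return out;
}
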