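#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nonbonded kernels for rigid four-site charge-on-spring water.
//
// Site layout: five consecutive rows per molecule in the order
// O, H1, H2, M, COS.  The charge vector has one entry per slot; in the
// GROMOS convention the M slot carries q_M - q_COS and the COS slot q_COS.
//
// Cutoff handling is molecular (charge-group based): a molecule pair is
// included if and only if the O-O minimum-image distance is below the
// cutoff, and every site pair of an included molecule pair uses that same
// image shift.  This keeps whole (neutral) molecules on either side of the
// cutoff and avoids monopole artefacts from cutting through dipoles.
//
// The total pair energy (Coulomb + reaction field + van der Waals) is
// multiplied by a quintic switching function S(r_OO) that goes smoothly
// from 1 at r_sw to 0 at r_c; without it the residual molecule-pair energy
// at the crossing (order of the dipole-dipole interaction at r_c) is
// discontinuous and pumps heat into the system in small boxes.  The
// gradient of S contributes a force along the O-O axis.  Setting
// r_sw >= r_c (or <= 0) disables switching (plain molecular truncation).
//
// Reaction field beyond the cutoff (relative permittivity eps_rf enters via
// crf = (2 eps_rf - 2)/(2 eps_rf + 1)):
//   V(r) = felec qi qj [ 1/r + crf r^2/(2 rc^3) - (1 + crf/2)/rc ]
// which vanishes at r = rc.

static inline void switch_fn(double r, double rsw, double rc,
                             double &S, double &dS) {
  if (r <= rsw) { S = 1.0; dS = 0.0; return; }
  if (r >= rc)  { S = 0.0; dS = 0.0; return; }
  const double x = (r - rsw) / (rc - rsw);
  const double x2 = x * x;
  S = 1.0 + x2 * x * (-10.0 + x * (15.0 - 6.0 * x));
  dS = x2 * (-30.0 + x * (60.0 - 30.0 * x)) / (rc - rsw);
}

// [[Rcpp::export]]
List cos_nb_kernel(NumericMatrix pos, NumericVector q, NumericMatrix com,
                   double L, double rc, double rsw, double crf,
                   double c6, double c8, double c11, double felec) {
  const int nsite = 5;
  const int n = pos.nrow();
  const int nmol = n / nsite;
  const bool pbc = L > 0.0;
  const bool cut = rc > 0.0;
  const bool sw = cut && rsw > 0.0 && rsw < rc;
  const double rc2 = cut ? rc * rc : 0.0;
  const double krf = cut ? crf / (2.0 * rc * rc * rc) : 0.0;
  const double vshift = cut ? (1.0 + 0.5 * crf) / rc : 0.0;

  double ecoul = 0.0, evdw = 0.0, vir = 0.0;
  NumericMatrix F(n, 3);
  double fa[nsite][3], fb[nsite][3];

  for (int a = 0; a < nmol; ++a) {
    const int ra = a * nsite;
    for (int b = a + 1; b < nmol; ++b) {
      const int rb = b * nsite;
      // image shift from the O-O separation
      double sx = 0.0, sy = 0.0, sz = 0.0;
      double dx = pos(ra, 0) - pos(rb, 0);
      double dy = pos(ra, 1) - pos(rb, 1);
      double dz = pos(ra, 2) - pos(rb, 2);
      if (pbc) {
        sx = -L * std::nearbyint(dx / L);
        sy = -L * std::nearbyint(dy / L);
        sz = -L * std::nearbyint(dz / L);
      }
      const double ox = dx + sx, oy = dy + sy, oz = dz + sz;
      const double r2oo = ox * ox + oy * oy + oz * oz;
      if (cut && r2oo > rc2) continue;
      const double roo = std::sqrt(r2oo);

      for (int i = 0; i < nsite; ++i)
        for (int k = 0; k < 3; ++k) { fa[i][k] = 0.0; fb[i][k] = 0.0; }
      double ec = 0.0, ev = 0.0;

      // van der Waals between oxygen sites
      {
        if (r2oo < 1e-12) stop("cos_nb_kernel: O-O pair at zero separation");
        const double ir2 = 1.0 / r2oo;
        const double ir6 = ir2 * ir2 * ir2;
        const double ir11 = ir6 * ir2 * ir2 / roo;
        ev = -c6 * ir6 - c8 * ir6 * ir2 + c11 * ir11;
        const double fr = (-6.0 * c6 * ir6 - 8.0 * c8 * ir6 * ir2 +
                           11.0 * c11 * ir11) * ir2;
        fa[0][0] += fr * ox; fa[0][1] += fr * oy; fa[0][2] += fr * oz;
        fb[0][0] -= fr * ox; fb[0][1] -= fr * oy; fb[0][2] -= fr * oz;
      }

      // Coulomb + reaction field over charged site pairs
      for (int i = 0; i < nsite; ++i) {
        const double qi = q[i];
        if (qi == 0.0) continue;
        const double xi = pos(ra + i, 0), yi = pos(ra + i, 1), zi = pos(ra + i, 2);
        for (int j = 0; j < nsite; ++j) {
          const double qj = q[j];
          if (qj == 0.0) continue;
          const double rx = xi - pos(rb + j, 0) + sx;
          const double ry = yi - pos(rb + j, 1) + sy;
          const double rz = zi - pos(rb + j, 2) + sz;
          const double r2 = rx * rx + ry * ry + rz * rz;
          if (r2 < 1e-12) stop("cos_nb_kernel: charge pair at zero separation");
          const double r = std::sqrt(r2);
          const double qq = felec * qi * qj;
          ec += qq * (1.0 / r + krf * r2 - vshift);
          const double fr = qq * (1.0 / (r2 * r) - 2.0 * krf);
          fa[i][0] += fr * rx; fa[i][1] += fr * ry; fa[i][2] += fr * rz;
          fb[j][0] -= fr * rx; fb[j][1] -= fr * ry; fb[j][2] -= fr * rz;
        }
      }

      double S = 1.0, dS = 0.0;
      if (sw) switch_fn(roo, rsw, rc, S, dS);
      ecoul += S * ec;
      evdw  += S * ev;

      double fabx = 0.0, faby = 0.0, fabz = 0.0;  // total force on molecule a
      for (int i = 0; i < nsite; ++i) {
        F(ra + i, 0) += S * fa[i][0]; F(ra + i, 1) += S * fa[i][1];
        F(ra + i, 2) += S * fa[i][2];
        F(rb + i, 0) += S * fb[i][0]; F(rb + i, 1) += S * fb[i][1];
        F(rb + i, 2) += S * fb[i][2];
        fabx += S * fa[i][0]; faby += S * fa[i][1]; fabz += S * fa[i][2];
      }
      if (sw && dS != 0.0) {
        // -d(S)/d(r_a) (ec + ev): acts along the O-O axis on the oxygens
        const double g = -(ec + ev) * dS / roo;
        F(ra, 0) += g * ox; F(ra, 1) += g * oy; F(ra, 2) += g * oz;
        F(rb, 0) -= g * ox; F(rb, 1) -= g * oy; F(rb, 2) -= g * oz;
        fabx += g * ox; faby += g * oy; fabz += g * oz;
      }

      // molecular virial: total pair force dotted with the COM separation
      const double cx = com(a, 0) - com(b, 0) + sx;
      const double cy = com(a, 1) - com(b, 1) + sy;
      const double cz = com(a, 2) - com(b, 2) + sz;
      vir += fabx * cx + faby * cy + fabz * cz;
    }
  }
  return List::create(_["ecoul"] = ecoul, _["evdw"] = evdw,
                      _["virial"] = vir, _["forces"] = F);
}

// Electric field at one target position per molecule (the M site or the COS
// particle), from all sites of all *other* molecules, with the same
// molecular cutoff/switching rule and reaction-field distance dependence as
// the energy kernel (the switching factor S(r_OO) multiplies the
// electrostatic pair energy, hence also the field its gradient exerts on
// the charge-on-spring particle):
//   E(r) = felec sum_j S qj (1/r^3 - crf/rc^3) rvec

// [[Rcpp::export]]
NumericMatrix cos_field_kernel(NumericMatrix pos, NumericVector q,
                               NumericMatrix targets,
                               double L, double rc, double rsw, double crf,
                               double felec) {
  const int nsite = 5;
  const int nmol = pos.nrow() / nsite;
  const bool pbc = L > 0.0;
  const bool cut = rc > 0.0;
  const bool sw = cut && rsw > 0.0 && rsw < rc;
  const double rc2 = cut ? rc * rc : 0.0;
  const double krf2 = cut ? crf / (rc * rc * rc) : 0.0;  // 2*krf

  NumericMatrix E(nmol, 3);
  for (int a = 0; a < nmol; ++a) {
    const int ra = a * nsite;
    const double tx = targets(a, 0), ty = targets(a, 1), tz = targets(a, 2);
    double ex = 0.0, ey = 0.0, ez = 0.0;
    for (int b = 0; b < nmol; ++b) {
      if (b == a) continue;
      const int rb = b * nsite;
      double sx = 0.0, sy = 0.0, sz = 0.0;
      double dx = pos(ra, 0) - pos(rb, 0);
      double dy = pos(ra, 1) - pos(rb, 1);
      double dz = pos(ra, 2) - pos(rb, 2);
      if (pbc) {
        sx = -L * std::nearbyint(dx / L);
        sy = -L * std::nearbyint(dy / L);
        sz = -L * std::nearbyint(dz / L);
      }
      double S = 1.0, dS = 0.0;
      if (cut) {
        const double ox = dx + sx, oy = dy + sy, oz = dz + sz;
        const double r2oo = ox * ox + oy * oy + oz * oz;
        if (r2oo > rc2) continue;
        if (sw) switch_fn(std::sqrt(r2oo), rsw, rc, S, dS);
      }
      for (int j = 0; j < nsite; ++j) {
        const double qj = q[j];
        if (qj == 0.0) continue;
        const double rx = tx - pos(rb + j, 0) + sx;
        const double ry = ty - pos(rb + j, 1) + sy;
        const double rz = tz - pos(rb + j, 2) + sz;
        const double r2 = rx * rx + ry * ry + rz * rz;
        if (r2 < 1e-12) stop("cos_field_kernel: target coincides with a charge");
        const double r = std::sqrt(r2);
        const double c = S * felec * qj * (1.0 / (r2 * r) - krf2);
        ex += c * rx; ey += c * ry; ez += c * rz;
      }
    }
    E(a, 0) = ex; E(a, 1) = ey; E(a, 2) = ez;
  }
  return E;
}
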