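#include <Rcpp.h>
using namespace Rcpp;

// Explicit sub-stepped update of the FHN reaction at every vertex.
// All parameter vectors are per-vertex (length n). stim is nu*h(t) per
// vertex, held constant over the step. Returns nothing; v and w are
// modified in place (they are duplicated on the R side when needed).
// [[Rcpp::export(name = ".react_step")]]
void react_step(NumericVector v, NumericVector w,
                const NumericVector& stim,
                const NumericVector& k,
                const NumericVector& v1, const NumericVector& v2,
                const NumericVector& v3,
                const NumericVector& inv_e1cm,
                const NumericVector& e2,
                const NumericVector& beta, const NumericVector& gamma,
                const NumericVector& delta,
                double dt, int nsub) {
  const int n = v.size();
  const double h = dt / nsub;
  for (int s = 0; s < nsub; ++s) {
    for (int i = 0; i < n; ++i) {
      const double vi = v[i], wi = w[i];
      const double cub = k[i] * (vi - v1[i]) * (v2[i] - vi) * (vi - v3[i]);
      const double dv = (cub - wi + stim[i]) * inv_e1cm[i];
      const double dw = e2[i] * (beta[i] * vi - gamma[i] * wi + delta[i]);
      v[i] = vi + h * dv;
      w[i] = wi + h * dw;
    }
  }
}

// Biot-Savart superposition of current-dipole fields:
// B(p) = mu0/4pi * sum_e Q_e x (p - r_e) / |p - r_e|^3.
// Throws if any evaluation point is closer than excl to a dipole.
// [[Rcpp::export(name = ".bs_field")]]
NumericMatrix bs_field(const NumericMatrix& points,
                       const NumericMatrix& dip_pos,
                       const NumericMatrix& dip_mom,
                       double excl) {
  const int np = points.nrow(), nd = dip_pos.nrow();
  const double c0 = 1e-7; // mu0 / 4pi
  NumericMatrix B(np, 3);
  const double e2 = excl * excl;
  for (int p = 0; p < np; ++p) {
    double bx = 0, by = 0, bz = 0;
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    for (int d = 0; d < nd; ++d) {
      const double rx = px - dip_pos(d, 0);
      const double ry = py - dip_pos(d, 1);
      const double rz = pz - dip_pos(d, 2);
      const double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 < e2)
        stop("singular evaluation: point inside dipole exclusion radius");
      const double inv_r3 = 1.0 / (r2 * std::sqrt(r2));
      const double qx = dip_mom(d, 0), qy = dip_mom(d, 1), qz = dip_mom(d, 2);
      bx += (qy * rz - qz * ry) * inv_r3;
      by += (qz * rx - qx * rz) * inv_r3;
      bz += (qx * ry - qy * rx) * inv_r3;
    }
    B(p, 0) = c0 * bx; B(p, 1) = c0 * by; B(p, 2) = c0 * bz;
  }
  return B;
}
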