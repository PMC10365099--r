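// 3D total-variation denoising, Chambolle's dual projection algorithm
// (rudin-osher-fatemi model). Weight convention: larger weight = stronger
// smoothing; the dual variable is rescaled by the weight so `weight` plays
// the role of the fidelity trade-off lambda.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
arma::cube cpp_tv_chambolle(const arma::cube& image, double weight, double eps,
                            int max_iter) {
  const uword nx = image.n_rows, ny = image.n_cols, nz = image.n_slices;
  cube p0(nx, ny, nz, fill::zeros), p1(nx, ny, nz, fill::zeros),
      p2(nx, ny, nz, fill::zeros);
  cube g0(nx, ny, nz, fill::zeros), g1(nx, ny, nz, fill::zeros),
      g2(nx, ny, nz, fill::zeros);
  cube d(nx, ny, nz, fill::zeros);
  cube out = image;
  const double tau = 1.0 / (2.0 * 3.0);
  double E_init = 0.0, E_prev = 0.0;
  for (int i = 0; i < max_iter; ++i) {
    if (i > 0) {
      // d = divergence of p (adjoint of forward differences)
      d = -(p0 + p1 + p2);
      for (uword z = 0; z < nz; ++z)
        for (uword y = 0; y < ny; ++y)
          for (uword x = 1; x < nx; ++x) d(x, y, z) += p0(x - 1, y, z);
      for (uword z = 0; z < nz; ++z)
        for (uword y = 1; y < ny; ++y)
          for (uword x = 0; x < nx; ++x) d(x, y, z) += p1(x, y - 1, z);
      for (uword z = 1; z < nz; ++z)
        for (uword y = 0; y < ny; ++y)
          for (uword x = 0; x < nx; ++x) d(x, y, z) += p2(x, y, z - 1);
      out = image + d;
    }
    double E = accu(d % d);
    // forward differences of the current estimate
    g0.zeros(); g1.zeros(); g2.zeros();
    for (uword z = 0; z < nz; ++z)
      for (uword y = 0; y < ny; ++y)
        for (uword x = 0; x + 1 < nx; ++x)
          g0(x, y, z) = out(x + 1, y, z) - out(x, y, z);
    for (uword z = 0; z < nz; ++z)
      for (uword y = 0; y + 1 < ny; ++y)
        for (uword x = 0; x < nx; ++x)
          g1(x, y, z) = out(x, y + 1, z) - out(x, y, z);
    for (uword z = 0; z + 1 < nz; ++z)
      for (uword y = 0; y < ny; ++y)
        for (uword x = 0; x < nx; ++x)
          g2(x, y, z) = out(x, y, z + 1) - out(x, y, z);
    for (uword z = 0; z < nz; ++z)
      for (uword y = 0; y < ny; ++y)
        for (uword x = 0; x < nx; ++x) {
          double nrm = std::sqrt(g0(x, y, z) * g0(x, y, z) +
                                 g1(x, y, z) * g1(x, y, z) +
                                 g2(x, y, z) * g2(x, y, z));
          E += weight * nrm;
          double scale = 1.0 + nrm * tau / weight;
          p0(x, y, z) = (p0(x, y, z) - tau * g0(x, y, z)) / scale;
          p1(x, y, z) = (p1(x, y, z) - tau * g1(x, y, z)) / scale;
          p2(x, y, z) = (p2(x, y, z) - tau * g2(x, y, z)) / scale;
        }
    E /= (double)image.n_elem;
    if (i == 0) {
      E_init = E;
      E_prev = E;
    } else {
      if (std::fabs(E_prev - E) < eps * E_init) break;
      E_prev = E;
    }
  }
  return out;
}
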