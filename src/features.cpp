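// Batched per-partition conformational features.  Positions arrive in nm as
// cubes indexed (observation, bead, axis); axis 0 = x (flow), 1 = y
// (vorticity), 2 = z (gradient).  One call computes the 17 per-partition
// features of one contour segment for every observation.  Scalar reference
// implementations of the same quantities live in R and serve as the oracle
// for this fast path in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// order eigenpairs by descending eigenvalue; among (near-)ties prefer the
// eigenvector most aligned with x, then y, then z, so degenerate
// configurations give a deterministic answer.
static void order_eigs(const arma::vec &eval, const arma::mat &evec,
                       int *ord) {
  ord[0] = 2; ord[1] = 1; ord[2] = 0;  // eig_sym returns ascending
  const double tol = 1e-12 * std::max(1.0, std::abs(eval(2)));
  for (int a = 0; a < 3; ++a) {
    for (int b = a + 1; b < 3; ++b) {
      if (std::abs(eval(ord[a]) - eval(ord[b])) <= tol) {
        // tie: prefer larger |v_x|, then larger |v_y|
        const double ax = std::abs(evec(0, ord[a])), bx = std::abs(evec(0, ord[b]));
        const double ay = std::abs(evec(1, ord[a])), by = std::abs(evec(1, ord[b]));
        if (bx > ax + 1e-12 || (std::abs(bx - ax) <= 1e-12 && by > ay + 1e-12))
          std::swap(ord[a], ord[b]);
      }
    }
  }
}

// [[Rcpp::export(name = ".seg_features")]]
arma::mat seg_features_cpp(const arma::cube &pos_t, const arma::cube &pos_prev,
                           int start, int end, double lcc_threshold,
                           double dt_s, double shear_rate) {
  const int nobs = pos_t.n_rows;
  const int nbead = pos_t.n_cols;
  if (end <= start || end > nbead) stop("bad partition range");
  const int k = end - start;
  arma::mat out(nobs, 17);

  for (int o = 0; o < nobs; ++o) {
    // per-axis accumulators over the partition
    double com[3], comp[3], mx[3], mn[3];
    for (int ax = 0; ax < 3; ++ax) {
      double s = 0.0, sp = 0.0;
      double lo = pos_t(o, start, ax), hi = lo;
      for (int b = start; b < end; ++b) {
        const double v = pos_t(o, b, ax);
        s += v;
        sp += pos_prev(o, b, ax);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      com[ax] = s / k;
      comp[ax] = sp / k;
      mn[ax] = lo;
      mx[ax] = hi;
    }

    // COM velocity and flow-induced displacement
    for (int ax = 0; ax < 3; ++ax)
      out(o, ax) = (com[ax] - comp[ax]) / dt_s;
    out(o, 3) = std::abs(shear_rate * com[2] * dt_s);

    // per-axis spans
    for (int ax = 0; ax < 3; ++ax) out(o, 4 + ax) = mx[ax] - mn[ax];

    // end-to-end distance of the partition
    {
      double ee2 = 0.0;
      for (int ax = 0; ax < 3; ++ax) {
        const double d = pos_t(o, end - 1, ax) - pos_t(o, start, ax);
        ee2 += d * d;
      }
      out(o, 7) = std::sqrt(ee2);
    }

    // gyration components and covariance (1/k normalisation)
    arma::mat33 cov(arma::fill::zeros);
    for (int b = start; b < end; ++b) {
      double d[3];
      for (int ax = 0; ax < 3; ++ax) d[ax] = pos_t(o, b, ax) - com[ax];
      for (int ax = 0; ax < 3; ++ax)
        for (int ay = ax; ay < 3; ++ay) cov(ax, ay) += d[ax] * d[ay];
    }
    cov /= k;
    cov(1, 0) = cov(0, 1); cov(2, 0) = cov(0, 2); cov(2, 1) = cov(1, 2);
    const double rgx = std::sqrt(cov(0, 0));
    const double rgy = std::sqrt(cov(1, 1));
    const double rgz = std::sqrt(cov(2, 2));
    out(o, 8) = rgx;
    out(o, 9) = rgy;
    out(o, 10) = rgz;
    out(o, 11) = std::sqrt(cov(0, 0) + cov(1, 1) + cov(2, 2));

    // flow-variation fraction
    const double rsum = rgx + rgy + rgz;
    out(o, 12) = (rsum > 0.0) ? rgx / rsum : 0.0;

    // local chain concentration: all chain beads within threshold of the
    // partition COM, over the total bead count
    {
      const double t2 = lcc_threshold * lcc_threshold;
      int cnt = 0;
      for (int b = 0; b < nbead; ++b) {
        double r2 = 0.0;
        for (int ax = 0; ax < 3; ++ax) {
          const double d = pos_t(o, b, ax) - com[ax];
          r2 += d * d;
        }
        if (r2 <= t2) ++cnt;
      }
      out(o, 13) = (double)cnt / nbead;
    }

    // principal-axis projections on the flow direction
    {
      arma::vec eval;
      arma::mat evec;
      arma::eig_sym(eval, evec, cov);
      int ord[3];
      order_eigs(eval, evec, ord);
      for (int j = 0; j < 3; ++j) out(o, 14 + j) = std::abs(evec(0, ord[j]));
    }
  }
  return out;
}
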