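// Crank-Nicolson IMEX integrator for sheets of coupled excitable cables.
//
// Both models reduce to the same semi-discrete form
//     dv/dt = L v + r(v, w) + I(t),   dw/dt = eps (v + a - b w)
// where L = (lateral operator) x (axial second difference with zero-flux
// mirrored-ghost boundaries). The lateral operator is diagonalized once in R
// (B = Q diag(d) Qinv for the discrete sheet; the inverse lateral Helmholtz
// composition for the continuum), so the implicit CN solve decouples into
// one constant tridiagonal system along z per lateral mode. The reaction
// r(v,w) = v - v^3/3 - w, the recovery equation and the stimulus are
// advanced with explicit forward Euler from the step-start state, so the
// implicit solve stays linear; the linear diffusion part retains CN's
// second-order accuracy and unconditional stability.
//
// The voltage is carried in both physical space (for the reaction and the
// recovery update) and the lateral eigenbasis (for the diffusion solve), so
// each step costs two dense (n_lat x n_lat) * (n_lat x n_z) products plus
// O(n_lat * n_z) scalar work. The axial second difference commutes with the
// lateral transform, so it is applied directly to the modal field.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List cn_imex_core(const arma::mat& v0, const arma::mat& w0,
                        const arma::mat& Q, const arma::mat& Qinv,
                        const arma::vec& dmode,
                        double dz, double dt, int n_steps,
                        double a, double b, double eps,
                        const arma::mat& events, // cols: row0, onset, dur, amp, j0, j1
                        int snap_stride,
                        const arma::uvec& rec_idx, // 0-based z columns to record
                        bool record_w, bool reaction_on,
                        double t0) {
  const uword nl = v0.n_rows, nz = v0.n_cols;
  if (dmode.n_elem != nl) Rcpp::stop("mode count must equal lateral node count");
  if (nz < 2) Rcpp::stop("need at least two axial nodes");

  // Per-mode CN tridiagonal factors along z (Thomas, precomputed).
  // System per mode p: (1 + 2 beta_p) on the diagonal, -beta_p off-diagonal,
  // with the mirrored-ghost boundary rows carrying -2 beta_p.
  const vec beta = (dt / 2.0) * dmode / (dz * dz);
  mat denom(nl, nz), cp(nl, nz);
  {
    const vec d = 1.0 + 2.0 * beta;
    denom.col(0) = d;
    cp.col(0) = (-2.0 * beta) / denom.col(0);
    for (uword j = 1; j < nz; ++j) {
      const double lfac = (j == nz - 1) ? 2.0 : 1.0;
      denom.col(j) = d + (lfac * beta) % cp.col(j - 1);
      cp.col(j) = (-beta) / denom.col(j);
    }
  }

  const int n_events = events.n_rows;
  const uword n_rec = rec_idx.n_elem;
  const int n_snap = n_steps / snap_stride + 1;

  cube vs(nl, n_rec, n_snap);
  cube ws(record_w ? nl : 0, record_w ? n_rec : 0, record_w ? n_snap : 0);
  vec times(n_snap);

  mat v = v0, w = w0;
  mat vm = Qinv * v;                 // modal voltage, kept in sync with v
  mat r_phys(nl, nz), rm(nl, nz), rhs(nl, nz);

  auto record = [&](int k, double t) {
    times(k) = t;
    for (uword j = 0; j < n_rec; ++j) vs.slice(k).col(j) = v.col(rec_idx(j));
    if (record_w)
      for (uword j = 0; j < n_rec; ++j) ws.slice(k).col(j) = w.col(rec_idx(j));
  };
  record(0, t0);

  const double idz2 = 1.0 / (dz * dz), halfdt = dt / 2.0;
  const double* dm = dmode.memptr();
  int snap_k = 1;
  for (int n = 0; n < n_steps; ++n) {
    const double t = t0 + n * dt;

    // explicit reaction + stimulus, in physical space
    if (reaction_on) {
      const double* pv = v.memptr();
      const double* pw = w.memptr();
      double* pr = r_phys.memptr();
      const uword m = nl * nz;
      for (uword k = 0; k < m; ++k)
        pr[k] = dt * (pv[k] - pv[k] * pv[k] * pv[k] / 3.0 - pw[k]);
    } else {
      r_phys.zeros();
    }
    for (int e = 0; e < n_events; ++e) {
      if (events(e, 1) <= t && t < events(e, 1) + events(e, 2)) {
        const uword r = (uword)events(e, 0);
        const uword j0 = (uword)events(e, 4), j1 = (uword)events(e, 5);
        const double amp = dt * events(e, 3);
        for (uword j = j0; j <= j1; ++j) r_phys(r, j) += amp;
      }
    }
    rm = Qinv * r_phys;

    // rhs in modal space: vm + (dt/2) d % Lzz(vm) + transformed reaction
    for (uword j = 0; j < nz; ++j) {
      const double* c0 = vm.colptr(j);
      const double* cm = vm.colptr(j == 0 ? 1 : j - 1);
      const double* cpl = vm.colptr(j == nz - 1 ? nz - 2 : j + 1);
      const double* pr = rm.colptr(j);
      double* po = rhs.colptr(j);
      for (uword p = 0; p < nl; ++p)
        po[p] = c0[p] + pr[p] +
                halfdt * dm[p] * idz2 * (cm[p] - 2.0 * c0[p] + cpl[p]);
    }

    // Thomas solve along z, all modes at once (vm becomes the new modal v)
    {
      double* x0 = vm.colptr(0);
      const double* b0 = rhs.colptr(0);
      const double* dn0 = denom.colptr(0);
      for (uword p = 0; p < nl; ++p) x0[p] = b0[p] / dn0[p];
      const double* pbeta = beta.memptr();
      for (uword j = 1; j < nz; ++j) {
        const double lfac = (j == nz - 1) ? 2.0 : 1.0;
        double* xj = vm.colptr(j);
        const double* xp = vm.colptr(j - 1);
        const double* bj = rhs.colptr(j);
        const double* dnj = denom.colptr(j);
        for (uword p = 0; p < nl; ++p)
          xj[p] = (bj[p] + lfac * pbeta[p] * xp[p]) / dnj[p];
      }
      for (uword j = nz - 1; j-- > 0;) {
        double* xj = vm.colptr(j);
        const double* xn = vm.colptr(j + 1);
        const double* cj = cp.colptr(j);
        for (uword p = 0; p < nl; ++p) xj[p] -= cj[p] * xn[p];
      }
    }

    // forward-Euler recovery update from the pre-step voltage, then
    // refresh physical v
    {
      const double* pv = v.memptr();
      double* pw = w.memptr();
      const uword m = nl * nz;
      const double de = dt * eps;
      for (uword k = 0; k < m; ++k)
        pw[k] += de * (pv[k] + a - b * pw[k]);
    }
    v = Q * vm;

    if ((n + 1) % snap_stride == 0) {
      record(snap_k, t0 + (n + 1) * dt);
      ++snap_k;
    }
    if ((n & 255) == 255 && !v.is_finite())
      Rcpp::stop("solution lost finiteness near t = %g; reduce dt", t);
  }
  if (!v.is_finite())
    Rcpp::stop("solution lost finiteness by t = %g; reduce dt",
               t0 + n_steps * dt);

  return Rcpp::List::create(
      Rcpp::Named("times") = times,
      Rcpp::Named("v") = vs,
      Rcpp::Named("w") = ws,
      Rcpp::Named("v_final") = v,
      Rcpp::Named("w_final") = w);
}
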