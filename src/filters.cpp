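// Core numerics for buffer-wise stream processing: zero-phase IIR
// filtering along channel rows and the per-sample adaptive artifact
// regression of the online engine. Kept in compiled code because the
// stream recomputes the filter at the sampling rate.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// steady-state initial filter state for a unit step input (matches
// scipy's lfilter_zi); removes start-up transients in filtfilt when
// scaled by the first sample
static vec lfilter_zi(const vec& b0, const vec& a0) {
  const uword n = std::max(b0.n_elem, a0.n_elem);
  vec b = zeros<vec>(n), a = zeros<vec>(n);
  b.head(b0.n_elem) = b0;
  a.head(a0.n_elem) = a0;
  b /= a[0]; a /= a[0];
  const uword m = n - 1;
  mat comp = zeros<mat>(m, m);          // companion(a)
  comp.row(0) = -a.subvec(1, m).t();
  for (uword i = 1; i < m; ++i) comp(i, i - 1) = 1.0;
  mat IminusA = eye(m, m) - comp.t();
  vec B = b.subvec(1, m) - a.subvec(1, m) * b[0];
  return solve(IminusA, B);
}

// direct-form II transposed single-pass IIR along a vector (a[0] == 1),
// with initial state zi * x[0]
static void iir_pass(const vec& b, const vec& a, const vec& zi,
                     const double* x, double* y, uword n) {
  const uword nb = b.n_elem, na = a.n_elem;
  const uword nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (uword k = 0; k < nz; ++k) z[k] = zi[k] * x[0];
  for (uword i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = (nz > 0 ? z[0] : 0.0) + b[0] * xi;
    for (uword k = 0; k < nz; ++k) {
      double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      double znext = (k + 1 < nz) ? z[k + 1] : 0.0;
      z[k] = znext + bk * xi - ak * yi;
    }
    y[i] = yi;
  }
}

// zero-phase forward-backward filtering of one row: odd-reflect padding
// plus steady-state initial conditions on both passes
static void filtfilt_row(const vec& b, const vec& a, const vec& zi, vec& x) {
  const uword n = x.n_elem;
  const uword order = std::max(b.n_elem, a.n_elem) - 1;
  uword pad = 3 * order;
  if (pad >= n) pad = n - 1;
  const uword m = n + 2 * pad;
  vec ext(m), tmp(m);
  // odd reflection: 2*x[0] - x[pad..1], x, 2*x[n-1] - x[n-2..]
  for (uword i = 0; i < pad; ++i) ext[i] = 2.0 * x[0] - x[pad - i];
  for (uword i = 0; i < n; ++i) ext[pad + i] = x[i];
  for (uword i = 0; i < pad; ++i) ext[pad + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  iir_pass(b, a, zi, ext.memptr(), tmp.memptr(), m);
  tmp = reverse(tmp);
  iir_pass(b, a, zi, tmp.memptr(), ext.memptr(), m);
  ext = reverse(ext);
  for (uword i = 0; i < n; ++i) x[i] = ext[pad + i];
}

// [[Rcpp::export]]
arma::mat cpp_filtfilt_mat(const arma::vec& b, const arma::vec& a, arma::mat X) {
  // rows are channels, columns are samples
  vec zi = lfilter_zi(b, a);
  for (uword r = 0; r < X.n_rows; ++r) {
    vec row = X.row(r).t();
    filtfilt_row(b, a, zi, row);
    X.row(r) = row.t();
  }
  return X;
}

// cascade of second-order sections (rows of b0 b1 b2 a0 a1 a2) with
// per-section steady-state initial conditions
static void bandpass_window(mat& W, const mat& sos, const std::vector<vec>& zis,
                            bool demean) {
  // a high-pass edge the short window cannot support is realized as
  // window demeaning instead (see the R-side design rule)
  if (demean) W.each_col() -= mean(W, 1);
  for (uword s = 0; s < sos.n_rows; ++s) {
    vec b = sos.row(s).subvec(0, 2).t();
    vec a = sos.row(s).subvec(3, 5).t();
    for (uword r = 0; r < W.n_rows; ++r) {
      vec row = W.row(r).t();
      filtfilt_row(b, a, zis[s], row);
      W.row(r) = row.t();
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_stream_loop(const arma::mat& X,
                           const arma::mat& sos, bool demean,
                           const arma::mat& CR, const arma::mat& WA,
                           const arma::mat& K, int nT,
                           double ridge_rel, double cond_max, int stride) {
  // X: nE x N raw sensor stream; outputs one (Y, B) per sample once the
  // buffer is full. WA may have zero rows (no artifact subspace).
  const uword nE = X.n_rows, N = X.n_cols;
  const uword nA = WA.n_rows;
  if (N < (uword)nT) Rcpp::stop("stream shorter than one buffer");
  const uword nOut = N - nT + 1;
  mat Y(nE, nOut), B(K.n_rows, nOut);
  vec ratio(nOut, fill::zeros);
  std::vector<vec> zis;
  for (uword sct = 0; sct < sos.n_rows; ++sct)
    zis.push_back(lfilter_zi(sos.row(sct).subvec(0, 2).t(),
                             sos.row(sct).subvec(3, 5).t()));
  mat Fproj;          // nE x nE cleaning projector of the current buffer
  bool haveF = false;
  for (uword t = nT - 1, o = 0; t < N; ++t, ++o) {
    mat W = X.cols(t - nT + 1, t);
    bandpass_window(W, sos, zis, demean);
    mat Xq = CR * W;
    mat Xp;
    if (nA == 0) {
      Xp = Xq;
    } else if (stride <= 1 || !haveF || (o % (uword)stride) == 0) {
      mat SA = WA * Xq;                       // nA x nT
      mat G = SA * SA.t();
      double tr = trace(G);
      double xqE = accu(Xq % Xq);
      if (tr <= 1e-12 * xqE) {                // artifact subspace silent in buffer
        Xp = Xq;
        Fproj = eye(nE, nE);
        haveF = true;
        Y.col(o) = Xp.col(nT - 1);
        B.col(o) = K * Y.col(o);
        continue;
      }
      if (rcond(symmatu(G)) < 1.0 / cond_max) G.diag() += ridge_rel * tr / nA;
      mat coef = (Xq * SA.t()) * inv_sympd(symmatu(G));   // nE x nA
      Fproj = eye(nE, nE) - coef * WA;
      haveF = true;
      Xp = Xq - coef * SA;
      double den = norm(SA, "fro");
      ratio[o] = den > 0 ? norm(WA * Xp, "fro") / den : 0.0;
    } else {
      Xp = Fproj * Xq;
      mat SA = WA * Xq;
      double den = norm(SA, "fro");
      ratio[o] = den > 0 ? norm(WA * Xp, "fro") / den : 0.0;
    }
    Y.col(o) = Xp.col(nT - 1);
    B.col(o) = K * Y.col(o);
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("annihilation") = ratio);
}
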