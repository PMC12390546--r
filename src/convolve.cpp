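#include <Rcpp.h>
using namespace Rcpp;

// 1-D "valid" convolutions on pre-padded, time-major inputs. These are the
// hot loops of the EEGNet forward/backward pass; everything else in the
// network reduces to BLAS matrix products at the R level.
//
// Layout: Xp is a (Tp x R) matrix, one time series per column (R = batch x
// maps). W holds one filter per column (k x F). Padding/cropping conventions
// are handled by the caller, which passes the desired output length t_out
// (t_out <= Tp - k + 1).

// Shared filters: every column is convolved with every filter.
// Returns a [t_out, R, F] array.
// [[Rcpp::export]]
NumericVector conv1d_fwd(const NumericMatrix& Xp, const NumericMatrix& W,
                         const int t_out) {
  const int Tp = Xp.nrow(), R = Xp.ncol(), k = W.nrow(), F = W.ncol();
  if (t_out > Tp - k + 1) stop("t_out too large for padded input");
  NumericVector out(static_cast<R_xlen_t>(t_out) * R * F);
  const double* x = Xp.begin();
  const double* w = W.begin();
  double* o = out.begin();
  for (int f = 0; f < F; ++f) {
    const double* wf = w + static_cast<R_xlen_t>(f) * k;
    for (int r = 0; r < R; ++r) {
      const double* xr = x + static_cast<R_xlen_t>(r) * Tp;
      double* orf = o + (static_cast<R_xlen_t>(f) * R + r) * t_out;
      for (int t = 0; t < t_out; ++t) {
        double acc = 0.0;
        for (int j = 0; j < k; ++j) acc += wf[j] * xr[t + j];
        orf[t] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(t_out, R, F);
  return out;
}

// Gradient w.r.t. the (padded) input of conv1d_fwd.
// dY: [t_out, R, F] array; returns (Tp x R) matrix.
// [[Rcpp::export]]
NumericMatrix conv1d_bwd_x(const NumericVector& dY, const NumericMatrix& W,
                           const int Tp) {
  IntegerVector d = dY.attr("dim");
  const int t_out = d[0], R = d[1], F = d[2], k = W.nrow();
  NumericMatrix dX(Tp, R);
  const double* g = dY.begin();
  const double* w = W.begin();
  double* dx = dX.begin();
  for (int f = 0; f < F; ++f) {
    const double* wf = w + static_cast<R_xlen_t>(f) * k;
    for (int r = 0; r < R; ++r) {
      const double* grf = g + (static_cast<R_xlen_t>(f) * R + r) * t_out;
      double* dxr = dx + static_cast<R_xlen_t>(r) * Tp;
      for (int t = 0; t < t_out; ++t) {
        const double gv = grf[t];
        if (gv == 0.0) continue;
        for (int j = 0; j < k; ++j) dxr[t + j] += wf[j] * gv;
      }
    }
  }
  return dX;
}

// Gradient w.r.t. the shared filters. Returns (k x F).
// [[Rcpp::export]]
NumericMatrix conv1d_bwd_w(const NumericVector& dY, const NumericMatrix& Xp,
                           const int k) {
  IntegerVector d = dY.attr("dim");
  const int t_out = d[0], R = d[1], F = d[2], Tp = Xp.nrow();
  if (Tp < t_out + k - 1) stop("padded input shorter than required");
  NumericMatrix dW(k, F);
  const double* g = dY.begin();
  const double* x = Xp.begin();
  double* dw = dW.begin();
  for (int f = 0; f < F; ++f) {
    double* dwf = dw + static_cast<R_xlen_t>(f) * k;
    for (int r = 0; r < R; ++r) {
      const double* grf = g + (static_cast<R_xlen_t>(f) * R + r) * t_out;
      const double* xr = x + static_cast<R_xlen_t>(r) * Tp;
      for (int j = 0; j < k; ++j) {
        double acc = 0.0;
        for (int t = 0; t < t_out; ++t) acc += grf[t] * xr[t + j];
        dwf[j] += acc;
      }
    }
  }
  return dW;
}

// Depthwise: column r is convolved only with filter map[r] (1-based).
// Returns a (t_out x R) matrix.
// [[Rcpp::export]]
NumericMatrix dwconv1d_fwd(const NumericMatrix& Xp, const NumericMatrix& W,
                           const IntegerVector& map, const int t_out) {
  const int Tp = Xp.nrow(), R = Xp.ncol(), k = W.nrow();
  if (map.size() != R) stop("map length must equal the number of columns");
  NumericMatrix out(t_out, R);
  const double* x = Xp.begin();
  const double* w = W.begin();
  double* o = out.begin();
  for (int r = 0; r < R; ++r) {
    const double* wf = w + static_cast<R_xlen_t>(map[r] - 1) * k;
    const double* xr = x + static_cast<R_xlen_t>(r) * Tp;
    double* orr = o + static_cast<R_xlen_t>(r) * t_out;
    for (int t = 0; t < t_out; ++t) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += wf[j] * xr[t + j];
      orr[t] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix dwconv1d_bwd_x(const NumericMatrix& dY, const NumericMatrix& W,
                             const IntegerVector& map, const int Tp) {
  const int t_out = dY.nrow(), R = dY.ncol(), k = W.nrow();
  NumericMatrix dX(Tp, R);
  const double* g = dY.begin();
  const double* w = W.begin();
  double* dx = dX.begin();
  for (int r = 0; r < R; ++r) {
    const double* wf = w + static_cast<R_xlen_t>(map[r] - 1) * k;
    const double* grr = g + static_cast<R_xlen_t>(r) * t_out;
    double* dxr = dx + static_cast<R_xlen_t>(r) * Tp;
    for (int t = 0; t < t_out; ++t) {
      const double gv = grr[t];
      if (gv == 0.0) continue;
      for (int j = 0; j < k; ++j) dxr[t + j] += wf[j] * gv;
    }
  }
  return dX;
}

// [[Rcpp::export]]
NumericMatrix dwconv1d_bwd_w(const NumericMatrix& dY, const NumericMatrix& Xp,
                             const IntegerVector& map, const int k,
                             const int n_filters) {
  const int t_out = dY.nrow(), R = dY.ncol(), Tp = Xp.nrow();
  NumericMatrix dW(k, n_filters);
  const double* g = dY.begin();
  const double* x = Xp.begin();
  double* dw = dW.begin();
  for (int r = 0; r < R; ++r) {
    double* dwf = dw + static_cast<R_xlen_t>(map[r] - 1) * k;
    const double* grr = g + static_cast<R_xlen_t>(r) * t_out;
    const double* xr = x + static_cast<R_xlen_t>(r) * Tp;
    for (int j = 0; j < k; ++j) {
      double acc = 0.0;
      for (int t = 0; t < t_out; ++t) acc += grr[t] * xr[t + j];
      dwf[j] += acc;
    }
  }
  return dW;
}

// ELU (alpha = 1) and its backward in terms of the forward output.
// [[Rcpp::export]]
NumericVector elu_cpp(const NumericVector& x) {
  NumericVector out = clone(x);
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (out[i] < 0) out[i] = std::exp(out[i]) - 1.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector elu_bwd_cpp(const NumericVector& dy, const NumericVector& out) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i)
    if (out[i] <= 0) dx[i] *= out[i] + 1.0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// Batch-normalization storing only (mu, istd); z is recomputed from the
// cached input in the backward pass, halving the forward's large writes.
// [[Rcpp::export]]
List bn_fwd2_cpp(const NumericMatrix& x, const NumericVector& gamma,
                 const NumericVector& beta, const double eps) {
  const int n = x.nrow(), f = x.ncol();
  NumericMatrix out(n, f);
  NumericVector mu(f), istd(f);
  for (int j = 0; j < f; ++j) {
    const double* xj = &x(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i];
    const double m = s / n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) { const double d = xj[i] - m; v += d * d; }
    const double is = 1.0 / std::sqrt(v / n + eps);
    mu[j] = m;
    istd[j] = is;
    const double g = gamma[j] * is, b = beta[j] - gamma[j] * is * m;
    double* oj = &out(0, j);
    for (int i = 0; i < n; ++i) oj[i] = g * xj[i] + b;
  }
  return List::create(_["out"] = out, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
List bn_bwd2_cpp(const NumericMatrix& dy, const NumericMatrix& x,
                 const NumericVector& mu, const NumericVector& istd,
                 const NumericVector& gamma) {
  const int n = dy.nrow(), f = dy.ncol();
  NumericMatrix dx(n, f);
  NumericVector dgamma(f), dbeta(f);
  for (int j = 0; j < f; ++j) {
    const double* dyj = &dy(0, j);
    const double* xj = &x(0, j);
    const double m = mu[j], is = istd[j];
    double sdy = 0.0, sdyz = 0.0;
    for (int i = 0; i < n; ++i) {
      sdy += dyj[i];
      sdyz += dyj[i] * (xj[i] - m) * is;
    }
    dgamma[j] = sdyz;
    dbeta[j] = sdy;
    const double m1 = sdy / n, m2 = sdyz / n;
    const double gi = gamma[j] * is;
    double* dxj = &dx(0, j);
    for (int i = 0; i < n; ++i)
      dxj[i] = gi * (dyj[i] - m1 - (xj[i] - m) * is * m2);
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
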