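#include <Rcpp.h>
using namespace Rcpp;

// Cross-correlation of a part filter with a HOG cell grid (template
// matching).  `cells` is rows x cols x d, `filt` is M x N x d,
// both in R's column-major layout with the row index fastest.  Returns the
// (rows-M+1) x (cols-N+1) response map over valid top-left anchor cells.
// [[Rcpp::export]]
NumericMatrix cpp_xcorr(NumericVector cells, NumericVector filt) {
  IntegerVector dc = cells.attr("dim");
  IntegerVector df = filt.attr("dim");
  const int R = dc[0], C = dc[1], D = dc[2];
  const int M = df[0], N = df[1];
  if (df[2] != D) stop("filter depth does not match feature depth");
  if (R < M || C < N) stop("feature grid smaller than the filter footprint");
  const int vr = R - M + 1, vc = C - N + 1;
  NumericMatrix out(vr, vc);
  const double *pc = cells.begin(), *pf = filt.begin();
  double *po = out.begin();
  for (int d = 0; d < D; ++d) {
    for (int n = 0; n < N; ++n) {
      for (int m = 0; m < M; ++m) {
        const double w = pf[m + M * (n + N * d)];
        if (w == 0.0) continue;
        for (int x = 0; x < vc; ++x) {
          const double *col = pc + (size_t)R * ((x + n) + (size_t)C * d) + m;
          double *oc = po + (size_t)vr * x;
          for (int y = 0; y < vr; ++y) oc[y] += w * col[y];
        }
      }
    }
  }
  return out;
}

// Dual coordinate descent for the margin QP
//   min_beta 1/2 ||beta - beta0||^2 + C sum_g xi_g
// over constraints y_i * <beta, Phi_i> >= 1 - xi_{group(i)} with box
// constraints 0 <= alpha_i and sum_{i in g} alpha_i <= C per slack group.
// PhiT holds one constraint per column; beta and alpha are warm starts.
// Cyclic sweeps; stops when the largest projected gradient in a sweep
// falls below tol.  Modifies copies; returns beta, alpha and sweeps used.
// [[Rcpp::export]]
List cpp_dcd(NumericMatrix PhiT, NumericVector y, IntegerVector group,
             double C, NumericVector beta_in, NumericVector alpha_in,
             int sweeps, double tol) {
  const int L = PhiT.nrow(), n = PhiT.ncol();
  NumericVector beta = clone(beta_in), alpha = clone(alpha_in);
  std::vector<double> qn(n);
  const double *P = PhiT.begin();
  for (int i = 0; i < n; ++i) {
    double s = 0;
    const double *col = P + (size_t)L * i;
    for (int k = 0; k < L; ++k) s += col[k] * col[k];
    qn[i] = s;
  }
  int ngr = 0;
  for (int i = 0; i < n; ++i) ngr = std::max(ngr, group[i]);
  std::vector<double> gsum(ngr, 0.0);
  for (int i = 0; i < n; ++i) gsum[group[i] - 1] += alpha[i];
  double *b = beta.begin();
  // active-set shrinking: constraints at alpha = 0 that are satisfied with
  // a margin sleep between the periodic full sweeps
  std::vector<char> active(n, 1);
  int sw = 0;
  for (sw = 0; sw < sweeps; ++sw) {
    const bool full = (sw % 10 == 0);
    double maxv = 0;
    for (int i = 0; i < n; ++i) {
      if (qn[i] <= 0) continue;
      if (!full && !active[i]) continue;
      const double *col = P + (size_t)L * i;
      double dot = 0;
      for (int k = 0; k < L; ++k) dot += col[k] * b[k];
      const double g = y[i] * dot - 1.0;
      const double U = C - (gsum[group[i] - 1] - alpha[i]);
      double a_new = alpha[i] - g / qn[i];
      if (a_new < 0) a_new = 0;
      if (a_new > U) a_new = U;
      if (a_new != alpha[i]) {
        const double d = (a_new - alpha[i]) * y[i];
        for (int k = 0; k < L; ++k) b[k] += d * col[k];
        gsum[group[i] - 1] += a_new - alpha[i];
        alpha[i] = a_new;
      }
      double pg = g;
      if (alpha[i] <= 0 && g > 0) pg = 0;
      else if (alpha[i] >= U && g < 0) pg = 0;
      if (std::abs(pg) > maxv) maxv = std::abs(pg);
      active[i] = !(alpha[i] <= 0 && g > tol);
    }
    if (full && maxv < tol) { ++sw; break; }
  }
  return List::create(_["beta"] = beta, _["alpha"] = alpha,
                      _["sweeps"] = sw);
}

// Max-plus "spring" message for one (child state, parent state) pair.
// score is the child's total score over its valid placements; the penalty
// for placing the child at (cy,cx) given the parent at (py,px) is
//   zx1*dx + zx2*dx^2 + zy1*dy + zy2*dy^2,  dx = cx-px-ax, dy = cy-py-ay
// (subtracted from the score).  Separable, so computed as two 1-D passes.
// Ties resolve to the smallest (y, x) in 0-based scan order; returned
// argmax indices are 1-based for R.
// [[Rcpp::export]]
List cpp_spring_max(NumericMatrix score, double zx1, double zx2,
                    double zy1, double zy2, double ax, double ay) {
  const int nr = score.nrow(), nc = score.ncol();
  NumericMatrix tmp(nr, nc);
  IntegerMatrix argx(nr, nc);
  for (int px = 0; px < nc; ++px) {
    for (int r = 0; r < nr; ++r) tmp(r, px) = R_NegInf;
    for (int cx = 0; cx < nc; ++cx) {
      const double dx = cx - px - ax;
      const double pen = zx1 * dx + zx2 * dx * dx;
      for (int r = 0; r < nr; ++r) {
        const double v = score(r, cx) - pen;
        if (v > tmp(r, px)) { tmp(r, px) = v; argx(r, px) = cx; }
      }
    }
  }
  NumericMatrix val(nr, nc);
  IntegerMatrix oargx(nr, nc), oargy(nr, nc);
  for (int px = 0; px < nc; ++px) {
    for (int py = 0; py < nr; ++py) {
      double best = R_NegInf;
      int by = 0;
      for (int cy = 0; cy < nr; ++cy) {
        const double dy = cy - py - ay;
        const double v = tmp(cy, px) - (zy1 * dy + zy2 * dy * dy);
        if (v > best) { best = v; by = cy; }
      }
      val(py, px) = best;
      oargy(py, px) = by + 1;
      oargx(py, px) = argx(by, px) + 1;
    }
  }
  return List::create(_["val"] = val, _["argy"] = oargy, _["argx"] = oargx);
}
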