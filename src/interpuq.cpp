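#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Sign-alternation count over the second differences of the piecewise-linear
// path (x, y).  Gradient changes with |change| <= tol are transparent: they
// are skipped when scanning for alternations (a flat kink is neither a
// positive nor a negative curvature event).
static int count_core(const double* x, const double* y, int n, double tol) {
  if (n < 3) return 0;
  int count = 0;
  int prev_sign = 0;
  double g_prev = (y[1] - y[0]) / (x[1] - x[0]);
  for (int i = 1; i + 1 < n; ++i) {
    double g = (y[i + 1] - y[i]) / (x[i + 1] - x[i]);
    double d = g - g_prev;
    g_prev = g;
    int s = (d > tol) ? 1 : ((d < -tol) ? -1 : 0);
    if (s == 0) continue;
    if (prev_sign != 0 && s != prev_sign) ++count;
    prev_sign = s;
  }
  return count;
}

static void check_increasing(const NumericVector& x) {
  for (int i = 1; i < x.size(); ++i)
    if (!(x[i] > x[i - 1]))
      stop("invalid path: x must be strictly increasing");
}

// Merge the measured path with k extra points (xi ascending, all distinct
// from measured x) into the workspace wx/wy, then count inflexions.
static int merged_count(const std::vector<double>& xm,
                        const std::vector<double>& ym,
                        const double* xi, const double* yi, int k,
                        double tol,
                        std::vector<double>& wx, std::vector<double>& wy) {
  const int n = (int)xm.size();
  wx.resize(n + k);
  wy.resize(n + k);
  int i = 0, j = 0, p = 0;
  while (i < n || j < k) {
    if (j >= k || (i < n && xm[i] < xi[j])) {
      wx[p] = xm[i]; wy[p] = ym[i]; ++i;
    } else {
      wx[p] = xi[j]; wy[p] = yi[j]; ++j;
    }
    ++p;
  }
  return count_core(wx.data(), wy.data(), n + k, tol);
}

static inline bool ok_rule(int count, int ref, bool le) {
  return le ? (count <= ref) : (count == ref);
}

// [[Rcpp::export]]
int count_inflexions_cpp(NumericVector x, NumericVector y, double tol) {
  if (x.size() != y.size()) stop("x and y lengths differ");
  if (x.size() < 2) stop("invalid path: need at least 2 points");
  check_increasing(x);
  return count_core(x.begin(), y.begin(), x.size(), tol);
}

// Plausibility of inserting the single point (xins, ys[i]) into the measured
// path, for each candidate y.
// [[Rcpp::export]]
LogicalVector insertion_plausible_cpp(NumericVector xm, NumericVector ym,
                                      double xins, NumericVector ys,
                                      int ref, double tol, bool le) {
  std::vector<double> mx(xm.begin(), xm.end()), my(ym.begin(), ym.end());
  std::vector<double> wx, wy;
  LogicalVector out(ys.size());
  for (int i = 0; i < ys.size(); ++i) {
    double yi = ys[i];
    out[i] = ok_rule(merged_count(mx, my, &xins, &yi, 1, tol, wx, wy), ref, le);
  }
  return out;
}

// Min/max plausible y for a single insertion at xins, scanning a grid over
// [win_lo, win_hi] (always including the anchor, a y known to be plausible)
// and refining each edge by bisection to tol_y.
// [[Rcpp::export]]
NumericVector pointwise_bounds_cpp(NumericVector xm, NumericVector ym,
                                   double xins, int ref,
                                   double win_lo, double win_hi, double anchor,
                                   int grid_n, double tol_y, double tol,
                                   bool le) {
  std::vector<double> mx(xm.begin(), xm.end()), my(ym.begin(), ym.end());
  std::vector<double> wx, wy;
  auto plaus = [&](double yv) {
    return ok_rule(merged_count(mx, my, &xins, &yv, 1, tol, wx, wy), ref, le);
  };
  if (!plaus(anchor))
    stop("internal error: anchor value not plausible at x = %f", xins);
  if (win_hi <= win_lo) return NumericVector::create(anchor, anchor);

  double lo_pl = anchor, hi_pl = anchor;  // outermost plausible values seen
  double step = (win_hi - win_lo) / (grid_n - 1);
  for (int i = 0; i < grid_n; ++i) {
    double yv = win_lo + i * step;
    if (plaus(yv)) {
      if (yv < lo_pl) lo_pl = yv;
      if (yv > hi_pl) hi_pl = yv;
    }
  }
  // refine lower edge between the last implausible value below lo_pl and lo_pl
  double lo = lo_pl;
  if (lo_pl > win_lo) {
    double a = std::max(win_lo, lo_pl - step), b = lo_pl;
    if (plaus(a)) { lo = win_lo; /* grid missed; extend scan by bisection from window edge */
      a = win_lo; b = lo_pl;
      if (plaus(a)) lo = a; else {
        while (b - a > tol_y) { double m = 0.5 * (a + b); if (plaus(m)) b = m; else a = m; }
        lo = b;
      }
    } else {
      while (b - a > tol_y) { double m = 0.5 * (a + b); if (plaus(m)) b = m; else a = m; }
      lo = b;
    }
  }
  double hi = hi_pl;
  if (hi_pl < win_hi) {
    double a = hi_pl, b = std::min(win_hi, hi_pl + step);
    if (plaus(b)) { hi = win_hi;
      a = hi_pl; b = win_hi;
      if (plaus(b)) hi = b; else {
        while (b - a > tol_y) { double m = 0.5 * (a + b); if (plaus(m)) a = m; else b = m; }
        hi = a;
      }
    } else {
      while (b - a > tol_y) { double m = 0.5 * (a + b); if (plaus(m)) a = m; else b = m; }
      hi = a;
    }
  }
  return NumericVector::create(lo, hi);
}

// Acceptance-rejection sampling of guide configurations.  Each guide y is
// drawn uniformly within its envelope span; the configuration is accepted iff
// the merged path keeps the reference inflexion budget.  Uses R's RNG.
// [[Rcpp::export]]
List mc_sample_cpp(NumericVector xm, NumericVector ym, NumericVector gx,
                   NumericVector glo, NumericVector ghi,
                   int n_accept, int ref, double tol, bool le,
                   double max_attempts) {
  const int G = gx.size();
  std::vector<double> mx(xm.begin(), xm.end()), my(ym.begin(), ym.end());
  std::vector<double> gxi(gx.begin(), gx.end());
  std::vector<double> gyi(G);
  std::vector<double> wx, wy;
  NumericMatrix samples(n_accept, G);
  double attempts = 0;
  int accepted = 0;
  while (accepted < n_accept) {
    if (attempts >= max_attempts)
      stop("sampling exhausted: %d of %d configurations accepted after %.0f attempts",
           accepted, n_accept, attempts);
    attempts += 1;
    for (int j = 0; j < G; ++j)
      gyi[j] = glo[j] + unif_rand() * (ghi[j] - glo[j]);
    int c = merged_count(mx, my, gxi.data(), gyi.data(), G, tol, wx, wy);
    if (ok_rule(c, ref, le)) {
      for (int j = 0; j < G; ++j) samples(accepted, j) = gyi[j];
      ++accepted;
    }
  }
  return List::create(_["samples"] = samples, _["attempts"] = attempts);
}

// One step of a directional pass: weights over the current column's midpoints
// given the probabilities of the previously processed adjacent column.
// [[Rcpp::export]]
NumericVector pass_weights_cpp(NumericVector xm, NumericVector ym,
                               double x_cur, NumericVector mid_cur,
                               double x_prev, NumericVector mid_prev,
                               NumericVector p_prev,
                               int ref, double tol, bool le) {
  std::vector<double> mx(xm.begin(), xm.end()), my(ym.begin(), ym.end());
  std::vector<double> wx, wy;
  double xi[2], yi[2];
  const bool cur_first = x_cur < x_prev;
  NumericVector w(mid_cur.size());
  for (int a = 0; a < mid_cur.size(); ++a) {
    double acc = 0;
    for (int b = 0; b < mid_prev.size(); ++b) {
      if (p_prev[b] <= 0) continue;
      if (cur_first) { xi[0] = x_cur; yi[0] = mid_cur[a]; xi[1] = x_prev; yi[1] = mid_prev[b]; }
      else           { xi[0] = x_prev; yi[0] = mid_prev[b]; xi[1] = x_cur; yi[1] = mid_cur[a]; }
      if (ok_rule(merged_count(mx, my, xi, yi, 2, tol, wx, wy), ref, le))
        acc += p_prev[b];
    }
    w[a] = acc;
  }
  return w;
}

// Joint combination for an interior column: weight of each midpoint b given
// the left neighbour's left-conditional and the right neighbour's
// right-conditional probabilities.
// [[Rcpp::export]]
NumericVector joint_weights_cpp(NumericVector xm, NumericVector ym,
                                double x_l, NumericVector mid_l, NumericVector p_l,
                                double x_c, NumericVector mid_c,
                                double x_r, NumericVector mid_r, NumericVector p_r,
                                int ref, double tol, bool le) {
  std::vector<double> mx(xm.begin(), xm.end()), my(ym.begin(), ym.end());
  std::vector<double> wx, wy;
  double xi[3] = { x_l, x_c, x_r };
  double yi[3];
  NumericVector w(mid_c.size());
  for (int b = 0; b < mid_c.size(); ++b) {
    double acc = 0;
    yi[1] = mid_c[b];
    for (int a = 0; a < mid_l.size(); ++a) {
      if (p_l[a] <= 0) continue;
      yi[0] = mid_l[a];
      for (int c = 0; c < mid_r.size(); ++c) {
        if (p_r[c] <= 0) continue;
        yi[2] = mid_r[c];
        if (ok_rule(merged_count(mx, my, xi, yi, 3, tol, wx, wy), ref, le))
          acc += p_l[a] * p_r[c];
      }
    }
    w[b] = acc;
  }
  return w;
}

// Exhaustive enumeration over one midpoint per guide column; returns the
// per-column counts of fully plausible combinations plus the survivor count.
// [[Rcpp::export]]
List enumerate_joint_cpp(NumericVector xm, NumericVector ym,
                         NumericVector gx, List midpoints,
                         int ref, double tol, bool le) {
  const int G = gx.size();
  std::vector<std::vector<double>> mids(G);
  for (int j = 0; j < G; ++j)
    mids[j] = as<std::vector<double>>(midpoints[j]);
  std::vector<double> mx(xm.begin(), xm.end()), my(ym.begin(), ym.end());
  std::vector<double> gxi(gx.begin(), gx.end());
  std::vector<double> gyi(G);
  std::vector<double> wx, wy;
  std::vector<std::vector<double>> counts(G);
  for (int j = 0; j < G; ++j) counts[j].assign(mids[j].size(), 0.0);
  std::vector<int> idx(G, 0);
  double survivors = 0, examined = 0;
  for (;;) {
    for (int j = 0; j < G; ++j) gyi[j] = mids[j][idx[j]];
    examined += 1;
    if (ok_rule(merged_count(mx, my, gxi.data(), gyi.data(), G, tol, wx, wy),
                ref, le)) {
      survivors += 1;
      for (int j = 0; j < G; ++j) counts[j][idx[j]] += 1;
    }
    int j = G - 1;
    while (j >= 0) {
      if (++idx[j] < (int)mids[j].size()) break;
      idx[j] = 0;
      --j;
    }
    if (j < 0) break;
  }
  List out(G);
  for (int j = 0; j < G; ++j) out[j] = wrap(counts[j]);
  return List::create(_["counts"] = out, _["survivors"] = survivors,
                      _["examined"] = examined);
}
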