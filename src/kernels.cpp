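#include <Rcpp.h>
using namespace Rcpp;

// Hard-core CSR by dart throwing: each point is proposed uniformly on
// [0,W) x [0,H) (optionally inset by `margin`) and rejected while it falls
// within `dmin` of an accepted point. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix hardcore_csr_cpp(int n, double W, double H, double dmin,
                               double margin, int max_attempts) {
  NumericMatrix out(n, 2);
  std::vector<double> xs, ys;
  xs.reserve(n);
  ys.reserve(n);
  const double d2 = dmin * dmin;
  const double w = W - 2.0 * margin, h = H - 2.0 * margin;
  if (w <= 0.0 || h <= 0.0) stop("margin leaves no room inside the window");
  for (int k = 0; k < n; ++k) {
    bool placed = false;
    for (int a = 0; a < max_attempts; ++a) {
      const double px = margin + unif_rand() * w;
      const double py = margin + unif_rand() * h;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        const double dx = xs[j] - px, dy = ys[j] - py;
        if (dx * dx + dy * dy < d2) { ok = false; break; }
      }
      if (ok) {
        xs.push_back(px);
        ys.push_back(py);
        placed = true;
        break;
      }
    }
    if (!placed)
      stop("hard-core packing failed: could not place point %d of %d after %d attempts",
           k + 1, n, max_attempts);
  }
  for (int k = 0; k < n; ++k) { out(k, 0) = xs[k]; out(k, 1) = ys[k]; }
  return out;
}

// Raw pairwise-offset histogram: for every ordered pair (i, j), i != j, the
// offset (x_j - x_i, y_j - y_i) falling inside (-L, L)^2 increments its bin.
// Bin b (0-based) covers [-L + b*bin, -L + (b+1)*bin).
// [[Rcpp::export]]
IntegerMatrix pair_hist_cpp(NumericVector x, NumericVector y,
                            double L, double bin) {
  const int nb = (int) std::lround(2.0 * L / bin);
  IntegerMatrix out(nb, nb);
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx <= -L || dy <= -L) continue;
      const int ix = (int) std::floor((dx + L) / bin);
      const int iy = (int) std::floor((dy + L) / bin);
      if (ix >= nb || iy >= nb) continue;
      out(ix, iy)++;
    }
  }
  return out;
}

// Translation edge correction: weight of lag bin (bx, by) is the fraction of
// reference points that stay inside the window when shifted by the bin
// center. For each point the admissible bins form a rectangle in lag space,
// so we accumulate rectangle indicators with a 2D difference array.
// [[Rcpp::export]]
NumericMatrix edge_weights_cpp(NumericVector x, NumericVector y,
                               double W, double H, double L, double bin) {
  const int nb = (int) std::lround(2.0 * L / bin);
  const int n = x.size();
  NumericMatrix diff(nb + 1, nb + 1);
  for (int i = 0; i < n; ++i) {
    // bin center c_b = -L + (b + 0.5) * bin must satisfy 0 <= x + c_b < W
    // => b in [ (L - x)/bin - 0.5 , (L + W - x)/bin - 0.5 )
    int bx0 = (int) std::ceil((L - x[i]) / bin - 0.5);
    int bx1 = (int) std::floor((L + W - x[i]) / bin - 0.5 - 1e-12);
    int by0 = (int) std::ceil((L - y[i]) / bin - 0.5);
    int by1 = (int) std::floor((L + H - y[i]) / bin - 0.5 - 1e-12);
    if (bx0 < 0) bx0 = 0;
    if (by0 < 0) by0 = 0;
    if (bx1 > nb - 1) bx1 = nb - 1;
    if (by1 > nb - 1) by1 = nb - 1;
    if (bx0 > bx1 || by0 > by1) continue;
    diff(bx0, by0) += 1.0;
    diff(bx1 + 1, by0) -= 1.0;
    diff(bx0, by1 + 1) -= 1.0;
    diff(bx1 + 1, by1 + 1) += 1.0;
  }
  NumericMatrix out(nb, nb);
  for (int bx = 0; bx < nb; ++bx)
    for (int by = 0; by < nb; ++by) {
      double v = diff(bx, by);
      if (bx > 0) v += out(bx - 1, by);
      if (by > 0) v += out(bx, by - 1);
      if (bx > 0 && by > 0) v -= out(bx - 1, by - 1);
      out(bx, by) = v;
    }
  for (int bx = 0; bx < nb; ++bx)
    for (int by = 0; by < nb; ++by)
      out(bx, by) /= n;
  return out;
}

// Minimum pairwise distance (exhaustive); returns Inf for n < 2.
// [[Rcpp::export]]
double min_pair_dist_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
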