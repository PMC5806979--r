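// Scanline stereo by dynamic programming with the sampling-insensitive
// pixel dissimilarity (Birchfield-Tomasi).
//
// Cost of a monotone matching M between a left and a right scanline:
//   sum over matches of d(xl, xr)  -  |M| * kappa_r  +  N_occ * kappa_occ
// where N_occ counts maximal runs of unmatched pixels in either image
// (boundary runs included). Matches satisfy 0 <= xl - xr <= max_disparity
// and are strictly increasing in both coordinates (ordering constraint).
// The DP below is globally optimal for this objective; prefix minima are
// maintained band-limited so one row costs O(W * max_disparity).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Linearly interpolated intensity at half-pixel offsets, edge-clamped.
static inline double half_lo(const double* I, int x) {
  return x > 0 ? 0.5 * (I[x] + I[x - 1]) : I[x];
}
static inline double half_hi(const double* I, int n, int x) {
  return x < n - 1 ? 0.5 * (I[x] + I[x + 1]) : I[x];
}

// One-sided measure: distance from L[xl] to the interval spanned by the
// right signal over [xr - 1/2, xr + 1/2].
static inline double dbar(const double* L, const double* R, int n, int xl, int xr) {
  double a = half_lo(R, xr), b = half_hi(R, n, xr), c = R[xr];
  double lo = std::min(c, std::min(a, b));
  double hi = std::max(c, std::max(a, b));
  double v = L[xl];
  if (v > hi) return v - hi;
  if (v < lo) return lo - v;
  return 0.0;
}

static inline double bt_dissim(const double* L, const double* R, int n, int xl, int xr) {
  return std::min(dbar(L, R, n, xl, xr), dbar(R, L, n, xr, xl));
}

// [[Rcpp::export]]
double cpp_bt_dissim(NumericVector left, NumericVector right, int xl, int xr) {
  int n = left.size();
  return bt_dissim(REAL(left), REAL(right), n, xl, xr);
}

struct RowResult {
  std::vector<int> disp;   // -1 where unmatched
  double cost;
};

struct ArgMin {
  double v; int i, j;
};

// DP over match positions (i = left index, j = right index, j in [i-D, i]).
static RowResult dp_row(const double* L, const double* R, int W,
                        int D, double kocc, double kr,
                        std::vector<double>& S, std::vector<int>& bpi,
                        std::vector<int>& bpj) {
  const int B = D + 1;
  S.assign((size_t)W * B, INF);
  bpi.assign((size_t)W * B, -1);
  bpj.assign((size_t)W * B, -1);

  // colMin2[j]: min over rows i' <= i-2 of S(i', j), with arg row
  std::vector<double> colMin2(W, INF);
  std::vector<int> colMin2Arg(W, -1);
  ArgMin oldAll = {INF, -1, -1};             // min over colMin2[j'], j' <= i-D-2
  // per-i scratch prefixes indexed by j
  std::vector<double> rowPre(W, INF), allPre(W, INF);
  std::vector<int> rowPreArg(W, -1), allPreArgI(W, -1), allPreArgJ(W, -1);

  double bestFinal = 2.0 * kocc;             // empty matching
  int bestI = -1, bestJ = -1;

  for (int i = 0; i < W; ++i) {
    // 1. fold row i-2's band into colMin2
    if (i >= 2) {
      int r = i - 2, dm = std::min(D, r);
      for (int d = 0; d <= dm; ++d) {
        int j = r - d;
        double v = S[(size_t)r * B + d];
        if (v < colMin2[j]) { colMin2[j] = v; colMin2Arg[j] = r; }
      }
    }
    // 2. advance the "old" running min to boundary j0 = i-D-2
    int j0 = i - D - 2;
    if (j0 >= 0 && colMin2[j0] < oldAll.v) {
      oldAll.v = colMin2[j0]; oldAll.i = colMin2Arg[j0]; oldAll.j = j0;
    }
    // 3. recent-window prefix of colMin2 over j' in [max(0, j0+1), i-2]
    {
      double run = oldAll.v; int ai = oldAll.i, aj = oldAll.j;
      int lo = std::max(0, j0 + 1);
      for (int j = lo; j <= i - 2; ++j) {
        if (colMin2[j] < run) { run = colMin2[j]; ai = colMin2Arg[j]; aj = j; }
        allPre[j] = run; allPreArgI[j] = ai; allPreArgJ[j] = aj;
      }
    }
    // 4. prefix of row i-1's band (ascending j)
    if (i >= 1) {
      int r = i - 1, dm = std::min(D, r);
      double run = INF; int aj = -1;
      for (int d = dm; d >= 0; --d) {     // ascending j = r - d
        int j = r - d;
        double v = S[(size_t)r * B + d];
        if (v < run) { run = v; aj = j; }
        rowPre[j] = run; rowPreArg[j] = aj;
      }
    }
    int dmax = std::min(D, i);
    for (int d = 0; d <= dmax; ++d) {
      int j = i - d;
      double dis = bt_dissim(L, R, W, i, j);
      // start: no prior match; one leading unmatched run per nonempty prefix
      double best = kocc * ((i > 0 ? 1 : 0) + (j > 0 ? 1 : 0));
      int pi = -1, pj = -1;
      if (i > 0 && j > 0) {
        int dprev = d;                     // (i-1) - (j-1)
        if (dprev <= i - 1) {
          double c = S[(size_t)(i - 1) * B + dprev];
          if (c < best) { best = c; pi = i - 1; pj = j - 1; }
        }
        int q = j - 2;
        if (q >= (i - 1) - std::min(D, i - 1) && q >= 0 && rowPre[q] + kocc < best) {
          best = rowPre[q] + kocc; pi = i - 1; pj = rowPreArg[q];
        }
      }
      if (i >= 2 && j >= 1 && colMin2[j - 1] + kocc < best) {
        best = colMin2[j - 1] + kocc; pi = colMin2Arg[j - 1]; pj = j - 1;
      }
      if (i >= 2 && j >= 2) {
        int q = j - 2;
        double v; int ai, aj;
        if (q <= j0) { v = oldAll.v; ai = oldAll.i; aj = oldAll.j; }
        else { v = allPre[q]; ai = allPreArgI[q]; aj = allPreArgJ[q]; }
        if (v + 2.0 * kocc < best) { best = v + 2.0 * kocc; pi = ai; pj = aj; }
      }
      double val = dis - kr + best;
      S[(size_t)i * B + d] = val;
      bpi[(size_t)i * B + d] = pi;
      bpj[(size_t)i * B + d] = pj;
      double fin = val + kocc * ((i < W - 1 ? 1 : 0) + (j < W - 1 ? 1 : 0));
      if (fin < bestFinal) { bestFinal = fin; bestI = i; bestJ = j; }
    }
  }

  RowResult out;
  out.disp.assign(W, -1);
  out.cost = bestFinal;
  int ci = bestI, cj = bestJ;
  while (ci >= 0) {
    int d = ci - cj;
    out.disp[ci] = d;
    int ni = bpi[(size_t)ci * B + d];
    int nj = bpj[(size_t)ci * B + d];
    ci = ni; cj = nj;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_match_scanline(NumericVector left, NumericVector right,
                        int max_disparity, double kappa_occ, double kappa_r) {
  int W = left.size();
  std::vector<double> S; std::vector<int> bpi, bpj;
  RowResult r = dp_row(REAL(left), REAL(right), W, max_disparity,
                       kappa_occ, kappa_r, S, bpi, bpj);
  IntegerVector disp(W, NA_INTEGER);
  LogicalVector valid(W, false);
  for (int i = 0; i < W; ++i) {
    if (r.disp[i] >= 0) { disp[i] = r.disp[i]; valid[i] = true; }
  }
  return List::create(_["disparity"] = disp, _["valid"] = valid, _["cost"] = r.cost);
}

// [[Rcpp::export]]
List cpp_match_image(NumericMatrix left, NumericMatrix right,
                     int max_disparity, double kappa_occ, double kappa_r) {
  int H = left.nrow(), W = left.ncol();
  IntegerMatrix disp(H, W);
  LogicalMatrix valid(H, W);
  std::vector<double> lrow(W), rrow(W), S;
  std::vector<int> bpi, bpj;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) { lrow[x] = left(y, x); rrow[x] = right(y, x); }
    RowResult r = dp_row(lrow.data(), rrow.data(), W, max_disparity,
                         kappa_occ, kappa_r, S, bpi, bpj);
    for (int x = 0; x < W; ++x) {
      if (r.disp[x] >= 0) { disp(y, x) = r.disp[x]; valid(y, x) = true; }
      else { disp(y, x) = NA_INTEGER; valid(y, x) = false; }
    }
  }
  return List::create(_["disparity"] = disp, _["valid"] = valid);
}
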