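// Banded global alignment with affine gap costs for near-identical
// sequences (complete mitogenomes differ from the reference by < 1%,
// with rare short indels, so a narrow band around the main diagonal
// contains the optimal path).
//
// Costs: match 0, mismatch `mis`, gap open `open` (+ `ext` per base).
// Returns run-length encoded operations: 0 = M (consume both),
// 1 = I (insertion, consume sample only), 2 = D (deletion, consume
// reference only).

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_banded_align")]]
List cpp_banded_align(std::string a, std::string b,
                      int mis, int open, int ext, int pad) {
  const int n = (int)a.size();    // reference
  const int m = (int)b.size();    // sample
  const int dl = m - n;
  const int lo = std::min(0, dl) - pad;
  const int hi = std::max(0, dl) + pad;
  const int W = hi - lo + 1;
  const int INF = 1 << 28;

  // three layers: 0 = M, 1 = Ix (gap in sample, deletion),
  // 2 = Iy (gap in reference, insertion)
  std::vector<int> M((size_t)(n + 1) * W, INF),
                   Ix((size_t)(n + 1) * W, INF),
                   Iy((size_t)(n + 1) * W, INF);
  // traceback: predecessor layer for each cell, per layer
  std::vector<uint8_t> tbM((size_t)(n + 1) * W, 255),
                       tbX((size_t)(n + 1) * W, 255),
                       tbY((size_t)(n + 1) * W, 255);

  auto K = [&](int i, int j) { return (size_t)i * W + (j - i - lo); };
  auto inBand = [&](int i, int j) {
    return j >= 0 && j <= m && (j - i) >= lo && (j - i) <= hi;
  };

  M[K(0, 0)] = 0;
  for (int j = 1; j <= m && inBand(0, j); ++j) {
    Iy[K(0, j)] = open + ext * j;
    tbY[K(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    if (inBand(i, 0)) {
      Ix[K(i, 0)] = open + ext * i;
      tbX[K(i, 0)] = (i == 1) ? 0 : 1;
    }
    int jlo = std::max(0, i + lo), jhi = std::min(m, i + hi);
    for (int j = std::max(1, jlo); j <= jhi; ++j) {
      size_t k = K(i, j);
      // M
      if (inBand(i - 1, j - 1)) {
        size_t p = K(i - 1, j - 1);
        int sub = (a[i - 1] == b[j - 1]) ? 0 : mis;
        int bestv = M[p]; uint8_t bl = 0;
        if (Ix[p] < bestv) { bestv = Ix[p]; bl = 1; }
        if (Iy[p] < bestv) { bestv = Iy[p]; bl = 2; }
        if (bestv < INF) { M[k] = bestv + sub; tbM[k] = bl; }
      }
      // Ix: consume a[i-1], gap in b
      if (inBand(i - 1, j)) {
        size_t p = K(i - 1, j);
        int vM = (M[p] < INF) ? M[p] + open + ext : INF;
        int vX = (Ix[p] < INF) ? Ix[p] + ext : INF;
        int vY = (Iy[p] < INF) ? Iy[p] + open + ext : INF;
        int bestv = vM; uint8_t bl = 0;
        if (vX < bestv) { bestv = vX; bl = 1; }
        if (vY < bestv) { bestv = vY; bl = 2; }
        if (bestv < INF) { Ix[k] = bestv; tbX[k] = bl; }
      }
      // Iy: consume b[j-1], gap in a
      if (inBand(i, j - 1)) {
        size_t p = K(i, j - 1);
        int vM = (M[p] < INF) ? M[p] + open + ext : INF;
        int vY = (Iy[p] < INF) ? Iy[p] + ext : INF;
        int vX = (Ix[p] < INF) ? Ix[p] + open + ext : INF;
        int bestv = vM; uint8_t bl = 0;
        if (vX < bestv) { bestv = vX; bl = 1; }
        if (vY < bestv) { bestv = vY; bl = 2; }
        if (bestv < INF) { Iy[k] = bestv; tbY[k] = bl; }
      }
    }
  }

  size_t kend = K(n, m);
  int bestv = M[kend]; int layer = 0;
  if (Ix[kend] < bestv) { bestv = Ix[kend]; layer = 1; }
  if (Iy[kend] < bestv) { bestv = Iy[kend]; layer = 2; }
  if (bestv >= INF) stop("alignment fell outside the band; increase pad");

  // traceback
  std::vector<int> ops;  // 0 M, 1 I, 2 D, reversed
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t k = K(i, j);
    if (layer == 0) {
      ops.push_back(0);
      layer = tbM[k]; --i; --j;
    } else if (layer == 1) {
      ops.push_back(2);
      layer = tbX[k]; --i;
    } else {
      ops.push_back(1);
      layer = tbY[k]; --j;
    }
  }
  // run-length encode in forward order
  std::vector<int> op, len;
  for (int t = (int)ops.size() - 1; t >= 0; --t) {
    if (!op.empty() && op.back() == ops[t]) ++len.back();
    else { op.push_back(ops[t]); len.push_back(1); }
  }
  return List::create(_["cost"] = bestv,
                      _["op"] = IntegerVector(op.begin(), op.end()),
                      _["len"] = IntegerVector(len.begin(), len.end()));
}
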