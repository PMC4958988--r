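#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Object perimeters from a label matrix by Moore boundary tracing.
// Chain steps between boundary pixel centres are weighted 1
// (4-neighbour) or sqrt(2) (diagonal), which reduces the rasterisation
// bias of 4-connected edge counting in compactness statistics such as
// 4*pi*A/P^2. Labels are positive integers; 0 is background. Returns a
// perimeter per label 1..nlab (0 for labels absent from the map).
// A single isolated pixel gets perimeter 4 (its cell boundary).

static const int DR[8] = {0, 1, 1, 1, 0, -1, -1, -1};   // E SE S SW W NW N NE
static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const double WT[8] = {1.0, M_SQRT2, 1.0, M_SQRT2,
                             1.0, M_SQRT2, 1.0, M_SQRT2};

// [[Rcpp::export]]
NumericVector chain_perimeter(IntegerMatrix lab, int nlab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(nlab, 0.0);
  std::vector<long> startR(nlab, -1), startC(nlab, -1);
  // topmost-leftmost pixel of each label (column-major scan is fine:
  // we just need a boundary pixel whose west neighbour is not the label)
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int L = lab(r, c);
      if (L > 0 && L <= nlab && startR[L - 1] < 0) {
        startR[L - 1] = r; startC[L - 1] = c;
      }
    }
  for (int L = 1; L <= nlab; ++L) {
    if (startR[L - 1] < 0) continue;
    const int sr = (int)startR[L - 1], sc = (int)startC[L - 1];
    // backtrack starts at the (background) west neighbour of the start
    int cr = sr, cc = sc, btr = sr, btc = sc - 1;
    const int b0r = btr, b0c = btc;
    double p = 0.0;
    bool isolated = true;
    long guard = 8L * (long)nr * nc + 16;
    while (guard-- > 0) {
      // direction from current to backtrack
      int dbt = 0;
      for (int k = 0; k < 8; ++k)
        if (cr + DR[k] == btr && cc + DC[k] == btc) { dbt = k; break; }
      int found = -1, lbr = btr, lbc = btc;
      for (int k = 1; k <= 8; ++k) {
        int dir = (dbt + k) % 8;
        int rr = cr + DR[dir], ccn = cc + DC[dir];
        bool in = rr >= 0 && rr < nr && ccn >= 0 && ccn < nc;
        if (in && lab(rr, ccn) == L) { found = dir; break; }
        lbr = rr; lbc = ccn;
      }
      if (found < 0) { isolated = true; break; }   // single pixel
      isolated = false;
      p += WT[found];
      btr = lbr; btc = lbc;
      cr += DR[found]; cc += DC[found];
      if (cr == sr && cc == sc && btr == b0r && btc == b0c) break;
    }
    per[L - 1] = isolated ? 4.0 : p;
  }
  return per;
}
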