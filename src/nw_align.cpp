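#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap costs.
// A gap of length g costs gap_open + g * gap_ext.  N scores 0 against
// anything.  Ties resolve deterministically (diagonal > gap-in-b > gap-in-a).

static inline int sub_score(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return 0;
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_ext) {
  const int NEG = INT32_MIN / 4;
  const size_t na = a.size(), nb = b.size();
  const size_t W = nb + 1;
  // state scores, rolling rows: 0 = M (diagonal), 1 = X (gap in b), 2 = Y (gap in a)
  std::vector<int> M0(W), X0(W), Y0(W), M1(W), X1(W), Y1(W);
  // traceback: 2 bits per state = predecessor state index
  std::vector<uint8_t> tb((na + 1) * W);

  M0[0] = 0; X0[0] = NEG; Y0[0] = NEG;
  for (size_t j = 1; j <= nb; ++j) {
    M0[j] = NEG; X0[j] = NEG;
    Y0[j] = -(gap_open + (int)j * gap_ext);
    tb[j] = (uint8_t)(2 << 4);       // Y from Y
  }
  for (size_t i = 1; i <= na; ++i) {
    M1[0] = NEG; Y1[0] = NEG;
    X1[0] = -(gap_open + (int)i * gap_ext);
    tb[i * W] = (uint8_t)(1 << 2);   // X from X
    for (size_t j = 1; j <= nb; ++j) {
      int s = sub_score(a[i - 1], b[j - 1], match, mismatch);
      // M: from any state at (i-1, j-1)
      int m0 = M0[j - 1], x0 = X0[j - 1], y0 = Y0[j - 1];
      int bestM = m0; uint8_t fromM = 0;
      if (x0 > bestM) { bestM = x0; fromM = 1; }
      if (y0 > bestM) { bestM = y0; fromM = 2; }
      int Mv = bestM + s;
      // X: consume a[i-1], gap in b; from (i-1, j)
      int fromTopM = M0[j] - (gap_open + gap_ext);
      int fromTopX = X0[j] - gap_ext;
      int fromTopY = Y0[j] - (gap_open + gap_ext);
      int Xv = fromTopM; uint8_t fromX = 0;
      if (fromTopX > Xv) { Xv = fromTopX; fromX = 1; }
      if (fromTopY > Xv) { Xv = fromTopY; fromX = 2; }
      // Y: consume b[j-1], gap in a; from (i, j-1)
      int fromLeftM = M1[j - 1] - (gap_open + gap_ext);
      int fromLeftX = X1[j - 1] - (gap_open + gap_ext);
      int fromLeftY = Y1[j - 1] - gap_ext;
      int Yv = fromLeftM; uint8_t fromY = 0;
      if (fromLeftX > Yv) { Yv = fromLeftX; fromY = 1; }
      if (fromLeftY > Yv) { Yv = fromLeftY; fromY = 2; }
      M1[j] = Mv; X1[j] = Xv; Y1[j] = Yv;
      tb[i * W + j] = (uint8_t)(fromM | (fromX << 2) | (fromY << 4));
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  int best = M0[nb]; int state = 0;
  if (X0[nb] > best) { best = X0[nb]; state = 1; }
  if (Y0[nb] > best) { best = Y0[nb]; state = 2; }

  std::string ga, gb;
  ga.reserve(na + nb); gb.reserve(na + nb);
  size_t i = na, j = nb;
  while (i > 0 || j > 0) {
    uint8_t cell = tb[i * W + j];
    int prev;
    if (state == 0) {
      prev = cell & 3;
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = (cell >> 2) & 3;
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i;
    } else {
      prev = (cell >> 4) & 3;
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j;
    }
    state = prev;
    if (i == 0 && j > 0) state = 2;
    else if (j == 0 && i > 0) state = 1;
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = best);
}
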