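#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment score (Gotoh three-state, score only).
// Sequences arrive as 0-based row indices into the substitution matrix.
// Gap convention: a gap of length g costs open + g * extend (open charged
// once at opening, extend per gap residue including the first);
// open/extend are passed as positive magnitudes.
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix mat,
                 int gap_open, int gap_extend) {
  const int la = a.size(), lb = b.size();
  const int open_first = gap_open + gap_extend;  // cost of first gap residue
  const int NEG = -1000000000;
  std::vector<int> Hrow(lb + 1, 0), Frow(lb + 1, NEG);
  int best = 0;
  for (int i = 1; i <= la; ++i) {
    const int ai = a[i - 1];
    int diag = 0;        // H[i-1][j-1]
    int Hleft = 0;       // H[i][j-1]
    int Eleft = NEG;     // E[i][j-1]
    for (int j = 1; j <= lb; ++j) {
      const int up = Hrow[j];  // H[i-1][j]
      const int e = std::max(Hleft - open_first, Eleft - gap_extend);
      const int f = std::max(up - open_first, Frow[j] - gap_extend);
      int h = diag + mat(ai, b[j - 1]);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      if (h > best) best = h;
      diag = up;
      Hrow[j] = h;
      Frow[j] = f;
      Hleft = h;
      Eleft = e;
    }
  }
  return best;
}
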