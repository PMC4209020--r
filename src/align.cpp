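#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of each member string against one
// reference, with match/mismatch scores and a linear gap penalty. Returns a
// matrix with one row per member: matching columns, columns where both
// sequences carry a residue, and total alignment length. Identity and
// coverage fractions are derived in R. Traceback prefers the diagonal, then
// the member-gap move, so results are deterministic.
// [[Rcpp::export(name = ".alignStatsBatch")]]
IntegerMatrix alignStatsBatch(CharacterVector members, std::string ref,
                              int match = 1, int mismatch = -1, int gap = -2) {
  const int n = members.size();
  const int m = ref.size();
  IntegerMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    std::string a = as<std::string>(members[r]);
    const int la = a.size();
    std::vector<std::vector<int> > S(la + 1, std::vector<int>(m + 1, 0));
    for (int i = 0; i <= la; ++i) S[i][0] = i * gap;
    for (int j = 0; j <= m; ++j) S[0][j] = j * gap;
    for (int i = 1; i <= la; ++i) {
      const char ai = a[i - 1];
      for (int j = 1; j <= m; ++j) {
        const int d = S[i - 1][j - 1] + (ai == ref[j - 1] ? match : mismatch);
        const int u = S[i - 1][j] + gap;
        const int l = S[i][j - 1] + gap;
        int best = d;
        if (u > best) best = u;
        if (l > best) best = l;
        S[i][j] = best;
      }
    }
    int i = la, j = m, matches = 0, both = 0, len = 0;
    while (i > 0 || j > 0) {
      if (i > 0 && j > 0 &&
          S[i][j] == S[i - 1][j - 1] + (a[i - 1] == ref[j - 1] ? match : mismatch)) {
        ++both;
        if (a[i - 1] == ref[j - 1]) ++matches;
        --i; --j; ++len;
      } else if (i > 0 && S[i][j] == S[i - 1][j] + gap) {
        --i; ++len;
      } else {
        --j; ++len;
      }
    }
    out(r, 0) = matches;
    out(r, 1) = both;
    out(r, 2) = len;
  }
  return out;
}
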