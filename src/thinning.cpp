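#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen thinning of a binary image (0/1 integer matrix).
// Returns the 1-px-wide, 8-connected skeleton with topology preserved.
// [[Rcpp::export]]
IntegerMatrix zhang_suen_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // P2..P9 clockwise from north (north = r-1)
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (!p2 && p3) + (!p3 && p4) + (!p4 && p5) + (!p5 && p6) +
                  (!p6 && p7) + (!p7 && p8) + (!p8 && p9) + (!p9 && p2);
          if (A != 1) continue;
          if (pass == 0) {
            if ((p2 && p4 && p6) || (p4 && p6 && p8)) continue;
          } else {
            if ((p2 && p4 && p8) || (p2 && p6 && p8)) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          img(kill[i].first, kill[i].second) = 0;
      }
    }
  }
  return img;
}
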