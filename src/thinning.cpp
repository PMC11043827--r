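// Zhang-Suen morphological thinning of a binary mask to a one-pixel-wide
// skeleton.  Used for reticulum length measurement; no R-side loop could do
// this at acquisition scale.
#include <Rcpp.h>
using namespace Rcpp;

static inline int at(const LogicalMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// [[Rcpp::export(name = ".thin_zhang_suen")]]
LogicalMatrix thin_zhang_suen(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  std::vector<std::pair<int,int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          // neighbours clockwise from north (p2..p9)
          int p2 = at(m, r - 1, c),     p3 = at(m, r - 1, c + 1);
          int p4 = at(m, r, c + 1),     p5 = at(m, r + 1, c + 1);
          int p6 = at(m, r + 1, c),     p7 = at(m, r + 1, c - 1);
          int p8 = at(m, r, c - 1),     p9 = at(m, r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (!p2 && p3) + (!p3 && p4) + (!p4 && p5) + (!p5 && p6) +
                  (!p6 && p7) + (!p7 && p8) + (!p8 && p9) + (!p9 && p2);
          if (a != 1) continue;
          if (step == 0) {
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
          m(kill[i].first, kill[i].second) = false;
      }
    }
  }
  return m;
}
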