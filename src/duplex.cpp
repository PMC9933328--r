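#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular RNA/RNA hybridisation dynamic program, RNAhybrid-style:
// antiparallel duplex, Watson-Crick + GU pairs, nearest-neighbour stacks,
// bulges and internal loops capped at 1 nt per side, no intramolecular
// structure. Bases are coded A=0, C=1, G=2, U=3.

static const double NEG_INF = -1e18;
static const double POS_INF = 1e18;

// pair codes follow the R-side table ordering: AU CG GC GU UA UG
static inline int pairCode(int q, int t) {
  if (q == 0 && t == 3) return 0;  // AU
  if (q == 1 && t == 2) return 1;  // CG
  if (q == 2 && t == 1) return 2;  // GC
  if (q == 2 && t == 3) return 3;  // GU
  if (q == 3 && t == 0) return 4;  // UA
  if (q == 3 && t == 2) return 5;  // UG
  return -1;
}

// [[Rcpp::export(name = ".duplexDP")]]
List duplexDP(IntegerVector query, IntegerVector target,
              NumericMatrix stacks, double init, NumericVector endPen,
              double bulge1, double loop11) {
  const int m = query.size();
  const int nt = target.size();
  if (m == 0 || nt == 0)
    return List::create(_["energy"] = R_PosInf);

  // reverse the target so both indices increase along the duplex
  std::vector<int> r(nt);
  for (int j = 0; j < nt; ++j) r[j] = target[nt - 1 - j];

  std::vector<double> E((size_t)m * nt, POS_INF);
  std::vector<int> par((size_t)m * nt, -1);  // parent cell, -1 = duplex start
  std::vector<int> pc((size_t)m * nt, -1);

  double best = POS_INF;
  int bestCell = -1;

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < nt; ++j) {
      const int p = pairCode(query[i], r[j]);
      if (p < 0) continue;
      const size_t c = (size_t)i * nt + j;
      pc[c] = p;
      double e = init + endPen[p];  // open a duplex at this pair
      int from = -1;
      // contiguous stack
      if (i >= 1 && j >= 1) {
        const size_t c2 = c - nt - 1;
        if (pc[c2] >= 0 && E[c2] < POS_INF) {
          double cand = E[c2] + stacks(pc[c2], p);
          if (cand < e) { e = cand; from = (int)c2; }
        }
      }
      // 1-nt bulge in query (stack retained across a bulge of one)
      if (i >= 2 && j >= 1) {
        const size_t c2 = c - 2 * nt - 1;
        if (pc[c2] >= 0 && E[c2] < POS_INF) {
          double cand = E[c2] + bulge1 + stacks(pc[c2], p);
          if (cand < e) { e = cand; from = (int)c2; }
        }
      }
      // 1-nt bulge in target
      if (i >= 1 && j >= 2) {
        const size_t c2 = c - nt - 2;
        if (pc[c2] >= 0 && E[c2] < POS_INF) {
          double cand = E[c2] + bulge1 + stacks(pc[c2], p);
          if (cand < e) { e = cand; from = (int)c2; }
        }
      }
      // 1x1 internal loop (no stacking term across the loop)
      if (i >= 2 && j >= 2) {
        const size_t c2 = c - 2 * nt - 2;
        if (pc[c2] >= 0 && E[c2] < POS_INF) {
          double cand = E[c2] + loop11;
          if (cand < e) { e = cand; from = (int)c2; }
        }
      }
      E[c] = e;
      par[c] = from;
      const double closed = e + endPen[p];
      if (closed < best) { best = closed; bestCell = (int)c; }
    }
  }

  if (bestCell < 0)
    return List::create(_["energy"] = R_PosInf);

  // traceback: paired positions (1-based, original orientation)
  std::vector<int> qpos, tpos;
  int c = bestCell;
  while (c >= 0) {
    int i = c / nt, j = c % nt;
    qpos.push_back(i + 1);
    tpos.push_back(nt - j);  // reversed index -> original 1-based position
    c = par[c];
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(tpos.begin(), tpos.end());

  return List::create(_["energy"] = best,
                      _["qpos"] = wrap(qpos),
                      _["tpos"] = wrap(tpos));
}
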