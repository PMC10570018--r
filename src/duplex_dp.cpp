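#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex DP.
//
// Bases are coded A=0, C=1, G=2, U=3. The target is supplied 5'->3';
// internally it is reversed so that an antiparallel non-crossing
// pairing becomes co-linear (both indices increasing), turning the
// problem into a gapped chain of helices.
//
// Model: each WC/GU pair scores a weight from `wmat`; helices must be
// >= 2 consecutive pairs; between consecutive helices an interior
// loop/bulge of total unpaired length g (summed over both strands,
// g >= 1) costs gap_open + gap_extend * g; dangling ends are free.
//
// Tie-break: higher score, then more paired bases, then the 5'-most
// paired target base (largest reversed index of the final pair).

struct Cell {
  double score;
  int npairs;
  int prev_state; // 0 = start, 1 = from M1, 2 = from M2
  int pi, pk;     // previous pair coordinates (1-based), 0 if none
  bool valid;
};

static inline bool better(double s1, int n1, double s2, int n2) {
  if (s1 != s2) return s1 > s2;
  return n1 > n2;
}

// [[Rcpp::export]]
List duplex_dp_cpp(IntegerVector mi, IntegerVector tg,
                   NumericMatrix wmat, double gap_open,
                   double gap_extend) {
  const int m = mi.size();
  const int n = tg.size();
  // reversed target codes
  std::vector<int> tr(n);
  for (int k = 0; k < n; ++k) tr[k] = tg[n - 1 - k];

  auto W = [&](int i, int k) -> double {
    return wmat(mi[i - 1], tr[k - 1]); // 0 when not pairable
  };

  std::vector<Cell> M1((m + 1) * (n + 1)), M2((m + 1) * (n + 1));
  auto at = [&](std::vector<Cell>& M, int i, int k) -> Cell& {
    return M[i * (n + 1) + k];
  };
  for (int i = 0; i <= m; ++i)
    for (int k = 0; k <= n; ++k) {
      at(M1, i, k).valid = false;
      at(M2, i, k).valid = false;
    }

  for (int i = 1; i <= m; ++i) {
    for (int k = 1; k <= n; ++k) {
      double w = W(i, k);
      if (w <= 0) continue;
      // M1: first pair of a (new) helix
      {
        Cell c;
        c.score = w; c.npairs = 1; c.prev_state = 0; c.pi = 0; c.pk = 0;
        c.valid = true;
        for (int ip = 1; ip < i; ++ip) {
          for (int kp = 1; kp < k; ++kp) {
            int g = (i - ip - 1) + (k - kp - 1);
            if (g < 1) continue; // adjacent => helix continuation, not M1
            Cell& p = at(M2, ip, kp);
            if (!p.valid) continue;
            double s = p.score + w - (gap_open + gap_extend * g);
            if (better(s, p.npairs + 1, c.score, c.npairs)) {
              c.score = s; c.npairs = p.npairs + 1;
              c.prev_state = 2; c.pi = ip; c.pk = kp;
            }
          }
        }
        at(M1, i, k) = c;
      }
      // M2: helix extension (run length >= 2)
      if (i >= 2 && k >= 2) {
        Cell& p1 = at(M1, i - 1, k - 1);
        Cell& p2 = at(M2, i - 1, k - 1);
        Cell c; c.valid = false;
        if (p1.valid) {
          c.score = p1.score + w; c.npairs = p1.npairs + 1;
          c.prev_state = 1; c.pi = i - 1; c.pk = k - 1; c.valid = true;
        }
        if (p2.valid) {
          double s = p2.score + w;
          if (!c.valid || better(s, p2.npairs + 1, c.score, c.npairs)) {
            c.score = s; c.npairs = p2.npairs + 1;
            c.prev_state = 2; c.pi = i - 1; c.pk = k - 1; c.valid = true;
          }
        }
        if (c.valid) at(M2, i, k) = c;
      }
    }
  }

  // best complete pairing ends a helix (M2) or is empty
  double best = 0.0; int bestn = 0, bi = 0, bk = 0;
  bool found = false;
  for (int i = 1; i <= m; ++i) {
    for (int k = 1; k <= n; ++k) {
      Cell& c = at(M2, i, k);
      if (!c.valid) continue;
      bool take;
      if (!found) {
        take = better(c.score, c.npairs, best, bestn);
      } else if (c.score != best) {
        take = c.score > best;
      } else if (c.npairs != bestn) {
        take = c.npairs > bestn;
      } else {
        take = k > bk; // larger reversed index = 5'-most target start
      }
      if (take) {
        best = c.score; bestn = c.npairs; bi = i; bk = k; found = true;
      }
    }
  }

  IntegerMatrix pairs(bestn, 2);
  if (found) {
    int i = bi, k = bk, state = 2, row = bestn - 1;
    while (i > 0) {
      pairs(row, 0) = i;
      pairs(row, 1) = n - k + 1; // back to original 5'->3' target coords
      --row;
      Cell& c = (state == 2) ? at(M2, i, k) : at(M1, i, k);
      int ps = c.prev_state, pi = c.pi, pk = c.pk;
      if (ps == 0) break;
      i = pi; k = pk; state = ps;
    }
  }
  return List::create(_["score"] = found ? best : 0.0,
                      _["pairs"] = pairs);
}
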