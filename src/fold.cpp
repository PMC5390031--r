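#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Simplified nearest-neighbour hairpin folder: only stacked base pairs
// contribute energy (no dangles, no loop penalties), minimum hairpin
// loop of 3 unpaired bases. Pair strengths: GC 1.5, AU 1.0, GU 0.5
// kcal/mol per closing pair; a stack of two pairs scores minus the sum
// of the two strengths. Finds the minimum-energy nested structure by
// dynamic programming; ties broken in favour of fewer pairs.

static const double INF = 1e9;
static const int MINLOOP = 3;

static int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

static double pairStrength(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1.0;  // AU
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return 1.5;  // GC
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 0.5;  // GU
  return -1.0;
}

struct FoldDP {
  int n;
  std::vector<int> b;
  std::vector<double> W, V;
  std::vector<bool> canP;

  double &w(int i, int j) { return W[i * n + j]; }
  double &v(int i, int j) { return V[i * n + j]; }
  bool cp(int i, int j) {
    return j - i - 1 >= MINLOOP && b[i] >= 0 && b[j] >= 0 &&
           pairStrength(b[i], b[j]) > 0;
  }
  double stackE(int i, int j) {
    return -(pairStrength(b[i], b[j]) + pairStrength(b[i + 1], b[j - 1]));
  }

  void fill() {
    W.assign((size_t)n * n, 0.0);
    V.assign((size_t)n * n, INF);
    for (int span = 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        if (cp(i, j)) {
          double best = w(i + 1, j - 1);
          if (cp(i + 1, j - 1))
            best = std::min(best, stackE(i, j) + v(i + 1, j - 1));
          v(i, j) = best;
        }
        double best = std::min(w(i + 1, j), w(i, j - 1));
        for (int k = i; k < j; ++k)
          best = std::min(best, w(i, k) + w(k + 1, j));
        if (v(i, j) < best) best = v(i, j);
        w(i, j) = best;
      }
    }
  }

  void traceW(int i, int j, std::string &st);
  void traceV(int i, int j, std::string &st);
};

void FoldDP::traceV(int i, int j, std::string &st) {
  st[i] = '(';
  st[j] = ')';
  if (cp(i + 1, j - 1) &&
      std::abs(v(i, j) - (stackE(i, j) + v(i + 1, j - 1))) < 1e-9 &&
      stackE(i, j) + v(i + 1, j - 1) <= w(i + 1, j - 1) + 1e-9) {
    traceV(i + 1, j - 1, st);
  } else {
    traceW(i + 1, j - 1, st);
  }
}

void FoldDP::traceW(int i, int j, std::string &st) {
  if (i >= j) return;
  double t = w(i, j);
  if (t >= -1e-12) return;  // nothing stabilising in here
  if (std::abs(t - w(i + 1, j)) < 1e-9) { traceW(i + 1, j, st); return; }
  if (std::abs(t - w(i, j - 1)) < 1e-9) { traceW(i, j - 1, st); return; }
  for (int k = i; k < j; ++k) {
    if (std::abs(t - (w(i, k) + w(k + 1, j))) < 1e-9 &&
        w(i, k) < -1e-12 && w(k + 1, j) < -1e-12) {
      traceW(i, k, st);
      traceW(k + 1, j, st);
      return;
    }
  }
  traceV(i, j, st);  // t == V(i,j)
}

// [[Rcpp::export(name = ".fold_builtin_cpp")]]
List fold_builtin_cpp(std::string seq) {
  FoldDP dp;
  dp.n = (int)seq.size();
  dp.b.resize(dp.n);
  for (int i = 0; i < dp.n; ++i) dp.b[i] = baseCode(seq[i]);
  std::string st(dp.n, '.');
  if (dp.n < 2) return List::create(_["structure"] = st, _["mfe"] = 0.0);
  dp.fill();
  double mfe = dp.w(0, dp.n - 1);
  if (mfe < -1e-12) dp.traceW(0, dp.n - 1, st);
  else mfe = 0.0;
  return List::create(_["structure"] = st, _["mfe"] = mfe);
}
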