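#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Does any window of w consecutive bases contain >= k of the sorted
// positions? Inclusive windows: k positions qualify iff their span is
// <= w - 1. Circular genomes wrap the first k-1 positions past G.
static bool window_hit(std::vector<int> &pos, int k, int w, double G,
                       bool circular) {
  int n = pos.size();
  if (n < k) return false;
  std::sort(pos.begin(), pos.end());
  for (int i = 0; i + k - 1 < n; ++i)
    if (pos[i + k - 1] - pos[i] <= w - 1) return true;
  if (circular) {
    for (int j = 0; j < k - 1; ++j) {
      int i = n - k + 1 + j;               // run crossing the origin
      double span = (double)pos[j] + G - (double)pos[i];
      if (span <= w - 1) return true;
    }
  }
  return false;
}

// Monte-Carlo scan statistic: fraction of replicates in which some window
// of length w contains >= k of N uniform positions on {1..G}. Uses R's
// RNG, so set.seed() makes runs reproducible. For large N on a linear
// genome, positions are bucketed into width-w cells first: a window of
// length w intersects at most two adjacent cells, so a full sort is only
// needed when some adjacent cell pair holds >= k points (rare under the
// null), which keeps the inner loop O(N) per replicate.
// [[Rcpp::export]]
int scan_mc_cpp(double G, int N, int w, int k, int reps, bool circular) {
  std::vector<int> pos(N);
  bool bucketed = (!circular) && N > 512;
  long nb = bucketed ? (long)((G + w - 1) / w) : 0;
  std::vector<int> cell(bucketed ? nb : 0, 0);
  int successes = 0;

  for (int rep = 0; rep < reps; ++rep) {
    if ((rep & 4095) == 0) Rcpp::checkUserInterrupt();
    bool candidate = false;
    for (int j = 0; j < N; ++j) {
      int p = (int)(unif_rand() * G);
      if (p >= (int)G) p = (int)G - 1;
      pos[j] = p + 1;
      if (bucketed) {
        long b = p / w;
        int c = ++cell[b];
        if (!candidate) {
          if (c >= k) candidate = true;
          else if (b + 1 < nb && c + cell[b + 1] >= k) candidate = true;
          else if (b > 0 && c + cell[b - 1] >= k) candidate = true;
        }
      }
    }
    if (bucketed) {
      if (candidate && window_hit(pos, k, w, G, false)) ++successes;
      for (int j = 0; j < N; ++j) cell[(pos[j] - 1) / w] = 0;
    } else {
      if (window_hit(pos, k, w, G, circular)) ++successes;
    }
  }
  return successes;
}
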