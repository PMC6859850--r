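#include <Rcpp.h>
using namespace Rcpp;

static inline bool can_pair(char a, char b) {
  // DNA alphabet, RNA pairing rules: A:T(U), G:C, G:T(U) wobble
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Maximum number of nested base pairs (Nussinov DP), minimum hairpin loop
// of 3 unpaired nucleotides between any pair.
// [[Rcpp::export(name = ".max_pairs")]]
int max_pairs(std::string seq) {
  int n = seq.size();
  if (n < 5) return 0;
  std::vector<std::vector<int> > dp(n, std::vector<int>(n, 0));
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[i][j - 1];
      for (int k = i; k <= j - 4; ++k) {
        if (can_pair(seq[k], seq[j])) {
          int left = (k > i) ? dp[i][k - 1] : 0;
          int inner = dp[k + 1][j - 1] + 1;
          if (left + inner > best) best = left + inner;
        }
      }
      dp[i][j] = best;
    }
  }
  return dp[0][n - 1];
}
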