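#include <Rcpp.h>
using namespace Rcpp;

// Base-pair weights: G-C = 3, A-U = 2, G-U = 1 (T read as U).
// Encoding: A=0, C=1, G=2, U/T=3.
static inline int pair_weight(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1;
  return 0;
}

// Maximum total pair weight over nested structures with a minimum hairpin
// loop of `minloop` unpaired nucleotides, O(n^3) dynamic program.
static int nussinov_score(const std::vector<int>& s, int minloop) {
  int n = (int)s.size();
  if (n == 0) return 0;
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = minloop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1];  // j unpaired
      for (int k = i; k <= j - minloop - 1; ++k) {
        int w = pair_weight(s[k], s[j]);
        if (w > 0) {
          int left = (k > i) ? M[i][k - 1] : 0;
          int inner = (k + 1 <= j - 1) ? M[k + 1][j - 1] : 0;
          int cand = left + inner + w;
          if (cand > best) best = cand;
        }
      }
      M[i][j] = best;
    }
  }
  return M[0][n - 1];
}

static std::vector<int> encode(const std::string& seq) {
  std::vector<int> s(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    switch (seq[i]) {
      case 'A': case 'a': s[i] = 0; break;
      case 'C': case 'c': s[i] = 1; break;
      case 'G': case 'g': s[i] = 2; break;
      case 'U': case 'u': case 'T': case 't': s[i] = 3; break;
      default: stop("invalid character '%s' in sequence",
                    std::string(1, seq[i]).c_str());
    }
  }
  return s;
}

// [[Rcpp::export]]
NumericVector fold_mfe_cpp(CharacterVector seqs, int minloop) {
  NumericVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::vector<int> s = encode(as<std::string>(seqs[i]));
    out[i] = -(double)nussinov_score(s, minloop);
  }
  return out;
}

// Sliding-window profile: fold the `window`-nt window centred at each
// requested position (0-based, transcript coordinates); windows extending
// past either end yield NA.
// [[Rcpp::export]]
NumericVector window_mfe_cpp(std::string seq, IntegerVector centers,
                             int window, int minloop) {
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  int half = (window - 1) / 2;
  NumericVector out(centers.size());
  for (R_xlen_t c = 0; c < centers.size(); ++c) {
    int mid = centers[c];
    int lo = mid - half, hi = mid + half;  // inclusive
    if (lo < 0 || hi >= n) {
      out[c] = NA_REAL;
      continue;
    }
    std::vector<int> w(s.begin() + lo, s.begin() + hi + 1);
    out[c] = -(double)nussinov_score(w, minloop);
  }
  return out;
}
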