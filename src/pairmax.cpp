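#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

// Non-thermodynamic fallback folding: weighted base-pair maximization
// (Nussinov-style DP with per-pair pseudo-energies and a minimum hairpin
// loop of 3 nt). Pseudo-energies: GC -3, AT -2, GT -1 "kcal/mol". These
// values rank pairings sensibly but are NOT free energies; the default
// pipeline backend is a thermodynamic engine.
//
// Recursion (pair-anchored, O(n^3) with a small constant):
//   W(i,j) = min( W(i,j-1),
//                 min_{i<=k<=j-4, k~j} W(i,k-1) + ps(k,j) + W(k+1,j-1) )

static const int MIN_LOOP = 3;

static inline double pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1.0;
  return 1.0;  // not pairable
}

// [[Rcpp::export]]
List fold_pairmax_cpp(CharacterVector seqs) {
  int nseq = seqs.size();
  CharacterVector structures(nseq);
  NumericVector energies(nseq);

  for (int s = 0; s < nseq; ++s) {
    std::string sq = as<std::string>(seqs[s]);
    int n = sq.size();
    std::vector<double> W((size_t) n * n, 0.0);
    // W[i*n + j] for i <= j; 0 when the window cannot pair
    #define WIDX(i, j) W[(size_t)(i) * n + (j)]

    for (int j = MIN_LOOP + 1; j < n; ++j) {
      char cj = sq[j];
      for (int i = j - MIN_LOOP - 1; i >= 0; --i) {
        double best = WIDX(i, j - 1);  // j unpaired
        for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
          double ps = pair_score(sq[k], cj);
          if (ps > 0) continue;
          double v = ps + WIDX(k + 1, j - 1);
          if (k > i) v += WIDX(i, k - 1);
          if (v < best) best = v;
        }
        WIDX(i, j) = best;
      }
      if (j % 128 == 0) Rcpp::checkUserInterrupt();
    }

    // traceback
    std::string db(n, '.');
    std::vector<std::pair<int, int> > stack;
    if (n > MIN_LOOP + 1) stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      if (j - i < MIN_LOOP + 1) continue;
      double e = WIDX(i, j);
      if (e == 0.0) continue;
      if (e == WIDX(i, j - 1)) {
        stack.push_back(std::make_pair(i, j - 1));
        continue;
      }
      bool done = false;
      for (int k = i; k <= j - MIN_LOOP - 1 && !done; ++k) {
        double ps = pair_score(sq[k], sq[j]);
        if (ps > 0) continue;
        double v = ps + WIDX(k + 1, j - 1);
        if (k > i) v += WIDX(i, k - 1);
        if (v == e) {
          db[k] = '('; db[j] = ')';
          if (k > i) stack.push_back(std::make_pair(i, k - 1));
          stack.push_back(std::make_pair(k + 1, j - 1));
          done = true;
        }
      }
      if (!done) stop("pairmax traceback failed");  // cannot happen
    }
    #undef WIDX

    structures[s] = db;
    energies[s] = (n > MIN_LOOP + 1) ? W[(size_t) 0 * n + (n - 1)] : 0.0;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["structure"] = structures, _["mfe"] = energies);
}
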