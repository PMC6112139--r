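#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base-pair maximization folder (Nussinov-style dynamic program) over the
// DNA alphabet: canonical Watson-Crick pairs plus G:T wobble (the DNA image
// of G:U), minimum hairpin loop of 3 unpaired nucleotides.  The reported
// score is a pseudo minimum free energy: -(pair count) - 0.5 * (number of
// stacked pair adjacencies), so more pairs and more stacking give a lower
// (more negative) value.  It is NOT a thermodynamic energy; a thermodynamic
// folder can be plugged in upstream as long as it returns dot-bracket.

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default: return false;
  }
}

static const int MIN_LOOP = 3;

static void traceback(int i, int j,
                      const std::vector<std::vector<int> >& M,
                      const std::string& s, std::string& db) {
  if (j - i < MIN_LOOP + 1) return;
  if (M[i][j] == M[i][j - 1]) {
    traceback(i, j - 1, M, s, db);
    return;
  }
  // j is paired with some k; take the first k achieving the optimum
  for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
    if (!can_pair(s[k], s[j])) continue;
    int left = (k > i) ? M[i][k - 1] : 0;
    int in = (j - k >= MIN_LOOP + 2) ? M[k + 1][j - 1] : 0;
    if (left + in + 1 == M[i][j]) {
      db[k] = '(';
      db[j] = ')';
      if (k > i) traceback(i, k - 1, M, s, db);
      traceback(k + 1, j - 1, M, s, db);
      return;
    }
  }
}

// [[Rcpp::export]]
List fold_cpp(std::string seq) {
  int n = (int) seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c == 'U') { seq[i] = 'T'; c = 'T'; }
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'N')
      stop("fold: invalid character '%s' in sequence", std::string(1, c));
  }
  std::string db(n, '.');
  int pairs = 0;
  if (n > MIN_LOOP + 1) {
    std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
    for (int span = MIN_LOOP + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        int best = M[i][j - 1];
        for (int k = i; k <= j - MIN_LOOP - 1; ++k) {
          if (!can_pair(seq[k], seq[j])) continue;
          int left = (k > i) ? M[i][k - 1] : 0;
          int in = (j - k >= MIN_LOOP + 2) ? M[k + 1][j - 1] : 0;
          if (left + in + 1 > best) best = left + in + 1;
        }
        M[i][j] = best;
      }
    }
    pairs = M[0][n - 1];
    traceback(0, n - 1, M, seq, db);
  }
  // stacking bonus: pair (i,j) with (i+1,j-1) also paired
  std::vector<int> mate(n, -1);
  std::vector<int> st;
  for (int i = 0; i < n; ++i) {
    if (db[i] == '(') st.push_back(i);
    else if (db[i] == ')') { mate[i] = st.back(); mate[st.back()] = i; st.pop_back(); }
  }
  int stacks = 0;
  for (int i = 0; i < n; ++i)
    if (mate[i] > i && i + 1 < n && mate[i + 1] == mate[i] - 1) ++stacks;
  double mfe = -(double) pairs - 0.5 * (double) stacks;
  return List::create(_["structure"] = db, _["mfe"] = mfe,
                      _["n_pairs"] = pairs);
}
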