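#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Dynamic programming kernels for the sequence+structure profile model and
// the built-in local search engine. Sequences are encoded as integers
// (A=0, C=1, G=2, T=3; anything else < 0) before crossing into C++.

static inline double emis_at(const NumericMatrix& emis, int a, int col) {
  // unknown characters (N etc.) are scored as uninformative: 0 bits
  if (a < 0 || a > 3) return 0.0;
  return emis(a, col);
}

// Align a sequence to the L model columns maximizing the sum of
// single-column emissions with a linear gap penalty. free_ends = TRUE makes
// leading/trailing unaligned sequence free (max over all substrings =
// sliding-window scan); FALSE is a plain global alignment.
// Tie-break: match preferred over gap, then consuming a sequence character
// (leftmost alignment) over skipping a model column.
// [[Rcpp::export]]
List profile_align_cpp(IntegerVector seq, NumericMatrix emis, double gap,
                       bool free_ends) {
  const int L = emis.ncol();
  const int n = seq.size();
  // DP over (i = model column 0..L, j = sequence position 0..n)
  NumericMatrix S(L + 1, n + 1);
  IntegerMatrix tb(L + 1, n + 1); // 0 stop, 1 diag, 2 left (ins), 3 up (del)
  for (int j = 0; j <= n; ++j) {
    S(0, j) = free_ends ? 0.0 : -gap * j;
    tb(0, j) = (free_ends || j == 0) ? 0 : 2;
  }
  for (int i = 1; i <= L; ++i) {
    S(i, 0) = -gap * i;
    tb(i, 0) = 3;
  }
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= n; ++j) {
      double d = S(i - 1, j - 1) + emis_at(emis, seq[j - 1], i - 1);
      double l = S(i, j - 1) - gap;
      double u = S(i - 1, j) - gap;
      double best = d; int move = 1;
      if (l > best) { best = l; move = 2; }
      if (u > best) { best = u; move = 3; }
      S(i, j) = best;
      tb(i, j) = move;
    }
  }
  int jend = n;
  double score;
  if (free_ends) {
    score = S(L, 0);
    jend = 0;
    for (int j = 1; j <= n; ++j) {
      if (S(L, j) > score) { score = S(L, j); jend = j; } // ties -> smaller end
    }
  } else {
    score = S(L, n);
  }
  // traceback: record the sequence position matched to each column (-1 = gap)
  IntegerVector cols(L, -1);
  int i = L, j = jend;
  while (i > 0 || (!free_ends && j > 0)) {
    int move = tb(i, j);
    if (move == 0) break;
    if (move == 1)      { cols[i - 1] = j - 1; --i; --j; }
    else if (move == 2) { --j; }
    else                { --i; }
  }
  int jstart = j; // first sequence position consumed (0-based)
  return List::create(_["score"] = score, _["cols"] = cols,
                      _["start"] = jstart, _["end"] = jend);
}

// Ungapped diagonal scores: out[d] = sum_i e_i(seq[d+i]) for every offset d.
// Used as an accelerating prefilter before the exact gapped scan, in the
// spirit of the filter pipelines of profile-search tools.
// [[Rcpp::export]]
NumericVector diag_scores_cpp(IntegerVector seq, NumericMatrix emis) {
  const int L = emis.ncol();
  const int n = seq.size();
  if (n < L) return NumericVector(0);
  NumericVector out(n - L + 1);
  for (int d = 0; d + L <= n; ++d) {
    double s = 0.0;
    for (int i = 0; i < L; ++i) s += emis_at(emis, seq[d + i], i);
    out[d] = s;
  }
  return out;
}

static inline bool can_pair(int a, int b) {
  // Watson-Crick plus G:U wobble (T encodes U)
  if (a == 0 && b == 3) return true;
  if (a == 3 && b == 0) return true;
  if (a == 1 && b == 2) return true;
  if (a == 2 && b == 1) return true;
  if (a == 2 && b == 3) return true;
  if (a == 3 && b == 2) return true;
  return false;
}

static void nussinov_tb(const IntegerMatrix& N, const IntegerVector& seq,
                        int i, int j, int minloop, IntegerVector& partner) {
  if (j - i < minloop + 1) return;
  if (N(i, j) == N(i, j - 1)) { // j unpaired (preferred on ties)
    nussinov_tb(N, seq, i, j - 1, minloop, partner);
    return;
  }
  for (int k = i; k <= j - minloop - 1; ++k) {
    if (!can_pair(seq[k], seq[j])) continue;
    int left = (k > i) ? N(i, k - 1) : 0;
    int inner = (j - 1 >= k + 1) ? N(k + 1, j - 1) : 0;
    if (left + inner + 1 == N(i, j)) {
      partner[k] = j;
      partner[j] = k;
      if (k > i) nussinov_tb(N, seq, i, k - 1, minloop, partner);
      if (j - 1 >= k + 1) nussinov_tb(N, seq, k + 1, j - 1, minloop, partner);
      return;
    }
  }
}

// Maximum base-pairing (Nussinov) fold with a minimum loop length.
// Returns 0-based partner index per position, -1 if unpaired.
// [[Rcpp::export]]
IntegerVector nussinov_cpp(IntegerVector seq, int minloop) {
  const int n = seq.size();
  IntegerVector partner(n, -1);
  if (n == 0) return partner;
  IntegerMatrix N(n, n);
  for (int span = minloop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N(i, j - 1);
      for (int k = i; k <= j - minloop - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int left = (k > i) ? N(i, k - 1) : 0;
        int inner = (j - 1 >= k + 1) ? N(k + 1, j - 1) : 0;
        if (left + inner + 1 > best) best = left + inner + 1;
      }
      N(i, j) = best;
    }
  }
  nussinov_tb(N, seq, 0, n - 1, minloop, partner);
  return partner;
}

// Exact-word seed matching: 0-based subject positions where a word of
// length w from the query occurs verbatim. Words containing unknown
// characters never match. Rolling 2-bit hash over both sequences.
// [[Rcpp::export]]
IntegerVector seed_hits_cpp(IntegerVector q, IntegerVector s, int w) {
  std::vector<int> out;
  const int m = q.size(), n = s.size();
  if (w < 1 || w > 15 || m < w || n < w) return IntegerVector(0);
  const uint32_t mask = (1u << (2 * w)) - 1u;
  // flat byte table of query words (4^w entries; w <= 12 keeps it <= 16 MB),
  // falling back to a hash set for longer words
  const bool flat = w <= 12;
  std::vector<uint8_t> table;
  std::unordered_set<uint32_t> words;
  if (flat) table.assign((size_t)1 << (2 * w), 0);
  uint32_t code = 0; int run = 0, nwords = 0;
  for (int i = 0; i < m; ++i) {
    if (q[i] < 0 || q[i] > 3) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)q[i]) & mask;
    if (++run >= w) {
      if (flat) table[code] = 1; else words.insert(code);
      ++nwords;
    }
  }
  if (nwords == 0) return IntegerVector(0);
  code = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    if (s[j] < 0 || s[j] > 3) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)s[j]) & mask;
    if (++run >= w && (flat ? table[code] != 0 : words.count(code) > 0)) {
      out.push_back(j - w + 1);
    }
  }
  return wrap(out);
}

// Global (Needleman-Wunsch) alignment with a linear gap penalty.
// Returns per-alignment-column 0-based positions into q and s (-1 = gap).
// Tie-break: diagonal, then gap in s (consume q), then gap in q.
// [[Rcpp::export]]
List nw_align_cpp(IntegerVector q, IntegerVector s, double match,
                  double mismatch, double gap) {
  const int m = q.size(), n = s.size();
  NumericMatrix S(m + 1, n + 1);
  IntegerMatrix tb(m + 1, n + 1); // 1 diag, 2 left (gap in q), 3 up (gap in s)
  for (int j = 1; j <= n; ++j) { S(0, j) = -gap * j; tb(0, j) = 2; }
  for (int i = 1; i <= m; ++i) { S(i, 0) = -gap * i; tb(i, 0) = 3; }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double sub = (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ? match : mismatch;
      double d = S(i - 1, j - 1) + sub;
      double u = S(i - 1, j) - gap;
      double l = S(i, j - 1) - gap;
      double best = d; int move = 1;
      if (u > best) { best = u; move = 3; }
      if (l > best) { best = l; move = 2; }
      S(i, j) = best;
      tb(i, j) = move;
    }
  }
  std::vector<int> qi, si;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int move = tb(i, j);
    if (move == 1)      { qi.push_back(i - 1); si.push_back(j - 1); --i; --j; }
    else if (move == 2) { qi.push_back(-1);    si.push_back(j - 1); --j; }
    else                { qi.push_back(i - 1); si.push_back(-1);    --i; }
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(si.begin(), si.end());
  return List::create(_["score"] = S(m, n), _["qidx"] = wrap(qi),
                      _["sidx"] = wrap(si));
}

// Local (Smith-Waterman) alignment with affine gaps (a gap of length k costs
// gapopen + k * gapext). Returns the single best local alignment.
// Tie-break: smaller subject end, then smaller query end.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, double match,
                  double mismatch, double gapopen, double gapext) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e30;
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix tb(m + 1, n + 1); // state of best cell: 0 none, 1 M, 2 X(q gap), 3 Y(s gap)
  for (int i = 0; i <= m; ++i) { X(i, 0) = NEG; Y(i, 0) = NEG; }
  for (int j = 0; j <= n; ++j) { X(0, j) = NEG; Y(0, j) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double sub = (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ? match : mismatch;
      double prev = std::max(std::max(M(i - 1, j - 1), X(i - 1, j - 1)),
                             Y(i - 1, j - 1));
      M(i, j) = std::max(0.0, prev + sub);
      // X: gap in query (consume subject)
      X(i, j) = std::max(M(i, j - 1) - gapopen - gapext, X(i, j - 1) - gapext);
      // Y: gap in subject (consume query)
      Y(i, j) = std::max(M(i - 1, j) - gapopen - gapext, Y(i - 1, j) - gapext);
      double cell = std::max(std::max(M(i, j), X(i, j)), Y(i, j));
      if (cell > best) { best = cell; bi = i; bj = j; }
    }
  }
  // traceback from (bi,bj) in the best state
  int i = bi, j = bj;
  int nident = 0, alen = 0;
  int qend = bi, send = bj;
  int state;
  {
    double mm = M(i, j), xx = X(i, j), yy = Y(i, j);
    state = (mm >= xx && mm >= yy) ? 1 : (xx >= yy ? 2 : 3);
  }
  while (i > 0 && j > 0) {
    if (state == 1) {
      if (M(i, j) <= 0.0) break;
      double sub = (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ? match : mismatch;
      if (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ++nident;
      ++alen;
      double prev = M(i, j) - sub;
      --i; --j;
      if (prev == 0.0 && M(i, j) != 0.0 &&
          std::abs(prev - M(i, j)) > 1e-9) { /* reached local start */ }
      double mm = M(i, j), xx = X(i, j), yy = Y(i, j);
      double pm = std::max(std::max(mm, xx), yy);
      if (pm <= 0.0) break;
      state = (mm >= xx && mm >= yy) ? 1 : (xx >= yy ? 2 : 3);
    } else if (state == 2) { // gap in query
      ++alen;
      if (X(i, j) == M(i, j - 1) - gapopen - gapext) { --j; state = 1; }
      else { --j; state = 2; }
    } else { // gap in subject
      ++alen;
      if (Y(i, j) == M(i - 1, j) - gapopen - gapext) { --i; state = 1; }
      else { --i; state = 3; }
    }
  }
  int qstart = i, sstart = j; // 0-based starts
  return List::create(_["score"] = best, _["qstart"] = qstart,
                      _["qend"] = qend, _["sstart"] = sstart,
                      _["send"] = send, _["nident"] = nident,
                      _["alen"] = alen);
}
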