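#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Banded unit-cost edit distance (Levenshtein) restricted to diagonals
// |i - j| <= t.  Returns a value > t when the true distance exceeds the band.
static int banded_levenshtein(const std::string &a, const std::string &b,
                              int t) {
  const int n = (int)a.size(), m = (int)b.size();
  const int INF = 1 << 29;
  if (std::abs(n - m) > t) return t + 1;
  const int w = 2 * t + 1;  // band columns, k = j - i + t
  std::vector<int> prev(w, INF), cur(w, INF);
  for (int k = 0; k < w; ++k) {
    int j = k - t;
    if (j >= 0 && j <= m) prev[k] = j;  // row i = 0
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int k = 0; k < w; ++k) {
      int j = i + k - t;
      if (j < 0 || j > m) continue;
      int best = INF;
      if (j == 0) {
        best = i;
      } else {
        if (prev[k] < INF)
          best = prev[k] + (a[i - 1] == b[j - 1] ? 0 : 1);   // diagonal
        if (k > 0 && cur[k - 1] < INF)
          best = std::min(best, cur[k - 1] + 1);             // gap in a
      }
      if (k < w - 1 && prev[k + 1] < INF)
        best = std::min(best, prev[k + 1] + 1);              // gap in b
      cur[k] = best;
    }
    std::swap(prev, cur);
  }
  int k = m - n + t;
  return (k >= 0 && k < w) ? prev[k] : INF;
}

//' Unit-cost edit distance via band doubling
//'
//' Levenshtein distance (substitutions, insertions and deletions each cost 1)
//' computed with Ukkonen's O(ND) band-doubling scheme: the dynamic program is
//' evaluated inside a diagonal band of half-width t, and t is doubled until
//' the computed distance D satisfies D <= t, at which point it is exact.
//' For the near-identical sequences this package compares (satellite monomers
//' at >= 88% identity) D is small and the computation is close to linear.
//'
//' @param a,b nucleotide strings (plain character scalars)
//' @return integer edit distance
//' @export
// [[Rcpp::export]]
int ond_edit_distance(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  const int big = std::max(n, m);
  int t = std::max(1, std::abs(n - m));
  for (;;) {
    int d = banded_levenshtein(a, b, t);
    if (d <= t || t >= big) return d;
    t = std::min(2 * t, big);
  }
}

// Semi-global edit distance scan: model is aligned globally, the read end is
// anchored at each position j while the read start is free.  Returns, for
// every j in 1..n, the minimum edit distance of the model against any read
// substring ending at j (1-based inclusive).  O(|model| * |read|).
// [[Rcpp::export]]
IntegerVector semiglobal_end_scores(std::string model, std::string read) {
  const int m = (int)model.size(), n = (int)read.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0;  // free start in the read
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int best = prev[j - 1] + (model[i - 1] == read[j - 1] ? 0 : 1);
      int up = prev[j] + 1;
      int left = cur[j - 1] + 1;
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  IntegerVector out(n);
  for (int j = 1; j <= n; ++j) out[j - 1] = prev[j];
  return out;
}

// Recover the start of a semi-global hit whose (1-based, inclusive) end on
// the read is `end`.  The suffix-anchored problem is solved by running the
// end-scan on the reversed model against the reversed read window
// [end - |model| - pad, end].  Among window lengths achieving the minimum
// distance, the one closest to the model length is preferred (then the
// shorter).  Returns the 0-based start, so the hit is [start, end) half-open.
// [[Rcpp::export]]
int semiglobal_hit_start(std::string model, std::string read, int end,
                         int pad) {
  const int m = (int)model.size();
  int lo = std::max(0, end - m - pad);  // 0-based window start
  std::string seg = read.substr(lo, end - lo);
  std::reverse(seg.begin(), seg.end());
  std::reverse(model.begin(), model.end());
  IntegerVector sc = semiglobal_end_scores(model, seg);
  int bestL = 1, bestd = sc[0];
  for (int L = 2; L <= (int)seg.size(); ++L) {
    int d = sc[L - 1];
    if (d < bestd ||
        (d == bestd && std::abs(L - m) < std::abs(bestL - m)) ||
        (d == bestd && std::abs(L - m) == std::abs(bestL - m) && L < bestL)) {
      bestd = d;
      bestL = L;
    }
  }
  return end - bestL;
}

// Unit-cost global alignment with traceback, used for anchoring cluster
// members to the consensus medoid.  Ties prefer diagonal, then a gap in b,
// then a gap in a, making the traceback deterministic.  Returns the two
// gapped strings.
// [[Rcpp::export]]
CharacterVector global_align(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<std::vector<int>> D(n + 1, std::vector<int>(m + 1));
  for (int i = 0; i <= n; ++i) D[i][0] = i;
  for (int j = 0; j <= m; ++j) D[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int best = D[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      best = std::min(best, D[i - 1][j] + 1);
      best = std::min(best, D[i][j - 1] + 1);
      D[i][j] = best;
    }
  }
  std::string ga, gb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i][j] == D[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      ga += a[i - 1]; gb += b[j - 1]; --i; --j;
    } else if (i > 0 && D[i][j] == D[i - 1][j] + 1) {
      ga += a[i - 1]; gb += '-'; --i;
    } else {
      ga += '-'; gb += b[j - 1]; --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return CharacterVector::create(ga, gb);
}
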