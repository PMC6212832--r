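#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int BIG = 1000000;

// Global bounded-edit alignment of `ref` against `query`.
// D[g][j] = minimum substitutions aligning ref[0..i) to query[0..j) with
// exactly g indels; rows (i) are rolled. Returns the lexicographically
// minimal feasible (gaps, mismatches) with gaps <= max_gap and
// mismatches <= max_mm, or (-1, -1) if none exists.
static void align_global(const std::string& ref, const std::string& query,
                         int max_mm, int max_gap, int* out_g, int* out_m) {
  const int n = (int) ref.size(), m = (int) query.size();
  const int G = max_gap;
  std::vector<std::vector<int>> prev(G + 1, std::vector<int>(m + 1, BIG));
  std::vector<std::vector<int>> cur(G + 1, std::vector<int>(m + 1, BIG));
  for (int g = 0; g <= G; ++g)
    for (int j = 0; j <= m; ++j)
      prev[g][j] = (j == g) ? 0 : BIG;
  for (int i = 1; i <= n; ++i) {
    for (int g = 0; g <= G; ++g)
      std::fill(cur[g].begin(), cur[g].end(), BIG);
    for (int g = 0; g <= G; ++g) {
      for (int j = 0; j <= m; ++j) {
        int best = BIG;
        if (j >= 1) { // diagonal: consume one char of each
          int d = prev[g][j - 1] + (ref[i - 1] == query[j - 1] ? 0 : 1);
          if (d < best) best = d;
        }
        if (g >= 1) {
          int d = prev[g - 1][j]; // gap in query (ref char unmatched)
          if (d < best) best = d;
          if (j >= 1) {
            int d2 = cur[g - 1][j - 1]; // gap in ref (query char unmatched)
            if (d2 < best) best = d2;
          }
        }
        cur[g][j] = best;
      }
    }
    std::swap(prev, cur);
  }
  *out_g = -1; *out_m = -1;
  for (int g = 0; g <= G; ++g) {
    if (prev[g][m] <= max_mm) { *out_g = g; *out_m = prev[g][m]; return; }
  }
}

// [[Rcpp::export]]
IntegerMatrix align_barcodes_cpp(CharacterVector refs, std::string query,
                                 int max_mm, int max_gap) {
  const int n = refs.size();
  IntegerMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    int g, m;
    std::string ref = as<std::string>(refs[k]);
    align_global(ref, query, max_mm, max_gap, &g, &m);
    out(k, 0) = g;
    out(k, 1) = m;
  }
  colnames(out) = CharacterVector::create("gaps", "mismatches");
  return out;
}

// Semi-global search: the full primer is aligned against a substring of
// the read whose start is free; returns the 1-based end position in the
// read of the lexicographically-(gaps, mismatches) best feasible match
// (ties broken by the smallest end position), or -1 if none is feasible.
// [[Rcpp::export]]
int locate_primer_end_cpp(std::string read, std::string primer,
                          int max_mm, int max_gap) {
  const int n = (int) primer.size(), m = (int) read.size();
  const int G = max_gap;
  std::vector<std::vector<int>> prev(G + 1, std::vector<int>(m + 1, BIG));
  std::vector<std::vector<int>> cur(G + 1, std::vector<int>(m + 1, BIG));
  for (int j = 0; j <= m; ++j) prev[0][j] = 0; // free start in the read
  for (int i = 1; i <= n; ++i) {
    for (int g = 0; g <= G; ++g)
      std::fill(cur[g].begin(), cur[g].end(), BIG);
    for (int g = 0; g <= G; ++g) {
      for (int j = 0; j <= m; ++j) {
        int best = BIG;
        if (j >= 1) {
          int d = prev[g][j - 1] + (primer[i - 1] == read[j - 1] ? 0 : 1);
          if (d < best) best = d;
        }
        if (g >= 1) {
          int d = prev[g - 1][j];
          if (d < best) best = d;
          if (j >= 1) {
            int d2 = cur[g - 1][j - 1];
            if (d2 < best) best = d2;
          }
        }
        cur[g][j] = best;
      }
    }
    std::swap(prev, cur);
  }
  int best_g = -1, best_m = BIG, best_j = -1;
  for (int g = 0; g <= G && best_g < 0; ++g) {
    for (int j = 0; j <= m; ++j) {
      if (prev[g][j] <= max_mm && prev[g][j] < best_m) {
        best_g = g; best_m = prev[g][j]; best_j = j;
      }
    }
  }
  return best_g < 0 ? -1 : best_j;
}
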