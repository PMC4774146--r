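#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Single stem-loop folding by dynamic programming.
//
// A structure is a ladder of nested base pairs (i1,j1) ⊃ (i2,j2) ⊃ ...
// closed by one terminal loop; between consecutive pairs up to `max_gap`
// unpaired bases are allowed on each side (bulges / internal loops).
// Pairs are scored GC=3, AU=2, GU=1; every interior loop event costs
// loop_open + loop_ext * (unpaired bases). No multiloops, no pseudoknots.

static inline int pair_score(char a, char b) {
  // T and U are normalised to T upstream
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return -1;
}

// [[Rcpp::export]]
List fold_hairpin_cpp(std::string seq, int loop_min, int loop_max,
                      int max_gap, int loop_open, int loop_ext) {
  const int n = (int) seq.size();
  const int NEG = INT_MIN / 4;
  if (n < loop_min + 2) {
    return List::create(_["score"] = NA_INTEGER);
  }
  // S[i][j]: best score of a complete stem-loop whose outermost pair is (i,j)
  std::vector<int> S((size_t) n * n, NEG), NP((size_t) n * n, 0),
                   CH((size_t) n * n, -2);
  const int G = max_gap;
  for (int span = loop_min + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      int p = pair_score(seq[i], seq[j]);
      if (p < 0) continue;
      int best = NEG, bestNP = 0, bestCh = -2;
      int loop = j - i - 1;
      if (loop >= loop_min && loop <= loop_max) {
        best = 0; bestNP = 0; bestCh = -1;
      }
      for (int a = 0; a <= G; ++a) {
        int ii = i + 1 + a;
        if (ii >= j) break;
        for (int b = 0; b <= G; ++b) {
          int jj = j - 1 - b;
          if (ii >= jj) break;
          int inner = S[(size_t) ii * n + jj];
          if (inner <= NEG) continue;
          int pen = (a == 0 && b == 0) ? 0 : loop_open + loop_ext * (a + b);
          int v = inner - pen;
          int np = NP[(size_t) ii * n + jj];
          if (v > best || (v == best && np > bestNP)) {
            best = v; bestNP = np; bestCh = a * (G + 1) + b;
          }
        }
      }
      if (best > NEG) {
        S[(size_t) i * n + j] = p + best;
        NP[(size_t) i * n + j] = bestNP + 1;
        CH[(size_t) i * n + j] = bestCh;
      }
    }
  }
  // best outermost pair: max score, then more pairs, then leftmost/innermost
  int bi = -1, bj = -1, bs = NEG, bp = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int s = S[(size_t) i * n + j];
      if (s <= NEG) continue;
      int np = NP[(size_t) i * n + j];
      if (s > bs || (s == bs && (np > bp || (np == bp && false)))) {
        bs = s; bp = np; bi = i; bj = j;
      }
    }
  if (bi < 0) return List::create(_["score"] = NA_INTEGER);

  IntegerVector partner(n, 0);  // 1-based partner, 0 = unpaired
  std::vector<int> bulges, internals;
  int i = bi, j = bj, loop_size = -1;
  while (true) {
    partner[i] = j + 1;
    partner[j] = i + 1;
    int ch = CH[(size_t) i * n + j];
    if (ch == -1) { loop_size = j - i - 1; break; }
    int a = ch / (G + 1), b = ch % (G + 1);
    if (a > 0 && b == 0) bulges.push_back(a);
    else if (b > 0 && a == 0) bulges.push_back(b);
    else if (a > 0 && b > 0) internals.push_back(a + b);
    i = i + 1 + a;
    j = j - 1 - b;
  }
  return List::create(
    _["score"] = bs, _["n_pairs"] = bp,
    _["outer_i"] = bi + 1, _["outer_j"] = bj + 1,
    _["loop_i"] = i + 1, _["loop_j"] = j + 1,
    _["partner"] = partner, _["terminal_loop"] = loop_size,
    _["bulge_sizes"] = wrap(bulges),
    _["internal_loop_sizes"] = wrap(internals));
}

// 3'-adapter localisation: semi-global match of the adapter prefix at every
// start position, mismatches allowed up to floor(rate * matched length).
// Best candidate maximises (matched - 2*mismatches); ties go to the leftmost
// (longest adapter) occurrence. Returns the 0-based adapter start = insert
// length, or -1 when no acceptable occurrence exists.

// [[Rcpp::export]]
IntegerVector trim_positions_cpp(CharacterVector reads, std::string adapter,
                                 double max_error_rate, int min_overlap) {
  const int alen = (int) adapter.size();
  IntegerVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int L = (int) rd.size();
    int best = -1, bestP = -1;
    for (int p = 0; p <= L - min_overlap; ++p) {
      int matched = std::min(alen, L - p);
      int allowed = (int) (max_error_rate * matched + 1e-9);
      int mism = 0;
      for (int k = 0; k < matched && mism <= allowed; ++k)
        if (rd[p + k] != adapter[k]) ++mism;
      if (mism > allowed) continue;
      int sc = matched - 2 * mism;
      if (sc > best) { best = sc; bestP = p; }
    }
    out[r] = bestP;
  }
  return out;
}
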