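#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Pairwise DP aligners (Gotoh). Gap convention: a gap of length L costs
// gap_open + (L - 1) * gap_extend; gap_open == gap_extend gives linear gaps.
// Coordinates reported 1-based inclusive; empty local alignment -> zeros.

static const int NEG = INT_MIN / 4;

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4;
    default: return -1;
  }
}

struct Scorer {
  bool has_matrix;
  int match, mismatch;
  int mat[5][5];
  int operator()(char x, char y) const {
    int i = base_idx(x), j = base_idx(y);
    if (i < 0 || j < 0) stop("sequence contains a character outside {A,C,G,T,N}");
    if (has_matrix) return mat[i][j];
    if (i == 4 || j == 4) return 0;  // N pairs score 0 by default
    return (i == j) ? match : mismatch;
  }
};

static Scorer make_scorer(int match, int mismatch, Nullable<IntegerMatrix> matrix) {
  Scorer sc;
  sc.match = match; sc.mismatch = mismatch;
  sc.has_matrix = matrix.isNotNull();
  if (sc.has_matrix) {
    IntegerMatrix m(matrix);
    if (m.nrow() != 5 || m.ncol() != 5) stop("substitution matrix must be 5x5 over A,C,G,T,N");
    for (int i = 0; i < 5; ++i)
      for (int j = 0; j < 5; ++j) sc.mat[i][j] = m(i, j);
  }
  return sc;
}

// state codes for traceback: 0 = M (substitution), 1 = Ix (gap in b, consumes a),
// 2 = Iy (gap in a, consumes b)
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 int match, int mismatch, int gap_open, int gap_extend,
                 bool local, Nullable<IntegerMatrix> matrix = R_NilValue) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  Scorer sc = make_scorer(match, mismatch, matrix);

  IntegerMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1), S(n + 1, m + 1);
  M(0, 0) = NEG; Ix(0, 0) = NEG; Iy(0, 0) = NEG; S(0, 0) = 0;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = local ? NEG : gap_open + (i - 1) * gap_extend;
    S(i, 0) = local ? 0 : Ix(i, 0);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = local ? NEG : gap_open + (j - 1) * gap_extend;
    S(0, j) = local ? 0 : Iy(0, j);
  }

  int best = 0, besti = 0, bestj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      M(i, j) = S(i - 1, j - 1) + sc(a[i - 1], b[j - 1]);
      int ix_open = S(i - 1, j) == NEG ? NEG : S(i - 1, j) + gap_open;
      int ix_ext  = Ix(i - 1, j) == NEG ? NEG : Ix(i - 1, j) + gap_extend;
      Ix(i, j) = std::max(ix_open, ix_ext);
      int iy_open = S(i, j - 1) == NEG ? NEG : S(i, j - 1) + gap_open;
      int iy_ext  = Iy(i, j - 1) == NEG ? NEG : Iy(i, j - 1) + gap_extend;
      Iy(i, j) = std::max(iy_open, iy_ext);
      int s = std::max(M(i, j), std::max(Ix(i, j), Iy(i, j)));
      if (local) {
        s = std::max(s, 0);
        // tie-break: first strictly-better cell scanning a then b -> smallest ends
        if (s > best) { best = s; besti = i; bestj = j; }
      }
      S(i, j) = s;
    }
  }

  std::string states;
  int ai = 0, aj = 0, bi = 0, bj = 0, score = 0;

  if (local) {
    if (best <= 0) {
      return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0, _["states"] = "");
    }
    score = best;
    int i = besti, j = bestj;
    aj = besti; bj = bestj;
    // current state: argmax at (i,j); prefer M, then Ix, then Iy
    int st = (S(i, j) == M(i, j)) ? 0 : (S(i, j) == Ix(i, j) ? 1 : 2);
    while (true) {
      if (st == 0) {
        states.push_back(a[i - 1] == b[j - 1] ? 'M' : 'X');
        --i; --j;
        if (S(i, j) == 0) break;
        st = (S(i, j) == M(i, j)) ? 0 : (S(i, j) == Ix(i, j) ? 1 : 2);
      } else if (st == 1) {
        states.push_back('B');  // gap in b, consumes a
        bool ext = (i - 1 >= 1) && Ix(i - 1, j) != NEG && Ix(i, j) == Ix(i - 1, j) + gap_extend;
        --i;
        if (ext) { st = 1; continue; }
        if (S(i, j) == 0) break;
        st = (S(i, j) == M(i, j)) ? 0 : (S(i, j) == Ix(i, j) ? 1 : 2);
      } else {
        states.push_back('A');  // gap in a, consumes b
        bool ext = (j - 1 >= 1) && Iy(i, j - 1) != NEG && Iy(i, j) == Iy(i, j - 1) + gap_extend;
        --j;
        if (ext) { st = 2; continue; }
        if (S(i, j) == 0) break;
        st = (S(i, j) == M(i, j)) ? 0 : (S(i, j) == Ix(i, j) ? 1 : 2);
      }
    }
    ai = i + 1; bi = j + 1;
  } else {
    score = S(n, m);
    int i = n, j = m;
    int st = (S(i, j) == M(i, j)) ? 0 : (S(i, j) == Ix(i, j) ? 1 : 2);
    while (i > 0 || j > 0) {
      if (i == 0) { states.push_back('A'); --j; continue; }
      if (j == 0) { states.push_back('B'); --i; continue; }
      if (st == 0) {
        states.push_back(a[i - 1] == b[j - 1] ? 'M' : 'X');
        --i; --j;
      } else if (st == 1) {
        states.push_back('B');
        bool ext = Ix(i - 1, j) != NEG && Ix(i, j) == Ix(i - 1, j) + gap_extend;
        --i;
        if (ext) { st = 1; continue; }
      } else {
        states.push_back('A');
        bool ext = Iy(i, j - 1) != NEG && Iy(i, j) == Iy(i, j - 1) + gap_extend;
        --j;
        if (ext) { st = 2; continue; }
      }
      if (i == 0 || j == 0) continue;
      st = (S(i, j) == M(i, j)) ? 0 : (S(i, j) == Ix(i, j) ? 1 : 2);
    }
    ai = 1; bi = 1; aj = n; bj = m;
  }

  std::reverse(states.begin(), states.end());
  return List::create(_["score"] = score, _["a_start"] = ai, _["a_end"] = aj,
                      _["b_start"] = bi, _["b_end"] = bj, _["states"] = states);
}
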