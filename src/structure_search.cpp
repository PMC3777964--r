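// Exhaustive stem and H-type pseudoknot search.
//
// A stem is 1..(max_bulges+1) contiguous helices separated by one-sided
// internal bulges (<= max_bulge_len nt).  Stems are enumerated exhaustively
// (every outermost pair, every helix sub-length, every bulge placement); an
// H-type pseudoknot is an ordered pair of stems whose strands cross:
//   stem1.left < stem2.left < stem1.right < stem2.right.
// Scoring is the transparent per-pair scheme (G.C / A.U / G.U weights minus
// per-bulge penalties); the best structure is selected by score with a
// deterministic tie-break (higher score, longer stem1, 5'-most stem1,
// 5'-most stem2).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  int min_stem, max_stem, max_loop, max_bulges, max_bulge_len;
  int min_hairpin_loop, min_l1, min_l3;
  double score_gc, score_au, score_gu, bulge_open, bulge_per_nt;
  bool allow_gu;
};

// codes: A=0, C=1, G=2, T=3
inline double pairScore(int a, int b, const Params &P) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return P.score_gc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return P.score_au;
  if (P.allow_gu && ((a == 2 && b == 3) || (a == 3 && b == 2)))
    return P.score_gu;
  return -1.0;  // not pairable
}

struct Stem {
  // up to 3 helices: (i, j, len) for each; unused slots zeroed
  int h[9];
  int nhelix;
  int l0, l1, r0, r1;  // strand footprints (inclusive), with bulged nt
  int npairs, nbulge, bulge_nt;
  double score;
};

struct Enumerator {
  const std::vector<int> &s;
  const Params &P;
  int n;
  std::vector<std::vector<int>> run;  // max helix length from outer pair (i,j)
  std::vector<Stem> stems;

  Enumerator(const std::vector<int> &seq, const Params &p)
      : s(seq), P(p), n(seq.size()) {
    run.assign(n, std::vector<int>(n, 0));
    for (int i = n - 1; i >= 0; --i) {
      for (int j = i + 1; j < n; ++j) {
        if (pairScore(s[i], s[j], P) < 0) continue;
        run[i][j] = 1;
        if (i + 1 < j - 1 && run[i + 1][j - 1] > 0)
          run[i][j] += run[i + 1][j - 1];
      }
    }
  }

  void emit(int hel[9], int nh) {
    Stem st;
    for (int k = 0; k < 9; ++k) st.h[k] = hel[k];
    st.nhelix = nh;
    st.npairs = 0;
    st.nbulge = nh - 1;
    st.bulge_nt = 0;
    double sc = 0;
    for (int k = 0; k < nh; ++k) {
      int i = hel[3 * k], j = hel[3 * k + 1], L = hel[3 * k + 2];
      st.npairs += L;
      for (int t = 0; t < L; ++t) sc += pairScore(s[i + t], s[j - t], P);
      if (k > 0) {
        int pi = hel[3 * (k - 1)], pj = hel[3 * (k - 1) + 1],
            pl = hel[3 * (k - 1) + 2];
        int gl = i - (pi + pl);
        int gr = (pj - pl) - j;
        int g = gl > gr ? gl : gr;
        st.bulge_nt += g;
        sc -= P.bulge_open + P.bulge_per_nt * g;
      }
    }
    st.score = sc;
    st.l0 = hel[0];
    st.l1 = hel[3 * (nh - 1)] + hel[3 * (nh - 1) + 2] - 1;
    st.r0 = hel[3 * (nh - 1) + 1] - hel[3 * (nh - 1) + 2] + 1;
    st.r1 = hel[1];
    stems.push_back(st);
  }

  void extend(int hel[9], int nh, int pairsSoFar) {
    if (pairsSoFar >= P.min_stem) emit(hel, nh);
    if (nh > P.max_bulges) return;  // no more bulges allowed
    int li = hel[3 * (nh - 1)] + hel[3 * (nh - 1) + 2];      // next left pos
    int rj = hel[3 * (nh - 1) + 1] - hel[3 * (nh - 1) + 2];  // next right pos
    for (int gl = 0; gl <= P.max_bulge_len; ++gl) {
      for (int gr = 0; gr <= P.max_bulge_len; ++gr) {
        if ((gl > 0) == (gr > 0)) continue;  // exactly one side bulged
        int i2 = li + gl, j2 = rj - gr;
        if (i2 >= j2 || i2 < 0 || j2 >= n) continue;
        int maxL = run[i2][j2];
        for (int L2 = 1; L2 <= maxL && pairsSoFar + L2 <= P.max_stem; ++L2) {
          if (i2 + L2 - 1 >= j2 - L2 + 1) break;  // strands must not touch
          hel[3 * nh] = i2;
          hel[3 * nh + 1] = j2;
          hel[3 * nh + 2] = L2;
          extend(hel, nh + 1, pairsSoFar + L2);
        }
      }
    }
    for (int k = 3 * nh; k < 9; ++k) hel[k] = 0;
  }

  void enumerate() {
    int hel[9] = {0};
    for (int i = 0; i < n; ++i) {
      for (int j = i + 2; j < n; ++j) {
        int maxL = run[i][j];
        for (int L = 1; L <= maxL && L <= P.max_stem; ++L) {
          if (i + L - 1 >= j - L + 1) break;
          hel[0] = i;
          hel[1] = j;
          hel[2] = L;
          for (int k = 3; k < 9; ++k) hel[k] = 0;
          extend(hel, 1, L);
        }
      }
    }
  }
};

Params readParams(List bounds) {
  Params P;
  P.min_stem = as<int>(bounds["min_stem"]);
  P.max_stem = as<int>(bounds["max_stem"]);
  P.max_loop = as<int>(bounds["max_loop"]);
  P.max_bulges = as<int>(bounds["max_bulges"]);
  P.max_bulge_len = as<int>(bounds["max_bulge_len"]);
  P.min_hairpin_loop = as<int>(bounds["min_hairpin_loop"]);
  P.min_l1 = as<int>(bounds["min_l1"]);
  P.min_l3 = as<int>(bounds["min_l3"]);
  P.score_gc = as<double>(bounds["score_gc"]);
  P.score_au = as<double>(bounds["score_au"]);
  P.score_gu = as<double>(bounds["score_gu"]);
  P.bulge_open = as<double>(bounds["bulge_open"]);
  P.bulge_per_nt = as<double>(bounds["bulge_per_nt"]);
  P.allow_gu = as<bool>(bounds["allow_gu"]);
  return P;
}

IntegerMatrix stemPairs(const Stem &st) {
  IntegerMatrix m(st.npairs, 2);
  int r = 0;
  for (int k = 0; k < st.nhelix; ++k) {
    int i = st.h[3 * k], j = st.h[3 * k + 1], L = st.h[3 * k + 2];
    for (int t = 0; t < L; ++t) {
      m(r, 0) = i + t;
      m(r, 1) = j - t;
      ++r;
    }
  }
  return m;
}

}  // namespace

// [[Rcpp::export]]
List cpp_best_hairpin(IntegerVector seq_codes, List bounds) {
  Params P = readParams(bounds);
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  Enumerator E(s, P);
  E.enumerate();
  const Stem *best = nullptr;
  const double eps = 1e-9;
  for (const Stem &st : E.stems) {
    int loop = st.r0 - st.l1 - 1;
    if (loop < P.min_hairpin_loop || loop > P.max_loop) continue;
    if (best == nullptr || st.score > best->score + eps ||
        (st.score > best->score - eps &&
         (st.npairs > best->npairs ||
          (st.npairs == best->npairs && st.l0 < best->l0)))) {
      best = &st;
    }
  }
  if (best == nullptr) return List::create(Named("found") = false);
  return List::create(Named("found") = true, Named("score") = best->score,
                      Named("pairs") = stemPairs(*best),
                      Named("loop") = best->r0 - best->l1 - 1);
}

// [[Rcpp::export]]
List cpp_best_pseudoknot(IntegerVector seq_codes, List bounds) {
  Params P = readParams(bounds);
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  Enumerator E(s, P);
  E.enumerate();
  std::vector<int> ord(E.stems.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return E.stems[a].score > E.stems[b].score;
  });
  const double eps = 1e-9;
  double smax = ord.empty() ? 0 : E.stems[ord[0]].score;
  int b1 = -1, b2 = -1;
  double bestsc = 0;
  bool found = false;
  for (size_t a = 0; a < ord.size(); ++a) {
    const Stem &s1 = E.stems[ord[a]];
    if (found && s1.score + smax < bestsc - eps) break;
    for (size_t b = 0; b < ord.size(); ++b) {
      const Stem &s2 = E.stems[ord[b]];
      double tot = s1.score + s2.score;
      if (found && tot < bestsc - eps) break;
      int L1 = s2.l0 - s1.l1 - 1;
      int L2 = s1.r0 - s2.l1 - 1;
      int L3 = s2.r0 - s1.r1 - 1;
      if (L1 < P.min_l1 || L2 < 0 || L3 < P.min_l3) continue;
      if (L1 > P.max_loop || L2 > P.max_loop || L3 > P.max_loop) continue;
      bool better = false;
      if (!found || tot > bestsc + eps) {
        better = true;
      } else if (tot > bestsc - eps) {
        const Stem &c1 = E.stems[b1];
        const Stem &c2 = E.stems[b2];
        if (s1.npairs > c1.npairs) better = true;
        else if (s1.npairs == c1.npairs) {
          if (s1.l0 < c1.l0) better = true;
          else if (s1.l0 == c1.l0 && s2.l0 < c2.l0) better = true;
        }
      }
      if (better) {
        found = true;
        bestsc = tot;
        b1 = ord[a];
        b2 = ord[b];
      }
    }
  }
  if (!found) return List::create(Named("found") = false);
  const Stem &s1 = E.stems[b1];
  const Stem &s2 = E.stems[b2];
  return List::create(
      Named("found") = true, Named("score") = bestsc,
      Named("stem1_pairs") = stemPairs(s1), Named("stem2_pairs") = stemPairs(s2),
      Named("stem1_score") = s1.score, Named("stem2_score") = s2.score,
      Named("loops") = IntegerVector::create(s2.l0 - s1.l1 - 1,
                                             s1.r0 - s2.l1 - 1,
                                             s2.r0 - s1.r1 - 1));
}

// [[Rcpp::export]]
int cpp_count_stems(IntegerVector seq_codes, List bounds) {
  Params P = readParams(bounds);
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  Enumerator E(s, P);
  E.enumerate();
  return E.stems.size();
}
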