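#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Gotoh local alignment (affine gaps) with a canonical deterministic
// traceback. Scoring: +match for identities, +mismatch (negative) for
// substitutions; a gap of length L costs gap_open + L * gap_ext
// (Biostrings/EMBOSS convention). Local alignments start and end with an
// aligned (match/mismatch) column; the optimum is the maximum over the
// match-state matrix.
//
// Canonical rules (mirrored exactly by the pure-R test oracle):
//   * end cell: maximal M score, ties -> smallest window index, then
//     smallest contig index;
//   * traceback preference in every state: stop (local start, M only, when
//     the continuation value is 0) else M > Ix > Iy, where Ix consumes a
//     contig base (gap in the window) and Iy consumes a window base (gap in
//     the contig).

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".gotoh_local")]]
List gotoh_local(std::string w, std::string c,
                 double match = 1.0, double mismatch = -2.0,
                 double gap_open = 3.0, double gap_ext = 1.0) {
  const int m = (int) w.size(), n = (int) c.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0);
  const double open1 = gap_open + gap_ext;   // cost of the first gapped base

  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Ix((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Iy((m + 1) * (n + 1), NEG_INF);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = (w[i - 1] == c[j - 1]) ? match : mismatch;
      double prev = 0.0;
      const double pm = M[at(i - 1, j - 1)], px = Ix[at(i - 1, j - 1)],
                   py = Iy[at(i - 1, j - 1)];
      if (pm > prev) prev = pm;
      if (px > prev) prev = px;
      if (py > prev) prev = py;
      M[at(i, j)] = s + prev;

      double vx = M[at(i, j - 1)] - open1;
      if (Ix[at(i, j - 1)] - gap_ext > vx) vx = Ix[at(i, j - 1)] - gap_ext;
      if (Iy[at(i, j - 1)] - open1 > vx) vx = Iy[at(i, j - 1)] - open1;
      Ix[at(i, j)] = vx;

      double vy = M[at(i - 1, j)] - open1;
      if (Ix[at(i - 1, j)] - open1 > vy) vy = Ix[at(i - 1, j)] - open1;
      if (Iy[at(i - 1, j)] - gap_ext > vy) vy = Iy[at(i - 1, j)] - gap_ext;
      Iy[at(i, j)] = vy;

      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  if (bi < 0)  // no positive-scoring alignment
    return List::create(_["score"] = 0.0);

  // traceback
  int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
  int identities = 0;
  int w_min = m, w_max = -1, c_min = n, c_max = -1;
  int contig_break = -1;          // filled by caller-supplied bp via R side
  std::vector<int> wi_at_step;    // window index consumed (or -1)
  std::vector<int> cj_after;      // contig chars consumed before this window char
  for (;;) {
    if (state == 0) {
      // consumes w[i-1], c[j-1]
      if (w[i - 1] == c[j - 1]) ++identities;
      if (i - 1 < w_min) w_min = i - 1;
      if (i - 1 > w_max) w_max = i - 1;
      if (j - 1 < c_min) c_min = j - 1;
      if (j - 1 > c_max) c_max = j - 1;
      wi_at_step.push_back(i - 1);
      cj_after.push_back(j - 1);
      const double s = (w[i - 1] == c[j - 1]) ? match : mismatch;
      const double v = M[at(i, j)] - s;
      --i; --j;
      if (v <= 0.0) break;  // local start
      if (M[at(i, j)] == v) state = 0;
      else if (Ix[at(i, j)] == v) state = 1;
      else state = 2;
    } else if (state == 1) {
      // gap in window: consumes c[j-1]
      if (j - 1 < c_min) c_min = j - 1;
      if (j - 1 > c_max) c_max = j - 1;
      const double v = Ix[at(i, j)];
      --j;
      if (M[at(i, j)] - open1 == v) state = 0;
      else if (Ix[at(i, j)] - gap_ext == v) state = 1;
      else state = 2;
    } else {
      // gap in contig: consumes w[i-1]
      if (i - 1 < w_min) w_min = i - 1;
      if (i - 1 > w_max) w_max = i - 1;
      wi_at_step.push_back(i - 1);
      cj_after.push_back(j);  // downstream contig begins at j (0-based)
      const double v = Iy[at(i, j)];
      --i;
      if (M[at(i, j)] - open1 == v) state = 0;
      else if (Ix[at(i, j)] - open1 == v) state = 1;
      else state = 2;
    }
  }

  return List::create(
      _["score"] = best, _["identities"] = identities,
      _["w_start"] = w_min, _["w_end"] = w_max + 1,
      _["c_start"] = c_min, _["c_end"] = c_max + 1,
      _["step_window_index"] = IntegerVector(wi_at_step.begin(), wi_at_step.end()),
      _["step_contig_pos"] = IntegerVector(cj_after.begin(), cj_after.end()));
}

// Deterministic pseudo-rank in [0, 100): FNV-1a 64-bit over the key bytes,
// splitmix64 finisher, top 53 bits mapped to the unit interval. Stable
// across platforms and R sessions by construction.
// [[Rcpp::export(name = ".rank_hash")]]
NumericVector rank_hash(CharacterVector key) {
  const R_xlen_t n = key.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) {
    const char *s = CHAR(STRING_ELT(key, k));
    uint64_t h = 1469598103934665603ULL;
    for (const char *p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= 1099511628211ULL;
    }
    // splitmix64 finisher
    h += 0x9e3779b97f4a7c15ULL;
    h = (h ^ (h >> 30)) * 0xbf58476d1ce4e5b9ULL;
    h = (h ^ (h >> 27)) * 0x94d049bb133111ebULL;
    h = h ^ (h >> 31);
    out[k] = (double)(h >> 11) / 9007199254740992.0 * 100.0;  // 2^53
  }
  return out;
}
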