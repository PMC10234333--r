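#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap Smith-Waterman on integer-encoded sequences.
// Codes are 0-based indices into `submat`; `ambig` marks a code (N or X)
// that never counts as an identity even when equal on both sides.
// Opening a gap costs gap_open + gap_ext for its first character.

namespace {

struct SwResult {
  double score = 0.0;
  int matches = 0, cols = 0, gaps = 0;
  int q_start = 0, q_end = -1, s_start = 0, s_end = -1; // 0-based inclusive
  bool found = false;
};

SwResult sw_core(const int *q, int n, const int *s, int m,
                 const NumericMatrix &submat, double go, double ge, int ambig) {
  SwResult res;
  if (n == 0 || m == 0) return res;
  const double NEG = -1e30;
  std::vector<double> Mrow(m + 1, 0.0), Xrow(m + 1, NEG), Yrow(m + 1, NEG);
  std::vector<double> Mprev(m + 1, 0.0), Xprev(m + 1, NEG), Yprev(m + 1, NEG);
  // tbM: 0 = fresh local start, 1/2/3 = diagonal from M/X/Y
  // tbX: 1 = open (from M), 2 = extend;  tbY likewise
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    std::swap(Mprev, Mrow); std::swap(Xprev, Xrow); std::swap(Yprev, Yrow);
    Mrow[0] = 0.0; Xrow[0] = NEG; Yrow[0] = NEG;
    const size_t off = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      // X: gap in subject (consumes query char i)
      double x_open = Mprev[j] - go - ge, x_ext = Xprev[j] - ge;
      if (x_open >= x_ext) { Xrow[j] = x_open; tbX[off + j] = 1; }
      else                 { Xrow[j] = x_ext;  tbX[off + j] = 2; }
      // Y: gap in query (consumes subject char j)
      double y_open = Mrow[j - 1] - go - ge, y_ext = Yrow[j - 1] - ge;
      if (y_open >= y_ext) { Yrow[j] = y_open; tbY[off + j] = 1; }
      else                 { Yrow[j] = y_ext;  tbY[off + j] = 2; }
      // M: diagonal, local restart allowed
      double m_best = Mprev[j - 1]; unsigned char m_tb = 1;
      if (Xprev[j - 1] > m_best) { m_best = Xprev[j - 1]; m_tb = 2; }
      if (Yprev[j - 1] > m_best) { m_best = Yprev[j - 1]; m_tb = 3; }
      if (m_best <= 0.0) { m_best = 0.0; m_tb = 0; }
      double val = m_best + submat(q[i - 1], s[j - 1]);
      if (val <= 0.0) { Mrow[j] = 0.0; tbM[off + j] = 0; }
      else {
        Mrow[j] = val; tbM[off + j] = m_tb;
        if (val > best) { best = val; bi = i; bj = j; }
      }
    }
  }
  if (best <= 0.0) return res;
  res.found = true;
  res.score = best;
  res.q_end = bi - 1; res.s_end = bj - 1;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = X, 2 = Y
  while (true) {
    const size_t off = (size_t)i * (m + 1);
    if (state == 0) {
      unsigned char t = tbM[off + j];
      ++res.cols;
      if (q[i - 1] == s[j - 1] && q[i - 1] != ambig) ++res.matches;
      --i; --j;
      if (t == 0 || t == 1) {
        if (t == 0) { res.q_start = i; res.s_start = j; break; }
        state = 0;
      } else state = (t == 2) ? 1 : 2;
    } else if (state == 1) { // gap in subject, consumed q[i-1]
      ++res.cols; ++res.gaps;
      unsigned char t = tbX[off + j];
      --i;
      state = (t == 1) ? 0 : 1;
    } else {                 // gap in query, consumed s[j-1]
      ++res.cols; ++res.gaps;
      unsigned char t = tbY[off + j];
      --j;
      state = (t == 1) ? 0 : 2;
    }
  }
  return res;
}

List sw_to_list(const SwResult &r) {
  if (!r.found) return List::create(Named("found") = false);
  return List::create(
      Named("found") = true, Named("score") = r.score,
      Named("matches") = r.matches, Named("cols") = r.cols,
      Named("gaps") = r.gaps,
      Named("q_start") = r.q_start + 1, Named("q_end") = r.q_end + 1,
      Named("s_start") = r.s_start + 1, Named("s_end") = r.s_end + 1);
}

} // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix submat,
                  double gap_open, double gap_ext, int ambig) {
  SwResult r = sw_core(INTEGER(q), q.size(), INTEGER(s), s.size(), submat,
                       gap_open, gap_ext, ambig);
  return sw_to_list(r);
}

namespace {

typedef std::unordered_map<uint64_t, std::vector<int>> KmerIndex;

KmerIndex build_kmer_index(const int *sp, int m, int k, uint64_t mask) {
  KmerIndex index;
  index.reserve(m);
  uint64_t key = 0;
  int run = 0;
  for (int j = 0; j < m; ++j) {
    int c = sp[j];
    if (c < 0 || c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) index[key].push_back(j - k + 1);
  }
  return index;
}

// Seeded best local hit of one query against an indexed subject: diagonal
// voting in bins of width `band`, full affine SW on a banded subject window
// around each of the top `max_bins` bins with at least `min_votes` votes.
SwResult seeded_best_hit(const int *qp, int n, const int *sp, int m,
                         const KmerIndex &index, uint64_t mask,
                         const NumericMatrix &submat, double gap_open,
                         double gap_ext, int ambig, int k, int band,
                         int max_bins, int min_votes) {
  std::unordered_map<int, int> bins; // diagonal bin -> votes
  uint64_t key = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = qp[i];
    if (c < 0 || c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      auto it = index.find(key);
      if (it != index.end()) {
        int qpos = i - k + 1;
        for (int spos : it->second) {
          int diag = spos - qpos;
          int bin = (diag >= 0) ? diag / band : -(((-diag) + band - 1) / band);
          bins[bin] += 1;
        }
      }
    }
  }
  SwResult best;
  if (bins.empty()) return best;
  std::vector<std::pair<int, int>> ranked; // (votes, bin)
  ranked.reserve(bins.size());
  for (auto &kv : bins)
    if (kv.second >= min_votes) ranked.push_back({kv.second, kv.first});
  std::sort(ranked.begin(), ranked.end(),
            [](const std::pair<int, int> &a, const std::pair<int, int> &b) {
              if (a.first != b.first) return a.first > b.first;
              return a.second < b.second;
            });
  int tried = 0;
  for (auto &vb : ranked) {
    if (tried++ >= max_bins) break;
    int diag_lo = vb.second * band;  // bin covers diagonals [diag_lo, diag_lo + band)
    int w_lo = diag_lo - band;
    int w_hi = diag_lo + 2 * band + n;
    if (w_lo < 0) w_lo = 0;
    if (w_hi > m) w_hi = m;
    if (w_hi - w_lo < k) continue;
    SwResult r = sw_core(qp, n, sp + w_lo, w_hi - w_lo, submat,
                         gap_open, gap_ext, ambig);
    if (r.found && r.score > best.score) {
      r.s_start += w_lo; r.s_end += w_lo;
      best = r;
    }
  }
  return best;
}

} // namespace

// Single-query interface. Subjects no longer than `full_limit` (or queries
// shorter than k) skip seeding and run plain SW.
// [[Rcpp::export(name = ".best_local_hit_cpp")]]
List best_local_hit_cpp(IntegerVector q, IntegerVector s, NumericMatrix submat,
                        double gap_open, double gap_ext, int ambig,
                        int k, int band, int max_bins, int min_votes,
                        int full_limit) {
  const int n = q.size(), m = s.size();
  if (m <= full_limit || n < k) {
    return sw_to_list(sw_core(INTEGER(q), n, INTEGER(s), m, submat,
                              gap_open, gap_ext, ambig));
  }
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  KmerIndex index = build_kmer_index(INTEGER(s), m, k, mask);
  return sw_to_list(seeded_best_hit(INTEGER(q), n, INTEGER(s), m, index,
                                    mask, submat, gap_open, gap_ext, ambig,
                                    k, band, max_bins, min_votes));
}

// Batch interface for ANIb: all fragments of one query genome against one
// subject strand; the subject k-mer index is built once.
// [[Rcpp::export(name = ".best_local_hits_batch_cpp")]]
List best_local_hits_batch_cpp(List queries, IntegerVector s,
                               NumericMatrix submat, double gap_open,
                               double gap_ext, int ambig, int k, int band,
                               int max_bins, int min_votes, int full_limit) {
  const int m = s.size();
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const bool seeded = m > full_limit;
  KmerIndex index;
  if (seeded) index = build_kmer_index(INTEGER(s), m, k, mask);
  List out(queries.size());
  for (int qi = 0; qi < queries.size(); ++qi) {
    IntegerVector q = queries[qi];
    const int n = q.size();
    SwResult r;
    if (!seeded || n < k) {
      r = sw_core(INTEGER(q), n, INTEGER(s), m, submat, gap_open, gap_ext,
                  ambig);
    } else {
      r = seeded_best_hit(INTEGER(q), n, INTEGER(s), m, index, mask, submat,
                          gap_open, gap_ext, ambig, k, band, max_bins,
                          min_votes);
    }
    out[qi] = sw_to_list(r);
  }
  return out;
}
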