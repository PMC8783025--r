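// Seed-and-extend affine-gap local alignment for intrinsic-barcode
// demultiplexing of long RNA reads, plus a full Smith-Waterman oracle.
//
// Conventions: scores are raw alignment scores (match reward positive,
// mismatch penalty negative, a gap of length k costs open + k * extend).
// All reported intervals are 1-based inclusive. Only the forward strand is
// scored (dRNA-seq is strand-specific).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const int NEG = -1000000000;

struct Hit {
  int score;
  int qs, qe, rs, re; // 1-based inclusive
};

struct Params {
  int match, mismatch, gap_open, gap_extend;
  int word, band, min_score;
  int small_cutoff;   // n*m at or below which all seed diagonals are kept
  double rel_frac;    // relative seed-count threshold for large problems
};

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// tie-break: higher score, then lower reference start, then lower query start
static inline bool better(int sc, int rs, int qs, int bsc, int brs, int bqs) {
  if (sc != bsc) return sc > bsc;
  if (rs != brs) return rs < brs;
  return qs < bqs;
}

// three-state cell: score plus the (qs, rs) where the local alignment began
struct Cell { int v, qs, rs; };

static inline Cell cmax(const Cell& a, const Cell& b) {
  if (a.v != b.v) return a.v > b.v ? a : b;
  if (a.rs != b.rs) return a.rs < b.rs ? a : b;
  return a.qs <= b.qs ? a : b;
}

// Affine-gap Smith-Waterman restricted to diagonals d = j - i in [dlo, dhi].
// With dlo = -(n) and dhi = m this is the full DP (used by the oracle path
// through a separately written function below, kept independent).
static Hit sw_banded(const std::vector<int>& q, const std::vector<int>& r,
                     int dlo, int dhi, const Params& p) {
  const int n = (int)q.size(), m = (int)r.size();
  const int oe = p.gap_open + p.gap_extend, e = p.gap_extend;
  const Cell none{NEG, 0, 0};

  std::vector<Cell> Mp(m + 2, none), Xp(m + 2, none), Yp(m + 2, none);
  std::vector<Cell> Mc(m + 2, none), Xc(m + 2, none), Yc(m + 2, none);

  Hit best{0, 0, 0, 0, 0};
  int bqs = 1 << 30, brs = 1 << 30;

  int i0 = std::max(1, 1 - dhi), i1 = std::min(n, m - dlo);
  for (int i = i0; i <= i1; ++i) {
    int a = std::max(1, i + dlo), b = std::min(m, i + dhi);
    if (a > b) continue;
    Mc[a - 1] = Xc[a - 1] = Yc[a - 1] = none; // left edge outside band
    for (int j = a; j <= b; ++j) {
      int s = (q[i - 1] >= 0 && q[i - 1] == r[j - 1]) ? p.match : p.mismatch;

      // gap in reference (consumes query char), extends down a column
      Cell X = none;
      if (Mp[j].v > NEG) X = Cell{Mp[j].v - oe, Mp[j].qs, Mp[j].rs};
      if (Xp[j].v > NEG) X = cmax(X, Cell{Xp[j].v - e, Xp[j].qs, Xp[j].rs});

      // gap in query (consumes reference char), extends along the row
      Cell Y = none;
      if (Mc[j - 1].v > NEG) Y = Cell{Mc[j - 1].v - oe, Mc[j - 1].qs, Mc[j - 1].rs};
      if (Yc[j - 1].v > NEG) Y = cmax(Y, Cell{Yc[j - 1].v - e, Yc[j - 1].qs, Yc[j - 1].rs});

      Cell D = cmax(cmax(Mp[j - 1], Xp[j - 1]), Yp[j - 1]);
      Cell M;
      if (D.v <= 0) M = Cell{s, i, j};      // start a fresh local alignment
      else M = Cell{D.v + s, D.qs, D.rs};

      Mc[j] = M; Xc[j] = X; Yc[j] = Y;

      if (M.v > 0 && better(M.v, M.rs, M.qs, best.score, brs, bqs)) {
        best.score = M.v; best.qs = M.qs; best.rs = M.rs;
        best.qe = i; best.re = j;
        bqs = M.qs; brs = M.rs;
      }
    }
    // the cell entering the band on the next row must not read stale state
    if (b + 1 <= m + 1) { Mc[b + 1] = Xc[b + 1] = Yc[b + 1] = none; }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return best;
}

// ---------------------------------------------------------------------------
// Full Smith-Waterman oracle: straightforward row-major three-state DP,
// written independently of the banded code path above.
// ---------------------------------------------------------------------------
static Hit sw_full(const std::vector<int>& q, const std::vector<int>& r,
                   const Params& p) {
  const int n = (int)q.size(), m = (int)r.size();
  const int oe = p.gap_open + p.gap_extend, e = p.gap_extend;
  const Cell none{NEG, 0, 0};

  std::vector<Cell> Mp(m + 1, none), Xp(m + 1, none), Yp(m + 1, none);
  std::vector<Cell> Mc(m + 1, none), Xc(m + 1, none), Yc(m + 1, none);

  Hit best{0, 0, 0, 0, 0};
  int bqs = 1 << 30, brs = 1 << 30;

  for (int i = 1; i <= n; ++i) {
    Mc[0] = Xc[0] = Yc[0] = none;
    for (int j = 1; j <= m; ++j) {
      int s = (q[i - 1] >= 0 && q[i - 1] == r[j - 1]) ? p.match : p.mismatch;

      Cell X = none;
      if (Mp[j].v > NEG) X = Cell{Mp[j].v - oe, Mp[j].qs, Mp[j].rs};
      if (Xp[j].v > NEG) X = cmax(X, Cell{Xp[j].v - e, Xp[j].qs, Xp[j].rs});

      Cell Y = none;
      if (Mc[j - 1].v > NEG) Y = Cell{Mc[j - 1].v - oe, Mc[j - 1].qs, Mc[j - 1].rs};
      if (Yc[j - 1].v > NEG) Y = cmax(Y, Cell{Yc[j - 1].v - e, Yc[j - 1].qs, Yc[j - 1].rs});

      Cell D = cmax(cmax(Mp[j - 1], Xp[j - 1]), Yp[j - 1]);
      Cell M;
      if (D.v <= 0) M = Cell{s, i, j};
      else M = Cell{D.v + s, D.qs, D.rs};

      Mc[j] = M; Xc[j] = X; Yc[j] = Y;

      if (M.v > 0 && better(M.v, M.rs, M.qs, best.score, brs, bqs)) {
        best.score = M.v; best.qs = M.qs; best.rs = M.rs;
        best.qe = i; best.re = j;
        bqs = M.qs; brs = M.rs;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return best;
}

// exact word seeds -> diagonal counts -> kept diagonals -> clustered bands
static std::vector<std::pair<int,int>> seed_bands(const std::vector<int>& q,
                                                  const std::vector<int>& r,
                                                  const Params& p) {
  const int n = (int)q.size(), m = (int)r.size(), w = p.word;
  std::vector<std::pair<int,int>> bands;
  if (n < w || m < w) return bands;

  uint32_t mask = (w >= 16) ? 0xFFFFFFFFu : ((1u << (2 * w)) - 1u);
  std::vector<std::vector<int>> idx(mask + 1);
  {
    uint32_t h = 0; int run = 0;
    for (int j = 0; j < m; ++j) {
      int c = r[j];
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & mask; ++run;
      if (run >= w) idx[h].push_back(j - w + 1);
    }
  }

  std::vector<int> diag_count(n + m + 1, 0); // diagonal d = j - i, offset by n
  {
    uint32_t h = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = q[i];
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & mask; ++run;
      if (run >= w) {
        int qpos = i - w + 1;
        for (int rpos : idx[h]) ++diag_count[(rpos - qpos) + n];
      }
    }
  }

  int maxc = 0;
  for (int c : diag_count) maxc = std::max(maxc, c);
  if (maxc == 0) return bands;

  // small problems: extend every seed; large: demand corroborated diagonals
  int thr;
  if ((long long)n * m <= p.small_cutoff) thr = 1;
  else thr = std::max(2, (int)std::ceil(p.rel_frac * maxc));

  std::vector<int> kept;
  for (int d = 0; d < (int)diag_count.size(); ++d)
    if (diag_count[d] >= thr) kept.push_back(d - n);
  if (kept.empty()) return bands;

  int lo = kept[0], hi = kept[0];
  for (size_t k = 1; k < kept.size(); ++k) {
    if (kept[k] - hi <= p.band) hi = kept[k];
    else { bands.push_back({lo - p.band, hi + p.band}); lo = hi = kept[k]; }
  }
  bands.push_back({lo - p.band, hi + p.band});
  return bands;
}

static std::vector<Hit> seeded_hits(const std::vector<int>& q,
                                    const std::vector<int>& r,
                                    const Params& p) {
  std::vector<Hit> hits;
  for (auto& bd : seed_bands(q, r, p)) {
    Hit h = sw_banded(q, r, bd.first, bd.second, p);
    if (h.score >= p.min_score && h.score > 0) hits.push_back(h);
  }
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.rs != b.rs) return a.rs < b.rs;
    return a.qs < b.qs;
  });
  std::vector<Hit> out;
  for (auto& h : hits) {
    bool dup = false;
    for (auto& o : out)
      if (o.qs == h.qs && o.qe == h.qe && o.rs == h.rs && o.re == h.re) { dup = true; break; }
    if (!dup) out.push_back(h);
  }
  return out;
}

static Params make_params(int match, int mismatch, int gap_open, int gap_extend,
                          int word, int band, int min_score, int small_cutoff,
                          double rel_frac) {
  Params p;
  p.match = match; p.mismatch = mismatch; p.gap_open = gap_open;
  p.gap_extend = gap_extend; p.word = word; p.band = band;
  p.min_score = min_score; p.small_cutoff = small_cutoff; p.rel_frac = rel_frac;
  return p;
}

// [[Rcpp::export]]
List cpp_local_align(std::string query, std::string reference, int match,
                     int mismatch, int gap_open, int gap_extend) {
  Params p = make_params(match, mismatch, gap_open, gap_extend, 4, 16, 0, 0, 0.05);
  std::vector<int> q = encode(query), r = encode(reference);
  Hit h = sw_full(q, r, p);
  return List::create(_["score"] = h.score, _["qs"] = h.qs, _["qe"] = h.qe,
                      _["rs"] = h.rs, _["re"] = h.re);
}

// [[Rcpp::export]]
DataFrame cpp_seeded_align(std::string query, std::string reference, int match,
                           int mismatch, int gap_open, int gap_extend, int word,
                           int band, int min_score, int small_cutoff,
                           double rel_frac) {
  Params p = make_params(match, mismatch, gap_open, gap_extend, word, band,
                         min_score, small_cutoff, rel_frac);
  std::vector<int> q = encode(query), r = encode(reference);
  std::vector<Hit> hits = seeded_hits(q, r, p);
  int nh = (int)hits.size();
  IntegerVector sc(nh), qs(nh), qe(nh), rs(nh), re(nh);
  for (int i = 0; i < nh; ++i) {
    sc[i] = hits[i].score; qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    rs[i] = hits[i].rs; re[i] = hits[i].re;
  }
  return DataFrame::create(_["score"] = sc, _["qs"] = qs, _["qe"] = qe,
                           _["rs"] = rs, _["re"] = re);
}

// Pooled demultiplexing: a long-word diagonal screen shortlists candidate
// designs, then each candidate is scored with the seeded banded aligner.
// Reads with no hit >= min_score are unassigned; two designs sharing the top
// score make the read a tie.
// [[Rcpp::export]]
DataFrame cpp_demux(CharacterVector reads, CharacterVector refs, int match,
                    int mismatch, int gap_open, int gap_extend, int word,
                    int band, int min_score, int small_cutoff, double rel_frac,
                    int shortlist_word, int shortlist_k) {
  int nr = reads.size(), nd = refs.size();
  Params p = make_params(match, mismatch, gap_open, gap_extend, word, band,
                         min_score, small_cutoff, rel_frac);

  std::vector<std::vector<int>> R(nd);
  for (int d = 0; d < nd; ++d) R[d] = encode(std::string(refs[d]));

  const int sw = shortlist_word;
  const uint64_t smask = (sw >= 32) ? ~0ULL : ((1ULL << (2 * sw)) - 1ULL);
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> sidx;
  for (int d = 0; d < nd; ++d) {
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < (int)R[d].size(); ++j) {
      int c = R[d][j];
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & smask; ++run;
      if (run >= sw) sidx[h].push_back({d, j - sw + 1});
    }
  }

  IntegerVector best_idx(nr), best_score(nr), rs(nr), re(nr), qs(nr), qe(nr);
  LogicalVector tie(nr);

  const int DBIN = 8; // diagonal bin width for the screen
  std::vector<std::unordered_map<int,int>> bins(nd);
  std::vector<int> touched;

  for (int k = 0; k < nr; ++k) {
    std::vector<int> q = encode(std::string(reads[k]));
    int n = (int)q.size();

    for (int d : touched) bins[d].clear();
    touched.clear();
    std::vector<int> screen(nd, 0);
    {
      uint64_t h = 0; int run = 0;
      for (int i = 0; i < n; ++i) {
        int c = q[i];
        if (c < 0) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t)c) & smask; ++run;
        if (run >= sw) {
          auto it = sidx.find(h);
          if (it == sidx.end()) continue;
          int qpos = i - sw + 1;
          for (auto& pr : it->second) {
            int d = pr.first, diag = (pr.second - qpos) / DBIN;
            if (bins[d].empty()) touched.push_back(d);
            int v = ++bins[d][diag];
            if (v > screen[d]) screen[d] = v;
          }
        }
      }
    }

    std::vector<int> cand;
    int smax = 0;
    for (int d = 0; d < nd; ++d) smax = std::max(smax, screen[d]);
    if (smax > 0) {
      std::vector<std::pair<int,int>> ranked;
      for (int d = 0; d < nd; ++d)
        if (screen[d] > 0) ranked.push_back({-screen[d], d});
      std::sort(ranked.begin(), ranked.end());
      for (auto& pr : ranked) {
        // keep the top K plus everything tied with the screen maximum
        if ((int)cand.size() < shortlist_k || -pr.first == smax)
          cand.push_back(pr.second);
        else break;
      }
    } else {
      for (int d = 0; d < nd; ++d) cand.push_back(d); // no screen signal
    }

    int b1 = NEG, b2 = NEG, bd = -1;
    Hit bh{0,0,0,0,0};
    for (int d : cand) {
      std::vector<Hit> hs = seeded_hits(q, R[d], p);
      if (hs.empty()) continue;
      int sc = hs[0].score;
      if (sc > b1) { b2 = b1; b1 = sc; bd = d; bh = hs[0]; }
      else if (sc == b1 && d != bd) { b2 = sc; }
      else if (sc > b2) { b2 = sc; }
    }

    if (bd < 0 || b1 < min_score) {
      best_idx[k] = NA_INTEGER;
      best_score[k] = (bd < 0) ? NA_INTEGER : b1;
      tie[k] = false;
      rs[k] = re[k] = qs[k] = qe[k] = NA_INTEGER;
    } else if (b2 == b1) {
      best_idx[k] = NA_INTEGER; best_score[k] = b1; tie[k] = true;
      rs[k] = re[k] = qs[k] = qe[k] = NA_INTEGER;
    } else {
      best_idx[k] = bd + 1; best_score[k] = b1; tie[k] = false;
      rs[k] = bh.rs; re[k] = bh.re; qs[k] = bh.qs; qe[k] = bh.qe;
    }
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return DataFrame::create(_["design_index"] = best_idx, _["score"] = best_score,
                           _["tie"] = tie, _["rs"] = rs, _["re"] = re,
                           _["qs"] = qs, _["qe"] = qe);
}
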